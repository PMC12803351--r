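# Reading genome annotation feature tables.

#' Construct a genome annotation object
#'
#' A lightweight container for one genome's protein-coding features: a
#' `features` data frame with columns `genome_id`, `feature_id`, `product`,
#' `gene_name`, `protein_id`. Entries sharing a `protein_id` are collapsed to
#' one feature (deduplication key: `protein_id` when present, otherwise
#' `(genome_id, feature_id)`).
#'
#' @param genome_id Non-empty genome identifier.
#' @param features Data frame with at least a `product` column; missing
#'   `feature_id`/`gene_name`/`protein_id` columns are filled with `NA`.
#' @param species,phylum,genus Optional taxonomy labels.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, features = NULL,
                              species = NA_character_,
                              phylum = NA_character_,
                              genus = NA_character_) {
  .assert(.is_string(genome_id) && nzchar(genome_id),
          "genome_id must be a non-empty string")
  if (is.null(features)) {
    features <- data.frame(genome_id = character(), feature_id = character(),
                           product = character(), gene_name = character(),
                           protein_id = character(),
                           stringsAsFactors = FALSE)
  }
  .assert(is.data.frame(features), "features must be a data frame")
  .assert("product" %in% names(features),
          "features must contain a 'product' column")
  n <- nrow(features)
  out <- data.frame(
    genome_id = rep(genome_id, n),
    feature_id = if ("feature_id" %in% names(features))
      as.character(features$feature_id) else sprintf("feat_%06d", seq_len(n)),
    product = ifelse(is.na(features$product), "",
                     as.character(features$product)),
    gene_name = if ("gene_name" %in% names(features))
      as.character(features$gene_name) else rep(NA_character_, n),
    protein_id = if ("protein_id" %in% names(features))
      as.character(features$protein_id) else rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  out <- .dedupe_features(out)
  structure(
    list(genome_id = genome_id, species = species, phylum = phylum,
         genus = genus, features = out),
    class = "genome_annotation"
  )
}

# Collapse duplicate protein ids (first occurrence wins); features without a
# protein_id are keyed by (genome_id, feature_id).
.dedupe_features <- function(feat) {
  if (nrow(feat) == 0L) return(feat)
  key <- ifelse(!is.na(feat$protein_id) & nzchar(feat$protein_id),
                paste0("p:", feat$protein_id),
                paste0("f:", feat$genome_id, ":", feat$feature_id))
  feat <- feat[!duplicated(key), , drop = FALSE]
  rownames(feat) <- NULL
  feat
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d features\n",
              x$genome_id, nrow(x$features)))
  invisible(x)
}

#' Parse a genome annotation file
#'
#' Reads protein-coding features and their `product` strings from a GenBank
#' flat file, a GFF3 file (CDS features with a `product=` attribute; parsed
#' with \pkg{rtracklayer}) or a tab-separated table with columns `genome_id`,
#' `protein_id`, `product` (optionally `gene_name`, `feature_id`). Duplicate
#' `protein_id` entries are collapsed to a single feature.
#'
#' @param path Path to the annotation file.
#' @param format One of `"gff3"`, `"genbank"`, `"tsv"`.
#' @param genome_id Genome identifier; defaults to the file name without
#'   extension (for TSV, the mandatory `genome_id` column is used and must
#'   be constant — use [read_annotation_table()] for multi-genome tables).
#' @param species,phylum,genus Optional taxonomy labels attached to the result.
#' @return A [genome_annotation()] object.
#' @export
parse_annotation <- function(path, format = c("gff3", "genbank", "tsv"),
                             genome_id = NULL,
                             species = NA_character_, phylum = NA_character_,
                             genus = NA_character_) {
  format <- match.arg(format)
  .assert(file.exists(path), "annotation file not found: %s", path)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[A-Za-z0-9.]+$", "", basename(path))
  }
  feat <- switch(format,
    gff3 = .parse_gff3(path),
    genbank = .parse_genbank(path),
    tsv = {
      tab <- .read_annotation_tsv(path)
      ids <- unique(tab$genome_id)
      .assert(length(ids) <= 1L,
              "TSV %s contains %d genome ids; use read_annotation_table()",
              path, length(ids))
      if (length(ids) == 1L) genome_id <- ids
      tab
    })
  genome_annotation(genome_id, feat, species = species, phylum = phylum,
                    genus = genus)
}

.parse_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   stop(sprintf("failed to parse GFF3 file %s: %s",
                                path, conditionMessage(e)), call. = FALSE)
                 })
  df <- as.data.frame(gr)
  if (nrow(df) > 0L && "type" %in% names(df)) {
    df <- df[as.character(df$type) == "CDS", , drop = FALSE]
  }
  get_col <- function(nm) {
    if (nm %in% names(df)) as.character(df[[nm]]) else
      rep(NA_character_, nrow(df))
  }
  data.frame(
    feature_id = {
      id <- get_col("ID")
      ifelse(is.na(id), sprintf("cds_%06d", seq_len(nrow(df))), id)
    },
    product = {
      p <- get_col("product")
      ifelse(is.na(p), "", p)
    },
    gene_name = get_col("gene"),
    protein_id = get_col("protein_id"),
    stringsAsFactors = FALSE
  )
}

# Minimal GenBank flat-file parser: walks the FEATURES table collecting CDS
# features and their /product, /protein_id, /gene and /locus_tag qualifiers.
# Qualifier values may continue across lines; continuations are joined with a
# space. Only feature-table structure is interpreted, never sequence.
.parse_genbank <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) {
                      stop(sprintf("unreadable GenBank file %s: %s", path,
                                   conditionMessage(e)), call. = FALSE)
                    })
  in_features <- FALSE
  feats <- list()
  cur <- NULL
  cur_qual <- NULL
  flush_feature <- function() {
    if (!is.null(cur) && identical(cur$key, "CDS")) {
      feats[[length(feats) + 1L]] <<- cur
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^FEATURES", ln)) { in_features <- TRUE; next }
    if (in_features && grepl("^(ORIGIN|CONTIG|BASE COUNT|//)", ln)) {
      in_features <- FALSE
      next
    }
    if (!in_features) next
    if (grepl("^ {5}\\S", ln)) {              # new feature
      flush_feature()
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      cur <- list(key = key, quals = list())
      cur_qual <- NULL
    } else if (grepl("^ {21}/", ln)) {        # new qualifier
      if (is.null(cur)) {
        stop(sprintf("malformed GenBank feature table at line %d of %s",
                     i, path), call. = FALSE)
      }
      body <- sub("^ {21}/", "", ln)
      if (grepl("=", body, fixed = TRUE)) {
        qname <- sub("=.*$", "", body)
        qval <- sub("^[^=]*=", "", body)
        qval <- gsub("^\"|\"$", "", qval)
      } else {
        qname <- body
        qval <- ""
      }
      cur$quals[[qname]] <- qval
      cur_qual <- qname
    } else if (grepl("^ {21}\\S", ln) && !is.null(cur_qual)) {
      # continuation of the previous qualifier value
      more <- gsub("^\\s+|\"$", "", ln)
      cur$quals[[cur_qual]] <- paste(cur$quals[[cur_qual]], more)
    }
  }
  flush_feature()
  n <- length(feats)
  q <- function(f, nm, default = NA_character_) {
    v <- f$quals[[nm]]
    if (is.null(v)) default else v
  }
  data.frame(
    feature_id = vapply(seq_len(n), function(j) {
      lt <- q(feats[[j]], "locus_tag")
      if (is.na(lt)) sprintf("cds_%06d", j) else lt
    }, character(1)),
    product = vapply(feats, function(f) q(f, "product", ""), character(1)),
    gene_name = vapply(feats, function(f) q(f, "gene"), character(1)),
    protein_id = vapply(feats, function(f) q(f, "protein_id"), character(1)),
    stringsAsFactors = FALSE
  )
}

.read_annotation_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) {
      stop(sprintf("unreadable annotation TSV %s: %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  miss <- setdiff(c("genome_id", "protein_id", "product"), names(tab))
  .assert(length(miss) == 0L,
          "annotation TSV %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  tab
}

#' Read a multi-genome annotation table
#'
#' Reads a tab-separated table with columns `genome_id`, `protein_id`,
#' `product` (optionally `gene_name`, `genus`, `species`, `phylum`) and splits
#' it into one [genome_annotation()] per genome.
#'
#' @param path Path to the TSV file.
#' @return Named list of `genome_annotation` objects.
#' @export
read_annotation_table <- function(path) {
  tab <- .read_annotation_tsv(path)
  ids <- unique(tab$genome_id)
  out <- lapply(ids, function(g) {
    sub <- tab[tab$genome_id == g, , drop = FALSE]
    meta <- function(nm) {
      if (nm %in% names(sub)) as.character(sub[[nm]][1]) else NA_character_
    }
    genome_annotation(g, sub, species = meta("species"),
                      phylum = meta("phylum"), genus = meta("genus"))
  })
  names(out) <- ids
  out
}

#' Write annotations to a multi-genome TSV
#'
#' Inverse of [read_annotation_table()]: one row per feature with the genome's
#' taxonomy labels repeated.
#'
#' @param annotations List of [genome_annotation()] objects.
#' @param path Output file path.
#' @return Invisibly, the written data frame.
#' @export
write_annotation_tsv <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    f <- a$features
    if (nrow(f) == 0L) return(NULL)
    f$genus <- a$genus
    f$species <- a$species
    f$phylum <- a$phylum
    f
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(genome_id = character(), feature_id = character(),
                      product = character(), gene_name = character(),
                      protein_id = character(), genus = character(),
                      species = character(), phylum = character())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
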