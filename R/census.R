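# Keyword census of sugar transporters and glycolytic enzymes.

#' Count sugar transporters in one genome by keyword rules
#'
#' A feature contributes to a subtype (ABC, PTS, MFS) only if its product
#' contains every gate term (default "sugar" and "transporter",
#' case-insensitive) and at least one subtype token. Each feature increments a
#' subtype at most once by default; a product matching tokens of two subtypes
#' increments both. The total is the sum of the three subtype counts.
#'
#' @param annotation A [genome_annotation()] object.
#' @param rules A [keyword_ruleset()].
#' @param per_occurrence If `TRUE`, count every token occurrence within a
#'   product instead of at most one increment per feature per subtype.
#' @return One-row data frame with columns `genome_id`, `abc`, `pts`, `mfs`,
#'   `total`.
#' @examples
#' ann <- genome_annotation("g1",
#'   data.frame(product = c("sugar ABC transporter permease",
#'                          "MFS sugar transporter")))
#' census_transporters(ann)
#' @export
census_transporters <- function(annotation, rules = keyword_ruleset(),
                                per_occurrence = FALSE) {
  .assert(inherits(annotation, "genome_annotation"),
          "annotation must be a genome_annotation")
  .assert(inherits(rules, "keyword_ruleset"), "rules must be a keyword_ruleset")
  products <- annotation$features$product
  counts <- c(ABC = 0L, PTS = 0L, MFS = 0L)
  if (length(products) > 0L) {
    gate <- .gate_pass(products, rules$gate_terms)
    gated <- products[gate]
    for (cat in names(counts)) {
      tokens <- rules$subtype_tokens[[cat]]
      if (length(gated) == 0L) next
      if (per_occurrence) {
        counts[cat] <- sum(vapply(gated, function(p) {
          sum(vapply(tokens, .term_count, integer(1), text = p))
        }, integer(1)))
      } else {
        hit <- vapply(gated, function(p) {
          any(vapply(tokens, .term_matches, logical(1), text = p,
                     abbrev_boundary = TRUE))
        }, logical(1))
        counts[cat] <- sum(hit)
      }
    }
  }
  data.frame(genome_id = annotation$genome_id,
             abc = as.integer(counts["ABC"]),
             pts = as.integer(counts["PTS"]),
             mfs = as.integer(counts["MFS"]),
             total = as.integer(sum(counts)),
             stringsAsFactors = FALSE)
}

#' Census a collection of genomes
#'
#' Applies [census_transporters()] to each annotation and binds the results,
#' carrying genus/species/phylum labels when present.
#'
#' @inheritParams census_transporters
#' @param annotations List of [genome_annotation()] objects.
#' @return Data frame with one row per genome: `genome_id`, `genus`,
#'   `species`, `phylum`, `abc`, `pts`, `mfs`, `total`.
#' @export
census_table <- function(annotations, rules = keyword_ruleset(),
                         per_occurrence = FALSE) {
  rows <- lapply(annotations, function(a) {
    cen <- census_transporters(a, rules, per_occurrence)
    cen$genus <- a$genus
    cen$species <- a$species
    cen$phylum <- a$phylum
    cen
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(genome_id = character(), abc = integer(),
                      pts = integer(), mfs = integer(), total = integer(),
                      genus = character(), species = character(),
                      phylum = character())
  }
  rownames(out) <- NULL
  out[, c("genome_id", "genus", "species", "phylum",
          "abc", "pts", "mfs", "total")]
}

#' Screen a genome for glycolytic enzymes
#'
#' An enzyme is called present (1) when any feature product or gene name
#' matches any of its configured search terms, case-insensitively.
#'
#' @inheritParams census_transporters
#' @return Named integer vector (0/1) over the configured enzyme symbols.
#' @export
screen_enzymes <- function(annotation, rules = keyword_ruleset()) {
  .assert(inherits(annotation, "genome_annotation"),
          "annotation must be a genome_annotation")
  .assert(inherits(rules, "keyword_ruleset"), "rules must be a keyword_ruleset")
  feats <- annotation$features
  texts <- c(feats$product, feats$gene_name[!is.na(feats$gene_name)])
  texts <- tolower(texts)
  vapply(rules$enzyme_terms, function(terms) {
    if (length(texts) == 0L) return(0L)
    hit <- any(vapply(terms, function(tm) {
      any(grepl(tolower(tm), texts, fixed = TRUE))
    }, logical(1)))
    as.integer(hit)
  }, integer(1))
}

#' Call glycolytic pathway completeness
#'
#' A pathway is complete (1) iff every required enzyme is present.
#'
#' @param presence Named 0/1 vector as returned by [screen_enzymes()].
#' @param definition Character vector of required enzyme symbols, e.g. one
#'   element of [pathway_definitions()].
#' @return 0 or 1.
#' @export
pathway_complete <- function(presence, definition) {
  .assert(length(definition) >= 1L, "pathway definition must be non-empty")
  miss <- setdiff(definition, names(presence))
  .assert(length(miss) == 0L,
          "required enzyme(s) absent from presence mapping: %s",
          paste(miss, collapse = ", "))
  as.integer(all(presence[definition] == 1L))
}

#' Pathway completeness table for a genome collection
#'
#' @param annotations List of [genome_annotation()] objects.
#' @param rules A [keyword_ruleset()].
#' @param definitions Named list of pathway definitions
#'   (default [pathway_definitions()]).
#' @return Data frame with `genome_id` and one 0/1 column per pathway.
#' @export
pathway_table <- function(annotations, rules = keyword_ruleset(),
                          definitions = pathway_definitions()) {
  rows <- lapply(annotations, function(a) {
    pres <- screen_enzymes(a, rules)
    vals <- vapply(definitions, function(d) pathway_complete(pres, d),
                   integer(1))
    cbind(data.frame(genome_id = a$genome_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select top species per phylum and subsample their genomes
#'
#' Per phylum, the `top_k` species with the most genomes are kept (ties broken
#' by descending genome count, then lexicographic species name); per selected
#' species, at most `per_species_cap` genomes are drawn without replacement
#' under the seed.
#'
#' @param genomes Data frame with columns `genome_id`, `species`, `phylum`.
#' @param top_k Species kept per phylum (default 20).
#' @param per_species_cap Maximum genomes sampled per species (default 20).
#' @param seed Integer seed controlling the subsampling.
#' @return Data frame of selected rows of `genomes` (stable order: phylum,
#'   species rank, genome id).
#' @export
select_species <- function(genomes, top_k = 20L, per_species_cap = 20L,
                           seed = 1L) {
  .assert(is.data.frame(genomes) &&
            all(c("genome_id", "species", "phylum") %in% names(genomes)),
          "genomes must have columns genome_id, species, phylum")
  phyla <- unique(genomes$phylum)
  picks <- list()
  for (ph in sort(phyla)) {
    sub <- genomes[genomes$phylum == ph, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("phylum %s has no species; skipping", ph))
      next
    }
    tab <- as.data.frame(table(species = sub$species),
                         stringsAsFactors = FALSE)
    tab <- tab[order(-tab$Freq, tab$species), , drop = FALSE]
    keep_sp <- utils::head(tab$species, top_k)
    for (k in seq_along(keep_sp)) {
      sp <- keep_sp[k]
      rows <- sub[sub$species == sp, , drop = FALSE]
      rows <- rows[order(rows$genome_id), , drop = FALSE]
      m <- min(per_species_cap, nrow(rows))
      idx <- with_seed(derive_seed(seed, match(sp, sort(unique(genomes$species)))),
                       sample.int(nrow(rows), m))
      picks[[length(picks) + 1L]] <- rows[sort(idx), , drop = FALSE]
    }
  }
  out <- do.call(rbind, picks)
  if (is.null(out)) out <- genomes[0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genus-level mean transporter census with subsampling
#'
#' Per genus, at most `cap` genomes are subsampled without replacement under
#' the seed, and the arithmetic mean of each subtype count (and the total) is
#' reported along with the number of genomes used.
#'
#' @param censuses Data frame as from [census_table()]; must carry a `genus`
#'   column and counts `abc`, `pts`, `mfs`, `total`.
#' @param cap Maximum genomes per genus (default 100).
#' @param seed Integer seed for the subsampling.
#' @return Data frame with columns `genus`, `n_genomes_used`, `mean_abc`,
#'   `mean_pts`, `mean_mfs`, `mean_total`, ordered by genus. The subsampled
#'   genome ids are attached as attribute `"subsample"` (named list).
#' @export
genus_mean_census <- function(censuses, cap = 100L, seed = 1L) {
  .assert(is.data.frame(censuses) &&
            all(c("genus", "abc", "pts", "mfs", "total") %in% names(censuses)),
          "censuses must have columns genus, abc, pts, mfs, total")
  cen <- censuses[!is.na(censuses$genus) & nzchar(censuses$genus), ,
                  drop = FALSE]
  dropped <- setdiff(unique(censuses$genus), unique(cen$genus))
  if (nrow(cen) < nrow(censuses)) {
    message(sprintf("excluded %d genome(s) without a genus label",
                    nrow(censuses) - nrow(cen)))
  }
  genera <- sort(unique(cen$genus))
  subsample <- list()
  rows <- lapply(seq_along(genera), function(i) {
    g <- genera[i]
    sub <- cen[cen$genus == g, , drop = FALSE]
    sub <- sub[order(sub$genome_id), , drop = FALSE]
    m <- min(cap, nrow(sub))
    idx <- with_seed(derive_seed(seed, i), sample.int(nrow(sub), m))
    sub <- sub[idx, , drop = FALSE]
    subsample[[g]] <<- sub$genome_id
    data.frame(genus = g, n_genomes_used = m,
               mean_abc = mean(sub$abc), mean_pts = mean(sub$pts),
               mean_mfs = mean(sub$mfs), mean_total = mean(sub$total),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(genus = character(), n_genomes_used = integer(),
                      mean_abc = numeric(), mean_pts = numeric(),
                      mean_mfs = numeric(), mean_total = numeric())
  }
  rownames(out) <- NULL
  attr(out, "subsample") <- subsample
  out
}
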