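# Annotation parsing and the transporter/enzyme keyword census.

test_that("TSV annotations parse, with the empty-file and schema cases", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("genome_id\tprotein_id\tproduct", path)
  ann <- parse_annotation(path, "tsv", genome_id = "gEmpty")
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann$features), 0L)

  write.table(data.frame(genome_id = "g1",
                         protein_id = c("p1", "p2", "p2"),
                         product = c("sugar ABC transporter", "x", "x")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- parse_annotation(path, "tsv")
  expect_equal(nrow(ann$features), 2L)   # duplicate protein_id collapsed

  writeLines(c("genome_id\tprotein_id", "g1\tp1"), path)
  expect_error(parse_annotation(path, "tsv"), "missing column")
})

test_that("GFF3 CDS features parse and duplicate protein ids collapse", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_fixture(path)
  ann <- parse_annotation(path, "gff3", genome_id = "gGff")
  expect_equal(nrow(ann$features), 4L)   # 5 CDS lines, 2 share a protein_id
  expect_true("sugar ABC transporter permease" %in% ann$features$product)
  expect_equal(sum(ann$features$product == "MFS sugar transporter"), 1L)
})

test_that("GenBank flat files parse, including multi-line products", {
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank_fixture(path)
  ann <- parse_annotation(path, "genbank", genome_id = "gGbk")
  expect_equal(nrow(ann$features), 3L)
  expect_setequal(ann$features$product,
                  c("sugar ABC transporter permease",
                    "PTS sugar transporter subunit IIA",
                    "hypothetical protein"))
  expect_equal(ann$features$gene_name[ann$features$product ==
                                        "PTS sugar transporter subunit IIA"],
               "ptsG")
})

test_that("census applies the gate-then-subtype rule", {
  one <- function(p) {
    census_transporters(genome_annotation("g", data.frame(product = p)))
  }
  expect_equal(unlist(one("sugar ABC transporter permease")[, 2:5]),
               c(abc = 1L, pts = 0L, mfs = 0L, total = 1L))
  # gate term "sugar" missing: nothing counted
  expect_equal(one("glucose ABC transporter")$total, 0L)

  cen <- census_transporters(six_product_annotation())
  expect_equal(cen$abc, 1L)
  expect_equal(cen$pts, 1L)
  expect_equal(cen$mfs, 1L)
  expect_equal(cen$total, 3L)

  # empty annotation: all-zero census
  cen0 <- census_transporters(genome_annotation("g0"))
  expect_equal(cen0$total, 0L)
})

test_that("census counts per feature by default and per occurrence on request", {
  ann <- genome_annotation("g", data.frame(
    product = "sugar ABC transporter fused to another ABC transporter"))
  expect_equal(census_transporters(ann)$abc, 1L)
  expect_equal(census_transporters(ann, per_occurrence = TRUE)$abc, 2L)
  # a product matching two subtypes increments both
  both <- genome_annotation("g", data.frame(
    product = "sugar transporter, ABC/MFS hybrid"))
  cen <- census_transporters(both)
  expect_equal(cen$abc + cen$mfs, 2L)
  expect_equal(cen$total, 2L)
})

test_that("census invariants: permutation, monotonicity, gate soundness", {
  products <- c(replicate(4, sample(decoy_products(), 1)),
                "sugar ABC transporter", "PTS sugar transporter",
                "MFS sugar transporter")
  base <- genome_annotation("g", data.frame(product = products))
  cen <- census_transporters(base)
  for (i in 1:5) {
    perm <- genome_annotation("g", data.frame(product = sample(products)))
    expect_equal(census_transporters(perm)[, 2:5], cen[, 2:5])
  }
  # appending any feature never decreases a count
  more <- genome_annotation("g", data.frame(
    product = c(products, "sugar ABC transporter permease")))
  cen2 <- census_transporters(more)
  expect_true(all(unlist(cen2[, 2:5]) >= unlist(cen[, 2:5])))
  # removing "sugar" zeroes a product's contribution
  gateless <- genome_annotation("g", data.frame(
    product = sub("sugar ?", "", products)))
  expect_equal(census_transporters(gateless)$total, 0L)
})

test_that("enzyme screen flags configured enzymes from products or genes", {
  rules <- keyword_ruleset()
  ann <- genome_annotation("g", data.frame(
    product = c("glucokinase", "pyruvate kinase I", "elongation factor Tu")))
  pres <- screen_enzymes(ann, rules)
  expect_equal(sum(pres), 2L)
  expect_equal(unname(pres[c("HEX", "PYK")]), c(1L, 1L))
  # empty annotation: all enzymes absent
  expect_true(all(screen_enzymes(genome_annotation("g0"), rules) == 0L))
  # gene_name matches count too
  ann2 <- genome_annotation("g", data.frame(product = "protein of unknown function",
                                            gene_name = "phosphoglucomutase"))
  expect_equal(unname(screen_enzymes(ann2, rules)["PGM"]), 1L)
})

test_that("pathway completeness requires every listed enzyme", {
  pres <- c(HEX = 1L, PFK = 1L, PYK = 1L, G6PD = 1L, PGD = 0L, RPI = 1L,
            PGM = 0L, EDD = 0L, KDGP = 0L)
  defs <- pathway_definitions()
  expect_equal(pathway_complete(pres, defs$EMP), 1L)
  expect_equal(pathway_complete(pres, defs$PPP), 0L)   # PGD missing
  expect_equal(pathway_complete(pres, defs$ED), 0L)
  expect_error(pathway_complete(pres[1:3], defs$PPP), "absent")
})

test_that("species selection caps, tie-breaks deterministically, and is seeded", {
  # fewer species than top_k: everything kept
  g <- data.frame(genome_id = sprintf("g%02d", 1:6),
                  species = rep(c("a", "b", "c"), each = 2),
                  phylum = "P")
  expect_equal(nrow(select_species(g, top_k = 20, per_species_cap = 20)), 6L)

  # 50 genomes, cap 20: exactly 20 distinct ids, identical across reruns
  big <- data.frame(genome_id = sprintf("g%03d", 1:50), species = "s",
                    phylum = "P")
  s1 <- select_species(big, per_species_cap = 20, seed = 5)
  s2 <- select_species(big, per_species_cap = 20, seed = 5)
  expect_equal(nrow(s1), 20L)
  expect_equal(anyDuplicated(s1$genome_id), 0L)
  expect_identical(s1, s2)
  expect_false(identical(select_species(big, per_species_cap = 20, seed = 6),
                         s1))

  # two species tied at the last slot: descending count then lexicographic
  tie <- data.frame(
    genome_id = sprintf("g%02d", 1:25),
    species = rep(c("sp_a", "sp_b", "sp_c", "sp_d", "sp_e"), each = 5),
    phylum = "P")
  sel <- select_species(tie, top_k = 3, per_species_cap = 5, seed = 1)
  expect_setequal(unique(sel$species), c("sp_a", "sp_b", "sp_c"))
})

test_that("genus mean census averages seeded subsamples", {
  # single genome: means equal counts
  cen <- data.frame(genome_id = "g1", genus = "A", abc = 3L, pts = 1L,
                    mfs = 0L, total = 4L)
  out <- genus_mean_census(cen)
  expect_equal(out$mean_abc, 3)
  expect_equal(out$mean_total, 4)
  expect_equal(out$n_genomes_used, 1L)

  # two genomes: arithmetic mean
  cen2 <- data.frame(genome_id = c("g1", "g2"), genus = "A",
                     abc = c(2L, 4L), pts = 0L, mfs = 0L, total = c(2L, 4L))
  expect_equal(genus_mean_census(cen2)$mean_abc, 3)

  # 150 genomes, cap 100: means recomputed over the logged subsample
  set.seed(42)
  cen3 <- data.frame(genome_id = sprintf("g%03d", 1:150), genus = "B",
                     abc = rpois(150, 5), pts = rpois(150, 2),
                     mfs = rpois(150, 1))
  cen3$total <- cen3$abc + cen3$pts + cen3$mfs
  out3 <- genus_mean_census(cen3, cap = 100, seed = 9)
  expect_equal(out3$n_genomes_used, 100L)
  ids <- attr(out3, "subsample")$B
  expect_length(ids, 100L)
  sub <- cen3[cen3$genome_id %in% ids, ]
  expect_equal(out3$mean_abc, mean(sub$abc))
  expect_equal(out3$mean_total, mean(sub$total))
  # invariant: mean_total decomposes into the subtype means
  expect_equal(out3$mean_total, out3$mean_abc + out3$mean_pts + out3$mean_mfs,
               tolerance = 1e-9)

  # cap >= n equals the exact mean over all genomes
  out_all <- genus_mean_census(cen3, cap = 1000, seed = 1)
  expect_equal(out_all$mean_abc, mean(cen3$abc))
  expect_equal(out_all$n_genomes_used, 150L)
})
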