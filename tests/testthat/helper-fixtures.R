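# In-code fixtures shared across test files.

# The six-product census fixture: exactly one matching product per subtype.
six_product_annotation <- function() {
  genome_annotation("fix6", data.frame(product = c(
    "sugar ABC transporter",
    "PTS sugar transporter subunit IIA",
    "MFS sugar transporter",
    "sugar transporter",
    "sugar porter",
    "ABC transporter"
  )))
}

# >= 50 decoy products, none of which may be counted: gate-term-missing,
# token-missing, and lowercase-abbreviation traps.
decoy_products <- function() {
  c(
    sprintf("glucose ABC transporter permease %d", 1:10),       # no "sugar"
    sprintf("amino acid ABC transporter subunit %d", 1:8),      # no "sugar"
    sprintf("sugar porter family protein %d", 1:8),             # no "transporter"
    sprintf("sugar-binding periplasmic protein %d", 1:6),       # no "transporter"
    sprintf("MFS transporter %d", 1:6),                         # no "sugar"
    sprintf("PTS system glucose-specific transporter %d", 1:6), # no "sugar"
    "sugar transporter abcdef domain protein",                  # lowercase abc
    "sugar transporter, mfsX-like protein",                     # lowercase mfs
    "sugar transporter ptsy homolog",                           # lowercase pts
    sprintf("hypothetical protein %d", 1:8)
  )
}

write_gff3_fixture <- function(path) {
  lines <- c(
    "##gff-version 3",
    paste("ctg1\ttest\tCDS\t1\t300\t.\t+\t0",
          "ID=cds1;product=sugar ABC transporter permease;protein_id=WP_001;gene=abcA",
          sep = "\t"),
    paste("ctg1\ttest\tCDS\t301\t600\t.\t+\t0",
          "ID=cds2;product=PTS sugar transporter subunit IIA;protein_id=WP_002",
          sep = "\t"),
    paste("ctg1\ttest\tCDS\t601\t900\t.\t+\t0",
          "ID=cds3;product=MFS sugar transporter;protein_id=WP_003",
          sep = "\t"),
    # duplicate protein_id: must collapse with cds3
    paste("ctg1\ttest\tCDS\t901\t1200\t.\t+\t0",
          "ID=cds4;product=MFS sugar transporter;protein_id=WP_003",
          sep = "\t"),
    paste("ctg1\ttest\tCDS\t1201\t1500\t.\t+\t0",
          "ID=cds5;product=hypothetical protein;protein_id=WP_005",
          sep = "\t")
  )
  writeLines(lines, path)
  path
}

write_genbank_fixture <- function(path) {
  lines <- c(
    "LOCUS       TEST01                  1500 bp    DNA     linear   BCT 01-JAN-2024",
    "DEFINITION  synthetic test genome.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1500",
    '                     /organism="synthetic construct"',
    "     CDS             1..300",
    '                     /locus_tag="T0001"',
    '                     /product="sugar ABC transporter',
    '                     permease"',
    '                     /protein_id="AAA00001.1"',
    "     CDS             301..600",
    '                     /gene="ptsG"',
    '                     /product="PTS sugar transporter subunit IIA"',
    '                     /protein_id="AAA00002.1"',
    "     CDS             601..900",
    '                     /product="hypothetical protein"',
    "ORIGIN",
    "//"
  )
  writeLines(lines, path)
  path
}

# Independent brute-force mutual information over the 2x2 joint table, in
# bits; written as an explicit cell-by-cell sum, separate from the package's
# vectorised path.
brute_force_mi <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in 0:1) {
    for (b in 0:1) {
      nab <- sum(x == a & y == b)
      if (nab > 0) {
        pxy <- nab / n
        px <- sum(x == a) / n
        py <- sum(y == b) / n
        mi <- mi + pxy * log2(pxy / (px * py))
      }
    }
  }
  mi
}

brute_force_entropy <- function(x) {
  p <- c(mean(x == 0), mean(x == 1))
  -sum(p[p > 0] * log2(p[p > 0]))
}
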