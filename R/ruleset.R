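# Keyword rules for the annotation screen.

#' Default glycolytic enzyme search terms
#'
#' Nine enzymes spanning the Embden-Meyerhof-Parnas (EMP), pentose phosphate
#' (PPP) and Entner-Doudoroff (ED) pathways, each with a list of annotation
#' product search terms. Hexokinase carries the usual bacterial alternates
#' ("sugar kinase", "glucokinase", "ROK family kinase") since many genomes
#' lack a feature literally named hexokinase. The list is a configurable
#' default: users with a curated enzyme panel should override it.
#'
#' @return Named list mapping enzyme symbol to a character vector of terms.
#' @export
default_enzyme_terms <- function() {
  list(
    HEX  = c("hexokinase", "sugar kinase", "glucokinase", "ROK family kinase"),
    PFK  = c("6-phosphofructokinase", "phosphofructokinase"),
    PYK  = c("pyruvate kinase"),
    G6PD = c("glucose-6-phosphate dehydrogenase",
             "glucose 6-phosphate 1-dehydrogenase"),
    PGD  = c("6-phosphogluconate dehydrogenase",
             "phosphogluconate dehydrogenase"),
    RPI  = c("ribose-5-phosphate isomerase", "ribose 5-phosphate isomerase"),
    PGM  = c("phosphoglucomutase"),
    EDD  = c("phosphogluconate dehydratase",
             "6-phosphogluconate dehydratase"),
    KDGP = c("2-keto-3-deoxy-6-phosphogluconate aldolase",
             "KDPG aldolase",
             "2-dehydro-3-deoxy-phosphogluconate aldolase",
             "2-dehydro-3-deoxyphosphogluconate aldolase")
  )
}

#' Default glycolytic pathway definitions
#'
#' Each pathway is called complete when three representative enzymes are all
#' present: EMP (hexokinase-equivalent, 6-phosphofructokinase, pyruvate
#' kinase), PPP (glucose-6-phosphate dehydrogenase, 6-phosphogluconate
#' dehydrogenase, ribose-5-phosphate isomerase) and ED
#' (glucose-6-phosphate dehydrogenase, phosphogluconate dehydratase,
#' KDPG aldolase).
#'
#' @return Named list mapping pathway id (EMP, PPP, ED) to a character vector
#'   of required enzyme symbols.
#' @export
pathway_definitions <- function() {
  list(
    EMP = c("HEX", "PFK", "PYK"),
    PPP = c("G6PD", "PGD", "RPI"),
    ED  = c("G6PD", "EDD", "KDGP")
  )
}

#' Construct a keyword ruleset for the transporter/enzyme screen
#'
#' The screen follows a gate-then-subtype rule: a feature product must contain
#' every gate term (case-insensitive substring; default "sugar" and
#' "transporter") before it is classified into transporter subtypes by the
#' subtype tokens. Uppercase abbreviation tokens (e.g. "ABC", "PTS", "MFS")
#' are matched case-sensitively on word boundaries so that e.g. a lowercase
#' "abc" buried inside another word never matches; multi-word expansions
#' ("ATP-binding cassette", "phosphotransferase", "major facilitator") are
#' matched case-insensitively as substrings.
#'
#' @param gate_terms Character vector of required gate terms.
#' @param subtype_tokens Named list with entries `ABC`, `PTS`, `MFS`, each a
#'   non-empty character vector of tokens.
#' @param enzyme_terms Named list of enzyme search terms, as
#'   [default_enzyme_terms()].
#' @return An object of class `keyword_ruleset`.
#' @examples
#' rules <- keyword_ruleset()
#' rules$gate_terms
#' @export
keyword_ruleset <- function(gate_terms = c("sugar", "transporter"),
                            subtype_tokens = list(
                              ABC = c("ABC", "ATP-binding cassette"),
                              PTS = c("PTS", "phosphotransferase"),
                              MFS = c("MFS", "major facilitator")),
                            enzyme_terms = default_enzyme_terms()) {
  .assert(is.character(gate_terms) && length(gate_terms) >= 1L,
          "gate_terms must be a non-empty character vector")
  .assert(is.list(subtype_tokens) &&
            setequal(names(subtype_tokens), c("ABC", "PTS", "MFS")),
          "subtype_tokens must have exactly the categories ABC, PTS, MFS")
  for (nm in names(subtype_tokens)) {
    .assert(is.character(subtype_tokens[[nm]]) &&
              length(subtype_tokens[[nm]]) >= 1L,
            "subtype_tokens$%s must be a non-empty character vector", nm)
  }
  .assert(is.list(enzyme_terms) && length(enzyme_terms) >= 1L &&
            !is.null(names(enzyme_terms)) && all(nzchar(names(enzyme_terms))),
          "enzyme_terms must be a named list of search-term vectors")
  structure(
    list(gate_terms = gate_terms,
         subtype_tokens = subtype_tokens[c("ABC", "PTS", "MFS")],
         enzyme_terms = enzyme_terms),
    class = "keyword_ruleset"
  )
}

# TRUE if `term` occurs in `text`. Abbreviation tokens (all caps/digits) match
# case-sensitively on word boundaries; everything else is a case-insensitive
# substring match.
.term_matches <- function(term, text, abbrev_boundary = FALSE) {
  if (abbrev_boundary && grepl("^[A-Z0-9]+$", term)) {
    grepl(paste0("\\b", term, "\\b"), text)
  } else {
    grepl(tolower(term), tolower(text), fixed = TRUE)
  }
}

# Vectorised over features: TRUE where all gate terms present.
.gate_pass <- function(products, gate_terms) {
  low <- tolower(products)
  pass <- rep(TRUE, length(products))
  for (g in gate_terms) pass <- pass & grepl(tolower(g), low, fixed = TRUE)
  pass
}

# Number of occurrences of token in text (for the per-occurrence mode).
.term_count <- function(term, text) {
  if (grepl("^[A-Z0-9]+$", term)) {
    m <- gregexpr(paste0("\\b", term, "\\b"), text)[[1]]
  } else {
    m <- gregexpr(tolower(term), tolower(text), fixed = TRUE)[[1]]
  }
  if (m[1] == -1L) 0L else length(m)
}
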