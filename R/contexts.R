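# Shared vocabulary: genes, drug contexts, recommendation categories.

PGX_GENES <- c("CYP2D6", "CYP2C19", "CYP2B6", "SLCO1B1")

#' The six harmonized recommendation categories
#'
#' All drug-recommendation output in the package is drawn from this closed
#' vocabulary. "Not determined" marks a diplotype that exists but cannot be
#' scored (uncertain/unknown allele function); "No call" marks a gene for
#' which no diplotype record exists at all.
#'
#' @return Character vector of the six category labels.
#' @export
#' @examples
#' recommendation_categories()
recommendation_categories <- function() {
  c("Use as directed",
    "Adjust dosage",
    "Avoid and/or use alternative medication",
    "Use with caution",
    "Not determined",
    "No call")
}

# metabolizer-style phenotype labels (CYP2D6, CYP2C19, CYP2B6) and
# transporter-function labels (SLCO1B1); Indeterminate is shared
METABOLIZER_LABELS <- c("Ultrarapid", "Rapid", "Normal", "Intermediate", "Poor")
FUNCTION_LABELS <- c("IncreasedFunction", "NormalFunction", "DecreasedFunction",
                     "PossiblyDecreasedFunction", "PoorFunction")

phenotype_vocabulary <- function(gene) {
  if (gene == "SLCO1B1") FUNCTION_LABELS else METABOLIZER_LABELS
}

#' Drug contexts and the genes they depend on
#'
#' Each drug context is a drug (or drug group) with a CPIC-style
#' recommendation rule. The sertraline context depends on two genes
#' (CYP2B6 and CYP2C19, in that order); all other contexts are single-gene.
#'
#' @return Named list mapping context id to an ordered character vector of
#'   gene symbols.
#' @export
#' @examples
#' drug_contexts()$sertraline
drug_contexts <- function() {
  list(
    codeine_tramadol        = "CYP2D6",
    lova_pita_simva         = "SLCO1B1",
    pravastatin             = "SLCO1B1",
    atorvastatin            = "SLCO1B1",
    sertraline              = c("CYP2B6", "CYP2C19"),
    citalopram_escitalopram = "CYP2C19"
  )
}

context_genes <- function(context) {
  ctx <- drug_contexts()
  if (!context %in% names(ctx)) {
    stop("unknown drug context: '", context, "'", call. = FALSE)
  }
  ctx[[context]]
}

#' Harmonize a raw recommendation label into the six-category vocabulary
#'
#' Upstream interpretation tools phrase the same action in different ways;
#' this maps a raw label onto the closed six-category vocabulary via a
#' case- and punctuation-insensitive synonym table. Unknown labels are an
#' error, never a silent pass-through.
#'
#' @param raw Non-empty character scalar, the label as emitted by a tool.
#' @return One of [recommendation_categories()].
#' @export
#' @examples
#' harmonize_label("use as directed")
#' harmonize_label("AVOID")
harmonize_label <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw))) {
    stop("raw label must be a non-empty string", call. = FALSE)
  }
  key <- gsub("[^a-z0-9]+", "", tolower(raw))
  syn <- harmonize_synonyms()
  hit <- syn[[key]]
  if (is.null(hit)) {
    stop("cannot harmonize recommendation label: '", raw, "'", call. = FALSE)
  }
  hit
}

harmonize_synonyms <- function() {
  canon <- recommendation_categories()
  syn <- list()
  norm <- function(x) gsub("[^a-z0-9]+", "", tolower(x))
  for (cat in canon) syn[[norm(cat)]] <- cat
  # common tool phrasings
  extra <- list(
    "avoid"                      = canon[3],
    "usealternativemedication"   = canon[3],
    "alternativemedication"      = canon[3],
    "avoiduse"                   = canon[3],
    "adjustdose"                 = canon[2],
    "dosageadjustment"           = canon[2],
    "doseadjustment"             = canon[2],
    "standarddosing"             = canon[1],
    "normalriskusasdirected"     = canon[1],
    "caution"                    = canon[4],
    "indeterminate"              = canon[5],
    "notdetermined"              = canon[5],
    "nd"                         = canon[5],
    "nocall"                     = canon[6],
    # HLA-style positive/negative semantics: a detected high-risk allele
    # means avoid; no detection means standard use (no "Not determined"
    # exists for those genes)
    "positive"                   = canon[3],
    "negative"                   = canon[1]
  )
  for (k in names(extra)) syn[[k]] <- extra[[k]]
  syn
}
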