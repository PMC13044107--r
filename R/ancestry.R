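# Ancestry-threshold cohort selection.
#
# Input is the per-individual output of an admixture estimator run against
# reference panels (for the Japanese cohort: the 1000 Genomes JPT panel):
# one fraction per panel, summing to 1. The analysis cohort is everyone
# whose focal-panel fraction meets an inclusive threshold; the default
# 0.875 approximates the 1000 Genomes requirement of four grandparents
# born in-country while tolerating minor admixture.

#' Ancestry threshold
#'
#' @param panel Reference-panel label the threshold applies to.
#' @param minimum Inclusive minimum fraction in \[0, 1\].
#' @return List with class `pgx_ancestry_threshold`.
#' @export
#' @examples
#' ancestry_threshold()  # JPT >= 0.875
ancestry_threshold <- function(panel = "JPT", minimum = 0.875) {
  stopifnot(is.character(panel), length(panel) == 1L)
  if (!is.numeric(minimum) || length(minimum) != 1L ||
      minimum < 0 || minimum > 1) {
    stop("minimum must be a fraction in [0, 1]", call. = FALSE)
  }
  structure(list(panel = panel, minimum = minimum),
            class = "pgx_ancestry_threshold")
}

#' Read admixture proportions (wide or long TSV)
#'
#' Two dialects are accepted, matching the shapes admixture estimators
#' emit: wide (`individual_id` plus one numeric column per panel) and long
#' (`individual_id`, `panel`, `fraction`). Both normalize to the wide
#' form. Proportions are validated — each individual's fractions must sum
#' to 1 within 1e-6 — never silently renormalized.
#'
#' @param x A file path or a data frame in either dialect.
#' @return Wide data frame: `individual_id` plus one column per panel.
#' @export
read_admixture <- function(x) {
  df <- if (is.character(x)) utils::read.delim(x, stringsAsFactors = FALSE) else x
  if (!is.data.frame(df) || !"individual_id" %in% names(df)) {
    stop("admixture input needs an 'individual_id' column", call. = FALSE)
  }
  if (all(c("panel", "fraction") %in% names(df))) {
    wide <- stats::reshape(df[c("individual_id", "panel", "fraction")],
                           idvar = "individual_id", timevar = "panel",
                           direction = "wide")
    names(wide) <- sub("^fraction\\.", "", names(wide))
    rownames(wide) <- NULL
    df <- wide
  }
  validate_admixture(df)
}

validate_admixture <- function(profiles) {
  panels <- setdiff(names(profiles), "individual_id")
  if (length(panels) == 0L) stop("no panel columns present", call. = FALSE)
  if (anyDuplicated(profiles$individual_id)) {
    stop("duplicated individual_id in admixture input", call. = FALSE)
  }
  frac <- as.matrix(profiles[panels])
  if (anyNA(frac)) {
    bad <- profiles$individual_id[which(rowSums(is.na(frac)) > 0)[1]]
    stop("individual '", bad, "' is missing a panel fraction", call. = FALSE)
  }
  if (any(frac < 0 | frac > 1)) {
    stop("admixture fractions must lie in [0, 1]", call. = FALSE)
  }
  sums <- rowSums(frac)
  off <- abs(sums - 1) > 1e-6
  if (any(off)) {
    stop("admixture fractions for individual '",
         profiles$individual_id[which(off)[1]],
         "' sum to ", format(sums[which(off)[1]], digits = 10),
         ", not 1 (profiles are validated, never renormalized)",
         call. = FALSE)
  }
  profiles
}

panel_fractions <- function(profiles, panel) {
  if (!panel %in% names(profiles)) {
    stop("admixture input has no '", panel, "' panel column", call. = FALSE)
  }
  frac <- profiles[[panel]]
  if (anyNA(frac)) {
    bad <- profiles$individual_id[which(is.na(frac))[1]]
    stop("individual '", bad, "' is missing the ", panel, " fraction",
         call. = FALSE)
  }
  frac
}

#' Select the analysis cohort by ancestry threshold
#'
#' Retains exactly the individuals whose focal-panel fraction is greater
#' than or equal to the threshold (inclusive: a fraction of exactly 0.875
#' is retained at the default threshold). Input order is preserved and the
#' two id vectors partition the input.
#'
#' @param profiles Validated wide admixture table (see
#'   [read_admixture()]).
#' @param threshold See [ancestry_threshold()].
#' @return List with `retained` and `excluded` id vectors.
#' @export
filter_cohort <- function(profiles, threshold = ancestry_threshold()) {
  profiles <- validate_admixture(profiles)
  frac <- panel_fractions(profiles, threshold$panel)
  keep <- frac >= threshold$minimum
  list(retained = profiles$individual_id[keep],
       excluded = profiles$individual_id[!keep])
}

#' Sensitivity of the retained count to the threshold
#'
#' Re-filters at threshold - delta, the threshold, and threshold + delta,
#' reporting the retained counts; a robust threshold choice moves the
#' count only slightly.
#'
#' @inheritParams filter_cohort
#' @param delta Threshold perturbation; `minimum +/- delta` must stay in
#'   \[0, 1\].
#' @return Named numeric vector `c(lower = , at = , upper = )` of retained
#'   counts (thresholds `minimum - delta`, `minimum`, `minimum + delta`).
#' @export
#' @examples
#' prof <- data.frame(individual_id = 1:4,
#'                    JPT = c(1, 0.9, 0.88, 0.6), OTH = c(0, 0.1, 0.12, 0.4))
#' threshold_sensitivity(prof, delta = 0.025)
threshold_sensitivity <- function(profiles, threshold = ancestry_threshold(),
                                  delta = 0.025) {
  if (threshold$minimum - delta < 0 || threshold$minimum + delta > 1) {
    stop("threshold +/- delta must stay within [0, 1]", call. = FALSE)
  }
  count_at <- function(m) {
    length(filter_cohort(profiles,
                         ancestry_threshold(threshold$panel, m))$retained)
  }
  c(lower = count_at(threshold$minimum - delta),
    at    = count_at(threshold$minimum),
    upper = count_at(threshold$minimum + delta))
}

#' Histogram of focal-panel ancestry fractions
#'
#' Bins partition \[0, 1\]; every bin is left-closed, right-open except the
#' last, which also includes 1, so bin counts always sum to the number of
#' profiles. A bin is flagged retained when it lies entirely at or above
#' the threshold.
#'
#' @inheritParams filter_cohort
#' @param bin_width Positive bin width.
#' @return Data frame `bin_start`, `bin_end`, `count`, `retained`.
#' @export
ancestry_histogram <- function(profiles, threshold = ancestry_threshold(),
                               bin_width = 0.025) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive", call. = FALSE)
  }
  edges <- unique(c(seq(0, 1, by = bin_width), 1))
  frac <- if (nrow(profiles)) {
    panel_fractions(validate_admixture(profiles), threshold$panel)
  } else {
    numeric(0)
  }
  idx <- findInterval(frac, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    count = counts,
    retained = edges[-length(edges)] >= threshold$minimum
  )
}
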