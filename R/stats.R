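# Population statistics: Wilson intervals, risk differences, z-tests,
# FDR control, and the two-population comparison table.

#' Wilson score confidence interval for a binomial proportion
#'
#' Without continuity correction; preferred over the Wald interval for its
#' coverage near 0 and 1. The normal quantile is computed exactly from the
#' requested confidence level.
#'
#' @param count Number of successes, `0 <= count <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param confidence Two-sided confidence level (default 0.95).
#' @return Named numeric `c(low = , high = )`, both in \[0, 1\].
#' @export
#' @examples
#' wilson_ci(581, 2471)  # ~ (0.219, 0.252)
wilson_ci <- function(count, n, confidence = 0.95) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(count) || length(count) != 1L || count < 0 || count > n) {
    stop("count must satisfy 0 <= count <= n", call. = FALSE)
  }
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- count / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Reconstruct an integer count from a rounded proportion
#'
#' Published frequency tables usually print a rounded percentage and a
#' sample size; the underlying count is recovered as the nearest integer
#' to `proportion * n` (half away from zero).
#'
#' @param proportion Fraction in \[0, 1\].
#' @param n Sample size.
#' @return Integer in \[0, n\].
#' @export
#' @examples
#' reconstruct_count(0.235, 2471)  # 581
reconstruct_count <- function(proportion, n) {
  stopifnot(length(proportion) == 1L, length(n) == 1L)
  if (proportion < 0 || proportion > 1) {
    stop("proportion must be in [0, 1]", call. = FALSE)
  }
  if (n < 1 || n != round(n)) stop("n must be a positive integer", call. = FALSE)
  as.integer(min(n, floor(proportion * n + 0.5)))
}

#' Risk difference with Wald confidence interval
#'
#' `rd = p1 - p2`; the interval is the asymptotic-normal (Wald) interval
#' without continuity correction, half-width
#' `z * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @param n1,n2 Sample sizes.
#' @param confidence Two-sided confidence level.
#' @return Named numeric `c(rd = , ci_low = , ci_high = )`.
#' @export
#' @examples
#' risk_difference(0.710, 632, 0.532, 21185)
risk_difference <- function(p1, n1, p2, n2, confidence = 0.95) {
  stopifnot(n1 >= 1, n2 >= 1, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  rd <- p1 - p2
  half <- z * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  c(rd = rd, ci_low = rd - half, ci_high = rd + half)
}

#' Two-proportion z-test (pooled, two-sided)
#'
#' Standard pooled-proportion z statistic with two-sided p-value
#' `2 * (1 - pnorm(|z|))`. Equal sample proportions give exactly z = 0,
#' p = 1. Degenerate pooled proportions (0 or 1, where the statistic is
#' undefined) return z = 0, p = 1 with a message rather than an error —
#' a non-result, which small simulated cohorts can produce.
#'
#' @param x1,x2 Success counts.
#' @param n1,n2 Sample sizes.
#' @return Named numeric `c(z = , p_value = )`.
#' @export
#' @examples
#' two_prop_z(449, 632, 11270, 21185)
two_prop_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  if (p1 == p2) return(c(z = 0, p_value = 1))
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    message("two_prop_z: degenerate pooled proportion; returning z = 0, p = 1")
    return(c(z = 0, p_value = 1))
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  c(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR control; a thin validated wrapper over
#' `stats::p.adjust(method = "BH")`, returning q-values in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\], non-empty.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || length(p_values) == 0L) {
    stop("p_values must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Decision thresholds for the population comparison
#'
#' A divergence is flagged practically meaningful when the absolute risk
#' difference reaches `rd_threshold` (default 5 percentage points) and
#' statistically significant when the BH q-value falls below `q_threshold`
#' (default 0.05).
#'
#' @param rd_threshold Absolute risk-difference cutoff.
#' @param q_threshold FDR cutoff.
#' @param confidence Confidence level used for all intervals.
#' @return List with class `pgx_thresholds`.
#' @export
decision_thresholds <- function(rd_threshold = 0.05, q_threshold = 0.05,
                                confidence = 0.95) {
  vals <- c(rd_threshold, q_threshold, confidence)
  if (any(vals <= 0 | vals >= 1)) {
    stop("all thresholds must lie in (0, 1)", call. = FALSE)
  }
  structure(list(rd_threshold = rd_threshold, q_threshold = q_threshold,
                 confidence = confidence), class = "pgx_thresholds")
}

#' Build a recommendation-frequency table from assigned categories
#'
#' Tabulates one population's per-individual recommendations into counts,
#' proportions and Wilson intervals per drug context and category. All six
#' categories are reported (zero counts included) so tables from different
#' populations always align.
#'
#' @param recommendations Long data frame `individual_id`, `context`,
#'   `category` (output of [assign_recommendations()]).
#' @param population Population label recorded on every row.
#' @param confidence Confidence level for the Wilson intervals.
#' @return Data frame `population`, `context`, `category`, `count`, `n`,
#'   `proportion`, `ci_low`, `ci_high`.
#' @export
frequency_table <- function(recommendations, population, confidence = 0.95) {
  stopifnot(all(c("individual_id", "context", "category") %in%
                  names(recommendations)))
  bad <- !recommendations$category %in% recommendation_categories()
  if (any(bad)) {
    stop("out-of-vocabulary category: ",
         unique(recommendations$category[bad])[1], call. = FALSE)
  }
  out <- lapply(unique(recommendations$context), function(ctx) {
    sub <- recommendations[recommendations$context == ctx, ]
    n <- length(unique(sub$individual_id))
    counts <- table(factor(sub$category, levels = recommendation_categories()))
    ci <- t(vapply(as.integer(counts), wilson_ci, numeric(2), n = n,
                   confidence = confidence))
    data.frame(population = population, context = ctx,
               category = names(counts), count = as.integer(counts), n = n,
               proportion = as.integer(counts) / n,
               ci_low = ci[, "low"], ci_high = ci[, "high"],
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Bundled reference recommendation-frequency tables
#'
#' CPIC-style population frequency tables shipped with the package: the
#' CPIC East Asian aggregate, a published Japanese WGS cohort, and an
#' independent Japanese CYP2D6 genotyping study (opioid context only),
#' with per-cell provenance notes.
#'
#' @param path Optional alternative TSV (columns `population`, `context`,
#'   `category`, `frequency`, `n`, `note`).
#' @return Data frame with those columns.
#' @export
reference_frequency_tables <- function(path = pgx_extdata("cpic_reference_frequencies.tsv")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("population", "context", "category", "frequency", "n")
  if (!all(required %in% names(df))) {
    stop("reference table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (!"note" %in% names(df)) df$note <- ""
  df$note[is.na(df$note)] <- ""
  df
}

#' Most frequent recommendation categories for a drug context
#'
#' Returns the `k` categories with the highest reference-population
#' frequency; ties break by the other population's frequency, then
#' lexicographically, so the selection is deterministic. If fewer than `k`
#' distinct categories exist, all are returned with a message.
#'
#' @param tbl,ref One-context frequency tables (data frames with
#'   `category` and a `proportion` or `frequency` column) for the study
#'   and reference populations.
#' @param k Number of categories to keep (default 2).
#' @return Character vector of category labels, highest frequency first.
#' @export
top_categories <- function(tbl, ref, k = 2L) {
  stopifnot(k >= 1L)
  freq_col <- function(d) if ("proportion" %in% names(d)) d$proportion else d$frequency
  ref_f <- stats::setNames(freq_col(ref), ref$category)
  tbl_f <- stats::setNames(freq_col(tbl), tbl$category)
  cats <- union(ref$category, tbl$category)
  ref_v <- ifelse(is.na(ref_f[cats]), 0, ref_f[cats])
  tbl_v <- ifelse(is.na(tbl_f[cats]), 0, tbl_f[cats])
  nonzero <- cats[ref_v > 0 | tbl_v > 0]
  if (length(nonzero) < k) {
    message("top_categories: only ", length(nonzero),
            " distinct non-empty categories available (k = ", k, ")")
    k <- length(nonzero)
  }
  ord <- order(-ref_v, -tbl_v, cats, method = "radix")
  cats[ord][seq_len(k)]
}

table_cell <- function(tbl, ctx, cat) {
  row <- tbl[tbl$context == ctx & tbl$category == cat, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  n <- row$n[1]
  x <- if ("count" %in% names(row) && !is.na(row$count[1])) {
    row$count[1]
  } else {
    p <- if ("proportion" %in% names(row)) row$proportion[1] else row$frequency[1]
    reconstruct_count(p, n)
  }
  list(x = as.integer(x), n = as.integer(n))
}

#' Compare recommendation frequencies between two populations
#'
#' For each drug context, restricts to the `k` most frequent categories in
#' the reference population, then computes per row: the risk difference
#' `p_study - p_ref` with its Wald interval, the pooled two-proportion
#' z-test, and — across all rows jointly — BH q-values. Rows are flagged
#' `meaningful` when `|rd|` reaches the practical threshold and
#' `significant` when `q` falls below the FDR threshold. Proportions on
#' both sides are first converted to integer counts
#' ([reconstruct_count()] when only a rounded frequency is given) and
#' recomputed as count/n, so results are consistent with the underlying
#' integer data.
#'
#' @param cohort,ref Frequency tables (from [frequency_table()],
#'   [reference_frequency_tables()] subsets, or any data frame with
#'   `context`, `category`, `n` and a `count`/`proportion`/`frequency`
#'   column). Both must cover the same set of contexts.
#' @param thresholds See [decision_thresholds()].
#' @param k Categories kept per context (default 2).
#' @return Data frame of class `pgx_comparison` with one row per (context,
#'   category): `context`, `category`, `p_jpn`, `n_jpn`, `p_ref`, `n_ref`,
#'   `rd`, `rd_ci_low`, `rd_ci_high`, `z`, `p_value`, `q_value`,
#'   `meaningful`, `significant`. The BH family size is attached as
#'   attribute `m`.
#' @export
compare_populations <- function(cohort, ref,
                                thresholds = decision_thresholds(), k = 2L) {
  contexts <- intersect(names(drug_contexts()), unique(ref$context))
  missing_ref <- setdiff(unique(cohort$context), unique(ref$context))
  missing_coh <- setdiff(unique(ref$context), unique(cohort$context))
  if (length(missing_ref) || length(missing_coh)) {
    stop("context coverage differs between tables: ",
         paste(c(missing_ref, missing_coh), collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (ctx in contexts) {
    coh_ctx <- cohort[cohort$context == ctx, , drop = FALSE]
    ref_ctx <- ref[ref$context == ctx, , drop = FALSE]
    for (cat in top_categories(coh_ctx, ref_ctx, k)) {
      a <- table_cell(cohort, ctx, cat)
      b <- table_cell(ref, ctx, cat)
      if (is.null(a)) a <- list(x = 0L, n = as.integer(coh_ctx$n[1]))
      if (is.null(b)) b <- list(x = 0L, n = as.integer(ref_ctx$n[1]))
      p1 <- a$x / a$n
      p2 <- b$x / b$n
      rd <- risk_difference(p1, a$n, p2, b$n, thresholds$confidence)
      zt <- two_prop_z(a$x, a$n, b$x, b$n)
      rows[[length(rows) + 1L]] <- data.frame(
        context = ctx, category = cat,
        p_jpn = p1, n_jpn = a$n, p_ref = p2, n_ref = b$n,
        rd = rd[["rd"]], rd_ci_low = rd[["ci_low"]],
        rd_ci_high = rd[["ci_high"]],
        z = zt[["z"]], p_value = zt[["p_value"]],
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$meaningful <- abs(out$rd) >= thresholds$rd_threshold
  out$significant <- out$q_value < thresholds$q_threshold
  attr(out, "m") <- nrow(out)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("pgx_comparison", class(out))
  out
}
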