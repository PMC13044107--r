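# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes, so the whole
# pipeline can be exercised without individual-level genomic data:
# Hardy-Weinberg diplotypes (random union of gametes) from per-gene allele
# frequency specs, admixture fractions with a near-1 mode plus an admixed
# tail, uniform demographics, and the identifying fields (kit id, user id,
# timestamp) that de-identification is supposed to strip. Genes are drawn
# independently — the four pharmacogenes sit on different chromosomes, so
# no linkage is modeled.

#' Allele-frequency specification for one gene
#'
#' @param gene Gene symbol.
#' @param frequencies Named numeric vector, allele name -> frequency;
#'   must sum to 1 within 1e-9, and every allele must exist in the active
#'   allele-function table.
#' @param tables Allele-function tables to validate against.
#' @return List with class `pgx_allele_spec`.
#' @export
allele_frequency_spec <- function(gene, frequencies,
                                  tables = default_allele_function_tables()) {
  stopifnot(gene %in% PGX_GENES, is.numeric(frequencies),
            !is.null(names(frequencies)))
  if (any(frequencies < 0)) stop("allele frequencies must be non-negative",
                                 call. = FALSE)
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop(gene, ": allele frequencies sum to ",
         format(sum(frequencies), digits = 12), ", not 1", call. = FALSE)
  }
  unknown <- setdiff(names(frequencies), tables[[gene]]$allele)
  if (length(unknown)) {
    stop(gene, ": allele(s) absent from the function table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(gene = gene, frequencies = frequencies),
            class = "pgx_allele_spec")
}

#' Default Japanese-like allele-frequency specs
#'
#' Calibration devices, not population estimates: chosen so the implied
#' recommendation-category probabilities resemble a Japanese cohort
#' (e.g. the CYP2D6 spec puts mass 0.53 on normal-function alleles, 0.42
#' on decreased, 0.05 on no-function, giving ~73% Normal metabolizers
#' under Hardy-Weinberg).
#'
#' @param tables Allele-function tables to validate against.
#' @return Named list of [allele_frequency_spec()]s, one per gene.
#' @export
default_allele_frequency_specs <- function(tables = default_allele_function_tables()) {
  specs <- list(
    CYP2D6  = c("*1" = 0.43, "*2" = 0.10, "*10" = 0.40, "*41" = 0.02,
                "*5" = 0.045, "*14" = 0.005),
    CYP2C19 = c("*1" = 0.60, "*2" = 0.28, "*3" = 0.11, "*17" = 0.01),
    CYP2B6  = c("*1" = 0.79, "*6" = 0.16, "*4" = 0.03, "*18" = 0.02),
    SLCO1B1 = c("*1" = 0.82, "*15" = 0.105, "*5" = 0.05, "*31" = 0.025)
  )
  mapply(allele_frequency_spec, names(specs), specs,
         MoreArgs = list(tables = tables), SIMPLIFY = FALSE)
}

#' Sample diplotype strings under Hardy-Weinberg equilibrium
#'
#' Each individual receives two independent allele draws (random union of
#' gametes); the pair is formatted with the numerically smaller allele
#' first.
#'
#' @param spec An [allele_frequency_spec()].
#' @param n Number of individuals.
#' @param seed Optional integer; when given the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return Character vector of diplotype strings, e.g. `"*1/*10"`.
#' @export
sample_diplotypes <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "pgx_allele_spec"), n >= 1)
  draw <- function() {
    alleles <- names(spec$frequencies)
    a1 <- sample(alleles, n, replace = TRUE, prob = spec$frequencies)
    a2 <- sample(alleles, n, replace = TRUE, prob = spec$frequencies)
    num <- function(a) as.numeric(sub("\\*", "", a))
    swap <- num(a1) > num(a2)
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    paste0(a1, "/", a2)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Ancestry mixture model
#'
#' With probability `mode_weight` an individual's focal-panel fraction is
#' drawn from a Beta(`high_shape`) distribution rescaled onto
#' `high_bounds` (mode at the upper end, emulating the near-1 pileup of a
#' well-matched cohort); otherwise uniformly from `tail_bounds` (the
#' admixed tail).
#'
#' @param mode_weight Probability of the high component.
#' @param high_bounds,tail_bounds Intervals within \[0, 1\].
#' @param high_shape Beta shape parameters `c(shape1, shape2)`.
#' @return List with class `pgx_ancestry_model`.
#' @export
ancestry_model <- function(mode_weight = 0.9, high_bounds = c(0.93, 1),
                           high_shape = c(5, 1), tail_bounds = c(0.5, 0.93)) {
  stopifnot(mode_weight >= 0, mode_weight <= 1,
            length(high_bounds) == 2L, length(tail_bounds) == 2L,
            all(c(high_bounds, tail_bounds) >= 0),
            all(c(high_bounds, tail_bounds) <= 1),
            high_bounds[1] < high_bounds[2], tail_bounds[1] < tail_bounds[2])
  structure(list(mode_weight = mode_weight, high_bounds = high_bounds,
                 high_shape = high_shape, tail_bounds = tail_bounds),
            class = "pgx_ancestry_model")
}

#' Sample focal-panel ancestry fractions
#'
#' @param model An [ancestry_model()].
#' @param n Number of individuals.
#' @param seed Optional integer seed (see [sample_diplotypes()]).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
sample_ancestry <- function(model = ancestry_model(), n, seed = NULL) {
  stopifnot(inherits(model, "pgx_ancestry_model"), n >= 1)
  draw <- function() {
    high <- stats::runif(n) < model$mode_weight
    out <- numeric(n)
    hb <- model$high_bounds
    out[high] <- hb[1] + (hb[2] - hb[1]) *
      stats::rbeta(sum(high), model$high_shape[1], model$high_shape[2])
    tb <- model$tail_bounds
    out[!high] <- stats::runif(sum(!high), tb[1], tb[2])
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Demographics model
#'
#' @param age_range Integer `c(min, max)` for uniform age draws.
#' @param sex Named probability vector over sex labels.
#' @param locations Named probability vector over purchase locations.
#' @return List with class `pgx_demographics_model`.
#' @export
demographics_model <- function(age_range = c(20L, 79L),
                               sex = c(female = 0.5, male = 0.5),
                               locations = c(tokyo = 0.4, osaka = 0.2,
                                             nagoya = 0.15, fukuoka = 0.15,
                                             sapporo = 0.1)) {
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2])
  if (abs(sum(sex) - 1) > 1e-9 || abs(sum(locations) - 1) > 1e-9) {
    stop("sex and location probabilities must each sum to 1", call. = FALSE)
  }
  structure(list(age_range = age_range, sex = sex, locations = locations),
            class = "pgx_demographics_model")
}

#' Full cohort specification
#'
#' @param n Cohort size.
#' @param seed Integer seed; all sampling in [generate_cohort()] is
#'   reproducible under it.
#' @param allele_specs One [allele_frequency_spec()] per gene.
#' @param ancestry See [ancestry_model()].
#' @param demographics See [demographics_model()].
#' @return List with class `pgx_cohort_spec`.
#' @export
cohort_spec <- function(n = 632L, seed = 1L,
                        allele_specs = default_allele_frequency_specs(),
                        ancestry = ancestry_model(),
                        demographics = demographics_model()) {
  stopifnot(n >= 1, is.numeric(seed))
  if (!all(vapply(allele_specs, inherits, logical(1), "pgx_allele_spec"))) {
    stop("allele_specs must be allele_frequency_spec objects", call. = FALSE)
  }
  if (!identical(sort(names(allele_specs)), sort(PGX_GENES))) {
    stop("allele_specs must cover exactly the four genes", call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 allele_specs = allele_specs, ancestry = ancestry,
                 demographics = demographics),
            class = "pgx_cohort_spec")
}

#' Generate a raw synthetic cohort
#'
#' Produces the records the real primary pipeline would hand over:
#' per-gene diplotype calls, a focal-panel admixture fraction (plus its
#' complement under an "OTHER" panel), demographics — and deliberately
#' also kit ids, user ids and timestamps, so that de-identification has
#' something to strip. Deterministic under `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return List of data frames: `samples` (kit_id, user_id, timestamp,
#'   age, sex, purchase_location, JPT, OTHER) and `diplotypes`
#'   (individual_id = kit_id, gene, diplotype).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "pgx_cohort_spec"))
  n <- spec$n
  withr::with_seed(spec$seed, {
    kit_id <- sprintf("KIT%06d", seq_len(n))
    user_id <- sprintf("USR%06d", sample(10^6 - 1L, n))
    timestamp <- format(
      as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
        cumsum(sample(60:3600, n, replace = TRUE)),
      "%Y-%m-%d %H:%M:%S")
    dm <- spec$demographics
    age <- sample(seq(dm$age_range[1], dm$age_range[2]), n, replace = TRUE)
    sex <- sample(names(dm$sex), n, replace = TRUE, prob = dm$sex)
    loc <- sample(names(dm$locations), n, replace = TRUE, prob = dm$locations)
    jpt <- sample_ancestry(spec$ancestry, n)
    diplotypes <- do.call(rbind, lapply(PGX_GENES, function(gene) {
      data.frame(individual_id = kit_id, gene = gene,
                 diplotype = sample_diplotypes(spec$allele_specs[[gene]], n),
                 row.names = NULL)
    }))
    list(
      samples = data.frame(kit_id = kit_id, user_id = user_id,
                           timestamp = timestamp, age = age, sex = sex,
                           purchase_location = loc,
                           JPT = jpt, OTHER = 1 - jpt, row.names = NULL),
      diplotypes = diplotypes
    )
  })
}

#' Closed-form recommendation-category probabilities implied by a spec
#'
#' Enumerates every diplotype (pair of alleles, Hardy-Weinberg
#' probability `f_i * f_j`, ordered pairs summed), translates each to a
#' phenotype and a recommendation, and accumulates exact category
#' probabilities. Multi-gene contexts take the product over their genes'
#' independent phenotype distributions. This is the analytic expectation
#' against which sampled pipelines can be checked.
#'
#' @param context Drug-context id.
#' @param allele_specs Per-gene [allele_frequency_spec()]s.
#' @inheritParams diplotype_phenotype
#' @param grids Recommendation grids.
#' @return Named numeric vector over the six categories, summing to 1.
#' @export
expected_category_probs <- function(context,
                                    allele_specs = default_allele_frequency_specs(),
                                    tables = default_allele_function_tables(),
                                    cutoffs = activity_score_cutoffs(),
                                    pair_grids = default_function_pair_grids(),
                                    grids = default_recommendation_grids()) {
  genes <- context_genes(context)
  phen_dist <- function(gene) {
    freqs <- allele_specs[[gene]]$frequencies
    alleles <- names(freqs)
    dist <- numeric(0)
    for (i in seq_along(alleles)) for (j in seq_along(alleles)) {
      d <- parse_diplotype(gene, paste0(alleles[i], "/", alleles[j]))
      ph <- diplotype_phenotype(d, tables, cutoffs, pair_grids)$phenotype
      dist[ph] <- (if (is.na(dist[ph])) 0 else dist[ph]) + freqs[i] * freqs[j]
    }
    dist
  }
  dists <- lapply(genes, phen_dist)
  combos <- expand.grid(lapply(dists, names), stringsAsFactors = FALSE)
  probs <- stats::setNames(numeric(6), recommendation_categories())
  for (r in seq_len(nrow(combos))) {
    labels <- as.character(combos[r, ])
    p <- prod(mapply(function(d, l) d[[l]], dists, labels))
    cat <- recommend(context, stats::setNames(as.list(labels), genes), grids)
    probs[cat] <- probs[cat] + p
  }
  probs
}
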