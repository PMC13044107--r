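# Shared fixtures and independent oracles, built once per test run.

FN_TABLES <- default_allele_function_tables()
PAIR_GRIDS <- default_function_pair_grids()
REC_GRIDS <- default_recommendation_grids()
CUTOFFS <- activity_score_cutoffs()

CATEGORIES <- recommendation_categories()

dip <- function(gene, text) parse_diplotype(gene, text)

# quick admixture frame: one JPT fraction per individual
admix <- function(jpt, ids = seq_along(jpt)) {
  data.frame(individual_id = ids, JPT = jpt, OTHER = 1 - jpt)
}

# independent step-up BH oracle (literal definition, deliberately naive)
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[ord[i]] <- min(1, min(vapply(i:m, function(j) p[ord[j]] * m / j,
                                   numeric(1))))
  }
  q
}

# display rounding to one decimal percent, half away from zero
round_half_up_pct <- function(x) floor(1000 * x + 0.5) / 10

# metabolizer-phenotype rank for monotonicity checks
phenotype_rank <- c(Poor = 1, Intermediate = 2, Normal = 3, Ultrarapid = 4)
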