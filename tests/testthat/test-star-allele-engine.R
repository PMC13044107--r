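test_that("diplotype parsing handles star-allele notation and rejects malformed input", {
  d <- dip("CYP2D6", "*1/*10")
  expect_equal(d$allele1$name, "*1")
  expect_equal(d$allele2$name, "*10")
  expect_equal(d$allele1$copies, 1L)

  dup <- dip("CYP2D6", "*1x2/*5")
  expect_equal(dup$allele1$name, "*1")
  expect_equal(dup$allele1$copies, 2L)
  expect_equal(dup$allele2$name, "*5")

  # tolerated: whitespace, gene prefix, suballele letters
  expect_equal(dip("CYP2D6", " *1 / *10 "), dip("CYP2D6", "*1/*10"))
  expect_equal(dip("CYP2D6", "CYP2D6*1/*10"), dip("CYP2D6", "*1/*10"))
  expect_equal(dip("CYP2C19", "*1A/*2"), dip("CYP2C19", "*1/*2"))

  # canonical ordering: allele order never matters
  expect_equal(dip("CYP2D6", "*10/*1"), dip("CYP2D6", "*1/*10"))
  expect_equal(dip("CYP2D6", "*5/*1x2"), dip("CYP2D6", "*1x2/*5"))

  expect_error(dip("CYP2D6", "*1*10"), "two alleles")
  expect_error(dip("CYP2D6", "*1/*10/*2"), "two alleles")
  expect_error(dip("CYP2D6", "*1x0/*2"), "copy number 0")
  expect_error(dip("CYP2D6", "CYP2C19*1/*2"), "gene prefix")
  expect_error(dip("CYP2D6", "*1-*10/*2"), "malformed")
  expect_error(dip("TPMT", "*1/*2"), "gene must be one of")
})

test_that("activity scores sum copy-weighted allele values and propagate NA", {
  t2d6 <- FN_TABLES$CYP2D6
  expect_equal(activity_score(dip("CYP2D6", "*1/*1"), t2d6), 2.0)
  expect_equal(activity_score(dip("CYP2D6", "*10/*41"), t2d6), 0.75)
  expect_equal(activity_score(dip("CYP2D6", "*5/*14"), t2d6), 0.0)
  expect_equal(activity_score(dip("CYP2D6", "*1x2/*5"), t2d6), 2.0)
  # uncertain-function or unlisted alleles make the score undefined, not 0
  expect_true(is.na(activity_score(dip("CYP2D6", "*1/*22"), t2d6)))
  expect_true(is.na(activity_score(dip("CYP2D6", "*1/*999"), t2d6)))
  expect_error(activity_score(dip("CYP2C19", "*1/*2"), t2d6), "CYP2D6 only")
})

test_that("activity-score additivity matches a brute-force sum over enumerated alleles", {
  t2d6 <- FN_TABLES$CYP2D6
  scored <- t2d6[!t2d6$function_class %in% c("uncertain", "unknown"), ]
  vals <- setNames(scored$activity_value, scored$allele)
  for (a in names(vals)) for (b in names(vals)) for (m in 1:3) for (n in 1:2) {
    d <- dip("CYP2D6", sprintf("%sx%d/%sx%d", a, m, b, n))
    expect_equal(activity_score(d, t2d6), m * vals[[a]] + n * vals[[b]])
  }
})

test_that("score binning partitions the score axis and is monotone in score", {
  expect_equal(phenotype_from_activity_score(0)$phenotype, "Poor")
  expect_equal(phenotype_from_activity_score(1.0)$phenotype, "Intermediate")
  expect_equal(phenotype_from_activity_score(1.25)$phenotype, "Normal")
  expect_equal(phenotype_from_activity_score(2.25)$phenotype, "Normal")
  expect_equal(phenotype_from_activity_score(2.5)$phenotype, "Ultrarapid")
  na_ph <- phenotype_from_activity_score(NA_real_)
  expect_equal(na_ph$phenotype, "Indeterminate")
  expect_true(is.na(na_ph$activity_score))
  expect_error(phenotype_from_activity_score(-0.5), "non-negative")
  expect_error(activity_score_cutoffs(pm_max = 2, im_max = 1), "pm_max < im_max")

  # every non-absent score maps to exactly one phenotype, rank nondecreasing
  set.seed(7)
  for (rep in 1:20) {
    b <- sort(runif(3, 0, 4))
    cuts <- activity_score_cutoffs(b[1], b[2], b[3])
    labels <- vapply(seq(0, 4, by = 0.25), function(s) {
      phenotype_from_activity_score(s, cuts)$phenotype
    }, character(1))
    expect_true(all(labels %in% names(phenotype_rank)))
    expect_true(all(diff(phenotype_rank[labels]) >= 0))
  }
})

test_that("function-pair lookup is order-free and falls back to Indeterminate", {
  expect_equal(phenotype_from_function_pair(dip("CYP2C19", "*2/*3"),
                                            FN_TABLES$CYP2C19,
                                            PAIR_GRIDS$CYP2C19)$phenotype,
               "Poor")
  expect_equal(phenotype_from_function_pair(dip("SLCO1B1", "*1/*15"),
                                            FN_TABLES$SLCO1B1,
                                            PAIR_GRIDS$SLCO1B1)$phenotype,
               "DecreasedFunction")
  # unknown/uncertain function, or allele missing from the table
  expect_equal(phenotype_from_function_pair(dip("CYP2C19", "*1/*12"),
                                            FN_TABLES$CYP2C19,
                                            PAIR_GRIDS$CYP2C19)$phenotype,
               "Indeterminate")
  expect_equal(phenotype_from_function_pair(dip("CYP2B6", "*1/*999"),
                                            FN_TABLES$CYP2B6,
                                            PAIR_GRIDS$CYP2B6)$phenotype,
               "Indeterminate")
  expect_error(phenotype_from_function_pair(dip("CYP2D6", "*1/*1")),
               "activity-score path")

  # symmetry across every gene and allele pair in the bundled tables
  for (gene in c("CYP2C19", "CYP2B6", "SLCO1B1")) {
    alleles <- FN_TABLES[[gene]]$allele
    for (a in alleles) for (b in alleles) {
      p1 <- phenotype_from_function_pair(dip(gene, paste0(a, "/", b)),
                                         FN_TABLES[[gene]], PAIR_GRIDS[[gene]])
      p2 <- phenotype_from_function_pair(dip(gene, paste0(b, "/", a)),
                                         FN_TABLES[[gene]], PAIR_GRIDS[[gene]])
      expect_identical(p1$phenotype, p2$phenotype)
    }
  }
})

test_that("cohort-level phenotype calling matches per-diplotype translation", {
  dt <- data.frame(
    individual_id = c("a", "a", "b", "b"),
    gene = c("CYP2D6", "CYP2C19", "CYP2D6", "CYP2C19"),
    diplotype = c("*1/*10", "*1/*1", "*5/*14", "*2/*3")
  )
  ph <- call_phenotypes(dt)
  expect_equal(ph$phenotype, c("Normal", "Normal", "Poor", "Poor"))
  expect_equal(ph$activity_score[c(1, 3)], c(1.25, 0))
  expect_true(all(is.na(ph$activity_score[c(2, 4)])))
})
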