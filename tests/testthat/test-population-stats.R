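test_that("Wilson intervals match the independent prop.test oracle and behave at the edges", {
  # oracle: stats::prop.test without continuity correction computes the
  # Wilson score interval
  for (n in c(10, 100, 2471, 21185)) {
    for (x in unique(c(0, 1, round(n / 3), round(n / 2), n))) {
      got <- wilson_ci(x, n)
      ref <- prop.test(x, n, correct = FALSE)$conf.int
      expect_equal(unname(got), as.numeric(ref), tolerance = 1e-10)
    }
  }
  expect_equal(unname(wilson_ci(0, 10)[1]), 0)
  expect_equal(unname(wilson_ci(10, 10)[2]), 1)
  expect_error(wilson_ci(5, 0), "positive integer")
  expect_error(wilson_ci(11, 10), "0 <= count <= n")

  # interval contains the point estimate; width shrinks with n
  widths <- vapply(c(50, 500, 5000), function(n) {
    ci <- wilson_ci(round(0.3 * n), n)
    expect_true(ci["low"] <= 0.31 && ci["high"] >= 0.29)
    unname(diff(ci))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("counts are reconstructed from rounded proportions by nearest integer", {
  expect_equal(reconstruct_count(0.235, 2471), 581L)   # 580.685
  expect_equal(reconstruct_count(0.532, 21185), 11270L) # 11270.42
  expect_equal(reconstruct_count(0, 500), 0L)
  expect_equal(reconstruct_count(1, 500), 500L)
  expect_equal(reconstruct_count(0.5, 5), 3L)          # half away from zero
  expect_error(reconstruct_count(1.2, 10), "\\[0, 1\\]")
})

test_that("risk difference uses the Wald interval and is antisymmetric", {
  rd <- risk_difference(0.710, 632, 0.532, 21185)
  expect_equal(unname(rd["rd"]), 0.178, tolerance = 1e-12)
  expect_equal(unname(rd["ci_low"]), 0.1420, tolerance = 1e-3)
  expect_equal(unname(rd["ci_high"]), 0.2140, tolerance = 1e-3)

  set.seed(41)
  for (i in 1:50) {
    p1 <- runif(1); p2 <- runif(1)
    n1 <- sample(10:5000, 1); n2 <- sample(10:5000, 1)
    a <- risk_difference(p1, n1, p2, n2)
    b <- risk_difference(p2, n2, p1, n1)
    expect_equal(unname(a["rd"]), -unname(b["rd"]))
    expect_equal(unname(a["ci_low"]), -unname(b["ci_high"]))
    expect_equal(unname(a["ci_high"]), -unname(b["ci_low"]))
    expect_true(a["ci_low"] <= a["rd"] && a["rd"] <= a["ci_high"])
  }
  z <- risk_difference(0.4, 100, 0.4, 250)
  expect_equal(unname(z["rd"]), 0)
})

test_that("pooled two-proportion z-test agrees with prop.test and handles degeneracy", {
  expect_equal(unname(two_prop_z(5, 10, 50, 100)), c(0, 1))
  expect_equal(unname(two_prop_z(0, 10, 0, 10)), c(0, 1))

  got <- two_prop_z(449, 632, 11270, 21185)
  expect_gt(got["z"], 8.8)
  expect_lt(got["p_value"], 1e-15)
  # oracle: z^2 equals the uncorrected chi-square statistic, p-values match
  set.seed(43)
  for (i in 1:30) {
    n1 <- sample(5:2000, 1); n2 <- sample(5:2000, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    if ((x1 + x2) %in% c(0, n1 + n2)) next
    got <- suppressMessages(two_prop_z(x1, n1, x2, n2))
    ref <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
    expect_equal(unname(got["z"]^2), unname(ref$statistic), tolerance = 1e-9)
    expect_equal(unname(got["p_value"]), ref$p.value, tolerance = 1e-9)
  }
})

test_that("BH q-values match the literal step-up definition on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "non-empty")

  set.seed(47)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_brute_force(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("top categories are chosen by reference frequency with deterministic ties", {
  ref <- data.frame(category = c("Use as directed", "Use with caution",
                                 "Not determined",
                                 "Avoid and/or use alternative medication"),
                    frequency = c(0.532, 0.385, 0.067, 0.015))
  tbl <- data.frame(category = ref$category,
                    frequency = c(0.710, 0.250, 0.030, 0.009))
  expect_equal(top_categories(tbl, ref, 2),
               c("Use as directed", "Use with caution"))
  expect_equal(top_categories(tbl, ref, 1), "Use as directed")
  one <- data.frame(category = "Use as directed", frequency = 1)
  expect_message(got <- top_categories(one, one, 2), "only 1")
  expect_equal(got, "Use as directed")
  # tie on reference frequency resolved by study frequency, then label
  ref2 <- data.frame(category = c("A...", "Adjust dosage", "Use with caution"),
                     frequency = c(0.4, 0.4, 0.2))
  tb2 <- data.frame(category = ref2$category, frequency = c(0.1, 0.5, 0.4))
  expect_equal(top_categories(tb2, ref2, 1), "Adjust dosage")
})

test_that("population comparison flags divergences and respects the BH family", {
  refs <- reference_frequency_tables()
  eas <- refs[refs$population == "east_asian", ]
  # self-comparison: all rd exactly 0, nothing flagged
  self <- compare_populations(eas, eas)
  expect_true(all(self$rd == 0))
  expect_true(all(self$q_value == 1))
  expect_false(any(self$meaningful | self$significant))
  expect_equal(attr(self, "m"), 12L)

  # single-context family: m = 2, q from hand BH on the two p-values
  jpn <- refs[refs$population == "japanese_cohort", ]
  one_ctx <- compare_populations(jpn[jpn$context == "sertraline", ],
                                 eas[eas$context == "sertraline", ])
  expect_equal(nrow(one_ctx), 2L)
  expect_equal(attr(one_ctx, "m"), 2L)
  expect_equal(one_ctx$q_value, bh_brute_force(one_ctx$p_value))
  # invariant: rd consistent with its own proportions
  expect_equal(one_ctx$rd, one_ctx$p_jpn - one_ctx$p_ref, tolerance = 1e-12)

  expect_error(compare_populations(jpn[jpn$context != "sertraline", ], eas),
               "sertraline")
})
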