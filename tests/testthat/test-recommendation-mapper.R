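test_that("recommendation lookup applies the No call / Not determined rules", {
  expect_equal(recommend("codeine_tramadol", c(CYP2D6 = "Normal")),
               "Use as directed")
  expect_equal(recommend("codeine_tramadol", c(CYP2D6 = "Ultrarapid")),
               "Avoid and/or use alternative medication")
  expect_equal(recommend("codeine_tramadol", c(CYP2D6 = "Indeterminate")),
               "Not determined")
  expect_equal(recommend("codeine_tramadol", list()), "No call")
  # two-gene sertraline rule
  expect_equal(recommend("sertraline", c(CYP2C19 = "Normal")), "No call")
  expect_equal(recommend("sertraline",
                         c(CYP2B6 = "Normal", CYP2C19 = "Normal")),
               "Use as directed")
  expect_equal(recommend("sertraline",
                         c(CYP2B6 = "Poor", CYP2C19 = "Normal")),
               "Adjust dosage")
  expect_equal(recommend("sertraline",
                         c(CYP2B6 = "Normal", CYP2C19 = "Poor")),
               "Avoid and/or use alternative medication")
  expect_error(recommend("warfarin", c(CYP2D6 = "Normal")), "unknown drug context")
})

test_that("recommendations never leave the six-category vocabulary", {
  set.seed(11)
  for (ctx in names(drug_contexts())) {
    genes <- drug_contexts()[[ctx]]
    vocab <- if (identical(genes, "SLCO1B1")) {
      c("IncreasedFunction", "NormalFunction", "DecreasedFunction",
        "PossiblyDecreasedFunction", "PoorFunction", "Indeterminate")
    } else {
      c("Ultrarapid", "Rapid", "Normal", "Intermediate", "Poor",
        "Indeterminate")
    }
    for (i in 1:50) {
      ph <- setNames(as.list(sample(vocab, length(genes), replace = TRUE)),
                     genes)
      expect_true(recommend(ctx, ph) %in% CATEGORIES)
    }
  }
})

test_that("statin contexts share 'Use as directed' mass and redistribute the rest", {
  statins <- c("lova_pita_simva", "pravastatin", "atorvastatin")
  set.seed(23)
  labels <- c("IncreasedFunction", "NormalFunction", "DecreasedFunction",
              "PossiblyDecreasedFunction", "PoorFunction", "Indeterminate")
  for (rep in 1:10) {
    w <- runif(length(labels))
    w <- w / sum(w)
    mass <- sapply(statins, function(ctx) {
      out <- setNames(numeric(length(CATEGORIES)), CATEGORIES)
      for (k in seq_along(labels)) {
        cat <- recommend(ctx, setNames(labels[k], "SLCO1B1"))
        out[cat] <- out[cat] + w[k]
      }
      out
    })
    # identical "Use as directed" and "Not determined" proportions
    expect_equal(var(mass["Use as directed", ]), 0)
    expect_equal(var(mass["Not determined", ]), 0)
    # remaining mass lands in the context-specific action category
    rest <- 1 - mass["Use as directed", 1] - mass["Not determined", 1]
    expect_equal(mass["Avoid and/or use alternative medication", "lova_pita_simva"],
                 rest)
    expect_equal(mass["Use with caution", "pravastatin"] +
                   mass["Avoid and/or use alternative medication", "pravastatin"],
                 rest)
    expect_equal(mass["Adjust dosage", "atorvastatin"] +
                   mass["Avoid and/or use alternative medication", "atorvastatin"],
                 rest)
  }
})

test_that("label harmonization is case/punctuation-insensitive and strict", {
  expect_equal(harmonize_label("use as directed"), "Use as directed")
  expect_equal(harmonize_label("Avoid and/or use alternative medication"),
               "Avoid and/or use alternative medication")
  expect_equal(harmonize_label("AVOID"),
               "Avoid and/or use alternative medication")
  expect_equal(harmonize_label("Adjust dose!"), "Adjust dosage")
  expect_equal(harmonize_label("no-call"), "No call")
  # HLA positive/negative semantics
  expect_equal(harmonize_label("POSITIVE"),
               "Avoid and/or use alternative medication")
  expect_equal(harmonize_label("negative"), "Use as directed")
  expect_error(harmonize_label("definitely prescribe"), "cannot harmonize")
  expect_error(harmonize_label(""), "non-empty")
})

test_that("diplotype-count tables convert to recommendation frequencies", {
  out <- convert_diplotype_table(
    "codeine_tramadol",
    data.frame(diplotype = c("*1/*1", "*10/*10"), count = c(50, 50)))
  expect_equal(setNames(out$proportion, out$category),
               c("Use as directed" = 0.5, "Use with caution" = 0.5))

  out2 <- convert_diplotype_table(
    "codeine_tramadol", data.frame(diplotype = "*5/*5", count = 10))
  expect_equal(out2$category, "Avoid and/or use alternative medication")
  expect_equal(out2$proportion, 1.0)

  expect_error(convert_diplotype_table("codeine_tramadol",
                                       data.frame(diplotype = character(0),
                                                  count = integer(0))),
               "empty")
  expect_error(convert_diplotype_table(
    "codeine_tramadol",
    data.frame(diplotype = c("*1/*1", "*1*10"), count = c(1, 1))),
    "row 2")
  expect_error(convert_diplotype_table(
    "sertraline", data.frame(diplotype = "*1/*1", count = 1)),
    "single-gene")
})

test_that("grid configuration is validated for totality and vocabulary", {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(contexts = list(codeine_tramadol = list(
    genes = list("CYP2D6"),
    cells = list(Ultrarapid = "Avoid and/or use alternative medication")))),
    tmp)
  expect_error(read_recommendation_grids(tmp), "missing cells")
  yaml::write_yaml(list(contexts = list(codeine_tramadol = list(
    genes = list("CYP2D6"),
    cells = as.list(setNames(rep("Prescribe freely", 5),
                             c("Ultrarapid", "Rapid", "Normal",
                               "Intermediate", "Poor")))))),
    tmp)
  expect_error(read_recommendation_grids(tmp), "out-of-vocabulary")
})
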