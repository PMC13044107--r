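# End-to-end pipeline orchestration and report rendering.

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

format_pct <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * x, digits))
}

#' Format a risk difference as a whole percent
#'
#' Display rounding used in comparison reports: whole percentage points,
#' half away from zero (0.178 -> "18%", -0.081 -> "-8%").
#'
#' @param rd Risk difference as a fraction.
#' @return Character scalar.
#' @export
format_rd <- function(rd) {
  sprintf("%d%%", as.integer(round_half_up(100 * rd)))
}

#' Render comparison rows and frequency tables as report text
#'
#' Applies the standard display rounding: one decimal for frequencies,
#' whole percents for risk differences and their intervals. Output is
#' deterministic for identical input.
#'
#' @param comparison Output of [compare_populations()].
#' @param freq Optional frequency table(s) (rows as from
#'   [frequency_table()]), rendered above the comparison.
#' @return Character vector of lines.
#' @export
render_report <- function(comparison, freq = NULL) {
  lines <- character(0)
  if (!is.null(freq)) {
    lines <- c(lines, "== Recommendation frequencies ==")
    for (r in seq_len(nrow(freq))) {
      row <- freq[r, ]
      p <- if ("proportion" %in% names(row)) row$proportion else row$frequency
      ci <- if (all(c("ci_low", "ci_high") %in% names(row)) &&
                !is.na(row$ci_low)) {
        sprintf(" (%s-%s)", format_pct(row$ci_low), format_pct(row$ci_high))
      } else ""
      lines <- c(lines, sprintf("%s | %s | %s | n=%d | %s%s",
                                row$population, row$context, row$category,
                                as.integer(row$n), format_pct(p), ci))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "== Population comparison ==")
  for (r in seq_len(nrow(comparison))) {
    row <- comparison[r, ]
    q <- if (row$q_value < 0.001) "<0.001" else sprintf("%.2f", row$q_value)
    flags <- paste0(if (row$meaningful) "M" else "-",
                    if (row$significant) "S" else "-")
    lines <- c(lines, sprintf(
      "%s | %s | %s vs %s | RD %s (%s to %s) | q %s | %s",
      row$context, row$category, format_pct(row$p_jpn), format_pct(row$p_ref),
      format_rd(row$rd), format_rd(row$rd_ci_low), format_rd(row$rd_ci_high),
      q, flags))
  }
  lines
}

#' Compare the bundled reference frequency tables
#'
#' "Cohort-free" mode: runs the two-population comparison directly on the
#' packaged CPIC-style frequency tables (study population vs reference
#' aggregate), reconstructing integer counts from the printed frequencies.
#'
#' @param study,reference Population labels in
#'   [reference_frequency_tables()].
#' @param thresholds See [decision_thresholds()].
#' @param tables Reference table data frame.
#' @return See [compare_populations()].
#' @export
#' @examples
#' cmp <- compare_reference_populations()
#' subset(cmp, meaningful & significant)
compare_reference_populations <- function(study = "japanese_cohort",
                                          reference = "east_asian",
                                          thresholds = decision_thresholds(),
                                          tables = reference_frequency_tables()) {
  pops <- unique(tables$population)
  for (p in c(study, reference)) {
    if (!p %in% pops) stop("population '", p, "' not in reference tables",
                           call. = FALSE)
  }
  coh <- tables[tables$population == study, , drop = FALSE]
  ref <- tables[tables$population == reference, , drop = FALSE]
  shared <- intersect(unique(coh$context), unique(ref$context))
  compare_populations(coh[coh$context %in% shared, ],
                      ref[ref$context %in% shared, ], thresholds)
}

#' Run the secondary pipeline end to end
#'
#' Orchestrates: ancestry filtering -> diplotype phenotyping ->
#' recommendation assignment -> de-identified aggregate store -> frequency
#' tables -> two-population comparison against a reference table. Writes
#' a frequency TSV, a comparison TSV, the store file, a run manifest
#' (inputs, config checksums, seed) and a plain-text report into
#' `out_dir`. All stages validate their inputs and abort naming the stage.
#'
#' @param cohort Raw cohort: list with `samples` and `diplotypes` as from
#'   [generate_cohort()], or `NULL` to read from `diplotypes_path` /
#'   `admixture_path`.
#' @param diplotypes_path,admixture_path TSV inputs (long diplotype table;
#'   wide or long admixture table) used when `cohort` is `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param threshold See [ancestry_threshold()].
#' @param thresholds See [decision_thresholds()].
#' @param reference Reference frequency table rows (single population).
#' @param population Label for the study population in outputs.
#' @param tables,cutoffs,pair_grids,grids Engine configuration.
#' @param seed Optional integer seed controlling the only stochastic step
#'   (generic-id generation), making reruns byte-identical.
#' @return Invisibly, a list: `retained`, `excluded`, `frequencies`,
#'   `comparison`, `store_path`, `manifest`.
#' @export
run_pipeline <- function(cohort = NULL, diplotypes_path = NULL,
                         admixture_path = NULL, out_dir,
                         threshold = ancestry_threshold(),
                         thresholds = decision_thresholds(),
                         reference = NULL,
                         population = "cohort",
                         tables = default_allele_function_tables(),
                         cutoffs = activity_score_cutoffs(),
                         pair_grids = default_function_pair_grids(),
                         grids = default_recommendation_grids(),
                         seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  inputs <- character(0)
  if (is.null(cohort)) {
    for (p in c(diplotypes_path, admixture_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("pipeline stage 'load': input path missing or nonexistent: ",
             if (is.null(p)) "(null)" else p, call. = FALSE)
      }
    }
    inputs <- c(diplotypes_path, admixture_path)
    cohort <- stage("load", list(
      samples = NULL,
      diplotypes = utils::read.delim(diplotypes_path, stringsAsFactors = FALSE)
    ))
    admixture <- stage("load", read_admixture(admixture_path))
  } else {
    admixture <- stage("load", {
      s <- cohort$samples
      validate_admixture(data.frame(individual_id = s$kit_id,
                                    s[setdiff(names(s),
                                              c("kit_id", "user_id", "timestamp",
                                                "age", "sex",
                                                "purchase_location"))]))
    })
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  sel <- stage("ancestry_filter", filter_cohort(admixture, threshold))
  dipl <- cohort$diplotypes
  dipl <- dipl[dipl$individual_id %in% sel$retained, , drop = FALSE]

  phen <- stage("phenotype", call_phenotypes(dipl, tables, cutoffs, pair_grids))
  rec <- stage("recommend", assign_recommendations(phen, grids = grids))

  store <- stage("aggregate", {
    samples <- cohort$samples
    if (is.null(samples)) {
      samples <- data.frame(kit_id = sel$retained)
    } else {
      samples <- samples[samples$kit_id %in% sel$retained, , drop = FALSE]
    }
    rec_kit <- rec
    names(rec_kit)[names(rec_kit) == "individual_id"] <- "kit_id"
    if (is.null(seed)) deidentify(samples, rec_kit)
    else withr::with_seed(seed, deidentify(samples, rec_kit))
  })
  store_path <- file.path(out_dir, "cohort_store.tsv")
  build_store(store, store_path)

  freq <- stage("frequency", frequency_table(rec, population,
                                             thresholds$confidence))
  comparison <- NULL
  if (!is.null(reference)) {
    comparison <- stage("compare", {
      shared <- intersect(unique(freq$context), unique(reference$context))
      compare_populations(freq[freq$context %in% shared, ],
                          reference[reference$context %in% shared, ],
                          thresholds)
    })
  }

  freq_path <- file.path(out_dir, "frequency_table.tsv")
  utils::write.table(freq, freq_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(comparison)) {
    cmp_path <- file.path(out_dir, "comparison_table.tsv")
    utils::write.table(as.data.frame(comparison), cmp_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(render_report(comparison, freq),
               file.path(out_dir, "report.txt"))
  }

  config_files <- vapply(c("allele_function_tables.tsv",
                           "function_pair_grids.yaml",
                           "recommendation_grids.yaml"),
                         pgx_extdata, character(1))
  manifest <- list(
    inputs = as.list(inputs),
    n_input = nrow(admixture),
    n_retained = length(sel$retained),
    threshold = unclass(threshold),
    thresholds = unclass(thresholds),
    seed = seed,
    config_checksums = as.list(tools::md5sum(config_files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(retained = sel$retained, excluded = sel$excluded,
                 frequencies = freq, comparison = comparison,
                 store_path = store_path, manifest = manifest))
}
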