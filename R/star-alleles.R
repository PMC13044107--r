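# Star-allele engine: diplotype parsing and gene-phenotype translation.

#' Parse a star-allele diplotype string
#'
#' Accepts the usual star-allele notation: two allele tokens separated by
#' `/`, each `*<digits>` with an optional copy-number suffix `x<digits>`
#' (e.g. `"*1x2/*5"` for a duplicated *1 over a whole-gene deletion).
#' Whitespace and a leading gene prefix (`"CYP2D6*1"`) are tolerated and
#' stripped; suballele letters are normalized to the numeric core
#' (`"*1A"` -> `"*1"`) because function is curated at the core-allele
#' level. The result is canonically ordered, so `*1/*10` and `*10/*1`
#' parse to the same object.
#'
#' @param gene One of CYP2D6, CYP2C19, CYP2B6, SLCO1B1.
#' @param text Diplotype string, e.g. `"*1/*10"`.
#' @return A `pgx_diplotype`: list with `gene`, `allele1`, `allele2`, each
#'   allele a list with `name` and `copies`.
#' @export
#' @examples
#' parse_diplotype("CYP2D6", "*1x2/*5")
parse_diplotype <- function(gene, text) {
  if (!is.character(gene) || length(gene) != 1L || !gene %in% PGX_GENES) {
    stop("gene must be one of: ", paste(PGX_GENES, collapse = ", "),
         call. = FALSE)
  }
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("diplotype must be a single string", call. = FALSE)
  }
  txt <- gsub("[[:space:]]+", "", text)
  parts <- strsplit(txt, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(nzchar(parts))) {
    stop("malformed diplotype '", text,
         "': expected exactly two alleles separated by '/'", call. = FALSE)
  }
  alleles <- lapply(parts, parse_star_allele, gene = gene)
  # canonical order: numeric core ascending, then copy number
  key <- vapply(alleles, function(a) {
    as.numeric(sub("\\*", "", a$name)) + a$copies / 1000
  }, numeric(1))
  alleles <- alleles[order(key)]
  structure(list(gene = gene, allele1 = alleles[[1]], allele2 = alleles[[2]]),
            class = "pgx_diplotype")
}

parse_star_allele <- function(token, gene) {
  m <- regexec("^([A-Za-z][A-Za-z0-9]*)?\\*([0-9]+)[A-Za-z]*(x([0-9]+))?$",
               token)
  g <- regmatches(token, m)[[1]]
  if (length(g) == 0L) {
    stop("malformed allele token '", token, "'", call. = FALSE)
  }
  prefix <- g[2]
  if (nzchar(prefix) && toupper(prefix) != toupper(gene)) {
    stop("allele token '", token, "' carries gene prefix '", prefix,
         "' but gene is ", gene, call. = FALSE)
  }
  copies <- if (nzchar(g[5])) as.integer(g[5]) else 1L
  if (copies < 1L) {
    stop("allele token '", token, "' has copy number 0", call. = FALSE)
  }
  list(name = paste0("*", g[3]), copies = copies)
}

format_diplotype <- function(d) {
  fmt <- function(a) paste0(a$name, if (a$copies > 1L) paste0("x", a$copies))
  paste0(fmt(d$allele1), "/", fmt(d$allele2))
}

#' @export
print.pgx_diplotype <- function(x, ...) {
  cat(x$gene, " ", format_diplotype(x), "\n", sep = "")
  invisible(x)
}

allele_row <- function(table, name) {
  i <- match(name, table$allele)
  if (is.na(i)) NULL else table[i, ]
}

#' CYP2D6 activity score of a diplotype
#'
#' The activity score is the copy-number-weighted sum of the two alleles'
#' activity values. It is undefined (`NA`) — not zero — whenever either
#' allele has uncertain/unknown function or is absent from the table, so
#' that unscorable diplotypes propagate to "Not determined" rather than
#' masquerading as poor metabolizers.
#'
#' @param d A `pgx_diplotype` with gene CYP2D6 (see [parse_diplotype()]).
#' @param table CYP2D6 allele-function table (one element of
#'   [default_allele_function_tables()]).
#' @return Non-negative numeric score, or `NA_real_`.
#' @export
#' @examples
#' tabs <- default_allele_function_tables()
#' activity_score(parse_diplotype("CYP2D6", "*10/*41"), tabs$CYP2D6)
activity_score <- function(d, table = default_allele_function_tables()$CYP2D6) {
  stopifnot(inherits(d, "pgx_diplotype"))
  if (d$gene != "CYP2D6") {
    stop("activity scores are defined for CYP2D6 only; got ", d$gene,
         call. = FALSE)
  }
  contribution <- function(a) {
    row <- allele_row(table, a$name)
    if (is.null(row) || row$function_class %in% UNSCORABLE_CLASSES ||
        is.na(row$activity_value)) {
      return(NA_real_)
    }
    a$copies * row$activity_value
  }
  v1 <- contribution(d$allele1)
  v2 <- contribution(d$allele2)
  if (is.na(v1) || is.na(v2)) NA_real_ else v1 + v2
}

gene_phenotype <- function(gene, phenotype, activity_score = NA_real_) {
  structure(list(gene = gene, phenotype = phenotype,
                 activity_score = activity_score),
            class = "pgx_phenotype")
}

#' @export
print.pgx_phenotype <- function(x, ...) {
  cat(x$gene, ": ", x$phenotype,
      if (!is.na(x$activity_score)) sprintf(" (AS = %g)", x$activity_score),
      "\n", sep = "")
  invisible(x)
}

#' Bin a CYP2D6 activity score into a metabolizer phenotype
#'
#' Score `<= pm_max` is Poor, `(pm_max, im_max)` Intermediate,
#' `[im_max, nm_max]` Normal (both bounds inclusive), above `nm_max`
#' Ultrarapid. An undefined score is Indeterminate.
#'
#' @param score Numeric activity score or `NA`.
#' @param cutoffs See [activity_score_cutoffs()].
#' @return A `pgx_phenotype` for CYP2D6 carrying the score.
#' @export
#' @examples
#' phenotype_from_activity_score(1.25)$phenotype  # "Normal"
phenotype_from_activity_score <- function(score,
                                          cutoffs = activity_score_cutoffs()) {
  stopifnot(inherits(cutoffs, "pgx_cutoffs"))
  if (is.null(score) || length(score) != 1L || is.na(score)) {
    return(gene_phenotype("CYP2D6", "Indeterminate"))
  }
  if (score < 0) stop("activity score must be non-negative", call. = FALSE)
  label <-
    if (score <= cutoffs$pm_max) "Poor"
    else if (score < cutoffs$im_max) "Intermediate"
    else if (score <= cutoffs$nm_max) "Normal"
    else "Ultrarapid"
  gene_phenotype("CYP2D6", label, activity_score = score)
}

#' Gene phenotype from the unordered pair of allele function classes
#'
#' For CYP2C19, CYP2B6 and SLCO1B1 the phenotype is a CPIC-style lookup on
#' the unordered pair of the two alleles' function classes. Any allele of
#' uncertain/unknown function, or missing from the function table, yields
#' Indeterminate. CYP2D6 must use the activity-score path instead.
#'
#' @param d A `pgx_diplotype`.
#' @param table The gene's allele-function table.
#' @param grid The gene's pair grid (one element of
#'   [default_function_pair_grids()]).
#' @return A `pgx_phenotype`.
#' @export
phenotype_from_function_pair <- function(d,
                                         table = default_allele_function_tables()[[d$gene]],
                                         grid = default_function_pair_grids()[[d$gene]]) {
  stopifnot(inherits(d, "pgx_diplotype"))
  if (d$gene == "CYP2D6") {
    stop("CYP2D6 phenotypes come from the activity-score path", call. = FALSE)
  }
  cls <- function(a) {
    row <- allele_row(table, a$name)
    if (is.null(row)) NA_character_ else row$function_class
  }
  c1 <- cls(d$allele1)
  c2 <- cls(d$allele2)
  if (is.na(c1) || is.na(c2) ||
      c1 %in% UNSCORABLE_CLASSES || c2 %in% UNSCORABLE_CLASSES) {
    return(gene_phenotype(d$gene, "Indeterminate"))
  }
  key <- paste(sort(c(c1, c2), method = "radix"), collapse = "|")
  cell <- grid[[key]]
  if (is.null(cell)) {
    stop(d$gene, ": pair grid has no cell for (", c1, ", ", c2, ")",
         call. = FALSE)
  }
  gene_phenotype(d$gene, cell)
}

#' Translate a diplotype into its gene phenotype
#'
#' Dispatches to the activity-score path for CYP2D6 and the function-pair
#' path otherwise.
#'
#' @inheritParams phenotype_from_function_pair
#' @param tables Full set of allele-function tables.
#' @param cutoffs See [activity_score_cutoffs()].
#' @param pair_grids Full set of pair grids.
#' @return A `pgx_phenotype`.
#' @export
#' @examples
#' diplotype_phenotype(parse_diplotype("CYP2D6", "*1/*10"))$phenotype
diplotype_phenotype <- function(d,
                                tables = default_allele_function_tables(),
                                cutoffs = activity_score_cutoffs(),
                                pair_grids = default_function_pair_grids()) {
  stopifnot(inherits(d, "pgx_diplotype"))
  if (d$gene == "CYP2D6") {
    phenotype_from_activity_score(activity_score(d, tables$CYP2D6), cutoffs)
  } else {
    phenotype_from_function_pair(d, tables[[d$gene]], pair_grids[[d$gene]])
  }
}

#' Phenotype every diplotype record in a cohort table
#'
#' Vectorized over a long-format diplotype table; distinct (gene,
#' diplotype) strings are scored once and mapped back, so cohorts of tens
#' of thousands of records stay fast.
#'
#' @param diplotypes Data frame with columns `individual_id`, `gene`,
#'   `diplotype`.
#' @inheritParams diplotype_phenotype
#' @return Data frame with columns `individual_id`, `gene`, `phenotype`,
#'   `activity_score`.
#' @export
call_phenotypes <- function(diplotypes,
                            tables = default_allele_function_tables(),
                            cutoffs = activity_score_cutoffs(),
                            pair_grids = default_function_pair_grids()) {
  required <- c("individual_id", "gene", "diplotype")
  if (!all(required %in% names(diplotypes))) {
    stop("diplotype table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  key <- paste(diplotypes$gene, diplotypes$diplotype, sep = "\r")
  uniq <- !duplicated(key)
  lookup <- lapply(which(uniq), function(i) {
    d <- parse_diplotype(diplotypes$gene[i], diplotypes$diplotype[i])
    diplotype_phenotype(d, tables, cutoffs, pair_grids)
  })
  names(lookup) <- key[uniq]
  data.frame(
    individual_id = diplotypes$individual_id,
    gene = diplotypes$gene,
    phenotype = vapply(lookup[key], `[[`, character(1), "phenotype"),
    activity_score = vapply(lookup[key], `[[`, numeric(1), "activity_score"),
    row.names = NULL
  )
}
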