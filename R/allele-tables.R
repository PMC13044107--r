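# Allele-function tables and diplotype/phenotype lookup grids.
#
# All lookup configuration ships as editable text under inst/extdata and is
# validated on load; checksums of the active files are recorded in pipeline
# run manifests so a result can always be tied to the exact tables used.

FUNCTION_CLASSES <- c("normal", "decreased", "no_function", "increased",
                      "uncertain", "unknown")
UNSCORABLE_CLASSES <- c("uncertain", "unknown")

pgx_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pgxpop")
  if (!nzchar(path)) stop("bundled config file not found: ", file, call. = FALSE)
  path
}

#' Read an allele-function table
#'
#' The table assigns each star allele a curated function class and, for
#' CYP2D6, an activity value (normal = 1, decreased in (0,1),
#' no function = 0). Alleles of class `uncertain` or `unknown` carry no
#' activity value and make any diplotype containing them unscorable.
#'
#' @param path TSV with columns `gene`, `allele`, `function_class`,
#'   `activity_value`.
#' @return Named list of per-gene data frames (columns `allele`,
#'   `function_class`, `activity_value`).
#' @export
read_allele_function_tables <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "allele", "function_class", "activity_value")
  if (!all(required %in% names(df))) {
    stop("allele-function table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  df$activity_value <- suppressWarnings(as.numeric(df$activity_value))
  bad <- !df$function_class %in% FUNCTION_CLASSES
  if (any(bad)) {
    stop("unknown function class: ",
         paste(unique(df$function_class[bad]), collapse = ", "), call. = FALSE)
  }
  tabs <- split(df[c("allele", "function_class", "activity_value")], df$gene)
  for (gene in names(tabs)) validate_function_table(gene, tabs[[gene]])
  lapply(tabs, function(t) { rownames(t) <- NULL; t })
}

validate_function_table <- function(gene, tab) {
  if (anyDuplicated(tab$allele)) {
    stop(gene, ": duplicated allele in function table", call. = FALSE)
  }
  unscored <- tab$function_class %in% UNSCORABLE_CLASSES
  if (any(!is.na(tab$activity_value[unscored]))) {
    stop(gene, ": uncertain/unknown alleles must not carry activity values",
         call. = FALSE)
  }
  if (gene == "CYP2D6") {
    scored <- !unscored
    v <- tab$activity_value[scored]
    cl <- tab$function_class[scored]
    if (anyNA(v)) stop("CYP2D6: scored alleles need an activity value", call. = FALSE)
    ok <- (cl == "normal" & v == 1) |
      (cl == "no_function" & v == 0) |
      (cl == "decreased" & v > 0 & v < 1) |
      (cl == "increased" & v > 1)
    if (!all(ok)) {
      stop("CYP2D6: activity value inconsistent with function class for ",
           paste(tab$allele[scored][!ok], collapse = ", "), call. = FALSE)
    }
  }
  invisible(tab)
}

#' Default allele-function tables bundled with the package
#'
#' CYP2D6 activity values follow current CPIC assignments for the common
#' Japanese alleles (*1 = *2 = 1.0, *10 = 0.25, *41 = 0.5, *5 = *14 = 0).
#'
#' @return See [read_allele_function_tables()].
#' @export
default_allele_function_tables <- function() {
  read_allele_function_tables(pgx_extdata("allele_function_tables.tsv"))
}

#' Read unordered function-pair phenotype grids
#'
#' For CYP2C19, CYP2B6 and SLCO1B1 the gene phenotype is a lookup on the
#' unordered pair of the two alleles' function classes. Grid keys are
#' stored canonically sorted, so allele order can never matter.
#'
#' @param path YAML file with a `grids` map of gene -> pair -> phenotype.
#' @return Named list of per-gene named lists.
#' @export
read_function_pair_grids <- function(path) {
  cfg <- yaml::read_yaml(path)
  grids <- cfg$grids
  for (gene in names(grids)) {
    vocab <- phenotype_vocabulary(gene)
    cells <- grids[[gene]]
    keys <- names(cells)
    resorted <- vapply(strsplit(keys, "|", fixed = TRUE), function(p) {
      paste(sort(p, method = "radix"), collapse = "|")
    }, character(1))
    if (!identical(keys, resorted)) {
      stop(gene, ": pair-grid keys must be canonically sorted", call. = FALSE)
    }
    bad <- !unlist(cells) %in% vocab
    if (any(bad)) {
      stop(gene, ": pair grid assigns out-of-vocabulary phenotype(s): ",
           paste(unique(unlist(cells)[bad]), collapse = ", "), call. = FALSE)
    }
    scorable <- setdiff(FUNCTION_CLASSES, UNSCORABLE_CLASSES)
    for (a in scorable) for (b in scorable) {
      key <- paste(sort(c(a, b), method = "radix"), collapse = "|")
      if (is.null(cells[[key]])) {
        stop(gene, ": pair grid missing cell for (", a, ", ", b, ")",
             call. = FALSE)
      }
    }
  }
  grids
}

#' @rdname read_function_pair_grids
#' @export
default_function_pair_grids <- function() {
  read_function_pair_grids(pgx_extdata("function_pair_grids.yaml"))
}

#' Activity-score cutoffs for CYP2D6 metabolizer phenotypes
#'
#' The recalibrated CPIC scheme: Poor at score 0, Intermediate on
#' (0, 1.25), Normal on \[1.25, 2.25\], Ultrarapid above 2.25. All three
#' bounds are configurable; the ordering invariant is enforced.
#'
#' @param pm_max Inclusive upper bound for Poor (default 0).
#' @param im_max Exclusive upper bound for Intermediate (default 1.25).
#' @param nm_max Inclusive upper bound for Normal (default 2.25).
#' @return A list with class `pgx_cutoffs`.
#' @export
#' @examples
#' activity_score_cutoffs()
activity_score_cutoffs <- function(pm_max = 0, im_max = 1.25, nm_max = 2.25) {
  stopifnot(is.numeric(pm_max), is.numeric(im_max), is.numeric(nm_max))
  if (!(pm_max < im_max && im_max < nm_max)) {
    stop("cutoffs must satisfy pm_max < im_max < nm_max", call. = FALSE)
  }
  structure(list(pm_max = pm_max, im_max = im_max, nm_max = nm_max),
            class = "pgx_cutoffs")
}
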