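# Privacy-conscious aggregate cohort store.
#
# Individual results arrive keyed by kit id (with a user linkage and
# timestamps living elsewhere in the commercial system). The aggregate
# store keeps only what population-level analysis needs — age, sex,
# purchase location, and the per-context recommendations — under a freshly
# generated generic id, so a leak of the store cannot be linked back to a
# person. The store is a single plain-text file holding two relational
# tables (cohort, recommendation) with a fixed, introspectable schema.

STORE_COHORT_FIELDS <- c("generic_id", "age", "sex", "purchase_location")
STORE_REC_FIELDS <- c("generic_id", "context", "category")
STORE_MAGIC <- "#%pgxstore 1"

random_generic_id <- function(n) {
  hex <- c(0:9, letters[1:6])
  vapply(seq_len(n), function(i) {
    paste(sample(hex, 16, replace = TRUE), collapse = "")
  }, character(1))
}

#' De-identify raw cohort records
#'
#' Strips every identifying field: kit ids are replaced by freshly
#' generated random generic ids (the kit-to-generic mapping is held only
#' in memory and never written out), user linkage and timestamps are
#' dropped, and only age, sex and purchase location survive as
#' demographics. Recommendation categories are validated against the
#' six-category vocabulary.
#'
#' @param samples Data frame with at least `kit_id`; optionally `age`,
#'   `sex`, `purchase_location` (plus any identifying columns, which are
#'   discarded).
#' @param recommendations Data frame `kit_id`, `context`, `category`.
#' @return A `pgx_cohort_store`: list of data frames `cohort`
#'   (generic_id, age, sex, purchase_location) and `recommendation`
#'   (generic_id, context, category).
#' @export
deidentify <- function(samples, recommendations) {
  if (!"kit_id" %in% names(samples)) {
    stop("samples must carry a kit_id column", call. = FALSE)
  }
  if (anyDuplicated(samples$kit_id)) {
    stop("duplicate kit id: ",
         samples$kit_id[duplicated(samples$kit_id)][1], call. = FALSE)
  }
  if (!all(c("kit_id", "context", "category") %in% names(recommendations))) {
    stop("recommendations must have columns kit_id, context, category",
         call. = FALSE)
  }
  bad <- !recommendations$category %in% recommendation_categories()
  if (any(bad)) {
    stop("out-of-vocabulary recommendation category: ",
         unique(recommendations$category[bad])[1], call. = FALSE)
  }
  orphan <- !recommendations$kit_id %in% samples$kit_id
  if (any(orphan)) {
    stop("recommendation for unknown kit id: ",
         unique(recommendations$kit_id[orphan])[1], call. = FALSE)
  }
  n <- nrow(samples)
  gid <- random_generic_id(n)
  while (anyDuplicated(gid)) gid[duplicated(gid)] <- random_generic_id(sum(duplicated(gid)))
  id_map <- stats::setNames(gid, samples$kit_id)
  opt <- function(col) {
    if (col %in% names(samples)) samples[[col]] else rep(NA, n)
  }
  cohort <- data.frame(
    generic_id = unname(gid),
    age = as.integer(opt("age")),
    sex = as.character(opt("sex")),
    purchase_location = as.character(opt("purchase_location")),
    stringsAsFactors = FALSE
  )
  rec <- data.frame(
    generic_id = unname(id_map[as.character(recommendations$kit_id)]),
    context = recommendations$context,
    category = recommendations$category,
    stringsAsFactors = FALSE
  )
  structure(list(cohort = cohort, recommendation = rec),
            class = "pgx_cohort_store")
}

#' @export
print.pgx_cohort_store <- function(x, ...) {
  cat("pgx cohort store:", nrow(x$cohort), "individuals,",
      nrow(x$recommendation), "recommendation rows\n")
  invisible(x)
}

#' Store schema (for introspection)
#'
#' @param store A `pgx_cohort_store` or a path to a store file.
#' @return Named list of column-name vectors, one per table.
#' @export
store_schema <- function(store) {
  if (is.character(store)) store <- read_store(store)
  lapply(store, names)
}

write_store_table <- function(con, name, df) {
  writeLines(paste0("#%table ", name), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' Write the aggregate store to a single file
#'
#' Serializes both tables (cohort, recommendation) into one plain-text
#' file; [read_store()] round-trips it exactly.
#'
#' @param store A `pgx_cohort_store`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
build_store <- function(store, path) {
  stopifnot(inherits(store, "pgx_cohort_store"))
  if (!identical(names(store$cohort), STORE_COHORT_FIELDS) ||
      !identical(names(store$recommendation), STORE_REC_FIELDS)) {
    stop("store violates the privacy schema", call. = FALSE)
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write store to '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(STORE_MAGIC, con)
  write_store_table(con, "cohort", store$cohort)
  write_store_table(con, "recommendation", store$recommendation)
  invisible(path)
}

#' Read an aggregate store file
#'
#' @param path Store file written by [build_store()].
#' @return A `pgx_cohort_store`.
#' @export
read_store <- function(path) {
  if (!file.exists(path)) stop("no store file at '", path, "'", call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != STORE_MAGIC) {
    stop("'", path, "' is not a pgx cohort store", call. = FALSE)
  }
  marks <- grep("^#%table ", lines)
  tables <- list()
  for (i in seq_along(marks)) {
    name <- sub("^#%table ", "", lines[marks[i]])
    from <- marks[i] + 1L
    to <- if (i < length(marks)) marks[i + 1L] - 1L else length(lines)
    tables[[name]] <- utils::read.delim(
      text = paste(lines[from:to], collapse = "\n"),
      stringsAsFactors = FALSE, na.strings = ""
    )
  }
  if (!all(c("cohort", "recommendation") %in% names(tables))) {
    stop("store file is missing a required table", call. = FALSE)
  }
  tables$cohort$age <- as.integer(tables$cohort$age)
  tables$cohort$sex <- as.character(tables$cohort$sex)
  tables$cohort$purchase_location <- as.character(tables$cohort$purchase_location)
  if (nrow(tables$recommendation)) {
    for (col in STORE_REC_FIELDS) {
      tables$recommendation[[col]] <- as.character(tables$recommendation[[col]])
    }
  }
  structure(tables[c("cohort", "recommendation")], class = "pgx_cohort_store")
}

#' Query recommendation frequencies from the store
#'
#' Computes a frequency table over the records matching all supplied
#' demographic filters. An empty selection is an error, never a 0/0
#' frequency.
#'
#' @param store A `pgx_cohort_store` (or store file path).
#' @param context Optional drug-context id(s) to restrict to.
#' @param age_range Optional `c(min, max)`, inclusive.
#' @param sex Optional sex label(s).
#' @param location Optional purchase-location label(s).
#' @param population Population label on the output (default "cohort").
#' @param confidence Confidence level for Wilson intervals.
#' @return See [frequency_table()].
#' @export
query_frequencies <- function(store, context = NULL, age_range = NULL,
                              sex = NULL, location = NULL,
                              population = "cohort", confidence = 0.95) {
  if (is.character(store)) store <- read_store(store)
  stopifnot(inherits(store, "pgx_cohort_store"))
  if (!is.null(context)) {
    unknown <- setdiff(context, names(drug_contexts()))
    if (length(unknown)) stop("unknown drug context: ", unknown[1], call. = FALSE)
  }
  keep <- rep(TRUE, nrow(store$cohort))
  if (!is.null(age_range)) {
    stopifnot(length(age_range) == 2L)
    keep <- keep & !is.na(store$cohort$age) &
      store$cohort$age >= age_range[1] & store$cohort$age <= age_range[2]
  }
  if (!is.null(sex)) keep <- keep & store$cohort$sex %in% sex
  if (!is.null(location)) keep <- keep & store$cohort$purchase_location %in% location
  ids <- store$cohort$generic_id[keep]
  if (length(ids) == 0L) stop("empty selection: no records match the filters",
                              call. = FALSE)
  rec <- store$recommendation[store$recommendation$generic_id %in% ids, ,
                              drop = FALSE]
  if (!is.null(context)) rec <- rec[rec$context %in% context, , drop = FALSE]
  if (nrow(rec) == 0L) stop("empty selection: no recommendation rows match",
                            call. = FALSE)
  names(rec)[names(rec) == "generic_id"] <- "individual_id"
  frequency_table(rec, population = population, confidence = confidence)
}
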