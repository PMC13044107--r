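# Recommendation mapper: phenotypes -> one of six harmonized categories.

#' Read recommendation grids
#'
#' A grid assigns a recommendation category to every combination of
#' in-vocabulary phenotypes for a drug context's genes (one phenotype per
#' gene, in context order). Totality is validated on load; tuples
#' containing Indeterminate or a missing gene are handled before the grid
#' ("Not determined" / "No call") and are not stored in it.
#'
#' @param path YAML file with a `contexts` map; each context has `genes`
#'   and `cells`.
#' @return Named list of contexts, each `list(genes=, cells=)`.
#' @export
read_recommendation_grids <- function(path) {
  cfg <- yaml::read_yaml(path)
  grids <- cfg$contexts
  canon <- drug_contexts()
  for (ctx in names(grids)) {
    genes <- unlist(grids[[ctx]]$genes)
    if (!is.null(canon[[ctx]]) && !identical(genes, canon[[ctx]])) {
      stop(ctx, ": grid gene list ", paste(genes, collapse = ","),
           " does not match the context definition", call. = FALSE)
    }
    cells <- grids[[ctx]]$cells
    bad <- !unlist(cells) %in% recommendation_categories()
    if (any(bad)) {
      stop(ctx, ": grid assigns out-of-vocabulary categories: ",
           paste(unique(unlist(cells)[bad]), collapse = "; "), call. = FALSE)
    }
    combos <- expand.grid(lapply(genes, phenotype_vocabulary),
                          stringsAsFactors = FALSE)
    keys <- do.call(paste, c(combos, sep = "|"))
    missing <- keys[!keys %in% names(cells)]
    if (length(missing)) {
      stop(ctx, ": grid missing cells for ", length(missing),
           " phenotype combination(s), e.g. ", missing[1], call. = FALSE)
    }
    grids[[ctx]]$genes <- genes
  }
  grids
}

#' @rdname read_recommendation_grids
#' @export
default_recommendation_grids <- function() {
  read_recommendation_grids(pgx_extdata("recommendation_grids.yaml"))
}

extract_phenotype_label <- function(x) {
  if (inherits(x, "pgx_phenotype")) x$phenotype
  else if (is.character(x) && length(x) == 1L) x
  else NA_character_
}

#' Map per-gene phenotypes to a recommendation category
#'
#' Applies, in order: "No call" if any required gene has no phenotype
#' record at all; "Not determined" if any required phenotype is
#' Indeterminate; otherwise the grid cell for the phenotype tuple.
#'
#' @param context Drug-context id (see [drug_contexts()]).
#' @param phenotypes Named list or character vector, gene -> phenotype
#'   label (or `pgx_phenotype`); a gene absent from the names, or mapped to
#'   `NA`, counts as missing.
#' @param grids Recommendation grids (see
#'   [default_recommendation_grids()]).
#' @return One of [recommendation_categories()].
#' @export
#' @examples
#' recommend("codeine_tramadol", c(CYP2D6 = "Normal"))
#' recommend("sertraline", c(CYP2B6 = "Poor", CYP2C19 = "Normal"))
recommend <- function(context, phenotypes,
                      grids = default_recommendation_grids()) {
  genes <- context_genes(context)
  labels <- vapply(genes, function(g) {
    if (!g %in% names(phenotypes)) NA_character_
    else extract_phenotype_label(phenotypes[[g]])
  }, character(1))
  if (anyNA(labels)) return("No call")
  if (any(labels == "Indeterminate")) return("Not determined")
  grid <- grids[[context]]
  if (is.null(grid)) stop("no grid for context '", context, "'", call. = FALSE)
  key <- paste(labels, collapse = "|")
  cell <- grid$cells[[key]]
  if (is.null(cell)) {
    stop(context, ": no grid cell for phenotype tuple (", key, ")",
         call. = FALSE)
  }
  cell
}

#' Assign recommendations for every individual and drug context
#'
#' @param phenotypes Output of [call_phenotypes()] (columns
#'   `individual_id`, `gene`, `phenotype`).
#' @param contexts Character vector of context ids (default: all six).
#' @inheritParams recommend
#' @return Long data frame `individual_id`, `context`, `category`.
#' @export
assign_recommendations <- function(phenotypes,
                                   contexts = names(drug_contexts()),
                                   grids = default_recommendation_grids()) {
  ids <- unique(phenotypes$individual_id)
  # per-individual gene -> phenotype label
  ph_key <- paste(phenotypes$individual_id, phenotypes$gene, sep = "\r")
  if (anyDuplicated(ph_key)) {
    stop("multiple phenotype records for the same individual and gene",
         call. = FALSE)
  }
  ph_map <- stats::setNames(phenotypes$phenotype, ph_key)
  out <- lapply(contexts, function(ctx) {
    genes <- context_genes(ctx)
    labels <- vapply(genes, function(g) {
      unname(ph_map[paste(ids, g, sep = "\r")])
    }, character(length(ids)))
    labels <- matrix(labels, nrow = length(ids))
    cat <- rep(NA_character_, length(ids))
    missing <- rowSums(is.na(labels)) > 0
    indet <- !missing & rowSums(labels == "Indeterminate") > 0
    cat[missing] <- "No call"
    cat[indet] <- "Not determined"
    rest <- !missing & !indet
    if (any(rest)) {
      keys <- do.call(paste, c(as.data.frame(labels[rest, , drop = FALSE]),
                               sep = "|"))
      cells <- grids[[ctx]]$cells
      if (is.null(cells)) stop("no grid for context '", ctx, "'", call. = FALSE)
      hit <- unlist(cells[keys], use.names = FALSE)
      if (length(hit) != sum(rest)) {
        stop(ctx, ": phenotype tuple(s) without a grid cell", call. = FALSE)
      }
      cat[rest] <- hit
    }
    data.frame(individual_id = ids, context = ctx, category = cat,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Convert an external diplotype frequency table into recommendation
#' frequencies
#'
#' Published genotyping studies often report per-diplotype counts rather
#' than phenotypes. This scores each diplotype (activity score or pair
#' lookup, then grid), sums the counts per recommendation category, and
#' returns proportions — the conversion used to compare externally
#' published CYP2D6 diplotype tables against recommendation-frequency
#' tables.
#'
#' @param context Single-gene drug-context id.
#' @param rows Data frame with columns `diplotype` and `count`
#'   (non-negative integers).
#' @inheritParams diplotype_phenotype
#' @param grids Recommendation grids.
#' @return Data frame `category`, `count`, `proportion` (categories with
#'   zero mass omitted).
#' @export
#' @examples
#' convert_diplotype_table("codeine_tramadol",
#'   data.frame(diplotype = c("*1/*1", "*10/*10"), count = c(50, 50)))
convert_diplotype_table <- function(context, rows,
                                    tables = default_allele_function_tables(),
                                    cutoffs = activity_score_cutoffs(),
                                    pair_grids = default_function_pair_grids(),
                                    grids = default_recommendation_grids()) {
  genes <- context_genes(context)
  if (length(genes) != 1L) {
    stop("convert_diplotype_table requires a single-gene context", call. = FALSE)
  }
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("empty diplotype table", call. = FALSE)
  }
  if (!all(c("diplotype", "count") %in% names(rows))) {
    stop("rows must have columns 'diplotype' and 'count'", call. = FALSE)
  }
  if (any(is.na(rows$count)) || any(rows$count < 0) ||
      any(rows$count != round(rows$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  gene <- genes[1]
  cats <- vapply(seq_len(nrow(rows)), function(i) {
    d <- tryCatch(parse_diplotype(gene, rows$diplotype[i]),
                  error = function(e) {
                    stop("row ", i, " ('", rows$diplotype[i], "'): ",
                         conditionMessage(e), call. = FALSE)
                  })
    ph <- diplotype_phenotype(d, tables, cutoffs, pair_grids)
    recommend(context, stats::setNames(list(ph), gene), grids)
  }, character(1))
  total <- sum(rows$count)
  if (total == 0L) stop("diplotype table has zero total count", call. = FALSE)
  counts <- tapply(rows$count, factor(cats, levels = recommendation_categories()),
                   sum, default = 0)
  keep <- counts > 0
  data.frame(category = names(counts)[keep],
             count = as.integer(counts[keep]),
             proportion = as.numeric(counts[keep]) / total,
             row.names = NULL)
}
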