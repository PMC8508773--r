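#' Construct a validated Ct matrix
#'
#' A `ct_matrix` is the universal input of the stability pipeline: a numeric
#' genes x samples matrix of RT-qPCR quantification-cycle (Ct) values.
#' Validation enforces finite Ct in (0, 45] (a 40-cycle protocol plus
#' headroom), unique gene and sample identifiers, and at least 2 genes and
#' 2 samples.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, or a
#'   data frame with one identifier column (see [as_ct_matrix()] for data
#'   frames).
#' @param genes,samples Optional character vectors overriding the dimnames.
#' @return A `ct_matrix` object (numeric matrix with class attribute).
#' @examples
#' m <- matrix(c(24, 25, 26, 23, 23.5, 24), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' ct_matrix(m)
#' @export
ct_matrix <- function(values, genes = rownames(values), samples = colnames(values)) {
  if (is.data.frame(values)) {
    return(as_ct_matrix(values))
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(genes) || is.null(samples)) {
    abort("gene and sample identifiers are required (row/column names).")
  }
  genes <- as.character(genes)
  samples <- as.character(samples)
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene ids: %s",
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample ids: %s",
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  if (nrow(values) < 2L || ncol(values) < 2L) {
    abort("a ct_matrix needs at least 2 genes and 2 samples.")
  }
  bad <- which(!is.finite(values) | values <= 0 | values > 45, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "non-finite or out-of-range Ct (must be in (0, 45]) at (gene, sample): %s",
      paste(sprintf("(%s, %s)", genes[bad[, 1L]], samples[bad[, 2L]])[
        seq_len(min(5L, nrow(bad)))], collapse = ", ")))
  }
  dimnames(values) <- list(genes, samples)
  structure(values, class = c("ct_matrix", "matrix", "array"))
}

#' Coerce a wide table of Ct values to a `ct_matrix`
#'
#' @param x Data frame whose first column holds identifiers and remaining
#'   columns numeric Ct values, or a numeric matrix.
#' @param orientation Either `"genes-as-rows"` (identifier column holds gene
#'   names) or `"samples-as-rows"`. Never guessed.
#' @return A [ct_matrix()].
#' @export
as_ct_matrix <- function(x, orientation = c("genes-as-rows", "samples-as-rows")) {
  orientation <- match.arg(orientation)
  if (inherits(x, "ct_matrix")) return(x)
  if (is.matrix(x)) return(ct_matrix(x))
  if (!is.data.frame(x)) abort("`x` must be a data frame or matrix.")
  ids <- as.character(x[[1L]])
  num <- x[-1L]
  not_num <- !vapply(num, is.numeric, logical(1L))
  if (any(not_num)) {
    bad <- which(not_num)[1L]
    col <- names(num)[bad]
    raw <- num[[bad]]
    cell <- which(is.na(suppressWarnings(as.numeric(as.character(raw)))))[1L]
    abort(sprintf("non-numeric Ct in column '%s'%s", col,
                  if (!is.na(cell)) sprintf(" (row id '%s')", ids[cell]) else ""))
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "samples-as-rows") m <- t(m)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    abort(sprintf(
      "missing Ct at (gene, sample): %s. Use read_ct_table(missing = \"impute\") with an annotation for replicate-mean imputation.",
      paste(sprintf("(%s, %s)", rownames(m)[bad[, 1L]], colnames(m)[bad[, 2L]])[
        seq_len(min(5L, nrow(bad)))], collapse = ", ")))
  }
  ct_matrix(m)
}

#' Read a Ct table from a delimited file
#'
#' Reads a CSV/TSV file with one header row and one identifier column and
#' returns a validated [ct_matrix()]. The table orientation must be stated
#' explicitly. Missing cells are rejected by default; with
#' `missing = "impute"` and a sample annotation, each missing value is
#' replaced by the mean of its gene's other replicates within the same
#' (cultivar, sample_class) cell.
#'
#' @param path File path; delimiter inferred from extension (`.csv` comma,
#'   otherwise tab).
#' @inheritParams as_ct_matrix
#' @param missing `"reject"` (default) or `"impute"`.
#' @param annotation Sample annotation tibble (required for imputation), as
#'   returned by [read_sample_annotation()].
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, orientation = c("genes-as-rows", "samples-as-rows"),
                          missing = c("reject", "impute"), annotation = NULL) {
  orientation <- match.arg(orientation)
  missing <- match.arg(missing)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # base parser: strtod round-trips doubles written at full precision exactly
  df <- utils::read.delim(path, sep = delim, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (missing == "reject" || !anyNA(df[-1L])) {
    return(as_ct_matrix(df, orientation))
  }
  if (is.null(annotation)) {
    abort("missing-value imputation requires `annotation`.")
  }
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  rownames(m) <- ids
  if (orientation == "samples-as-rows") m <- t(m)
  m <- impute_replicate_means(m, annotation)
  ct_matrix(m)
}

# Replicate-mean imputation within (cultivar, sample_class) cells.
impute_replicate_means <- function(m, annotation) {
  validate_annotation(annotation, colnames(m))
  cell <- setNames(paste(annotation$cultivar, annotation$sample_class),
                   annotation$sample_id)
  bad <- which(is.na(m), arr.ind = TRUE)
  for (i in seq_len(nrow(bad))) {
    g <- bad[i, 1L]; s <- bad[i, 2L]
    mates <- colnames(m)[cell[colnames(m)] == cell[colnames(m)[s]]]
    vals <- m[g, setdiff(mates, colnames(m)[s])]
    if (all(is.na(vals))) {
      abort(sprintf("cannot impute (%s, %s): no observed replicate in its (cultivar, sample_class) cell.",
                    rownames(m)[g], colnames(m)[s]))
    }
    m[g, s] <- mean(vals, na.rm = TRUE)
  }
  m
}

#' Read a sample annotation table
#'
#' Expects columns `sample_id`, `cultivar`, `sample_class`, `replicate`.
#' (cultivar, sample_class, replicate) triples must be unique.
#'
#' @param path CSV/TSV file path.
#' @return A tibble.
#' @export
read_sample_annotation <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ann <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_annotation(ann)
  tibble::as_tibble(ann)
}

validate_annotation <- function(ann, sample_ids = NULL) {
  need <- c("sample_id", "cultivar", "sample_class", "replicate")
  miss <- setdiff(need, names(ann))
  if (length(miss)) abort(sprintf("annotation lacks column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(ann$sample_id)) abort("annotation has duplicated sample_id.")
  trip <- paste(ann$cultivar, ann$sample_class, ann$replicate)
  if (anyDuplicated(trip)) abort("annotation has duplicated (cultivar, sample_class, replicate) triples.")
  if (any(ann$replicate <= 0)) abort("replicate must be a positive integer.")
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, ann$sample_id)
    if (length(miss)) {
      abort(sprintf("samples absent from annotation: %s",
                    paste(head(miss, 5L), collapse = ", ")))
    }
  }
  invisible(ann)
}

#' Subset samples of a Ct matrix by annotation predicate
#'
#' Forms an analysis group: the sub-matrix of samples (in input order) whose
#' annotation rows satisfy the predicate, e.g.
#' `subset_ct(ct, ann, cultivar != "blackberry")`.
#'
#' @param ct A [ct_matrix()].
#' @param annotation Annotation tibble covering all samples of `ct`.
#' @param ... Logical predicates over annotation columns (tidy evaluation, as
#'   in `dplyr::filter()`). Omit to keep every sample.
#' @param name Optional group label stored on the result.
#' @return A `ct_matrix` restricted to the matching samples, with attributes
#'   `group_name` and `annotation` (the matching annotation rows).
#' @export
subset_ct <- function(ct, annotation, ..., name = NULL) {
  ct <- as_ct_matrix(ct)
  validate_annotation(annotation, colnames(ct))
  ann <- annotation[match(colnames(ct), annotation$sample_id), , drop = FALSE]
  keep <- dplyr::filter(ann, ...)
  if (nrow(keep) == 0L) abort("selector matched no samples.")
  if (nrow(keep) < 2L) abort("selector must match at least 2 samples.")
  out <- ct_matrix(unclass(ct)[, keep$sample_id, drop = FALSE])
  attr(out, "group_name") <- name
  attr(out, "annotation") <- tibble::as_tibble(keep)
  out
}

#' Relative quantities from Ct values
#'
#' Transforms Ct to the unitless relative quantities required by geNorm and
#' NormFinder: per gene g and sample s, `Q_gs = E_g^(min_s' Ct_gs' - Ct_gs)`,
#' so the sample with the lowest Ct (most template) of each gene has Q = 1
#' exactly. E is the amplification efficiency (2 = perfect doubling).
#'
#' @param ct A [ct_matrix()].
#' @param efficiency Scalar or per-gene named vector in [1.5, 2.2].
#' @return An `rq_matrix` (genes x samples, values in (0, 1]).
#' @examples
#' ct <- ct_matrix(matrix(c(24, 25, 26, 23, 23, 23), nrow = 2, byrow = TRUE,
#'                 dimnames = list(c("a", "b"), c("s1", "s2", "s3"))))
#' relative_quantities(ct)["a", ]   # 1, 0.5, 0.25
#' @export
relative_quantities <- function(ct, efficiency = 2) {
  ct <- as_ct_matrix(ct)
  k <- nrow(ct)
  if (length(efficiency) == 1L) {
    eff <- rep(efficiency, k)
  } else {
    if (is.null(names(efficiency)) || !all(rownames(ct) %in% names(efficiency))) {
      abort("per-gene `efficiency` must be named for every gene.")
    }
    eff <- unname(efficiency[rownames(ct)])
  }
  if (any(eff < 1.5 | eff > 2.2)) {
    abort("amplification efficiency must lie in [1.5, 2.2].")
  }
  q <- unclass(ct)
  for (i in seq_len(k)) q[i, ] <- eff[i]^(min(q[i, ]) - q[i, ])
  structure(q, efficiency = setNames(eff, rownames(ct)),
            class = c("rq_matrix", "matrix", "array"))
}

#' Summarise Ct values
#'
#' @param ct A [ct_matrix()].
#' @param scope `"gene"` for one row per gene, `"global"` for a single row
#'   over all cells.
#' @return A tibble with columns `n`, `min`, `max`, `mean`, `median`, `sd`
#'   and `range_width` (plus `gene` for per-gene scope).
#' @export
describe_ct <- function(ct, scope = c("gene", "global")) {
  scope <- match.arg(scope)
  ct <- as_ct_matrix(ct)
  long <- tidy(ct)
  if (scope == "global") {
    dplyr::summarise(long, n = dplyr::n(), min = min(.data$ct),
                     max = max(.data$ct), mean = mean(.data$ct),
                     median = median(.data$ct), sd = sd(.data$ct),
                     range_width = max(.data$ct) - min(.data$ct))
  } else {
    dplyr::summarise(dplyr::group_by(long, .data$gene),
                     n = dplyr::n(), min = min(.data$ct), max = max(.data$ct),
                     mean = mean(.data$ct), median = median(.data$ct),
                     sd = sd(.data$ct),
                     range_width = max(.data$ct) - min(.data$ct),
                     .groups = "drop")
  }
}

#' @exportS3Method generics::tidy
tidy.ct_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x), times = ncol(x)),
    sample = rep(colnames(x), each = nrow(x)),
    ct = as.vector(unclass(x)))
}

#' @exportS3Method generics::tidy
tidy.rq_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x), times = ncol(x)),
    sample = rep(colnames(x), each = nrow(x)),
    quantity = as.vector(unclass(x)))
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d genes x %d samples, Ct %.3f-%.3f\n",
              nrow(x), ncol(x), min(x), max(x)))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE], 6L))
  invisible(x)
}

#' Write a Ct matrix to a tab-delimited file
#'
#' Genes as rows, UTF-8, '.' decimal separator. Round-trips through
#' [read_ct_table()].
#'
#' @param ct A [ct_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  ct <- as_ct_matrix(ct)
  df <- tibble::as_tibble(unclass(ct), rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}
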