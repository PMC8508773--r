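#' Comprehensive rank-sum ranking
#'
#' Combines the three method rankings into the composite stability score:
#' per gene, `rank_sum = G + N + B` (geNorm, NormFinder and BestKeeper dense
#' ranks), with the final comprehensive rank a dense rank by ascending
#' rank sum. The smaller the sum, the more stable the gene. Row order
#' breaks rank-sum ties by ascending geNorm M (when supplied) then name.
#'
#' @param ranks Tibble (or data frame) with columns `gene`, `genorm`,
#'   `normfinder`, `bestkeeper` holding each method's dense rank over the
#'   identical gene set.
#' @param m Optional tibble `gene`, `m` of full-panel geNorm M values used
#'   only to order tied rank sums.
#' @return A tibble (class `comprehensive_ranking`): `gene`, `genorm`,
#'   `normfinder`, `bestkeeper`, `rank_sum`, `final_rank`, ordered by
#'   `final_rank`.
#' @examples
#' rank_sum(published_rank_example())
#' @export
rank_sum <- function(ranks, m = NULL) {
  ranks <- tibble::as_tibble(ranks)
  need <- c("gene", "genorm", "normfinder", "bestkeeper")
  miss <- setdiff(need, names(ranks))
  if (length(miss)) abort(sprintf("`ranks` lacks column(s): %s", paste(miss, collapse = ", ")))
  for (col in need[-1L]) {
    if (anyNA(ranks[[col]])) {
      abort(sprintf("method '%s' is missing ranks for: %s", col,
                    paste(ranks$gene[is.na(ranks[[col]])], collapse = ", ")))
    }
  }
  out <- dplyr::mutate(ranks[need],
                       rank_sum = .data$genorm + .data$normfinder + .data$bestkeeper)
  if (!is.null(m)) {
    out <- dplyr::left_join(out, tibble::as_tibble(m)[c("gene", "m")], by = "gene")
  } else {
    out$m <- NA_real_
  }
  out$final_rank <- dense_rank_keys(out$rank_sum)
  out <- dplyr::arrange(out, .data$rank_sum, .data$m, .data$gene)
  out$m <- NULL
  class(out) <- c("comprehensive_ranking", class(out))
  out
}

# Check that two method results cover the same genes; abort with the diff.
check_gene_sets <- function(a, b, name_a, name_b) {
  extra <- setdiff(a, b)
  missing <- setdiff(b, a)
  if (length(extra) || length(missing)) {
    abort(sprintf("gene sets differ between %s and %s (only in %s: %s; only in %s: %s)",
                  name_a, name_b,
                  name_a, paste(extra, collapse = ", "),
                  name_b, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Run all three stability methods on one analysis group
#'
#' Executes geNorm, NormFinder and BestKeeper on a Ct matrix (or a subset of
#' one) and aggregates their dense ranks into the comprehensive rank-sum
#' ranking.
#'
#' @param ct A [ct_matrix()] (typically from [subset_ct()]).
#' @param annotation Optional annotation tibble; needed when
#'   `normfinder_groups` names an annotation column.
#' @param efficiency Amplification efficiency for [relative_quantities()].
#' @param v_cutoff,m_limit geNorm thresholds (defaults 0.15 and 1.5).
#' @param sd_mode,sd_limit BestKeeper options (defaults `"sample_sd"`, 1).
#' @param normfinder_groups `"auto"` (grouped by `sample_class` when the
#'   group spans at least two classes with two samples each, otherwise
#'   ungrouped), `"sample_class"`, `"cultivar"`, `"none"`, or an explicit
#'   per-sample factor.
#' @return An object of class `stability_analysis`: `genorm`, `normfinder`,
#'   `bestkeeper` fits, `ranking` (the [rank_sum()] table), `group_name`,
#'   `n_samples`.
#' @examples
#' sim <- simulate_ct(default_ct_spec(seed = 7))
#' fit <- analyze_group(sim$ct, sim$annotation)
#' head(fit$ranking, 3)
#' @export
analyze_group <- function(ct, annotation = NULL, efficiency = 2,
                          v_cutoff = 0.15, m_limit = 1.5,
                          sd_mode = "sample_sd", sd_limit = 1,
                          normfinder_groups = "auto") {
  ct <- as_ct_matrix(ct)
  annotation <- annotation %||% attr(ct, "annotation")

  groups <- resolve_nf_groups(ct, annotation, normfinder_groups)
  q <- relative_quantities(ct, efficiency)
  gn <- genorm(q, v_cutoff = v_cutoff, m_limit = m_limit)
  nf <- normfinder(q, groups = groups)
  bk <- bestkeeper(ct, sd_mode = sd_mode, sd_limit = sd_limit)

  check_gene_sets(gn$ranks$gene, nf$stability$gene, "geNorm", "NormFinder")
  check_gene_sets(gn$ranks$gene, bk$stats$gene, "geNorm", "BestKeeper")
  ranks <- tibble::tibble(
    gene = gn$ranks$gene,
    genorm = gn$ranks$rank,
    normfinder = nf$stability$rank[match(gn$ranks$gene, nf$stability$gene)],
    bestkeeper = bk$stats$rank[match(gn$ranks$gene, bk$stats$gene)])
  ranking <- rank_sum(ranks, m = gn$initial_m)

  structure(list(genorm = gn, normfinder = nf, bestkeeper = bk,
                 ranking = ranking,
                 group_name = attr(ct, "group_name"),
                 n_samples = ncol(ct),
                 normfinder_grouped = nf$grouped),
            class = "stability_analysis")
}

resolve_nf_groups <- function(ct, annotation, normfinder_groups) {
  if (is.null(normfinder_groups) || identical(normfinder_groups, "none")) {
    return(NULL)
  }
  if (length(normfinder_groups) == ncol(ct)) return(normfinder_groups)
  if (!is.character(normfinder_groups) || length(normfinder_groups) != 1L) {
    abort("`normfinder_groups` must be 'auto', 'none', an annotation column, or a per-sample factor.")
  }
  if (is.null(annotation)) {
    if (normfinder_groups == "auto") return(NULL)
    abort("annotation required to resolve `normfinder_groups`.")
  }
  validate_annotation(annotation, colnames(ct))
  ann <- annotation[match(colnames(ct), annotation$sample_id), ]
  col <- if (normfinder_groups == "auto") "sample_class" else normfinder_groups
  if (!col %in% names(ann)) abort(sprintf("annotation has no column '%s'.", col))
  f <- ann[[col]]
  if (normfinder_groups == "auto") {
    tab <- table(f)
    if (length(tab) < 2L || any(tab < 2L)) return(NULL)
  }
  f
}

#' @exportS3Method generics::tidy
tidy.stability_analysis <- function(x, ...) tibble::as_tibble(x$ranking)

#' @exportS3Method generics::glance
glance.stability_analysis <- function(x, ...) {
  top <- x$ranking$gene[x$ranking$final_rank == 1L]
  tibble::tibble(
    group = x$group_name %||% NA_character_,
    n_genes = nrow(x$ranking), n_samples = x$n_samples,
    most_stable = paste(sort(top), collapse = "/"),
    least_stable = x$ranking$gene[which.max(x$ranking$final_rank)],
    genorm_optimal_n = x$genorm$optimal_n,
    normfinder_grouped = x$normfinder_grouped)
}

#' @export
print.stability_analysis <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<stability_analysis>%s %d genes x %d samples\n",
              if (!is.na(g$group)) paste0(" [", g$group, "]") else "",
              g$n_genes, g$n_samples))
  cat(sprintf("most stable: %s; least stable: %s; geNorm optimal n: %s\n",
              g$most_stable, g$least_stable,
              ifelse(is.na(g$genorm_optimal_n), "none", g$genorm_optimal_n)))
  invisible(x)
}

#' The twelve standard study groups
#'
#' Builds the canonical analysis groups of a four-cultivar berry design from
#' a sample annotation: all samples; the three raspberry cultivars; all
#' fruit developmental stages; raspberry fruit stages; per-cultivar tissue
#' panels (all classes); and per-cultivar fruit stages.
#'
#' @param annotation Annotation tibble.
#' @param fruit_classes Sample classes counted as fruit developmental
#'   stages.
#' @param blackberry Cultivar label excluded from the raspberry-only groups.
#' @return Named list of sample-id character vectors.
#' @export
standard_groups <- function(annotation,
                            fruit_classes = c("green_fruit", "immature_fruit",
                                              "mature_fruit"),
                            blackberry = "blackberry") {
  validate_annotation(annotation)
  ann <- annotation
  rasp <- setdiff(unique(ann$cultivar), blackberry)
  sel <- function(keep) ann$sample_id[keep]
  groups <- list(
    all_samples = sel(rep(TRUE, nrow(ann))),
    three_raspberries = sel(ann$cultivar %in% rasp),
    all_fruit_stages = sel(ann$sample_class %in% fruit_classes),
    raspberry_fruit_stages = sel(ann$cultivar %in% rasp &
                                   ann$sample_class %in% fruit_classes))
  for (cv in unique(ann$cultivar)) {
    groups[[paste0(cv, "_tissues")]] <- sel(ann$cultivar == cv)
    groups[[paste0(cv, "_fruit_stages")]] <-
      sel(ann$cultivar == cv & ann$sample_class %in% fruit_classes)
  }
  groups
}

#' Run the stability pipeline over many analysis groups
#'
#' @param ct A [ct_matrix()] covering every sample referenced by `groups`.
#' @param annotation Annotation tibble.
#' @param groups Named list of sample-id vectors (default
#'   [standard_groups()]).
#' @param ... Passed to [analyze_group()].
#' @return A list with `fits` (named list of `stability_analysis`, `NULL`
#'   where a group failed), `summary` (one [generics::glance()] row per
#'   successful group) and `errors` (named character vector of failure
#'   messages).
#' @export
analyze_groups <- function(ct, annotation, groups = standard_groups(annotation),
                           ...) {
  ct <- as_ct_matrix(ct)
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    abort("`groups` must be uniquely named.")
  }
  fits <- vector("list", length(groups))
  names(fits) <- names(groups)
  errors <- character(0)
  for (nm in names(groups)) {
    res <- tryCatch({
      sub <- subset_ct(ct, annotation, .data$sample_id %in% groups[[nm]],
                       name = nm)
      analyze_group(sub, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[nm] <- conditionMessage(res)
    } else {
      fits[[nm]] <- res
    }
  }
  ok <- !vapply(fits, is.null, logical(1L))
  summary <- dplyr::bind_rows(purrr::map(fits[ok], glance))
  list(fits = fits, summary = summary, errors = errors)
}

#' Published comprehensive-ranking example
#'
#' Dense geNorm (G), NormFinder (N) and BestKeeper (B) stability ranks, and
#' their printed sum, reported for a 12-gene *Rubus* (blackberry/raspberry)
#' reference-gene panel. Two blocks are included: the full 72-sample panel
#' (`"all_samples"`) and the three raspberry cultivars
#' (`"three_raspberries"`). Used as a worked example for [rank_sum()] and in
#' the package's tests.
#'
#' @param block `"all_samples"` or `"three_raspberries"`.
#' @return Tibble: `gene`, `genorm`, `normfinder`, `bestkeeper`,
#'   `published_sum`.
#' @export
published_rank_example <- function(block = c("all_samples", "three_raspberries")) {
  block <- match.arg(block)
  all_samples <- tibble::tribble(
    ~gene,      ~genorm, ~normfinder, ~bestkeeper, ~published_sum,
    "RuEEF1A",   1L,  2L,  1L,  4L,
    "Ru18S",     1L,  3L,  2L,  6L,
    "RuTUBA",    2L,  1L,  3L,  6L,
    "RuUBC",     4L,  4L,  4L, 12L,
    "RuEF4A",    3L,  5L,  5L, 13L,
    "RuEEF1B",   5L,  6L,  6L, 17L,
    "RuUBQ",     6L,  7L,  7L, 20L,
    "Ru40S",     7L,  8L,  8L, 23L,
    "Ru30S",     8L,  9L, 10L, 27L,
    "RuPA",      9L, 10L,  9L, 28L,
    "RuF-box",  10L, 11L, 12L, 33L,
    "RuPGK",    11L, 12L, 11L, 34L)
  three_raspberries <- tibble::tribble(
    ~gene,      ~genorm, ~normfinder, ~bestkeeper, ~published_sum,
    "Ru18S",     1L,  3L,  2L,  6L,
    "RuEEF1A",   1L,  4L,  1L,  6L,
    "RuTUBA",    2L,  1L,  3L,  6L,
    "RuUBC",     3L,  2L,  4L,  9L,
    "RuEF4A",    4L,  6L,  5L, 15L,
    "RuEEF1B",   5L,  5L,  6L, 16L,
    "RuUBQ",     6L,  7L,  7L, 20L,
    "Ru40S",     7L,  8L,  8L, 23L,
    "RuPA",      9L,  9L,  9L, 27L,
    "Ru30S",     8L, 10L, 11L, 29L,
    "RuF-box",  10L, 11L, 10L, 31L,
    "RuPGK",    11L, 12L, 12L, 35L)
  switch(block, all_samples = all_samples,
         three_raspberries = three_raspberries)
}
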