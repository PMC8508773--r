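#' BestKeeper descriptive stability analysis
#'
#' Operates directly on raw Ct values (unlike geNorm/NormFinder): per gene it
#' reports the arithmetic and geometric mean, extremes, SD and CV
#' (`CV% = 100 * SD / mean`), flags genes whose SD exceeds `sd_limit`
#' (default 1 cycle) as unusable references, builds the BestKeeper index
#' (per-sample geometric mean of the retained genes' Ct) and correlates each
#' gene against it (Pearson r with a two-sided t-test p-value). Lower SD,
#' lower CV and higher r indicate a more stable gene; ranking is by
#' ascending SD (ties by CV then name).
#'
#' @param ct A [ct_matrix()].
#' @param sd_mode `"sample_sd"` (n-1 denominator, default) or
#'   `"mean_abs_dev"` (the original tool's mean absolute deviation from the
#'   arithmetic mean).
#' @param sd_limit Exclusion threshold on SD in cycles (default 1).
#' @param retained Optional manual character vector of genes to build the
#'   index from, overriding the SD rule.
#' @return An object of class `bestkeeper` with `stats` (tibble: gene, n,
#'   mean, geo_mean, min, max, sd, cv, excluded, rank, r, p), `index`
#'   (tibble: sample, index), `retained` and `sd_mode`.
#' @examples
#' sim <- simulate_ct(default_ct_spec(seed = 7))
#' bk <- bestkeeper(sim$ct)
#' head(tidy(bk), 3)
#' @export
bestkeeper <- function(ct, sd_mode = c("sample_sd", "mean_abs_dev"),
                       sd_limit = 1, retained = NULL) {
  sd_mode <- match.arg(sd_mode)
  stopifnot_scalar_number(sd_limit, "sd_limit", lower = 1e-12)
  ct <- as_ct_matrix(ct)
  if (ncol(ct) < 3L) abort("BestKeeper needs at least 3 samples.")
  m <- unclass(ct)   # ct_matrix guarantees Ct > 0, so geometric means exist

  disp <- switch(sd_mode,
    sample_sd = apply(m, 1L, sd),
    mean_abs_dev = apply(m, 1L, function(x) mean(abs(x - mean(x)))))
  stats <- tibble::tibble(
    gene = rownames(m),
    n = ncol(m),
    mean = unname(rowMeans(m)),
    geo_mean = unname(apply(m, 1L, geo_mean)),
    min = unname(apply(m, 1L, min)),
    max = unname(apply(m, 1L, max)),
    sd = unname(disp))
  stats$cv <- 100 * stats$sd / stats$mean
  stats$excluded <- stats$sd > sd_limit
  stats$rank <- dense_rank_keys(stats$sd, stats$cv, stats$gene)

  if (is.null(retained)) {
    retained <- stats$gene[!stats$excluded]
  } else {
    miss <- setdiff(retained, stats$gene)
    if (length(miss)) abort(sprintf("unknown retained gene(s): %s",
                                    paste(miss, collapse = ", ")))
  }
  if (length(retained) < 2L) {
    abort(paste0("fewer than 2 genes with SD <= ", sd_limit,
                 "; pass `retained` to select index genes manually."))
  }

  index <- apply(m[retained, , drop = FALSE], 2L, geo_mean)
  corr <- purrr::map(stats$gene, function(g) {
    x <- m[g, ]
    if (sd(x) == 0 || sd(index) == 0) {
      warn(sprintf("zero-variance gene '%s': correlation undefined.", g))
      return(list(r = NA_real_, p = NA_real_))
    }
    ht <- cor.test(x, index, method = "pearson")
    list(r = unname(ht$estimate), p = ht$p.value)
  })
  stats$r <- purrr::map_dbl(corr, "r")
  stats$p <- purrr::map_dbl(corr, "p")

  structure(list(
    stats = stats,
    index = tibble::tibble(sample = colnames(m), index = unname(index)),
    retained = retained,
    sd_mode = sd_mode,
    sd_limit = sd_limit
  ), class = "bestkeeper")
}

#' @exportS3Method generics::tidy
tidy.bestkeeper <- function(x, ...) {
  dplyr::arrange(x$stats, .data$rank, .data$gene)
}

#' @exportS3Method generics::glance
glance.bestkeeper <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$stats),
                 n_retained = length(x$retained),
                 n_excluded = sum(x$stats$excluded),
                 sd_mode = x$sd_mode,
                 min_sd = min(x$stats$sd),
                 best = x$stats$gene[which.min(x$stats$rank)])
}

#' @export
print.bestkeeper <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<bestkeeper> %d genes, %d excluded (SD > %.2f), best: %s (SD %.3f, %s)\n",
              g$n_genes, g$n_excluded, x$sd_limit, g$best, g$min_sd, x$sd_mode))
  invisible(x)
}

#' @rdname autoplot.genorm
#' @exportS3Method ggplot2::autoplot
autoplot.bestkeeper <- function(object, ...) {
  td <- tidy(object)
  td$gene <- factor(td$gene, levels = rev(td$gene))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$gene, y = .data$sd,
                                   fill = .data$excluded)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$sd_limit, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey35", `TRUE` = "firebrick")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "SD of Ct (cycles)") +
    ggplot2::theme_minimal()
}
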