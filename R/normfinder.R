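#' NormFinder model-based stability values
#'
#' Estimates a stability value S per candidate gene (log2 units, lower =
#' more stable) by variance decomposition of log-scale expression
#' `y = log2(Q)`, following the model-based approach of Andersen et al.
#' (2004).
#'
#' Ungrouped mode removes gene and sample (loading) effects by two-way
#' centering and estimates each gene's residual variance with the k/(k-2)
#' bias correction, so a gene is penalised only for variation that is not
#' shared by the whole panel. With a grouping factor, the per-group
#' intragroup variance is combined with a shrunken estimate of the gene's
#' systematic expression difference between groups:
#' `S_i = mean_g( |d~_ig| + sqrt(sigma2_ig / n_g) )`, where `d~` is the
#' group contrast shrunk towards 0 by an empirical-Bayes factor
#' `gamma2 / (gamma2 + sigma2_ig/n_g)` and `gamma2` is the method-of-moments
#' between-group variance of the contrasts net of their sampling variance.
#'
#' @inheritParams pairwise_variation
#' @param groups Optional per-sample factor (length = number of samples, or
#'   a named vector over sample ids). Each group needs at least 2 samples;
#'   grouped mode needs at least 2 groups.
#' @return An object of class `normfinder` with `stability` (tibble: gene,
#'   s, rank), `intragroup` (tibble: gene, group, sigma2), and, in grouped
#'   mode, `intergroup` (tibble: gene, group, d, d_shrunk) plus `gamma2`.
#' @examples
#' sim <- simulate_ct(default_ct_spec(seed = 7))
#' nf <- normfinder(relative_quantities(sim$ct))
#' head(tidy(nf))
#' @export
normfinder <- function(q, groups = NULL) {
  check_rq(q)
  k <- nrow(q)
  n <- ncol(q)
  if (k < 3L) abort("NormFinder needs at least 3 genes (k/(k-2) correction undefined otherwise).")
  y <- log2(unclass(q))
  genes <- rownames(y)

  if (is.null(groups)) {
    if (n < 4L) abort("ungrouped NormFinder needs at least 4 samples.")
    sigma2 <- nf_sigma2(y)
    s <- sqrt(sigma2)
    if (all(s == 0)) warn("zero-variance panel: all stability values are 0.")
    stability <- tibble::tibble(gene = genes, s = unname(s))
    stability$rank <- dense_rank_keys(stability$s)
    res <- list(stability = stability,
                intragroup = tibble::tibble(gene = genes, group = "(all)",
                                            sigma2 = unname(sigma2)),
                intergroup = NULL, gamma2 = NA_real_, grouped = FALSE)
    return(structure(res, class = "normfinder"))
  }

  if (!is.null(names(groups))) {
    if (!all(colnames(y) %in% names(groups))) {
      abort("named `groups` must cover every sample.")
    }
    groups <- groups[colnames(y)]
  }
  if (length(groups) != n) abort("`groups` must have one entry per sample.")
  f <- factor(groups)
  if (nlevels(f) < 2L) abort("grouped NormFinder needs at least 2 groups.")
  if (any(table(f) < 2L)) abort("every group needs at least 2 samples.")

  lev <- levels(f)
  n_g <- as.vector(table(f)[lev])
  sigma2 <- matrix(NA_real_, k, length(lev), dimnames = list(genes, lev))
  d <- matrix(NA_real_, k, length(lev), dimnames = list(genes, lev))
  for (gi in seq_along(lev)) {
    yg <- y[, f == lev[gi], drop = FALSE]
    sigma2[, gi] <- nf_sigma2(yg)
    d[, gi] <- rowMeans(yg) - mean(yg)
  }
  d <- d - rowMeans(d)  # center contrasts across groups, per gene

  samp_var <- sweep(sigma2, 2L, n_g, `/`)          # sigma2_ig / n_g
  gamma2 <- max(0, var(as.vector(d)) - mean(samp_var))
  shrink <- gamma2 / (gamma2 + samp_var)
  shrink[!is.finite(shrink)] <- 0                   # gamma2 = 0, samp_var = 0
  d_shrunk <- d * shrink
  s <- rowMeans(abs(d_shrunk) + sqrt(samp_var))
  if (all(s == 0)) warn("zero-variance panel: all stability values are 0.")

  stability <- tibble::tibble(gene = genes, s = unname(s))
  stability$rank <- dense_rank_keys(stability$s)
  structure(list(
    stability = stability,
    intragroup = tibble::tibble(gene = rep(genes, times = length(lev)),
                                group = rep(lev, each = k),
                                sigma2 = as.vector(sigma2)),
    intergroup = tibble::tibble(gene = rep(genes, times = length(lev)),
                                group = rep(lev, each = k),
                                d = as.vector(d),
                                d_shrunk = as.vector(d_shrunk)),
    gamma2 = gamma2,
    grouped = TRUE
  ), class = "normfinder")
}

# Bias-corrected per-gene variance after two-way (gene x sample) centering.
# E[sigma2_hat] = sigma2 under y_ij = alpha_i + beta_j + eps_ij.
nf_sigma2 <- function(y) {
  k <- nrow(y)
  n <- ncol(y)
  r <- y - rowMeans(y)
  r <- sweep(r, 2L, colMeans(r), `-`)
  v <- rowSums(r^2) / (n - 1L)
  pmax(0, (k / (k - 2)) * (v - sum(v) / (k * (k - 1L))))
}

#' @exportS3Method generics::tidy
tidy.normfinder <- function(x, ...) {
  dplyr::arrange(x$stability, .data$rank, .data$gene)
}

#' @exportS3Method generics::glance
glance.normfinder <- function(x, ...) {
  best <- x$stability$gene[x$stability$rank == 1L]
  tibble::tibble(n_genes = nrow(x$stability), grouped = x$grouped,
                 most_stable = paste(sort(best), collapse = "/"),
                 min_s = min(x$stability$s), max_s = max(x$stability$s))
}

#' @export
print.normfinder <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<normfinder> %d genes (%s); most stable: %s (S = %.3f)\n",
              g$n_genes, if (x$grouped) "grouped" else "ungrouped",
              g$most_stable, g$min_s))
  invisible(x)
}

#' @rdname autoplot.genorm
#' @exportS3Method ggplot2::autoplot
autoplot.normfinder <- function(object, ...) {
  td <- tidy(object)
  td$gene <- factor(td$gene, levels = rev(td$gene))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$gene, y = .data$s)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "stability value S (log2 units)") +
    ggplot2::theme_minimal()
}
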