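#' Pairwise variation between two candidate reference genes
#'
#' The geNorm building block: for genes j and k, the sample standard
#' deviation (n-1 denominator) over samples of the log2 expression ratio
#' `A_jk,s = log2(Q_js / Q_ks)`. Two genes that are perfectly co-regulated
#' (constant ratio) have V = 0 regardless of their individual variability.
#'
#' @param q An `rq_matrix` from [relative_quantities()].
#' @param gene_j,gene_k Gene names.
#' @return A single non-negative number (log2 units); symmetric in its gene
#'   arguments.
#' @export
pairwise_variation <- function(q, gene_j, gene_k) {
  check_rq(q)
  if (ncol(q) < 3L) abort("pairwise variation needs at least 3 samples.")
  for (g in c(gene_j, gene_k)) {
    if (!g %in% rownames(q)) abort(sprintf("gene '%s' not in matrix.", g))
  }
  sd(log2(q[gene_j, ] / q[gene_k, ]))
}

# Full symmetric matrix of pairwise variations on log2 quantities.
pairwise_variation_matrix <- function(a) {
  k <- nrow(a)
  v <- matrix(0, k, k, dimnames = list(rownames(a), rownames(a)))
  for (j in seq_len(k - 1L)) {
    for (l in (j + 1L):k) {
      v[j, l] <- v[l, j] <- sd(a[j, ] - a[l, ])
    }
  }
  v
}

#' geNorm expression-stability M values
#'
#' A gene's M is the arithmetic mean of its pairwise variations against every
#' other candidate on the panel; lower M = more stable. Genes with M below
#' 1.5 are conventionally considered usable reference genes.
#'
#' @inheritParams pairwise_variation
#' @return A tibble with columns `gene` and `m`, in input gene order.
#' @export
genorm_m <- function(q) {
  check_rq(q)
  if (nrow(q) < 3L) abort("M values need at least 3 genes.")
  if (ncol(q) < 3L) abort("M values need at least 3 samples.")
  m <- m_from_log2(log2(unclass(q)))
  tibble::tibble(gene = names(m), m = unname(m))
}

m_from_log2 <- function(a) {
  v <- pairwise_variation_matrix(a)
  rowSums(v) / (nrow(a) - 1L)
}

#' geNorm stability analysis
#'
#' Runs the complete geNorm procedure on a relative-quantity matrix:
#' full-panel M values, stepwise elimination of the least stable gene
#' (recomputing M after each removal) down to the final pair, dense stability
#' ranks (the final pair shares rank 1), the pairwise-variation series
#' `V_n/n+1` of normalization factors built from the n and n+1 most stable
#' genes, and the optimal reference-gene count (smallest n with
#' `V_n/n+1 < v_cutoff`).
#'
#' Ties in the elimination step are broken by removing the
#' lexicographically last gene name; the gene order used for NF_n membership
#' is stability rank, with ties resolved by full-panel M then name.
#'
#' @inheritParams pairwise_variation
#' @param v_cutoff Pairwise-variation cutoff below which n genes suffice
#'   (default 0.15).
#' @param m_limit Acceptability limit on M (default 1.5); reported as a flag,
#'   never used to drop genes.
#' @return An object of class `genorm` with components `initial_m`
#'   (tibble: gene, m, acceptable), `elimination` (tibble: step, gene,
#'   m_at_removal), `ranks` (tibble: gene, rank), `final_pair`, `v_series`
#'   (tibble: n, v, passes), `optimal_n` (integer, `NA` if no n passes) and
#'   `v_cutoff`.
#' @examples
#' sim <- simulate_ct(default_ct_spec(seed = 7))
#' fit <- genorm(relative_quantities(sim$ct))
#' glance(fit)
#' @export
genorm <- function(q, v_cutoff = 0.15, m_limit = 1.5) {
  check_rq(q)
  stopifnot_scalar_number(v_cutoff, "v_cutoff", lower = 1e-12)
  stopifnot_scalar_number(m_limit, "m_limit", lower = 1e-12)
  k <- nrow(q)
  if (k < 3L) abort("geNorm needs at least 3 genes.")
  if (ncol(q) < 3L) abort("geNorm needs at least 3 samples.")

  a <- log2(unclass(q))
  genes <- rownames(a)
  m0 <- m_from_log2(a)

  remaining <- genes
  elim <- character(0)
  m_at_removal <- numeric(0)
  while (length(remaining) > 2L) {
    m_cur <- m_from_log2(a[remaining, , drop = FALSE])
    worst <- m_cur[m_cur >= max(m_cur) - 1e-12]
    # deterministic tie-break: lexicographically last name
    drop_gene <- max(names(worst))
    elim <- c(elim, drop_gene)
    m_at_removal <- c(m_at_removal, m_cur[[drop_gene]])
    remaining <- setdiff(remaining, drop_gene)
  }
  final_pair <- sort(remaining)

  ranks <- setNames(integer(k), genes)
  ranks[final_pair] <- 1L
  if (length(elim)) ranks[elim] <- seq(k - 1L, 2L)

  # stability order for NF membership: rank, then full-panel M, then name
  stab_order <- genes[order(ranks[genes], m0[genes], genes)]

  nf_log2 <- function(n) colMeans(a[stab_order[seq_len(n)], , drop = FALSE])
  v_series <- tibble::tibble(n = integer(0), v = numeric(0))
  if (k >= 3L) {
    ns <- 2:(k - 1L)
    vs <- vapply(ns, function(n) sd(nf_log2(n) - nf_log2(n + 1L)), numeric(1L))
    v_series <- tibble::tibble(n = as.integer(ns), v = vs)
  }
  v_series$passes <- v_series$v < v_cutoff
  optimal_n <- if (any(v_series$passes)) min(v_series$n[v_series$passes]) else NA_integer_

  structure(list(
    initial_m = tibble::tibble(gene = genes, m = unname(m0),
                               acceptable = unname(m0) < m_limit),
    elimination = tibble::tibble(step = seq_along(elim), gene = elim,
                                 m_at_removal = m_at_removal),
    ranks = tibble::tibble(gene = genes, rank = unname(ranks)),
    final_pair = final_pair,
    stability_order = stab_order,
    v_series = v_series,
    optimal_n = optimal_n,
    v_cutoff = v_cutoff,
    m_limit = m_limit
  ), class = "genorm")
}

check_rq <- function(q) {
  if (!inherits(q, "rq_matrix")) {
    abort("expected an `rq_matrix`; see relative_quantities().")
  }
  invisible(q)
}

#' @exportS3Method generics::tidy
tidy.genorm <- function(x, ...) {
  dplyr::arrange(
    dplyr::left_join(x$initial_m, x$ranks, by = "gene"),
    .data$rank, .data$m, .data$gene)
}

#' @exportS3Method generics::glance
glance.genorm <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$initial_m),
    final_pair = paste(x$final_pair, collapse = "/"),
    v_2_3 = x$v_series$v[x$v_series$n == 2L][1L],
    optimal_n = x$optimal_n,
    v_cutoff = x$v_cutoff,
    all_acceptable = all(x$initial_m$acceptable))
}

#' @export
print.genorm <- function(x, ...) {
  cat(sprintf("<genorm> %d genes; most stable pair: %s\n",
              nrow(x$initial_m), paste(x$final_pair, collapse = " / ")))
  cat(sprintf("optimal reference-gene count: %s (V cutoff %.2f)\n",
              ifelse(is.na(x$optimal_n), "none below cutoff", x$optimal_n),
              x$v_cutoff))
  invisible(x)
}

#' Plot geNorm results
#'
#' Two-panel display: average expression stability M by stability rank
#' (least stable left, most stable right, the geNorm convention) and the
#' pairwise-variation series `V_n/n+1` against the cutoff.
#'
#' @param object A [genorm()] fit.
#' @param which `"m"`, `"v"` or `"both"`.
#' @param ... Unused.
#' @return A ggplot object (patchwork-free: `"both"` uses faceting).
#' @exportS3Method ggplot2::autoplot
autoplot.genorm <- function(object, which = c("m", "v", "both"), ...) {
  which <- match.arg(which)
  td <- tidy(object)
  m_df <- dplyr::mutate(td, panel = "average stability M",
                        x = factor(.data$gene,
                                   levels = rev(object$stability_order)),
                        y = .data$m)
  v_df <- dplyr::mutate(object$v_series, panel = "pairwise variation V",
                        x = factor(sprintf("V%d/%d", .data$n, .data$n + 1L)),
                        y = .data$v)
  df <- switch(which, m = m_df[c("panel", "x", "y")],
               v = v_df[c("panel", "x", "y")],
               both = rbind(m_df[c("panel", "x", "y")], v_df[c("panel", "x", "y")]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (which == "both") p <- p + ggplot2::facet_wrap(~panel, scales = "free")
  if (which == "v") {
    p <- p + ggplot2::geom_hline(yintercept = object$v_cutoff, linetype = 2)
  }
  p
}
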