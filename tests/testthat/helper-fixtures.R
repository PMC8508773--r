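# Shared fixture builders. All randomness is seeded at the call site.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal valid ct_matrix from a genes x samples numeric matrix.
make_ct <- function(values, genes = NULL, samples = NULL) {
  genes <- genes %||% paste0("g", seq_len(nrow(values)))
  samples <- samples %||% paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  ct_matrix(values)
}

# Random Ct panel with given per-gene noise SDs around baseline 25.
random_ct <- function(k, n, sigma = rep(0.5, k), seed = 1, baseline = 25,
                      loading_sd = 0) {
  set.seed(seed)
  u <- rnorm(n, 0, loading_sd)
  m <- baseline + matrix(rnorm(k * n), k, n) * sigma -
    matrix(u, k, n, byrow = TRUE)
  make_ct(m)
}

# Two-cultivar, two-class, r-replicate annotation matching n = 4 * r samples
# named s1..s(4r).
tiny_annotation <- function(r = 2) {
  grid <- expand.grid(replicate = seq_len(r),
                      sample_class = c("green_fruit", "leaf"),
                      cultivar = c("blackberry", "red_raspberry"),
                      stringsAsFactors = FALSE)
  tibble::tibble(sample_id = paste0("s", seq_len(nrow(grid))),
                 cultivar = grid$cultivar,
                 sample_class = grid$sample_class,
                 replicate = grid$replicate)
}

# Independent brute-force oracle for geNorm M: per gene, mean over other
# genes of sd of elementwise log2 ratios, written as plain double loops.
oracle_m_values <- function(q) {
  k <- nrow(q)
  m <- numeric(k)
  for (j in seq_len(k)) {
    vs <- c()
    for (l in seq_len(k)) {
      if (l == j) next
      ratios <- log2(q[j, ] / q[l, ])
      vs <- c(vs, sqrt(sum((ratios - mean(ratios))^2) / (length(ratios) - 1)))
    }
    m[j] <- mean(vs)
  }
  names(m) <- rownames(q)
  m
}

# Brute-force Pearson correlation (covariance over sd product).
oracle_pearson <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) / (sd(x) * sd(y)) *
    length(x) / (length(x) - 1)
}
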