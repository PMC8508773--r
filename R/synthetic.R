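#' Specify a synthetic Ct-data generator
#'
#' Defines the generative model for a seeded qPCR panel:
#' `Ct_is = b_i + delta_i,g(s) - u_s + eps_is`, with a per-sample loading
#' effect `u_s ~ N(0, tau^2)` shared across all genes of a sample (more
#' template = earlier Ct, hence the minus sign) and per-gene Gaussian noise
#' `eps_is ~ N(0, sigma_i^2)` on the Ct scale (multiplicative on the
#' quantity scale, the standard qPCR error model). Group effects `delta`
#' attach a Ct shift to all samples of a cultivar or sample-class level.
#'
#' @param genes Tibble with columns `gene`, `baseline` (Ct, in (15, 35)) and
#'   `sigma` (noise SD in cycles, >= 0).
#' @param effects Optional tibble of group effects with columns `gene`,
#'   `factor` (`"cultivar"` or `"sample_class"`), `level` and `delta`
#'   (cycles).
#' @param cultivars,sample_classes Character vectors defining the design.
#' @param replicates Biological replicates per (cultivar, sample_class) cell.
#' @param loading_sd Shared per-sample loading SD tau in cycles (default 0.3).
#' @param efficiency Amplification efficiency attached to the panel
#'   (default 2).
#' @param seed Integer seed; identical specs generate bit-identical data.
#' @return A `ct_sim_spec` list.
#' @seealso [default_ct_spec()], [simulate_ct()]
#' @export
ct_sim_spec <- function(genes, effects = NULL,
                        cultivars = c("blackberry", "black_raspberry",
                                      "red_raspberry", "yellow_raspberry"),
                        sample_classes = c("green_fruit", "immature_fruit",
                                           "mature_fruit", "leaf", "stem",
                                           "stem_apex"),
                        replicates = 3L, loading_sd = 0.3, efficiency = 2,
                        seed = 1L) {
  genes <- tibble::as_tibble(genes)
  need <- c("gene", "baseline", "sigma")
  miss <- setdiff(need, names(genes))
  if (length(miss)) abort(sprintf("`genes` lacks column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(genes$gene)) abort("duplicate gene names in `genes`.")
  if (any(genes$sigma < 0)) abort("`sigma` must be >= 0.")
  if (any(genes$baseline <= 15 | genes$baseline >= 35)) {
    abort("baselines must lie in (15, 35) cycles.")
  }
  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    miss <- setdiff(c("gene", "factor", "level", "delta"), names(effects))
    if (length(miss)) abort(sprintf("`effects` lacks column(s): %s", paste(miss, collapse = ", ")))
    if (!all(effects$factor %in% c("cultivar", "sample_class"))) {
      abort("effect `factor` must be 'cultivar' or 'sample_class'.")
    }
    if (!all(effects$gene %in% genes$gene)) abort("effects reference unknown genes.")
    bad <- !ifelse(effects$factor == "cultivar",
                   effects$level %in% cultivars,
                   effects$level %in% sample_classes)
    if (any(bad)) abort("effects reference unknown factor levels.")
  }
  stopifnot_scalar_number(loading_sd, "loading_sd", lower = 0)
  stopifnot_scalar_number(efficiency, "efficiency", lower = 1.5, upper = 2.2)
  if (replicates < 1L) abort("design cells need at least 1 replicate.")
  structure(list(genes = genes, effects = effects, cultivars = cultivars,
                 sample_classes = sample_classes,
                 replicates = as.integer(replicates),
                 loading_sd = loading_sd, efficiency = efficiency,
                 seed = as.integer(seed)),
            class = "ct_sim_spec")
}

#' Canonical 12-gene berry-panel simulation spec
#'
#' The package's default study design: 12 candidate reference genes measured
#' over 72 samples (4 cultivars x 6 sample classes -- three fruit
#' developmental stages, leaf, stem, stem apex -- x 3 biological
#' replicates), with baselines spanning roughly 22-31 cycles. Two genes are
#' designed stable (tight noise, no group structure: `RuEEF1A`, `Ru18S`),
#' one is designed unstable (`RuPGK`: 1.2-cycle noise plus a 1.5-cycle
#' mature-fruit shift), and the remainder fill the middle with moderate
#' noise and modest cultivar/stage effects, so every stability method has a
#' known ground truth to recover.
#'
#' @param seed Integer seed passed to [ct_sim_spec()].
#' @param include_target If `TRUE`, append a regulated non-reference target
#'   gene (`RuCYP73A`-like, strong fruit-stage shifts) for expression
#'   demonstrations; it is flagged `is_reference = FALSE` in the ground
#'   truth.
#' @return A `ct_sim_spec`.
#' @export
default_ct_spec <- function(seed = 1L, include_target = FALSE) {
  genes <- tibble::tribble(
    ~gene,      ~baseline, ~sigma,
    "Ru18S",        23.4,   0.12,
    "Ru30S",        28.6,   0.85,
    "Ru40S",        26.1,   0.70,
    "RuTUBA",       24.8,   0.30,
    "RuEEF1A",      25.0,   0.10,
    "RuEEF1B",      24.5,   0.35,
    "RuEF4A",       25.2,   0.32,
    "RuF-box",      30.2,   0.80,
    "RuUBC",        24.2,   0.40,
    "RuUBQ",        27.0,   0.60,
    "RuPA",         28.9,   0.90,
    "RuPGK",        25.5,   1.20)
  effects <- tibble::tribble(
    ~gene,      ~factor,        ~level,           ~delta,
    "RuPGK",    "sample_class", "mature_fruit",   -1.5,
    "RuPA",     "sample_class", "green_fruit",     0.7,
    "Ru30S",    "sample_class", "leaf",           -0.8,
    "RuF-box",  "cultivar",     "blackberry",      0.6,
    "RuUBQ",    "cultivar",     "red_raspberry",   0.5)
  if (include_target) {
    genes <- dplyr::bind_rows(genes, tibble::tibble(
      gene = "RuCYP73A", baseline = 27.5, sigma = 0.25))
    effects <- dplyr::bind_rows(effects, tibble::tribble(
      ~gene,       ~factor,        ~level,           ~delta,
      "RuCYP73A",  "sample_class", "immature_fruit", -1.0,
      "RuCYP73A",  "sample_class", "mature_fruit",   -2.5,
      "RuCYP73A",  "sample_class", "leaf",            1.0))
  }
  spec <- ct_sim_spec(genes, effects, seed = seed)
  spec$target_gene <- if (include_target) "RuCYP73A" else NULL
  spec
}

#' Simulate a Ct matrix with known ground truth
#'
#' Draws one dataset from a [ct_sim_spec()]. The same spec (including seed)
#' always yields bit-identical output; values are clamped to the valid Ct
#' domain (0, 45].
#'
#' @param spec A `ct_sim_spec`.
#' @return A list with elements `ct` (a [ct_matrix()]), `annotation`
#'   (tibble: sample_id, cultivar, sample_class, replicate) and `truth`
#'   (tibble per gene: baseline, sigma, max_abs_delta, expected_sd --
#'   `sqrt(sigma^2 + tau^2 + var(delta))` over the design -- plus
#'   `instability_rank`, 1 = designed most stable, ordered by sigma then
#'   max |delta|, and `is_reference`).
#' @export
simulate_ct <- function(spec) {
  if (!inherits(spec, "ct_sim_spec")) abort("`spec` must be a ct_sim_spec.")
  ann <- tidyr::expand_grid(cultivar = spec$cultivars,
                            sample_class = spec$sample_classes,
                            replicate = seq_len(spec$replicates))
  ann <- tibble::tibble(
    sample_id = paste(ann$cultivar, ann$sample_class, ann$replicate, sep = "."),
    ann)
  n <- nrow(ann)
  k <- nrow(spec$genes)
  genes <- spec$genes$gene

  # delta_i,g(s): genes x samples shift matrix from the effects table
  delta <- matrix(0, k, n, dimnames = list(genes, ann$sample_id))
  if (!is.null(spec$effects)) {
    for (i in seq_len(nrow(spec$effects))) {
      e <- spec$effects[i, ]
      hit <- ann[[e$factor]] == e$level
      delta[e$gene, hit] <- delta[e$gene, hit] + e$delta
    }
  }

  m <- with_seed(spec$seed, {
    u <- rnorm(n, 0, spec$loading_sd)
    eps <- matrix(rnorm(k * n), k, n) * spec$genes$sigma
    spec$genes$baseline + delta - rep(u, each = k) + eps
  })
  m <- pmin(pmax(m, 0.001), 45)
  dimnames(m) <- list(genes, ann$sample_id)

  design_var <- apply(delta, 1L, function(d) mean(d^2) - mean(d)^2)
  truth <- tibble::tibble(
    gene = genes,
    baseline = spec$genes$baseline,
    sigma = spec$genes$sigma,
    max_abs_delta = apply(abs(delta), 1L, max),
    expected_sd = sqrt(spec$genes$sigma^2 + spec$loading_sd^2 + design_var),
    is_reference = !genes %in% (spec$target_gene %||% character(0)))
  ref <- truth$gene[truth$is_reference]
  truth$instability_rank <- NA_integer_
  truth$instability_rank[truth$is_reference] <-
    dense_rank_keys(truth$sigma[truth$is_reference],
                    truth$max_abs_delta[truth$is_reference],
                    ref)

  list(ct = ct_matrix(m), annotation = ann, truth = truth)
}

#' Write one simulated dataset to disk
#'
#' Emits `ct.csv` (genes as rows), `annotations.csv` and `truth.json` under
#' `outdir`.
#'
#' @param spec A [ct_sim_spec()].
#' @param outdir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(spec, outdir) {
  sim <- simulate_ct(spec)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ct = file.path(outdir, "ct.csv"),
             annotation = file.path(outdir, "annotations.csv"),
             truth = file.path(outdir, "truth.json"))
  readr::write_csv(tibble::as_tibble(unclass(sim$ct), rownames = "gene"),
                   paths["ct"])
  readr::write_csv(sim$annotation, paths["annotation"])
  jsonlite::write_json(list(seed = spec$seed, loading_sd = spec$loading_sd,
                            efficiency = spec$efficiency, truth = sim$truth),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
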