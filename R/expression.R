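#' Relative expression by the 2^-ddCt method
#'
#' Quantifies a target gene relative to one or more reference genes and a
#' calibrator sample group. Per sample, the reference level is the
#' arithmetic mean of the reference genes' Ct (equivalent to geometric-mean
#' normalization on the quantity scale) and `dCt = Ct_target - Ct_ref`;
#' per group, `ddCt = mean(dCt) - mean(dCt_calibrator)` and
#' `fold = 2^-ddCt`, assuming perfect doubling per cycle. Replicate
#' dispersion is the SD of per-sample dCt within the group, propagated to a
#' fold-change range `2^-(ddCt -/+ SD)`.
#'
#' @param ct A [ct_matrix()].
#' @param annotation Annotation tibble covering the samples of `ct`.
#' @param target Target gene name.
#' @param references Character vector of reference gene names (must not
#'   include the target).
#' @param calibrator Baseline group label; defaults to `"green_fruit"` when
#'   present, otherwise the first group level.
#' @param group_col Annotation column defining the sample groups
#'   (default `"sample_class"`).
#' @return A tibble (class `ddct_result`) with one row per group: `group`,
#'   `n`, `delta_ct`, `sd_delta_ct`, `ddct`, `fold`, `fold_lo`, `fold_hi`;
#'   attributes `target`, `references`, `calibrator`.
#' @examples
#' sim <- simulate_ct(default_ct_spec(seed = 7, include_target = TRUE))
#' bb <- subset_ct(sim$ct, sim$annotation, cultivar == "blackberry")
#' ddct(bb, target = "RuCYP73A", references = c("RuEEF1A", "Ru18S"))
#' @export
ddct <- function(ct, annotation = NULL, target, references,
                 calibrator = NULL, group_col = "sample_class") {
  ct <- as_ct_matrix(ct)
  annotation <- annotation %||% attr(ct, "annotation")
  if (is.null(annotation)) abort("`annotation` is required.")
  validate_annotation(annotation, colnames(ct))
  if (length(references) == 0L) abort("`references` must be non-empty.")
  if (target %in% references) {
    abort(sprintf("target '%s' must not appear among the references.", target))
  }
  miss <- setdiff(c(target, references), rownames(ct))
  if (length(miss)) abort(sprintf("gene(s) not in matrix: %s", paste(miss, collapse = ", ")))
  ann <- annotation[match(colnames(ct), annotation$sample_id), ]
  if (!group_col %in% names(ann)) abort(sprintf("annotation has no column '%s'.", group_col))
  groups <- ann[[group_col]]

  calibrator <- calibrator %||%
    (if ("green_fruit" %in% groups) "green_fruit" else groups[1L])
  if (!calibrator %in% groups) {
    abort(sprintf("calibrator group '%s' has no samples.", calibrator))
  }

  m <- unclass(ct)
  ct_ref <- colMeans(m[references, , drop = FALSE])
  dct <- m[target, ] - ct_ref

  per_group <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = groups, dct = dct), .data$group),
    n = dplyr::n(),
    delta_ct = mean(.data$dct),
    sd_delta_ct = if (dplyr::n() > 1L) sd(.data$dct) else 0,
    .groups = "drop")
  cal_dct <- per_group$delta_ct[per_group$group == calibrator]
  out <- dplyr::mutate(per_group,
    ddct = .data$delta_ct - cal_dct,
    fold = 2^-.data$ddct,
    fold_lo = 2^-(.data$ddct + .data$sd_delta_ct),
    fold_hi = 2^-(.data$ddct - .data$sd_delta_ct))
  # keep annotation group order, calibrator's own fold is exactly 1
  out <- out[match(unique(groups), out$group), ]
  attr(out, "target") <- target
  attr(out, "references") <- references
  attr(out, "calibrator") <- calibrator
  class(out) <- c("ddct_result", class(out))
  out
}

#' Compare normalizations under alternative reference sets
#'
#' Recomputes [ddct()] fold changes under each candidate reference set and
#' summarises their disagreement: for every pair of reference sets, the
#' divergence is the maximum over groups of the absolute log2 ratio of fold
#' changes. A divergence near 0 means the choice between the sets is
#' immaterial; large values reproduce the distortion an unstable reference
#' gene imposes.
#'
#' @inheritParams ddct
#' @param ref_sets Named list (length >= 2) of reference-gene character
#'   vectors.
#' @return List with `folds` (tibble: group, ref_set, fold, ddct),
#'   `divergence` (tibble: ref_set_a, ref_set_b, divergence) and
#'   `max_divergence`.
#' @export
compare_normalizations <- function(ct, annotation = NULL, target, ref_sets,
                                   calibrator = NULL,
                                   group_col = "sample_class") {
  if (length(ref_sets) < 2L) abort("need at least 2 reference sets.")
  if (is.null(names(ref_sets)) || anyDuplicated(names(ref_sets))) {
    abort("`ref_sets` must be uniquely named.")
  }
  runs <- purrr::imap(ref_sets, function(refs, nm) {
    r <- ddct(ct, annotation, target = target, references = refs,
              calibrator = calibrator, group_col = group_col)
    tibble::tibble(group = r$group, ref_set = nm, fold = r$fold, ddct = r$ddct)
  })
  folds <- dplyr::bind_rows(runs)
  wide <- tidyr::pivot_wider(folds[c("group", "ref_set", "fold")],
                             names_from = "ref_set", values_from = "fold")
  nms <- names(ref_sets)
  pairs <- utils::combn(nms, 2L)
  divergence <- tibble::tibble(
    ref_set_a = pairs[1L, ], ref_set_b = pairs[2L, ],
    divergence = vapply(seq_len(ncol(pairs)), function(i) {
      max(abs(log2(wide[[pairs[1L, i]]] / wide[[pairs[2L, i]]])))
    }, numeric(1L)))
  list(folds = folds, divergence = divergence,
       max_divergence = max(divergence$divergence))
}

#' @exportS3Method generics::tidy
tidy.ddct_result <- function(x, ...) tibble::as_tibble(x)

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct_result> target %s vs ref(s) %s; calibrator '%s'\n",
              attr(x, "target"), paste(attr(x, "references"), collapse = "+"),
              attr(x, "calibrator")))
  print(tibble::as_tibble(x))
  invisible(x)
}

#' @rdname autoplot.genorm
#' @exportS3Method ggplot2::autoplot
autoplot.ddct_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$group <- factor(df$group, levels = df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$fold)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fold_lo,
                                        ymax = .data$fold_hi), width = 0.25) +
    ggplot2::labs(x = NULL,
                  y = sprintf("fold change of %s (2^-ddCt)", attr(object, "target"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
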