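#' Assemble and validate a run configuration
#'
#' Normalises the configuration consumed by [run_analysis()] and
#' [run_ddct()]. Thresholds default to the field conventions: geNorm M
#' limit 1.5 and V cutoff 0.15, BestKeeper SD limit 1 cycle.
#'
#' @param ct Path to the Ct table (CSV/TSV).
#' @param annotation Path to the sample-annotation table.
#' @param outdir Output directory.
#' @param orientation Table orientation for [read_ct_table()].
#' @param groups `"standard"` for [standard_groups()], or a named list of
#'   sample-id vectors.
#' @param methods Character subset of `c("genorm", "normfinder",
#'   "bestkeeper")`; the comprehensive ranking requires all three.
#' @param m_limit,v_cutoff,sd_limit,sd_mode,efficiency,normfinder_groups
#'   Method options, see [analyze_group()].
#' @param strict If `TRUE`, any group failure aborts the run.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(ct, annotation, outdir = ".",
                       orientation = "genes-as-rows", groups = "standard",
                       methods = c("genorm", "normfinder", "bestkeeper"),
                       m_limit = 1.5, v_cutoff = 0.15, sd_limit = 1,
                       sd_mode = "sample_sd", efficiency = 2,
                       normfinder_groups = "auto", strict = FALSE) {
  bad <- setdiff(methods, c("genorm", "normfinder", "bestkeeper"))
  if (length(bad)) abort(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  if (length(methods) == 0L) abort("at least one method must be enabled.")
  for (nm in c("m_limit", "v_cutoff", "sd_limit", "efficiency")) {
    stopifnot_scalar_number(get(nm), nm, lower = 1e-12)
  }
  if (!identical(groups, "standard")) {
    if (is.null(names(groups)) || anyDuplicated(names(groups))) {
      abort("`groups` must be 'standard' or a uniquely named list.")
    }
  }
  cfg <- list(ct = ct, annotation = annotation, outdir = outdir,
              orientation = orientation, groups = groups, methods = methods,
              m_limit = m_limit, v_cutoff = v_cutoff, sd_limit = sd_limit,
              sd_mode = sd_mode, efficiency = efficiency,
              normfinder_groups = normfinder_groups, strict = strict)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose fields mirror the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(sprintf("malformed config JSON: %s",
                                                    conditionMessage(e))))
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) abort(sprintf("unknown config field(s): %s",
                                     paste(unknown, collapse = ", ")))
  miss <- setdiff(c("ct", "annotation"), names(raw))
  if (length(miss)) abort(sprintf("config lacks required field(s): %s",
                                  paste(miss, collapse = ", ")))
  if (!is.null(raw$groups) && is.list(raw$groups)) {
    raw$groups <- lapply(raw$groups, as.character)
  }
  do.call(run_config, raw)
}

#' Run the full stability analysis and write reports
#'
#' Reads the configured inputs, runs the enabled methods on every analysis
#' group, and writes per-group TSVs (geNorm gene table and V series,
#' NormFinder, BestKeeper, comprehensive ranking) plus one machine-readable
#' `report.json` embedding the configuration, a configuration hash, package
#' version and any per-group warnings or errors.
#'
#' @param config A [run_config()] (or path to a JSON config).
#' @return The report list, invisibly. Files are written under
#'   `config$outdir`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  ct <- read_ct_table(config$ct, orientation = config$orientation)
  ann <- read_sample_annotation(config$annotation)
  validate_annotation(ann, colnames(ct))
  groups <- if (identical(config$groups, "standard")) {
    standard_groups(ann)
  } else {
    config$groups
  }

  all_methods <- length(setdiff(c("genorm", "normfinder", "bestkeeper"),
                                config$methods)) == 0L
  warnings <- character(0)
  if (!all_methods) {
    warnings <- c(warnings,
                  "comprehensive ranking skipped: it needs all three methods enabled.")
  }

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fits <- list(); errors <- character(0)
  for (nm in names(groups)) {
    res <- tryCatch({
      sub <- subset_ct(ct, ann, .data$sample_id %in% groups[[nm]], name = nm)
      if (all_methods) {
        analyze_group(sub, efficiency = config$efficiency,
                      v_cutoff = config$v_cutoff, m_limit = config$m_limit,
                      sd_mode = config$sd_mode, sd_limit = config$sd_limit,
                      normfinder_groups = config$normfinder_groups)
      } else {
        run_partial_group(sub, config)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (config$strict) abort(sprintf("group '%s' failed: %s", nm,
                                       conditionMessage(res)))
      errors[nm] <- conditionMessage(res)
    } else {
      fits[[nm]] <- res
      write_group_files(res, nm, config$outdir)
    }
  }

  report <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("refstab")),
    groups_run = names(fits),
    group_errors = as.list(errors),
    warnings = warnings,
    summary = if (all_methods && length(fits)) {
      dplyr::bind_rows(purrr::map(fits, glance))
    } else {
      NULL
    })
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(c(report, list(fits = fits)))
}

# Subset of analyze_group when not all methods are enabled.
run_partial_group <- function(sub, config) {
  out <- list(group_name = attr(sub, "group_name"), n_samples = ncol(sub))
  q <- NULL
  if (any(c("genorm", "normfinder") %in% config$methods)) {
    q <- relative_quantities(sub, config$efficiency)
  }
  if ("genorm" %in% config$methods) {
    out$genorm <- genorm(q, v_cutoff = config$v_cutoff,
                         m_limit = config$m_limit)
  }
  if ("normfinder" %in% config$methods) {
    groups <- resolve_nf_groups(sub, attr(sub, "annotation"),
                                config$normfinder_groups)
    out$normfinder <- normfinder(q, groups = groups)
  }
  if ("bestkeeper" %in% config$methods) {
    out$bestkeeper <- bestkeeper(sub, sd_mode = config$sd_mode,
                                 sd_limit = config$sd_limit)
  }
  structure(out, class = "partial_analysis")
}

write_group_files <- function(fit, nm, outdir) {
  path <- function(what) file.path(outdir, sprintf("%s.%s.tsv", nm, what))
  if (!is.null(fit$genorm)) {
    readr::write_tsv(tidy(fit$genorm), path("genorm"))
    readr::write_tsv(fit$genorm$v_series, path("genorm_v"))
  }
  if (!is.null(fit$normfinder)) {
    nf_tab <- tidy(fit$normfinder)
    if (fit$normfinder$grouped) {
      extra <- dplyr::left_join(fit$normfinder$intragroup,
                                fit$normfinder$intergroup,
                                by = c("gene", "group"))
      nf_tab <- dplyr::left_join(nf_tab, extra, by = "gene")
    }
    readr::write_tsv(nf_tab, path("normfinder"))
  }
  if (!is.null(fit$bestkeeper)) {
    readr::write_tsv(tidy(fit$bestkeeper), path("bestkeeper"))
  }
  if (!is.null(fit$ranking)) {
    readr::write_tsv(tibble::as_tibble(fit$ranking), path("comprehensive"))
  }
  invisible(NULL)
}

#' Run a ddCt expression report
#'
#' @param ct,annotation Paths to the Ct and annotation tables.
#' @param target Target gene name.
#' @param ref_sets Named list of reference-gene vectors; a single set runs
#'   [ddct()] alone, two or more also produce the divergence summary of
#'   [compare_normalizations()].
#' @param calibrator,group_col Passed to [ddct()].
#' @param outdir Output directory for `ddct.tsv` (and `divergence.tsv`).
#' @param orientation Table orientation.
#' @return List with `folds` and (when applicable) `divergence`, invisibly.
#' @export
run_ddct <- function(ct, annotation, target, ref_sets, calibrator = NULL,
                     group_col = "sample_class", outdir = ".",
                     orientation = "genes-as-rows") {
  mat <- read_ct_table(ct, orientation = orientation)
  ann <- read_sample_annotation(annotation)
  if (!is.list(ref_sets)) ref_sets <- list(refs = ref_sets)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (length(ref_sets) == 1L) {
    r <- ddct(mat, ann, target = target, references = ref_sets[[1L]],
              calibrator = calibrator, group_col = group_col)
    tab <- dplyr::mutate(tibble::as_tibble(r),
                         ref_set = names(ref_sets)[1L], .before = 1L)
    readr::write_tsv(tab, file.path(outdir, "ddct.tsv"))
    return(invisible(list(folds = tab, divergence = NULL)))
  }
  cmp <- compare_normalizations(mat, ann, target = target,
                                ref_sets = ref_sets, calibrator = calibrator,
                                group_col = group_col)
  readr::write_tsv(cmp$folds, file.path(outdir, "ddct.tsv"))
  readr::write_tsv(cmp$divergence, file.path(outdir, "divergence.tsv"))
  invisible(cmp)
}
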