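#' Pipeline run configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with its
#' default. The returned object is serialized alongside every output bundle
#' so a run is reproducible from its artifacts.
#'
#' @param method Baseline method, `"iterpoly"` or `"archull"`.
#' @param order,presmooth,tol Iterative-polynomial baseline parameters.
#' @param nu1_window,nu2_window Lorentzian fit windows, cm^-1.
#' @param snr_threshold SNR exclusion threshold (2.0 model bacteria,
#'   2.5 environmental).
#' @param signal_stat SNR signal statistic, `"mean"` or `"max"`.
#' @param n_signal_points Signal pixels for SNR and peak intensities (3--7).
#' @param ch_region C-H stretching normalization region, cm^-1.
#' @param af_window_nm Autofluorescence intensity window, nm.
#' @param cluster_window_nm Autofluorescence shape window for clustering, nm.
#' @param n_components Principal components fed to X-means.
#' @param k_init,k_max,xmeans_tolerance X-means parameters.
#' @param alpha Familywise significance level for group statistics.
#' @param control_group Name of the nonphototrophic control group defining
#'   the AF-positivity threshold (`NULL`: no thresholding).
#' @param seed Integer seed for the clustering initialization.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(method = "iterpoly", order = 12L, presmooth = 20L,
                       tol = 1e-4, nu1_window = c(1480, 1560),
                       nu2_window = c(1110, 1180), snr_threshold = 2.0,
                       signal_stat = "mean", n_signal_points = 5L,
                       ch_region = c(2800, 3022), af_window_nm = c(737, 776),
                       cluster_window_nm = c(665, 775), n_components = 7L,
                       k_init = 2L, k_max = 20L, xmeans_tolerance = 1e-4,
                       alpha = 0.05, control_group = NULL, seed = 1L) {
  cfg <- list(method = method, order = order, presmooth = presmooth,
              tol = tol, nu1_window = nu1_window, nu2_window = nu2_window,
              snr_threshold = snr_threshold, signal_stat = signal_stat,
              n_signal_points = n_signal_points, ch_region = ch_region,
              af_window_nm = af_window_nm,
              cluster_window_nm = cluster_window_nm,
              n_components = n_components, k_init = k_init, k_max = k_max,
              xmeans_tolerance = xmeans_tolerance, alpha = alpha,
              control_group = control_group, seed = seed)
  if (!cfg$method %in% c("iterpoly", "archull")) {
    stop("invalid config field 'method': ", cfg$method)
  }
  if (!cfg$signal_stat %in% c("mean", "max")) {
    stop("invalid config field 'signal_stat': ", cfg$signal_stat)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected with the offending field name; omitted keys take
#' their defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Per-cell descriptors from decomposed spectra
#'
#' Fits the nu1/nu2 Lorentzians on each cell's Raman component, computes the
#' silent-region SNR, the C-H norm of the last frame, normalized peak
#' intensities and the autofluorescence intensity, and assembles one record
#' per cell. Per-cell fit failures are recorded, not fatal.
#'
#' @param cells List of [timeseries_spectra()].
#' @param decomps Matching list of [decompose_cell()] results.
#' @param config A [run_config()].
#' @param groups Optional character vector of group labels (recycled names
#'   matched by cell id if named).
#' @return A data.frame with one row per cell: centers, FWHMs, SNR,
#'   normalized intensities, `af_intensity`, fit status columns.
#' @export
quantify_cells <- function(cells, decomps, config = run_config(),
                           groups = NULL) {
  stopifnot(length(cells) == length(decomps))
  rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    ts <- cells[[i]]
    dc <- decomps[[i]]
    f1 <- fit_lorentzian_peak(dc$raman, config$nu1_window, mode = "nu1")
    f2 <- fit_lorentzian_peak(dc$raman, config$nu2_window, mode = "nu2")
    ch <- tryCatch(ch_norm(ts$frames[[3L]], region = config$ch_region),
                   error = function(e) NA_real_)
    snr1 <- if (f1$accepted) {
      tryCatch(compute_snr(dc$raman, f1$center,
                           n_signal_points = config$n_signal_points,
                           signal_stat = config$signal_stat)$value,
               error = function(e) NA_real_)
    } else NA_real_
    snr2 <- if (f2$accepted) {
      tryCatch(compute_snr(dc$raman, f2$center,
                           n_signal_points = config$n_signal_points,
                           signal_stat = config$signal_stat)$value,
               error = function(e) NA_real_)
    } else NA_real_
    i1 <- if (f1$accepted && !is.na(ch)) {
      normalized_peak_intensity(dc$raman, f1, ch,
                                n_points = config$n_signal_points)
    } else NA_real_
    i2 <- if (f2$accepted && !is.na(ch)) {
      normalized_peak_intensity(dc$raman, f2, ch,
                                n_points = config$n_signal_points)
    } else NA_real_
    afi <- if (!is.na(ch)) {
      af_intensity(dc$autofluorescence, ch, window_nm = config$af_window_nm)
    } else NA_real_
    rows[[i]] <- data.frame(
      cell_id = ts$cell_id,
      nu1_center = f1$center, nu1_fwhm = f1$fwhm, nu1_accepted = f1$accepted,
      nu2_center = f2$center, nu2_fwhm = f2$fwhm, nu2_accepted = f2$accepted,
      snr = snr1, nu2_snr = snr2,
      nu1_intensity = i1, nu2_intensity = i2,
      ch_norm = ch, af_intensity = afi,
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rows)
  if (!is.null(groups)) {
    if (!is.null(names(groups))) {
      records$group <- unname(groups[records$cell_id])
    } else {
      stopifnot(length(groups) == nrow(records))
      records$group <- as.character(groups)
    }
  }
  records
}

#' Run the full analysis pipeline
#'
#' Orchestrates decomposition, peak fitting, SNR filtering, quantification,
#' AF thresholding, shape clustering and group statistics, end to end and
#' deterministically for a given config.
#'
#' @param cells List of [timeseries_spectra()], or a directory containing
#'   wide-format files readable by [read_timeseries()].
#' @param groups Optional group labels: a character vector (one per cell, or
#'   named by cell id) or a data.frame with `cell_id` and `group` columns.
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, the record table,
#'   cluster labels, statistics report, rejection log and config snapshot are
#'   written there.
#' @return List with `records` (all cells), `kept`, `rejected`,
#'   `af_threshold`, `clusters` (or NULL), `pca` (or NULL), `stats` (or
#'   NULL), `decompositions`, `config`.
#' @export
run_pipeline <- function(cells, groups = NULL, config = run_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(cells) && length(cells) == 1L) {
    files <- sort(list.files(cells, pattern = "\\.(tsv|txt|dat)$",
                             full.names = TRUE))
    if (!length(files)) stop("no spectrum files found in ", cells)
    cells <- lapply(files, read_timeseries)
  }
  if (!length(cells)) stop("no input cells")
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$cell_id)
  }
  decomps <- lapply(cells, decompose_cell, method = config$method,
                    order = config$order, presmooth = config$presmooth,
                    tol = config$tol)
  records <- quantify_cells(cells, decomps, config, groups)
  filt <- apply_snr_filter(records, config$snr_threshold)
  kept <- filt$kept

  thr <- NA_real_
  if (!is.null(config$control_group) && "group" %in% names(records)) {
    ctrl <- records$af_intensity[records$group == config$control_group &
                                   !is.na(records$af_intensity)]
    if (length(ctrl)) {
      thr <- af_threshold(ctrl)
      records$af_positive <- flag_af_positive(records$af_intensity, thr)
      kept$af_positive <- flag_af_positive(kept$af_intensity, thr)
    }
  }

  clusters <- NULL
  pca <- NULL
  cluster_ids <- kept$cell_id
  if (!is.na(thr)) cluster_ids <- kept$cell_id[kept$af_positive %in% TRUE]
  idx <- which(vapply(cells, function(ts) ts$cell_id, character(1))
               %in% cluster_ids)
  if (length(idx) >= max(2L, config$k_init)) {
    af_list <- lapply(decomps[idx], `[[`, "autofluorescence")
    m <- prepare_af_matrix(af_list, window_nm = config$cluster_window_nm)
    if (nrow(m) >= max(2L, config$k_init)) {
      pca <- af_pca(m, n_components = config$n_components)
      clusters <- xmeans(pca$scores, k_init = config$k_init,
                         k_max = config$k_max,
                         tolerance = config$xmeans_tolerance,
                         seed = config$seed)
      clusters$cell_id <- rownames(m)
      cl <- stats::setNames(clusters$labels, rownames(m))
      kept$af_cluster <- unname(cl[kept$cell_id])
    }
  }

  stats_out <- NULL
  if ("group" %in% names(kept) && length(unique(stats::na.omit(kept$group))) >= 2L) {
    by_group <- function(col) {
      ok <- !is.na(kept[[col]]) & !is.na(kept$group)
      split(kept[[col]][ok], kept$group[ok])
    }
    stats_out <- list()
    for (score in c("nu1_intensity", "af_intensity")) {
      g <- by_group(score)
      g <- g[lengths(g) > 0L]
      if (length(g) >= 2L) {
        stats_out[[score]] <- compare_groups(g, alpha = config$alpha)
      }
    }
  }

  out <- list(records = records, kept = kept, rejected = filt$rejected,
              af_threshold = thr, clusters = clusters, pca = pca,
              stats = stats_out, decompositions = decomps, config = config)
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

write_pipeline_outputs <- function(out, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_cell_records(out$records, file.path(output_dir, "records.csv"))
  write_cell_records(out$kept, file.path(output_dir, "records_kept.csv"))
  if (nrow(out$rejected)) {
    write_jsonl(out$rejected[, c("cell_id", "snr", "reject_reason")],
                file.path(output_dir, "rejections.jsonl"))
  }
  if (!is.null(out$clusters)) {
    utils::write.csv(
      data.frame(cell_id = out$clusters$cell_id %||%
                   as.character(seq_along(out$clusters$labels)),
                 cluster = out$clusters$labels),
      file.path(output_dir, "clusters.csv"), row.names = FALSE)
    ev <- out$pca$explained_variance
    utils::write.csv(
      data.frame(component = seq_along(ev), explained_variance = ev),
      file.path(output_dir, "explained_variance.csv"), row.names = FALSE)
  }
  if (!is.null(out$stats)) {
    con <- file(file.path(output_dir, "stats.txt"), "w")
    for (nm in names(out$stats)) {
      writeLines(paste0("== ", nm, " =="), con)
      x <- out$stats[[nm]]
      writeLines(sprintf("Kruskal-Wallis H = %.6g, df = %d, p = %.6g",
                         x$omnibus$H, x$omnibus$df, x$omnibus$p), con)
      writeLines(paste("letters:",
                       paste(names(x$letters), x$letters, sep = ":",
                             collapse = "  ")), con)
    }
    close(con)
  }
  write_run_config(out$config, file.path(output_dir, "config.yaml"))
  invisible(output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
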