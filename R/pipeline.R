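#' Pipeline stage runners
#'
#' File-level wrappers that chain the package's operations into the
#' subcommands exposed by the `thermonet` command-line script
#' (`exec/thermonet`). Each stage reads its inputs from disk, writes its
#' outputs, and logs the run parameters to a `<output>.meta` sidecar so
#' every artifact records how it was produced.
#'
#' @name pipeline
NULL

write_sidecar <- function(path, params) {
  writeLines(sprintf("%s=%s", names(params),
                     vapply(params, function(v) paste(format(v), collapse = ","), character(1))),
             paste0(path, ".meta"))
}

#' @describeIn pipeline Extract a ROI scalar series from a frame stack on
#'   disk (multi-page TIFF or image directory) and write it as a series CSV.
#'   `reduction = "pca"` uses the leading principal-component scores instead
#'   of the spatial mean.
#' @param video_path frame-stack file or directory.
#' @param roi integer vector `c(x0, y0, width, height)` (1-based), or `NULL`
#'   for the full frame.
#' @param out_csv,out_dir output locations.
#' @param subject_id,region,group provenance labels.
#' @param frame_rate_hz sampling rate metadata.
#' @param reduction `"mean"` or `"pca"`.
#' @export
run_extract <- function(video_path, roi = NULL, out_csv,
                        subject_id = "", region = "other", group = "",
                        frame_rate_hz = 9, reduction = c("mean", "pca")) {
  reduction <- match.arg(reduction)
  stack <- load_frame_stack(video_path, frame_rate_hz = frame_rate_hz)
  if (!is.null(roi))
    stack <- crop_roi(stack, roi_spec(roi[1], roi[2], roi[3], roi[4]))
  s <- if (reduction == "mean") {
    mean_series(stack, subject_id = subject_id, region = region, group = group)
  } else {
    pc <- pca_series(stack, k = 1)
    temperature_series(pc$component_series[, 1], frame_rate_hz = frame_rate_hz,
                       subject_id = subject_id, region = region, group = group)
  }
  write_series_csv(s, out_csv)
  write_sidecar(out_csv, list(stage = "extract", video = video_path,
                              roi = if (is.null(roi)) "full" else roi,
                              reduction = reduction))
  invisible(out_csv)
}

#' @describeIn pipeline Prepare and pool all series of a cohort manifest:
#'   zero origin, detrend, amplitude-normalize each series, then concatenate
#'   per group. Writes one pooled CSV per group into `out_dir` and returns
#'   the paths (named by group).
#' @param manifest_csv cohort manifest (columns file, subject_id, region,
#'   group).
#' @export
run_prep <- function(manifest_csv, out_dir) {
  mf <- read_manifest(manifest_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (g in unique(mf$group)) {
    rows <- mf[mf$group == g, , drop = FALSE]
    prepped <- lapply(seq_len(nrow(rows)), function(i) {
      s <- read_series_csv(rows$file[i])
      s$subject_id <- rows$subject_id[i]
      s$region <- rows$region[i]
      s$group <- g
      prep_series(s)
    })
    path <- file.path(out_dir, paste0("pooled_", g, ".csv"))
    write_pooled_csv(pool_series(prepped, group = g), path)
    write_sidecar(path, list(stage = "prep", manifest = manifest_csv,
                             group = g, n_segments = nrow(rows)))
    out[g] <- path
  }
  invisible(out)
}

#' @describeIn pipeline Map a pooled series CSV to a transition network;
#'   writes GraphML and a directed edge list.
#' @param pooled_csv a [write_pooled_csv()] file.
#' @param out_graphml,out_edgelist output files.
#' @param Q quantile count.
#' @param cross_boundaries,keep_self_loops see [build_transition_network()].
#' @export
run_map <- function(pooled_csv, out_graphml, out_edgelist, Q = 20,
                    cross_boundaries = FALSE, keep_self_loops = FALSE) {
  p <- read_pooled_csv(pooled_csv)
  net <- series_to_network(p, Q = Q, cross_boundaries = cross_boundaries,
                           keep_self_loops = keep_self_loops)
  write_network_graphml(net, out_graphml)
  write_network_edgelist(net, out_edgelist)
  write_sidecar(out_edgelist, list(stage = "map", pooled = pooled_csv, Q = Q,
                                   cross_boundaries = cross_boundaries,
                                   keep_self_loops = keep_self_loops))
  invisible(out_edgelist)
}

#' @describeIn pipeline Compute the edge betweenness table and its
#'   cumulative curve from a stored edge list.
#' @param edgelist_path a [write_network_edgelist()] file.
#' @param out_ebc_csv,out_curve_csv output files.
#' @param normalized see [edge_betweenness()].
#' @export
run_ebc <- function(edgelist_path, out_ebc_csv, out_curve_csv,
                    normalized = TRUE) {
  net <- read_network_edgelist(edgelist_path)
  tab <- edge_betweenness(net, normalized = normalized)
  write_ebc_csv(tab, out_ebc_csv)
  write_curve_csv(cumulative_curve(tab), out_curve_csv)
  write_sidecar(out_ebc_csv, list(stage = "ebc", edgelist = edgelist_path,
                                  normalized = normalized))
  invisible(out_ebc_csv)
}

#' @describeIn pipeline Fit the cutoff from control and case betweenness
#'   tables and serialize the model.
#' @param control_ebc_csv,case_ebc_csv [write_ebc_csv()] files.
#' @param out_model model output file.
#' @param q_used quantile count metadata.
#' @export
run_fit <- function(control_ebc_csv, case_ebc_csv, out_model, q_used = 20L) {
  model <- fit_cutoff(read_ebc_csv(control_ebc_csv),
                      read_ebc_csv(case_ebc_csv), q_used = q_used)
  write_cutoff_model(model, out_model)
  write_sidecar(out_model, list(stage = "fit", control = control_ebc_csv,
                                case = case_ebc_csv))
  invisible(out_model)
}

#' @describeIn pipeline Classify subjects (one betweenness-table CSV each)
#'   against a stored model; writes one CSV row per subject:
#'   `subject_id,max_ebc,cutoff,label,margin`.
#' @param model_path a [write_cutoff_model()] file.
#' @param subject_ebc_csvs character vector of [write_ebc_csv()] files,
#'   names used as subject IDs.
#' @export
run_classify <- function(model_path, subject_ebc_csvs, out_csv) {
  model <- read_cutoff_model(model_path)
  ids <- names(subject_ebc_csvs)
  if (is.null(ids)) ids <- basename(subject_ebc_csvs)
  rows <- lapply(seq_along(subject_ebc_csvs), function(i) {
    r <- classify_subject(read_ebc_csv(subject_ebc_csvs[i]), model,
                          subject_id = ids[i])
    data.frame(subject_id = r$subject_id, max_ebc = r$max_ebc,
               cutoff = r$cutoff, label = r$label, margin = r$margin)
  })
  utils::write.csv(do.call(rbind, rows), out_csv, row.names = FALSE, quote = FALSE)
  write_sidecar(out_csv, list(stage = "classify", model = model_path,
                              n_subjects = length(subject_ebc_csvs)))
  invisible(out_csv)
}

#' @describeIn pipeline Generate a two-cohort synthetic dataset on disk:
#'   series CSVs plus a manifest per cohort. The control cohort uses
#'   `regime_delta = 0`; the case cohort uses `delta`.
#' @param n_control,n_case cohort sizes.
#' @param seed master seed (case cohort offset by 10000).
#' @param delta case-cohort regime separation (default `3 * sigma`).
#' @param sigma innovation scale.
#' @param segments_per_subject recordings per subject.
#' @export
run_simulate <- function(out_dir, n_control = 36, n_case = 42, seed = 1L,
                         sigma = 0.05, delta = 3 * sigma,
                         segments_per_subject = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohorts <- list(
    control = simulate_cohort(n_control,
                              generator_params(sigma = sigma, regime_delta = 0, seed = seed),
                              group = "control",
                              segments_per_subject = segments_per_subject),
    case = simulate_cohort(n_case,
                           generator_params(sigma = sigma, regime_delta = delta,
                                            switch_prob = 0.02, seed = seed + 10000L),
                           group = "case",
                           segments_per_subject = segments_per_subject)
  )
  manifests <- character(0)
  for (g in names(cohorts)) {
    rows <- list()
    for (subj in cohorts[[g]]) for (k in seq_along(subj)) {
      s <- subj[[k]]
      f <- sprintf("%s_seg%d.csv", s$subject_id, k)
      write_series_csv(s, file.path(out_dir, f))
      rows[[length(rows) + 1L]] <- data.frame(
        file = f, subject_id = s$subject_id, region = s$region, group = g)
    }
    mpath <- file.path(out_dir, paste0("manifest_", g, ".csv"))
    utils::write.csv(do.call(rbind, rows), mpath, row.names = FALSE, quote = FALSE)
    write_sidecar(mpath, list(stage = "simulate", seed = seed, sigma = sigma,
                              delta = delta, group = g,
                              segments_per_subject = segments_per_subject))
    manifests[g] <- mpath
  }
  invisible(manifests)
}

#' @describeIn pipeline End-to-end convenience chain on synthetic data:
#'   simulate two cohorts, prep and pool them, map to networks, compute
#'   betweenness, fit the cutoff. Returns the fitted model path.
#' @param work_dir working directory for all intermediate artifacts.
#' @export
run_pipeline <- function(work_dir, seed = 1L, Q = 20, n_control = 36,
                         n_case = 42) {
  manifests <- run_simulate(file.path(work_dir, "sim"), n_control = n_control,
                            n_case = n_case, seed = seed)
  pooled <- c(run_prep(manifests["control"], file.path(work_dir, "prep")),
              run_prep(manifests["case"], file.path(work_dir, "prep")))
  ebc <- character(0)
  for (g in names(pooled)) {
    el <- file.path(work_dir, paste0("net_", g, ".edgelist"))
    run_map(pooled[g], file.path(work_dir, paste0("net_", g, ".graphml")), el, Q = Q)
    ebc[g] <- file.path(work_dir, paste0("ebc_", g, ".csv"))
    run_ebc(el, ebc[g], file.path(work_dir, paste0("curve_", g, ".csv")))
  }
  model <- file.path(work_dir, "cutoff_model.txt")
  run_fit(ebc["control"], ebc["case"], model, q_used = Q)
  invisible(model)
}
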