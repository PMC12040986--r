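med_iqr <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

write_run_config <- function(out_dir, config) {
  config$package_version <- as.character(packageVersion("volagree"))
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Compute and summarise segmentation metrics for a set of label maps
#'
#' Reads label maps listed in a manifest, evaluates [pairwise_metrics()]
#' per subject (candidate-vs-observers when a row has role
#' `"candidate"`, all observer pairs otherwise), and writes the per-pair
#' records plus median (IQR) summaries overall and per volume quartile
#' (quartiles of the mean observer volume). Subjects whose masks fail to
#' load or align are recorded in `errors.csv` and skipped; the run
#' fails only when every subject fails.
#'
#' @param manifest data.frame (or CSV path) with columns `subject_id`,
#'   `observer_id`, `path`, and optional `role` (`"observer"` default,
#'   or `"candidate"`).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the records and the summary table.
#' @export
run_metrics <- function(manifest, out_dir) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "observer_id", "path") %in% names(manifest)))
  if (is.null(manifest$role)) manifest$role <- "observer"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- list(); errs <- list()
  for (sid in unique(manifest$subject_id)) {
    rows <- manifest[manifest$subject_id == sid, ]
    res <- tryCatch({
      load1 <- function(r) read_label_map(r$path, subject_id = r$subject_id,
                                          observer_id = r$observer_id)
      obs_rows <- rows[rows$role != "candidate", ]
      masks <- lapply(seq_len(nrow(obs_rows)),
                      function(i) load1(obs_rows[i, ]))
      cand_rows <- rows[rows$role == "candidate", ]
      cand <- if (nrow(cand_rows)) load1(cand_rows[1, ]) else NULL
      pairwise_metrics(masks, candidate = cand)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[sid]] <- data.frame(subject_id = sid, error = conditionMessage(res))
    } else recs[[sid]] <- res
  }
  if (!length(recs))
    stop("all subjects failed: ",
         paste(vapply(errs, `[[`, character(1), "error"), collapse = "; "))
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  write.csv(records, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  if (length(errs))
    write.csv(do.call(rbind, errs), file.path(out_dir, "errors.csv"),
              row.names = FALSE)
  # quartiles of the per-subject mean reference volume
  vref <- tapply(records$volume_b_mm3, records$subject_id, mean)
  qb <- if (length(vref) >= 4) quantile(vref, c(0.25, 0.5, 0.75), type = 7)
        else rep(Inf, 3)
  qi <- setNames(1L + (vref > qb[1]) + (vref > qb[2]) + (vref > qb[3]),
                 names(vref))
  records$quartile <- paste0("Q", qi[records$subject_id])
  summarise <- function(rows, label) {
    out <- data.frame(group = label, n_pairs = nrow(rows))
    for (mcol in c("dice_pct", "assd_mm", "hd95_mm", "rve_pct")) {
      s <- med_iqr(rows[[mcol]])
      out[[paste0(mcol, "_median")]] <- s["median"]
      out[[paste0(mcol, "_q1")]] <- s["q1"]
      out[[paste0(mcol, "_q3")]] <- s["q3"]
    }
    out
  }
  summary_tab <- do.call(rbind, c(
    list(summarise(records, "All")),
    lapply(paste0("Q", 1:4), function(q)
      summarise(records[records$quartile == q, , drop = FALSE], q))))
  write.csv(summary_tab, file.path(out_dir, "metrics_summary.csv"),
            row.names = FALSE)
  write_run_config(out_dir, list(command = "metrics",
                                 n_subjects = length(unique(manifest$subject_id))))
  invisible(list(records = records, summary = summary_tab, errors = errs))
}

#' Run the full clinimetric evaluation of a candidate annotator
#'
#' The complete pipeline: percent deviations of the human volumes from
#' their per-subject mean, the sliding-window LOAM band with CIs,
#' classification of the candidate's volumes against the upper
#' agreement limit, the quartile-stratified comparability table, the
#' re-estimated band with the candidate included as an additional
#' observer, and the CI-overlap comparison of the two bands. All tables
#' are written as CSV next to a JSON run configuration (including the
#' seed); figures are written as PDF and regenerate from the CSVs.
#'
#' @param vm_human a [volume_matrix()] or CSV path ([read_volume_matrix()]).
#' @param candidate_volumes candidate volumes as accepted by
#'   [classify_candidate()], or a CSV path with `subject_id,volume_mm3`.
#' @param out_dir output directory.
#' @param window_size,step sliding-window settings.
#' @param rule classification rule, see [classify_candidate()].
#' @inheritParams loam
#' @param plot write `agreement_plot.pdf` (default TRUE).
#' @return Invisibly, a list with the band, classification, quartile
#'   summary, refit band, and band comparison.
#' @export
run_evaluate <- function(vm_human, candidate_volumes, out_dir,
                         window_size = 40, step = 1, z = 1.96,
                         ci = "gpq", n_draws = 2000, seed = 1L,
                         rule = "one_sided", plot = TRUE) {
  if (is.character(vm_human)) vm_human <- read_volume_matrix(vm_human)
  if (is.character(candidate_volumes))
    candidate_volumes <- read.csv(candidate_volumes, stringsAsFactors = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dev <- relative_deviations(vm_human)
  band <- sliding_window_loam(dev, window_size = window_size, step = step,
                              z = z, ci = ci, n_draws = n_draws, seed = seed)
  cls <- classify_candidate(candidate_volumes, vm_human, band, rule = rule)
  qs <- quartile_summary(cls)
  refit <- refit_with_candidate(vm_human, candidate_volumes,
                                window_size = window_size, step = step,
                                z = z, ci = ci, n_draws = n_draws,
                                seed = (seed + 10000L) %% .Machine$integer.max)
  cmp <- compare_bands(band, refit)
  write_agreement_band(band, file.path(out_dir, "band_human.csv"))
  write_agreement_band(refit, file.path(out_dir, "band_with_candidate.csv"))
  write.csv(cls, file.path(out_dir, "classification.csv"), row.names = FALSE)
  write.csv(as.data.frame(qs), file.path(out_dir, "quartile_summary.csv"),
            row.names = FALSE)
  write.csv(cmp$grid, file.path(out_dir, "band_comparison.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(n_comparable = sum(cls$comparable),
         n_subjects = nrow(cls),
         pct_comparable = 100 * mean(cls$comparable),
         overlap_fraction = cmp$overlap_fraction),
    file.path(out_dir, "evaluation_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plot) {
    grDevices::pdf(file.path(out_dir, "agreement_plot.pdf"), width = 7, height = 5)
    plot(band, overlay = refit, candidate = cls)
    grDevices::dev.off()
  }
  write_run_config(out_dir, list(
    command = "evaluate-observer", window_size = window_size, step = step,
    z = z, ci = ci, n_draws = n_draws, seed = seed, rule = rule))
  invisible(list(band = band, classification = cls, quartiles = qs,
                 refit = refit, comparison = cmp))
}

#' Write a synthetic fixture directory
#'
#' Volume mode: writes the simulated human matrix (`volumes.csv`),
#' candidate volumes (`candidate.csv`), and the truth record
#' (`truth.json`). Phantom mode (`phantoms = TRUE`): writes NIfTI masks
#' plus a `manifest.csv` consumable by [run_metrics()]. Every directory
#' gets the resolved configuration and seed as `run_config.json`.
#'
#' @param cfg a [simulation_config()] or [phantom_config()].
#' @param out_dir output directory.
#' @param phantoms write phantom masks instead of a volume matrix.
#' @param n_subjects,m_observers phantom-mode design size.
#' @return Invisibly, the generated object.
#' @export
run_simulate <- function(cfg, out_dir, phantoms = inherits(cfg, "phantom_config"),
                         n_subjects = 5, m_observers = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (phantoms) {
    sim <- simulate_observer_masks(cfg, n_subjects = n_subjects,
                                   m_observers = m_observers)
    rows <- list()
    for (s in sim$subjects) {
      dir.create(file.path(out_dir, s$subject_id), showWarnings = FALSE)
      tf <- file.path(out_dir, s$subject_id, "truth.nii.gz")
      write_label_map(s$truth, tf)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, observer_id = "truth", path = tf,
        role = "candidate", volume_mm3 = s$volumes[["truth"]])
      for (j in seq_along(s$observers)) {
        of <- file.path(out_dir, s$subject_id, sprintf("observer%02d.nii.gz", j))
        write_label_map(s$observers[[j]], of)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, observer_id = paste0("O", j), path = of,
          role = "observer", volume_mm3 = s$volumes[[paste0("O", j)]])
      }
    }
    write.csv(do.call(rbind, rows), file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
    write_run_config(out_dir, c(unclass(cfg),
                                list(command = "simulate", mode = "phantoms",
                                     n_subjects = n_subjects,
                                     m_observers = m_observers)))
    return(invisible(sim))
  }
  sim <- simulate_volume_matrix(cfg)
  cand <- simulate_candidate(sim)
  write_volume_matrix(sim$volumes, file.path(out_dir, "volumes.csv"))
  write.csv(data.frame(subject_id = names(cand), volume_mm3 = unname(cand)),
            file.path(out_dir, "candidate.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(true_volumes = as.list(sim$true_volumes),
         observer_effects = as.list(sim$observer_effects),
         true_loam_pct = sim$true_loam_pct),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_run_config(out_dir, c(unclass(cfg),
                              list(command = "simulate", mode = "volumes")))
  invisible(sim)
}
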