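#' Export a simulated session in BIDS-like layout
#'
#' Writes one 4-D NIfTI per run (voxels laid out along the first axis), a
#' BIDS-style events TSV per run (`onset`, `duration`, `trial_type`), the
#' ground-truth ROI masks as 3-D NIfTI volumes, and a YAML sidecar with the
#' design parameters, so that externally preprocessed real data in the same
#' layout can be substituted for the post-simulation stages. Requires the
#' RNifti package.
#'
#' @param session A `"sim_session"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bids <- function(session, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("package 'RNifti' is required for NIfTI export", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(session$runs)) {
    y <- session$runs[[r]]
    vol <- array(y, dim = c(nrow(y), 1L, 1L, ncol(y)))
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(1, 1, 1)
    RNifti::writeNifti(img, file.path(dir, sprintf("run-%02d_bold.nii.gz", r)))
    ev <- session$events[session$events$run == r, , drop = FALSE]
    bids <- data.frame(onset = ev$onset_s, duration = ev$duration_s,
                       trial_type = ev$condition)
    utils::write.table(bids, file.path(dir, sprintf("run-%02d_events.tsv", r)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  nv <- nrow(session$runs[[1]])
  for (nm in c("feedback", "feedforward", "surround")) {
    mask <- array(0L, dim = c(nv, 1L, 1L))
    mask[session$rois[[nm]]] <- 1L
    RNifti::writeNifti(RNifti::asNifti(mask),
                       file.path(dir, sprintf("mask-%s.nii.gz", nm)))
  }
  meta <- list(design = unclass(session$design),
               tr_s = session$design$tr_s, seed = session$seed,
               subject_id = session$subject_id, experiment = session$experiment)
  yaml::write_yaml(meta, file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Read a BIDS-like session directory
#'
#' Counterpart of [write_session_bids()]: reconstructs a session object
#' (runs, events, ROI masks) from NIfTI + TSV files. Ground-truth patterns
#' are not recoverable from files and are `NULL`; only the
#' post-simulation stages (GLM, ROI selection, decoding) apply to sessions
#' read this way.
#'
#' @param dir Directory written by [write_session_bids()] (or real data in
#'   the same layout).
#' @return A list with the `"sim_session"` structure (class
#'   `"sim_session"`, `truth` set to `NULL`).
#' @export
read_session_bids <- function(dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("package 'RNifti' is required for NIfTI import", call. = FALSE)
  }
  meta <- yaml::read_yaml(file.path(dir, "session.yaml"))
  design <- do.call(experiment_design,
                    meta$design[names(meta$design) %in%
                                  names(formals(experiment_design))])
  run_files <- sort(list.files(dir, "^run-\\d+_bold\\.nii", full.names = TRUE))
  runs <- lapply(run_files, function(f) {
    vol <- RNifti::readNifti(f)
    matrix(vol, nrow = dim(vol)[1], ncol = dim(vol)[4])
  })
  events <- do.call(rbind, lapply(seq_along(run_files), function(r) {
    ev <- utils::read.delim(file.path(dir, sprintf("run-%02d_events.tsv", r)))
    is_img <- grepl("^img", ev$trial_type)
    out <- data.frame(run = r, onset_s = ev$onset, duration_s = ev$duration,
                      condition = ev$trial_type,
                      trial_type = ifelse(is_img, "image", "mapping"),
                      sequence = NA_integer_,
                      image = NA_integer_, shift_deg = NA_real_,
                      trial = seq_len(nrow(ev)))
    out$image[is_img] <- as.integer(sub("^img(\\d+)_s.*$", "\\1",
                                        ev$trial_type[is_img]))
    out$shift_deg[is_img] <- as.numeric(sub("^img\\d+_s", "",
                                            ev$trial_type[is_img]))
    out
  }))
  rois <- list()
  for (nm in c("feedback", "feedforward", "surround")) {
    f <- file.path(dir, sprintf("mask-%s.nii.gz", nm))
    if (file.exists(f)) rois[[nm]] <- which(as.vector(RNifti::readNifti(f)) > 0)
  }
  structure(list(runs = runs, events = events, rois = rois, truth = NULL,
                 design = design, seed = meta$seed,
                 subject_id = meta$subject_id %||% NA_character_,
                 experiment = meta$experiment %||% NA_integer_),
            class = "sim_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write fold-level decoding results as a tidy CSV
#'
#' @param profiles Named list of per-subject [shift_profile()] data.frames
#'   (or a single data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decoding_table <- function(profiles, path) {
  if (is.data.frame(profiles)) profiles <- list(subject = profiles)
  tab <- do.call(rbind, lapply(names(profiles), function(id) {
    cbind(subject = id, profiles[[id]])
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write study results to disk
#'
#' Emits the condition-wise group table (CSV and/or JSON), the permutation
#' tests, the QC summary and the provenance record.
#'
#' @param results A [run_full_study()] object.
#' @param dir Output directory.
#' @param format `"csv"`, `"json"`, or both.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir, format = c("csv", "json")) {
  stopifnot(inherits(results, "study_results"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if ("csv" %in% format) {
    utils::write.csv(results$group_table, file.path(dir, "group_table.csv"),
                     row.names = FALSE)
    utils::write.csv(results$permutation_tests,
                     file.path(dir, "permutation_tests.csv"), row.names = FALSE)
    utils::write.csv(results$qc$summary, file.path(dir, "qc.csv"),
                     row.names = FALSE)
    utils::write.csv(results$subject_table,
                     file.path(dir, "subject_table.csv"), row.names = FALSE)
  }
  if ("json" %in% format) {
    jsonlite::write_json(
      list(group_table = results$group_table,
           permutation_tests = results$permutation_tests,
           qc = results$qc$summary,
           provenance = results$provenance),
      file.path(dir, "results.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  yaml::write_yaml(results$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Accuracy-versus-shift plot of a study
#'
#' Base-graphics rendering of the group decoding accuracies with bootstrap
#' CI bars, one panel per ROI, separate symbols per test mode, and the
#' chance level marked.
#'
#' @param x A [run_full_study()] object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.study_results <- function(x, ...) {
  tab <- x$group_table
  rois <- unique(tab$roi)
  old <- graphics::par(mfrow = c(1, length(rois)))
  on.exit(graphics::par(old))
  for (roi in rois) {
    sub <- tab[tab$roi == roi, ]
    graphics::plot(NA, xlim = range(sub$delta_deg), ylim = c(30, 100),
                   xlab = "shift delta (deg)", ylab = "accuracy (%)",
                   main = roi)
    graphics::abline(h = 50, lty = 2, col = "grey50")
    for (m in unique(sub$mode)) {
      sm <- sub[sub$mode == m, ]
      sm <- sm[order(sm$delta_deg), ]
      pch <- if (m == "ST") 19 else 1
      graphics::points(sm$delta_deg, sm$group_mean_pct, pch = pch, type = "b")
      graphics::arrows(sm$delta_deg,
                       sm$group_mean_pct - 100 * sm$ci_lower_offset,
                       sm$delta_deg,
                       sm$group_mean_pct + 100 * sm$ci_upper_offset,
                       angle = 90, code = 3, length = 0.03)
    }
    graphics::legend("topright", legend = unique(sub$mode),
                     pch = c(19, 1)[seq_along(unique(sub$mode))], bty = "n")
  }
  invisible(x)
}
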