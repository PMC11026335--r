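# Serialization: trial tables as CSV, pattern matrices as CSV + JSON
# sidecar.

#' Write / read a trial table as CSV
#'
#' Canonical header: `run,trial_index,onset_s,room,object,trial_type,phase`
#' with onsets in seconds. The stimulus duration and inter-trial interval
#' are not part of the table; supply them again when reading (they default
#' to the occlusion-task constants).
#'
#' @param table a `trial_table`.
#' @param path file path.
#' @return `write_trial_table` returns `path` invisibly;
#'   `read_trial_table` returns a `trial_table`.
#' @export
write_trial_table <- function(table, path) {
  validate_trial_table(table)
  out <- data.frame(run = table$run, trial_index = table$trial_index,
                    onset_s = table$onset, room = table$room,
                    object = table$object, trial_type = table$trial_type,
                    phase = table$phase)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @param stim_dur,iti timing constants to attach to the table read back.
#' @export
read_trial_table <- function(path, stim_dur = 4, iti = 2) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("run", "trial_index", "onset_s", "room", "object", "trial_type",
            "phase")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  names(df)[names(df) == "onset_s"] <- "onset"
  tab <- new_trial_table(df[c("run", "trial_index", "onset", "room",
                              "object", "trial_type", "phase")],
                         stim_dur, iti)
  validate_trial_table(tab)
  tab
}

#' Write / read subject pattern matrices
#'
#' `write_patterns` serializes a `subject_patterns` as three plain-text
#' files sharing a prefix: `<prefix>_patterns.csv` (the trial x voxel
#' matrix), `<prefix>_trials.csv` (the trial table) and `<prefix>.json`
#' (sidecar with subject, group, roi, dimensions and ground-truth
#' parameters when present). `read_patterns` enforces shape and label
#' consistency between matrix and sidecar.
#'
#' @param patterns a `subject_patterns`.
#' @param prefix path prefix (no extension).
#' @return `write_patterns` returns `prefix` invisibly; `read_patterns`
#'   returns a `subject_patterns`.
#' @export
write_patterns <- function(patterns, prefix) {
  stopifnot(inherits(patterns, "subject_patterns"))
  write.csv(as.data.frame(patterns$X), paste0(prefix, "_patterns.csv"),
            row.names = FALSE)
  write_trial_table(patterns$trials, paste0(prefix, "_trials.csv"))
  truth <- patterns$truth
  sidecar <- list(
    subject = patterns$subject, group = patterns$group, roi = patterns$roi,
    n_trials = nrow(patterns$X), n_voxels = ncol(patterns$X),
    phase = unique(patterns$trials$phase),
    stim_dur = attr(patterns$trials, "stim_dur"),
    iti = attr(patterns$trials, "iti"),
    truth = if (is.null(truth)) NULL else unclass(truth)
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(prefix)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(prefix) {
  sc_path <- paste0(prefix, ".json")
  if (!file.exists(sc_path))
    stop_data("missing sidecar: expected ", sc_path)
  sc <- jsonlite::fromJSON(sc_path)
  X <- as.matrix(read.csv(paste0(prefix, "_patterns.csv")))
  dimnames(X) <- NULL
  trials <- read_trial_table(paste0(prefix, "_trials.csv"),
                             stim_dur = sc$stim_dur, iti = sc$iti)
  if (nrow(X) != sc$n_trials || ncol(X) != sc$n_voxels)
    stop_data("matrix shape ", nrow(X), "x", ncol(X),
              " does not match sidecar ", sc$n_trials, "x", sc$n_voxels)
  if (nrow(trials) != nrow(X))
    stop_data("trial table rows (", nrow(trials),
              ") do not match pattern rows (", nrow(X), ")")
  truth <- if (!is.null(sc$truth))
    do.call(group_params, sc$truth[c("group", "n_voxels", "w_ctx",
                                     "w_mne_epi", "w_mne_sem", "w_ff",
                                     "noise_sd")])
  structure(list(X = X, trials = trials, subject = sc$subject,
                 group = sc$group, roi = sc$roi, truth = truth),
            class = "subject_patterns")
}
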