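# Plain-text interchange formats: signal CSV, annotation TSV, manifest CSV.

SIGNAL_HEADER <- c("time_s", "ecg", "eda", "rsp", "emg", "temp")

#' Write a recording to a signal CSV
#'
#' One row per sample at 1000 Hz, header `time_s,ecg,eda,rsp,emg,temp`.
#'
#' @param rec An `mm_recording`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- length(rec$channels$ecg)
  dt <- data.table::data.table(
    time_s = (seq_len(n) - 1) / rec$fs,
    ecg = rec$channels$ecg, eda = rec$channels$eda,
    rsp = rec$channels$rsp, emg = rec$channels$emg,
    temp = rec$channels$temp
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Load a recording from a signal CSV
#'
#' Parses the five channels, validates the schema, checks that the time
#' column is strictly increasing and that the implied sampling rate matches
#' 1000 Hz within 0.1%.
#'
#' @param path Signal CSV with header `time_s,ecg,eda,rsp,emg,temp`.
#' @param participant_id,condition Metadata attached to the recording
#'   (usually from the cohort manifest).
#' @return An `mm_recording`.
#' @export
load_recording <- function(path, participant_id = NA_character_,
                           condition = NA_character_) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  dt <- data.table::fread(path)
  missing_cols <- setdiff(SIGNAL_HEADER, names(dt))
  if (length(missing_cols) > 0) {
    stop("missing channel: ", paste(missing_cols, collapse = ", "))
  }
  for (cn in SIGNAL_HEADER) {
    if (!is.numeric(dt[[cn]])) stop("non-numeric values in column ", cn)
    bad <- which(is.na(dt[[cn]]))
    if (length(bad) > 0) {
      stop("parse error in column ", cn, " at row ", bad[1])
    }
  }
  tm <- dt$time_s
  if (length(tm) < 2) stop("recording too short: fewer than 2 samples")
  dts <- diff(tm)
  bad <- which(dts <= 0)
  if (length(bad) > 0) stop("non-monotone time column at row ", bad[1] + 1)
  fs_obs <- 1 / median(dts)
  if (abs(fs_obs - SYNTH_FS) / SYNTH_FS > 0.001) {
    stop(sprintf("sampling rate %.2f Hz differs from %d Hz by more than 0.1%%",
                 fs_obs, SYNTH_FS))
  }
  structure(list(
    participant_id = participant_id,
    condition = condition,
    fs = SYNTH_FS,
    duration = nrow(dt) / SYNTH_FS,
    channels = list(ecg = dt$ecg, eda = dt$eda, rsp = dt$rsp,
                    emg = dt$emg, temp = dt$temp)
  ), class = "mm_recording")
}

#' Write / read an event annotation TSV
#'
#' Annotation files are tab-separated with header
#' `event_id  label  start_s  end_s`.
#'
#' @param annotation Data frame with those four columns.
#' @param path File path.
#' @return `write_annotation()` returns `path` invisibly;
#'   `read_annotation()` returns the annotation data.frame.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(all(c("event_id", "label", "start_s", "end_s") %in%
                  names(annotation)))
  data.table::fwrite(annotation[, c("event_id", "label", "start_s", "end_s")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("event_id", "label", "start_s", "end_s")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    stop("annotation file missing column: ", paste(miss, collapse = ", "))
  }
  ann
}

#' Read a cohort manifest CSV
#'
#' @param path Manifest with columns `participant_id`, `condition`,
#'   `ending`, `recording_path`, `annotation_path`. Relative paths are
#'   resolved against the manifest's directory.
#' @return The manifest data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  man <- as.data.frame(data.table::fread(path))
  need <- c("participant_id", "condition", "ending",
            "recording_path", "annotation_path")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0) {
    stop("manifest missing column: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(man$participant_id)) {
    stop("manifest participant_ids are not unique")
  }
  base <- dirname(path)
  fix <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  man$recording_path <- fix(man$recording_path)
  man$annotation_path <- fix(man$annotation_path)
  man
}
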