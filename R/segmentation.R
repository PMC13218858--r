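# Event segmentation: cut annotated emotional-challenge intervals out of a
# continuous recording. Sample intervals are half-open, [round(start*fs),
# round(end*fs)), so adjacent events partition cleanly with no shared sample.

#' Cut annotated event segments from a recording
#'
#' @param rec An `mm_recording`.
#' @param annotations Data frame with columns `event_id`, `label`,
#'   `start_s`, `end_s`. Intervals must lie within the recording and must
#'   not overlap; they are processed in row order.
#' @return A list of `event_segment` objects, one per annotation row, each
#'   carrying `participant_id`, `event_id`, `label`, `start_s`, `end_s`,
#'   `fs` and the five sliced `channels`.
#' @export
extract_events <- function(rec, annotations) {
  stopifnot(inherits(rec, "mm_recording"))
  if (is.null(annotations) || nrow(annotations) == 0) return(list())
  need <- c("event_id", "label", "start_s", "end_s")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0) {
    stop("annotation table missing column: ", paste(miss, collapse = ", "))
  }
  bad <- annotations$start_s < 0 | annotations$end_s > rec$duration + 1e-9 |
    annotations$start_s >= annotations$end_s
  if (any(bad)) {
    stop("annotation interval out of bounds for event(s): ",
         paste(annotations$event_id[bad], collapse = ", "))
  }
  ord <- order(annotations$start_s)
  sorted <- annotations[ord, ]
  if (nrow(sorted) > 1) {
    ov <- which(sorted$start_s[-1] < sorted$end_s[-nrow(sorted)] - 1e-9)
    if (length(ov) > 0) {
      stop("overlapping annotation intervals for event(s): ",
           paste(unique(c(sorted$event_id[ov], sorted$event_id[ov + 1])),
                 collapse = ", "))
    }
  }
  n <- length(rec$channels$ecg)
  lapply(seq_len(nrow(annotations)), function(i) {
    i0 <- as.integer(round(annotations$start_s[i] * rec$fs)) + 1L
    i1 <- as.integer(round(annotations$end_s[i] * rec$fs))
    i1 <- min(i1, n)
    structure(list(
      participant_id = rec$participant_id,
      event_id = annotations$event_id[i],
      label = annotations$label[i],
      start_s = annotations$start_s[i],
      end_s = annotations$end_s[i],
      fs = rec$fs,
      channels = lapply(rec$channels, function(ch) ch[i0:i1])
    ), class = "event_segment")
  })
}
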