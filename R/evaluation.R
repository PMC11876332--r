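#' Root mean squared error
#'
#' @param predictions,truths Equal-length non-empty numeric vectors
#'   (degrees C).
#' @return `sqrt(mean((predictions - truths)^2))`.
#' @export
rmse <- function(predictions, truths) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length")
  }
  if (length(predictions) == 0) stop("empty input")
  sqrt(mean((predictions - truths)^2))
}

#' Per-temperature-group summary table
#'
#' One row per group: the measured-temperature range, mean and standard
#' deviation, the mean prediction, and the absolute delta between measured
#' and predicted means. Overall delta statistics (max, min, mean across
#' groups) summarize how well group means are recovered.
#'
#' @param results data.frame with columns `group`, `truth`, `prediction`
#'   (e.g. the `predictions` element of a `cv_result`).
#' @return A list with `groups` (the per-group data.frame) and `overall`
#'   (named vector `delta_max`, `delta_min`, `delta_mean`).
#' @export
group_table <- function(results) {
  if (nrow(results) == 0) stop("empty results")
  if (any(is.na(results$group))) stop("every result must be labeled with a group")
  gs <- sort(unique(results$group))
  rows <- lapply(gs, function(g) {
    r <- results[results$group == g, ]
    mm <- mean(r$truth)
    pm <- mean(r$prediction)
    data.frame(group = g,
               measured_min = min(r$truth), measured_max = max(r$truth),
               measured_mean = mm, measured_std = stats::sd(r$truth),
               predicted_mean = pm, delta = abs(mm - pm))
  })
  tab <- do.call(rbind, rows)
  list(groups = tab,
       overall = c(delta_max = max(tab$delta), delta_min = min(tab$delta),
                   delta_mean = mean(tab$delta)))
}

#' Per-group prediction distributions for violin plots
#'
#' @param results data.frame with columns `group` and `prediction`.
#' @return Named list (one entry per group, ascending) with `predictions`
#'   (sorted), `mean`, `q1` and `q3`. Quartiles use linear interpolation
#'   between order statistics (`stats::quantile` type 7).
#' @export
violin_data <- function(results) {
  if (nrow(results) == 0) stop("empty results")
  gs <- sort(unique(results$group))
  out <- lapply(gs, function(g) {
    p <- sort(results$prediction[results$group == g])
    q <- stats::quantile(p, c(0.25, 0.75), names = FALSE, type = 7)
    list(predictions = p, mean = mean(p), q1 = q[1], q3 = q[2])
  })
  names(out) <- as.character(gs)
  out
}

#' Per-recording prediction trace
#'
#' Predicts a temperature for a 100 ms chunk centred (without jitter) on
#' every retained peak of the recording -- including initiation-pulse peaks
#' before L1 -- and flags each as inside or outside the forward-motion
#' interval `[L1, L2]`. Only in-motion points enter the recording-level
#' aggregate; the pre-L1 points exist to show that the needle-at-rest
#' predictions are uninformative.
#'
#' @param net A trained `vt_net`.
#' @param recording An `annotated_recording`.
#' @param peaks A `peak_list` for the recording.
#' @return data.frame with `time` (s), `prediction` (degrees C) and
#'   `in_motion` (logical); zero rows when there are no peaks.
#' @export
recording_trace <- function(net, recording, peaks) {
  if (length(peaks$times) == 0) {
    return(data.frame(time = numeric(0), prediction = numeric(0),
                      in_motion = logical(0)))
  }
  dur <- length(recording$waveform) / recording$sample_rate
  chunks <- slice_peak_centered(recording, peaks, jitter_fraction = 0,
                                window = c(0, dur))
  times <- vapply(chunks, `[[`, numeric(1), "center_time")
  data.frame(time = times,
             prediction = predict_chunks(net, chunks),
             in_motion = times >= recording$L1 & times <= recording$L2)
}
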