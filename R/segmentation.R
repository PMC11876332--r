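#' @title Chunk extraction
#' @description Both dataset-construction strategies cut fixed 100 ms
#'   waveform snippets out of a recording: a plain sliding window with 25%
#'   overlap, and peak-centred slices where each detected event sits near
#'   the chunk centre with a uniform integer displacement of up to 25% of
#'   the chunk width.
#' @name segmentation
NULL

new_chunk <- function(samples, sample_rate, recording_id, center_time, label,
                      source, peak_offset = NA_integer_) {
  structure(list(samples = samples, sample_rate = sample_rate,
                 recording_id = recording_id, center_time = center_time,
                 label = label, source = source, peak_offset = peak_offset),
            class = "chunk")
}

chunk_samples_per_window <- function(sample_rate, chunk_s = 0.1) {
  round(chunk_s * sample_rate)
}

#' Sliding-window chunks of the forward-motion interval
#'
#' Consecutive 100 ms chunks with a 25% overlap (hop of 75 ms), starting at
#' `window[1]`; a final partial window is discarded. The closed-form chunk
#' count is `floor((N - W) / H) + 1` for a window of `N` samples.
#'
#' @param recording An `annotated_recording`.
#' @param window Two-element time window in seconds; defaults to
#'   `c(L1, L2)`, the forward motion inside the foam.
#' @param chunk_s Chunk duration in seconds (default 0.1).
#' @param overlap Fractional overlap between consecutive chunks (default
#'   0.25).
#' @return List of `chunk` objects (empty when the window is shorter than
#'   one chunk).
#' @export
slice_sliding <- function(recording, window = c(recording$L1, recording$L2),
                          chunk_s = 0.1, overlap = 0.25) {
  if (diff(window) <= 0) stop("window must have positive duration")
  sr <- recording$sample_rate
  W <- chunk_samples_per_window(sr, chunk_s)
  H <- W - round(overlap * W)
  s0 <- round(window[1] * sr) + 1L
  s1 <- min(round(window[2] * sr), length(recording$waveform))
  N <- s1 - s0 + 1L
  if (N < W) return(list())
  n_chunks <- (N - W) %/% H + 1L
  lapply(seq_len(n_chunks), function(k) {
    a <- s0 + (k - 1L) * H
    new_chunk(recording$waveform[a:(a + W - 1L)], sr,
              recording$recording_id,
              center_time = (a - 1L + W / 2) / sr,
              label = recording$measured_temperature,
              source = "sliding")
  })
}

#' Peak-centred chunks with uniform displacement
#'
#' One 100 ms chunk per retained peak inside `window`. The peak sample sits
#' at the chunk centre plus an integer displacement drawn uniformly from
#' `[-jitter_fraction * W, +jitter_fraction * W]` (`W` = chunk length), a
#' mild augmentation that stops the network keying on an always-centred
#' transient. Chunks that would cross the recording boundary are discarded
#' with a warning rather than shifted, which would distort the uniform
#' displacement distribution.
#'
#' @param recording An `annotated_recording`.
#' @param peaks A `peak_list` from [detect_peaks()].
#' @param jitter_fraction Maximum displacement as a fraction of the chunk
#'   width (default 0.25).
#' @param window Time window whose peaks are used; defaults to `c(L1, L2)`.
#' @param chunk_s Chunk duration in seconds (default 0.1).
#' @return List of `chunk` objects; each carries its drawn `peak_offset`
#'   (samples).
#' @export
slice_peak_centered <- function(recording, peaks, jitter_fraction = 0.25,
                                window = c(recording$L1, recording$L2),
                                chunk_s = 0.1) {
  sr <- recording$sample_rate
  W <- chunk_samples_per_window(sr, chunk_s)
  Q <- as.integer(floor(jitter_fraction * W))
  times <- peaks$times[peaks$times >= window[1] & peaks$times <= window[2]]
  if (length(times) == 0) return(list())

  d <- sample.int(2L * Q + 1L, length(times), replace = TRUE) - Q - 1L
  n <- length(recording$waveform)
  out <- vector("list", length(times))
  dropped <- 0L
  for (k in seq_along(times)) {
    p_idx <- round(times[k] * sr) + 1L
    pos <- W %/% 2L + d[k]          # 1-based peak position inside the chunk
    a <- p_idx - pos + 1L
    b <- a + W - 1L
    if (a < 1L || b > n) {
      dropped <- dropped + 1L
      next
    }
    out[[k]] <- new_chunk(recording$waveform[a:b], sr,
                          recording$recording_id,
                          center_time = (a - 1L + W / 2) / sr,
                          label = recording$measured_temperature,
                          source = "peak_centered",
                          peak_offset = d[k])
  }
  if (dropped > 0) {
    warning(dropped, " chunk(s) crossing the recording boundary discarded")
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Tabulate a list of chunks
#'
#' @param chunks List of `chunk` objects.
#' @return data.frame with one row per chunk: `chunk_id`, `recording_id`,
#'   `label` (degrees C), `center_time` (s), `source`, `peak_offset`.
#' @export
chunk_index <- function(chunks) {
  if (length(chunks) == 0) {
    return(data.frame(chunk_id = integer(0), recording_id = character(0),
                      label = numeric(0), center_time = numeric(0),
                      source = character(0), peak_offset = integer(0)))
  }
  data.frame(
    chunk_id = seq_along(chunks),
    recording_id = vapply(chunks, `[[`, character(1), "recording_id"),
    label = vapply(chunks, `[[`, numeric(1), "label"),
    center_time = vapply(chunks, `[[`, numeric(1), "center_time"),
    source = vapply(chunks, `[[`, character(1), "source"),
    peak_offset = vapply(chunks, function(ch) as.integer(ch$peak_offset),
                         integer(1)),
    stringsAsFactors = FALSE)
}

#' Detect peaks and cut peak-centred chunks for a whole recording set
#'
#' Convenience wrapper running [smooth_envelope()], [detect_peaks()] and
#' [slice_peak_centered()] over a list of recordings.
#'
#' @param recordings List of `annotated_recording` objects.
#' @param jitter_fraction See [slice_peak_centered()].
#' @param env_params See [smooth_envelope()].
#' @return List of `chunk` objects pooled over all recordings.
#' @export
peak_chunks <- function(recordings, jitter_fraction = 0.25,
                        env_params = envelope_params()) {
  out <- lapply(recordings, function(rec) {
    env <- smooth_envelope(rec$waveform, env_params)
    pk <- detect_peaks(env, rec$sample_rate)
    slice_peak_centered(rec, pk, jitter_fraction)
  })
  do.call(c, out)
}
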