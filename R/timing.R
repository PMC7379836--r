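#' Signal timing metadata
#'
#' Describes when a cellular event is active within a recording.  The
#' active interval is `[t_onset, t_end]`; everything else within
#' `[0, duration]` is silence.  Silence intervals are where noise power and
#' baseline medians are measured, so every processing stage carries this
#' object along.
#'
#' @param t_onset Event onset time (s).
#' @param t_end End of the active interval (s).  For persistent events
#'   (electroporation steps) this equals `duration`.
#' @param duration Total record duration (s).
#' @return An object of class `signal_timing` with fields `t_onset`,
#'   `t_end`, `duration`.
#' @examples
#' tm <- signal_timing(2.5, 2.8, 5)
#' active_frames(tm, fps = 100)[1:3]
#' @export
signal_timing <- function(t_onset, t_end, duration) {
  stopifnot(is_num(t_onset), is_num(t_end), is_num(duration))
  if (!(0 <= t_onset && t_onset < t_end && t_end <= duration))
    stopf("invalid timing: need 0 <= t_onset < t_end <= duration (got %g, %g, %g)",
          t_onset, t_end, duration)
  structure(list(t_onset = t_onset, t_end = t_end, duration = duration),
            class = "signal_timing")
}

#' @export
print.signal_timing <- function(x, ...) {
  cat(sprintf("signal_timing: active [%g, %g] s of %g s\n",
              x$t_onset, x$t_end, x$duration))
  invisible(x)
}

#' Frame indices of the active / silence intervals
#'
#' Frame `k` (1-based) occurs at time `t = (k - 1) / fps`.
#'
#' @param timing A [signal_timing()] object.
#' @param fps Frame rate (Hz).
#' @param n_frames Number of frames; defaults to `round(duration * fps)`.
#' @return Integer vector of frame indices.
#' @export
active_frames <- function(timing, fps, n_frames = round(timing$duration * fps)) {
  t <- (seq_len(n_frames) - 1) / fps
  which(t >= timing$t_onset & t <= timing$t_end)
}

#' @rdname active_frames
#' @export
silence_frames <- function(timing, fps, n_frames = round(timing$duration * fps)) {
  setdiff(seq_len(n_frames), active_frames(timing, fps, n_frames))
}
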