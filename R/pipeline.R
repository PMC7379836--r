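## Full-pipeline orchestration (mask -> MESS -> bleach correction -> BSS ->
## baseline centering -> SNR), the evaluation metrics, the fluorescence ->
## membrane-potential calibration, and the comparison baselines (blank
## subtraction, averaging, Butterworth low-pass).

#' Detect signal timing from the whole-cell mean trace
#'
#' Onset: time of the biggest modulus of the first difference.  End:
#' for persistent signals the record duration; for transitory signals
#' the first post-peak time the trace re-enters the noise band
#' (3 x MAD of the pre-onset samples around the pre-onset median).
#'
#' @param trace Whole-cell mean over time.
#' @param fps Frame rate (Hz).
#' @param transitory Flag.
#' @return A [signal_timing()].
#' @export
detect_timing <- function(trace, fps, transitory = TRUE) {
  n <- length(trace)
  if (n < 3) stopf("trace too short for timing detection")
  d <- diff(trace)
  if (max(abs(d)) == 0) stopf("no event detected: flat trace")
  i_on <- which.max(abs(d))
  t_onset <- i_on / fps
  duration <- n / fps
  if (!transitory)
    return(signal_timing(t_onset, duration, duration))
  pre <- trace[seq_len(i_on)]
  base <- stats::median(pre)
  band <- 3 * stats::mad(pre)
  dev <- abs(trace - base)
  i_pk <- i_on + which.max(dev[(i_on + 1):n])
  i_end <- which(dev < band & seq_len(n) > i_pk)[1]
  t_end <- if (is.na(i_end)) duration else (i_end - 1) / fps
  if (t_end <= t_onset) t_end <- duration
  signal_timing(t_onset, t_end, duration)
}

#' Relative amplitude error
#'
#' `(measured - true) / true`: positive = overestimate, `-1` = signal
#' lost entirely.
#'
#' @param measured,true_amplitude Amplitudes (same units).
#' @return Signed ratio.
#' @export
e_r_amp <- function(measured, true_amplitude) {
  if (any(true_amplitude == 0)) stopf("true amplitude must be non-zero")
  (measured - true_amplitude) / true_amplitude
}

## Maximal-amplitude modulus within the active interval.
peak_amplitude <- function(trace, timing, fps) {
  act <- active_frames(timing, fps, length(trace))
  max(abs(trace[act]))
}

#' Evaluation metrics of a filtered trace against the known truth
#'
#' @param filtered,truth Numeric vectors (same length).
#' @param timing A [signal_timing()].
#' @param fps Frame rate.
#' @return List: `e_r_amp` (relative maximal-amplitude error), `r`
#'   (Pearson correlation over the active interval), `rmse`,
#'   `peak_e_r_amp` (relative error at the true peak instant),
#'   `stationary_e_r_amp` (relative error of the post-onset median).
#' @export
trace_metrics <- function(filtered, truth, timing, fps) {
  act <- active_frames(timing, fps, length(truth))
  i_pk <- act[which.max(abs(truth[act]))]
  post <- act
  st_true <- stats::median(truth[post])
  list(
    e_r_amp = e_r_amp(peak_amplitude(filtered, timing, fps),
                      peak_amplitude(truth, timing, fps)),
    r = stats::cor(filtered[act], truth[act]),
    rmse = sqrt(mean((filtered - truth)^2)),
    peak_e_r_amp = e_r_amp(filtered[i_pk], truth[i_pk]),
    stationary_e_r_amp = if (st_true != 0)
      e_r_amp(stats::median(filtered[post]), st_true) else NA_real_)
}

#' Per-ROI SNR estimate (dB)
#'
#' Filtered-signal power over noise power, the latter taken from the
#' silence intervals of the bleach-corrected but unfiltered traces.
#'
#' @param filtered,corrected `trace_set`s with aligned rows.
#' @param timing A [signal_timing()].
#' @return Numeric vector of per-ROI SNR (dB).
#' @export
estimate_snr_db <- function(filtered, corrected, timing = filtered$timing) {
  stopifnot(inherits(filtered, "trace_set"), inherits(corrected, "trace_set"))
  T_ <- ncol(filtered$traces)
  sil <- silence_frames(timing, filtered$fps, T_)
  if (length(sil) == 0) stopf("empty silence interval")
  vapply(seq_len(filtered$n), function(j) {
    p_sig <- mean(filtered$traces[j, ]^2)
    noise <- corrected$traces[j, sil]
    p_noise <- mean((noise - mean(noise))^2)
    10 * log10(p_sig / p_noise)
  }, numeric(1))
}

#' Calibrate electroporation fluorescence to membrane potential
#'
#' `V(j, t) = -(EP(j, t) / AP_peak(j)) * AP_amp + V_rest`: the per-ROI
#' fluorescence deflection is normalized by that ROI's maximal AP
#' deflection and mapped linearly so that zero fluorescence change is
#' the resting potential and a full AP-sized negative deflection is the
#' AP peak (+40 mV with the defaults).
#'
#' @param ep_traces `trace_set` of electroporation traces (A.U.).
#' @param ap_peak Per-ROI modulus of the maximal AP amplitude (A.U.).
#' @param AP_amp AP amplitude (mV, default 120).
#' @param V_rest Resting potential (mV, default -80).
#' @return `trace_set` in mV.
#' @export
calibrate <- function(ep_traces, ap_peak, AP_amp = 120, V_rest = -80) {
  stopifnot(inherits(ep_traces, "trace_set"))
  if (length(ap_peak) != ep_traces$n)
    stopf("need one AP_peak per ROI (%d != %d)", length(ap_peak),
          ep_traces$n)
  if (any(!(ap_peak > 0))) stopf("AP_peak must be positive for every ROI")
  out <- ep_traces
  out$traces <- -(ep_traces$traces / ap_peak) * AP_amp + V_rest
  out
}

#' Run the full pipeline on a video
#'
#' Mask (auto-generated unless given) -> MESS -> ROI means -> timing
#' (detected unless configured) -> per-ROI photobleaching fit and
#' correction (DBPC with the exponential+linear model for transitory
#' signals, FDPC with the exponential+linear+step model for persistent
#' ones) -> BSS -> source selection -> reconstruction -> baseline
#' centering -> per-ROI SNR estimate.
#'
#' @param video A `video`.
#' @param mask Optional `mask`.
#' @param config A [run_config()].
#' @return List with `rois`, `raw`, `timing`, `fits`, `corrected`,
#'   `filtered`, `decomp`, `snr_db`, `config`.
#' @export
metroid <- function(video, mask = NULL, config = run_config()) {
  stopifnot(inherits(video, "video"), inherits(config, "run_config"))
  if (is.null(mask)) mask <- make_mask(video)
  rois <- mess(mask, config$n_in, config$n_out)
  raw <- roi_means(video, rois)

  whole <- rowMeans(matrix(video$frames, nrow = dim(video$frames)[1])[,
                           which(mask$pixels), drop = FALSE])
  duration <- dim(video$frames)[1] / video$fps
  timing <- if (!is.na(config$t_onset)) {
    t_end <- if (!is.na(config$t_end)) config$t_end else duration
    signal_timing(config$t_onset, t_end, duration)
  } else detect_timing(whole, video$fps, config$transitory)
  raw$timing <- timing

  if (config$bleach_correction) {
    mode <- if (config$transitory) "DBPC" else "FDPC"
    model <- if (config$transitory) "exp_lin" else "exp_lin_step"
    fits <- vector("list", raw$n)
    corrected <- raw
    for (j in seq_len(raw$n)) {
      fits[[j]] <- fit_bleach(raw$traces[j, ], timing, video$fps, mode,
                              model)
      corrected$traces[j, ] <- correct_bleach(raw$traces[j, ], fits[[j]],
                                              video$fps)
    }
  } else {
    fits <- NULL
    corrected <- raw
  }

  decomp <- decompose(corrected, config$method, config$m,
                      seed = config$seed)
  decomp <- if (identical(config$selection, "auto"))
    auto_select(decomp, timing)
  else { decomp$selected <- as.integer(config$selection); decomp }
  filtered <- reconstruct(decomp, wavelet = config$wavelet)
  for (j in seq_len(filtered$n))
    filtered$traces[j, ] <- center_baseline(filtered$traces[j, ], timing,
                                            video$fps)
  filtered$timing <- timing
  centered <- corrected
  for (j in seq_len(centered$n))
    centered$traces[j, ] <- center_baseline(centered$traces[j, ], timing,
                                            video$fps)
  snr_db <- estimate_snr_db(filtered, centered, timing)

  list(rois = rois, raw = raw, timing = timing, fits = fits,
       corrected = centered, filtered = filtered, decomp = decomp,
       snr_db = snr_db, config = config)
}

## ---- comparison baselines --------------------------------------------

#' Blank-subtraction baseline (BkS)
#'
#' Both videos are normalized by their first frames, the blank is
#' subtracted, and the normalization is reversed.  First-frame pixels
#' equal to zero are replaced by the frame's global mean (count
#' recorded in the `n_guarded` attribute).
#'
#' @param video,blank `video` objects of equal shape.
#' @return T x H x W array (may contain negative values).
#' @export
baseline_bks <- function(video, blank) {
  stopifnot(inherits(video, "video"), inherits(blank, "video"),
            identical(dim(video$frames), dim(blank$frames)))
  v1 <- video$frames[1, , ]; b1 <- blank$frames[1, , ]
  ng <- sum(v1 == 0) + sum(b1 == 0)
  v1[v1 == 0] <- mean(video$frames[1, , ])
  b1[b1 == 0] <- mean(blank$frames[1, , ])
  T_ <- dim(video$frames)[1]
  out <- video$frames - blank$frames * rep(v1 / b1, each = T_)
  attr(out, "n_guarded") <- ng
  out
}

#' Blank subtraction with detrending (BkSD)
#'
#' [baseline_bks()] followed by removal of a least-squares line fitted
#' on the silence intervals of each ROI trace.
#'
#' @inheritParams baseline_bks
#' @param rois A `roi_set`.
#' @param timing A [signal_timing()].
#' @return `trace_set` of detrended ROI traces.
#' @export
baseline_bksd <- function(video, blank, rois, timing) {
  arr <- baseline_bks(video, blank)
  tr <- roi_means_raw(arr, rois)
  T_ <- ncol(tr)
  tt <- (seq_len(T_) - 1) / video$fps
  sil <- silence_frames(timing, video$fps, T_)
  for (j in seq_len(nrow(tr))) {
    fit <- stats::lm.fit(cbind(1, tt[sil]), tr[j, sil])
    tr[j, ] <- tr[j, ] - (fit$coefficients[1] + fit$coefficients[2] * tt)
  }
  new_trace_set(tr, video$fps, timing)
}

#' Averaging baseline (avgN)
#'
#' Pixelwise mean of N same-signal videos followed by per-ROI
#' photobleaching correction (DBPC/exponential+linear for transitory,
#' FDPC/exponential+linear+step for persistent signals).
#'
#' @param videos List of `video` objects (equal shapes).
#' @param rois A `roi_set`.
#' @param timing A [signal_timing()].
#' @param transitory Flag selecting the correction scheme.
#' @return `trace_set` of corrected ROI traces of the averaged video.
#' @export
baseline_avg <- function(videos, rois, timing, transitory = TRUE) {
  stopifnot(length(videos) >= 2)
  d <- dim(videos[[1]]$frames)
  acc <- array(0, d)
  for (v in videos) {
    stopifnot(identical(dim(v$frames), d))
    acc <- acc + v$frames
  }
  acc <- acc / length(videos)
  tr <- roi_means_raw(acc, rois)
  fps <- videos[[1]]$fps
  mode <- if (transitory) "DBPC" else "FDPC"
  model <- if (transitory) "exp_lin" else "exp_lin_step"
  for (j in seq_len(nrow(tr))) {
    f <- fit_bleach(tr[j, ], timing, fps, mode, model)
    tr[j, ] <- correct_bleach(tr[j, ], f, fps)
  }
  new_trace_set(tr, fps, timing)
}

#' Butterworth low-pass comparison filter
#'
#' Zero-phase (forward-backward) 5th-order low-pass, the classical
#' digital-filtering alternative the BSS methods are compared against.
#'
#' @param trace Numeric vector.
#' @param fps Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz, default 10).
#' @param order Filter order (default 5).
#' @return Filtered trace.
#' @export
butter_lowpass <- function(trace, fps, cutoff = 10, order = 5) {
  bf <- signal::butter(order, cutoff / (fps / 2), type = "low")
  as.numeric(signal::filtfilt(bf, trace))
}
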