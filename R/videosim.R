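## Artificial fluorescence videos: basal fluorescence + BF-modulated
## membrane-potential signal with per-ROI SNR gains + double-exponential
## photobleaching + per-pixel Poisson shot noise.  Doubles as the fixture
## factory for the full-pipeline tests.

#' Estimate the basal fluorescence (illumination) image
#'
#' Gaussian-filters the first frame with a kernel as large as the
#' smallest spatial dimension, then normalizes the smooth image and
#' multiplies by the video's grand mean, so `mean(BF)` equals the grand
#' mean exactly.
#'
#' @param video A `video` object.
#' @return H x W basal fluorescence matrix (A.U.).
#' @export
estimate_bf <- function(video) {
  stopifnot(inherits(video, "video"))
  frame <- video$frames[1, , ]
  k <- min(dim(frame))
  if (k %% 2 == 0) k <- k - 1L
  brush <- EBImage::makeBrush(k, "Gaussian", sigma = k / 6)
  sm <- EBImage::filter2(frame, brush)
  sm <- pmax(sm, 0)
  sm / mean(sm) * mean(video$frames)
}

#' Uniform-field parameters for the prolate-spheroid potential model
#'
#' @param E Applied field magnitude (V/m).
#' @param a,b Major / minor semi-axes (um); if `NA` they are measured
#'   from the mask.
#' @param axis_angle Field direction relative to the cell major axis
#'   (radians; 0 = field along the major axis).
#' @param V_rest Resting potential (mV).
#' @param tau Post-pulse decay constant (s); the default 0.0167 s brings
#'   the deviation within ~5 % of zero 50 ms after the shock.
#' @param t_pulse Pulse time (s).
#' @param um_per_px Pixel size (um).
#' @return A `spheroid_field` list.
#' @export
spheroid_field <- function(E = 4e4, a = NA, b = NA, axis_angle = 0,
                           V_rest = -80, tau = 0.0167, t_pulse = 2.5,
                           um_per_px = 1) {
  stopifnot(is_num(E), is_num(tau), tau > 0, is_num(t_pulse))
  if (!is.na(a) && !is.na(b) && !(a >= b && b > 0))
    stopf("need a >= b > 0")
  structure(list(E = E, a = a, b = b, axis_angle = axis_angle,
                 V_rest = V_rest, tau = tau, t_pulse = t_pulse,
                 um_per_px = um_per_px),
            class = "spheroid_field")
}

## Depolarizing factor of a prolate spheroid along its major axis.
prolate_L <- function(a, b) {
  if (a == b) return(1 / 3)
  e <- sqrt(1 - (b / a)^2)
  (1 - e^2) / e^3 * (atanh(e) - e)
}

#' Field-induced membrane-potential deviation map (peak matrix)
#'
#' Steady-state induced transmembrane potential of a non-conducting
#' prolate spheroidal shell in a uniform field (Klee-Plonsey):
#' `dV = E * u / (1 - L_a) + E_perp * v / (1 - L_b)` with `u`, `v` the
#' coordinates along / across the major axis and `L` the depolarizing
#' factors (`L = 1/3` in the spherical limit, recovering the classic
#' `1.5 E a` polar deviation).  Depolarization toward the cathode,
#' hyperpolarization toward the anode; zero on the equatorial plane.
#'
#' @param mask A `mask` (defines center, axes and the support of the
#'   map).
#' @param field A [spheroid_field()].
#' @return H x W matrix of peak deviations (mV); 0 outside the mask.
#' @export
spheroid_potential <- function(mask, field) {
  stopifnot(inherits(mask, "mask"), inherits(field, "spheroid_field"))
  px <- mask$pixels
  idx <- which(px, arr.ind = TRUE)
  ctr <- colMeans(idx)
  theta <- mask_orientation(px)
  if (is.na(theta)) theta <- 0
  th <- theta * pi / 180
  ## u along the major axis, v across (pixel units)
  dy <- idx[, 1] - ctr[1]; dx <- idx[, 2] - ctr[2]
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  a <- field$a; b <- field$b
  if (is.na(a)) a <- max(abs(u)) * field$um_per_px
  if (is.na(b)) b <- max(abs(v)) * field$um_per_px
  if (!(a >= b)) { tmp <- a; a <- b; b <- tmp }
  La <- prolate_L(a, b)
  Lb <- (1 - La) / 2
  E_par <- field$E * cos(field$axis_angle)
  E_perp <- field$E * sin(field$axis_angle)
  ## um * V/m -> mV is a factor 1e-3
  dv <- (E_par * u / (1 - La) + E_perp * v / (1 - Lb)) *
    field$um_per_px * 1e-3
  out <- matrix(0, nrow(px), ncol(px))
  out[idx] <- dv
  out
}

#' Noise-free, bleach-free pure signal video
#'
#' AP: the normalized AP surrogate times `BF` at every mask pixel
#' (rank-1 space-time structure).  Electroporation: per-pixel membrane
#' potential `V_rest` before the pulse, then `(V_rest + peak(x, y))`
#' decaying exponentially toward 0 mV; the pre-pulse baseline is
#' subtracted before normalization so the signal term is zero during
#' silence, then the normalized trace is multiplied by `BF`.
#'
#' @param bf Basal fluorescence matrix.
#' @param mask A `mask` limiting the signal support.
#' @param kind `"AP"` or `"electroporation"`.
#' @param fps,duration,t_onset Timing of the record (s).
#' @param field A [spheroid_field()] (electroporation only).
#' @param ... Passed to [gen_ap()] (AP only).
#' @return List with `video` (T x H x W array), `timing`, and for
#'   electroporation the `peak` matrix.
#' @export
pure_signal_video <- function(bf, mask, kind = c("AP", "electroporation"),
                              fps, duration = 5, t_onset = 2.5,
                              field = spheroid_field(), ...) {
  kind <- match.arg(kind)
  px <- mask$pixels
  mbf <- bf * px
  if (kind == "AP") {
    src <- gen_ap(fps, duration, t_onset, ...)
    v <- src$values / max(abs(src$values))
    frames <- array(0, c(length(v), nrow(px), ncol(px)))
    for (t in which(v != 0)) frames[t, , ] <- v[t] * mbf
    return(list(video = frames, timing = src$timing, peak = NULL))
  }
  peak <- spheroid_potential(mask, field)
  n <- round(duration * fps)
  tt <- (seq_len(n) - 1) / fps
  post <- which(tt >= field$t_pulse)
  frames <- array(0, c(n, nrow(px), ncol(px)))
  dev_abs_max <- max(abs(field$V_rest + peak[px]), abs(field$V_rest))
  ## deviation from rest: 0 before the pulse, then the charged membrane
  ## (V_rest + peak) relaxing toward 0 mV with constant tau
  for (j in seq_along(post)) {
    decay <- exp(-(tt[post[j]] - field$t_pulse) / field$tau)
    Vt <- (field$V_rest + peak) * decay
    frames[post[j], , ] <- (Vt - field$V_rest) / dev_abs_max * mbf
  }
  timing <- signal_timing(field$t_pulse, duration, duration)
  list(video = frames, timing = timing, peak = peak)
}

#' Per-pixel zero-mean Poisson shot-noise video
#'
#' @param lam_map H x W matrix of Poisson rates (or a scalar), all > 0.
#' @param n_frames Number of frames.
#' @param seed Integer seed; each pixel's noise is drawn independently.
#' @param shape Required `c(H, W)` when `lam_map` is scalar.
#' @return T x H x W array.
#' @export
sim_noise_video <- function(lam_map, n_frames, seed = 0L, shape = NULL) {
  if (length(lam_map) == 1) {
    stopifnot(!is.null(shape))
    lam_map <- matrix(lam_map, shape[1], shape[2])
  }
  if (any(lam_map <= 0)) stopf("lambda map must be positive everywhere")
  H <- nrow(lam_map); W <- ncol(lam_map)
  noise <- with_seed(seed,
    stats::rpois(n_frames * H * W, rep(as.vector(lam_map),
                                       each = n_frames)))
  array(noise - rep(as.vector(lam_map), each = n_frames),
        c(n_frames, H, W))
}

#' Per-ROI gain matrix reaching target SNRs
#'
#' For each ROI the gain `g_j = sqrt(10^(db/10) * P_noise_j / P_sig_j)`
#' (powers measured on the ROI-mean traces of the pure-signal and
#' pure-noise videos) is written into every ROI pixel.
#'
#' @param signal_video T x H x W pure-signal array.
#' @param noise_video T x H x W pure-noise array.
#' @param rois A `roi_set`.
#' @param target_db Scalar or per-ROI vector of SNR targets (dB).
#' @return H x W gain matrix (0 outside the ROIs).
#' @export
gain_for_snr <- function(signal_video, noise_video, rois, target_db) {
  ids <- sort(unique(rois$labels[rois$labels > 0]))
  if (length(target_db) == 1) target_db <- rep(target_db, length(ids))
  stopifnot(length(target_db) == length(ids))
  T_ <- dim(signal_video)[1]
  sflat <- matrix(signal_video, nrow = T_)
  nflat <- matrix(noise_video, nrow = T_)
  g <- matrix(0, dim(signal_video)[2], dim(signal_video)[3])
  for (i in seq_along(ids)) {
    sel <- which(rois$labels == ids[i])
    ps <- mean(rowMeans(sflat[, sel, drop = FALSE])^2)
    pn <- mean(rowMeans(nflat[, sel, drop = FALSE])^2)
    if (ps == 0) stopf("ROI %d has zero signal power", ids[i])
    g[sel] <- sqrt(10^(target_db[i] / 10) * pn / ps)
  }
  g
}

default_bf <- function(H, W, mean_intensity = 400) {
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  illum <- exp(-(((g$r - H / 2) / H)^2 + ((g$c - W / 2) / W)^2))
  bf <- matrix(illum, H, W)
  bf / mean(bf) * mean_intensity
}

#' Simulation specification for an artificial video
#'
#' Collects every knob of the video generator with the study defaults:
#' a 61 x 121 frame holding an elliptical cell, 50 fps, 5 s, signal at
#' 2.5 s, Poisson rate 225 everywhere, target SNR -10 dB in all ROIs,
#' and a double-exponential photobleaching of 3 % + 1 % of `BF` with
#' rates 0.05 and 0.5 per second.
#'
#' @param H,W Frame size (px).
#' @param fps Frame rate (Hz).
#' @param duration Record length (s).
#' @param kind `"AP"` or `"electroporation"`.
#' @param target_db Scalar or per-ROI SNR target (dB).
#' @param lam Poisson rate map (scalar or H x W).
#' @param n_in,n_out MESS ROI counts.
#' @param bleach `NULL` for no bleaching, or
#'   `list(a1, b1, a2, b2)` (fractional amplitudes, rates 1/s).
#' @param mask Optional `mask`; default is a filled ellipse.
#' @param bf Optional basal fluorescence matrix; default a smooth
#'   vignetting profile of mean 400 A.U.
#' @param field A [spheroid_field()] for electroporation.
#' @param seed Master seed.
#' @return A `video_sim_spec` list.
#' @export
video_sim_spec <- function(H = 61, W = 121, fps = 100, duration = 5,
                           kind = c("AP", "electroporation"),
                           target_db = -10, lam = 225, n_in = 16L,
                           n_out = 16L,
                           bleach = list(a1 = 0.03, b1 = 0.05,
                                         a2 = 0.01, b2 = 0.5),
                           mask = NULL, bf = NULL,
                           field = spheroid_field(), seed = 0L) {
  kind <- match.arg(kind)
  if (is.null(mask))
    mask <- ellipse_mask(H, W, round(0.42 * H), round(0.45 * W))
  if (is.null(bf)) bf <- default_bf(H, W)
  structure(list(H = H, W = W, fps = fps, duration = duration, kind = kind,
                 target_db = target_db, lam = lam, n_in = n_in,
                 n_out = n_out, bleach = bleach, mask = mask, bf = bf,
                 field = field, seed = seed),
            class = "video_sim_spec")
}

bleach_component <- function(bf, n_frames, fps, bleach) {
  if (is.null(bleach)) return(array(0, c(n_frames, nrow(bf), ncol(bf))))
  tt <- (seq_len(n_frames) - 1) / fps
  f <- bleach$a1 * (exp(-bleach$b1 * tt) - 1) +
    bleach$a2 * (exp(-bleach$b2 * tt) - 1)
  outer(f, bf)  # T x H x W
}

#' Compose an artificial fluorescence video
#'
#' `F(x,y,t) = BF + g * Signal + Photobleaching(BF, t) + Noise`, with
#' negative intensities clipped to zero (count recorded in the
#' `n_clipped` attribute).  The ROIs used for the per-ROI gains are
#' produced by MESS on the spec's mask.
#'
#' @param spec A [video_sim_spec()].
#' @param noise_seed Seed for the noise video (defaults to the spec
#'   seed).
#' @return A `sim_video`: `video` (a `video` object), `rois`, `mask`,
#'   `bf`, `gain`, `timing`, `truth` (noise-free, bleach-free ROI-mean
#'   traces of the gained signal), and `components` (the four Eq-style
#'   terms, pre-clipping).
#' @export
compose_video <- function(spec, noise_seed = spec$seed) {
  stopifnot(inherits(spec, "video_sim_spec"))
  n_frames <- round(spec$duration * spec$fps)
  rois <- mess(spec$mask, spec$n_in, spec$n_out)
  pure <- pure_signal_video(spec$bf, spec$mask, spec$kind, spec$fps,
                            spec$duration, field = spec$field)
  noise <- sim_noise_video(spec$lam, n_frames, seed = noise_seed,
                           shape = c(spec$H, spec$W))
  g <- gain_for_snr(pure$video, noise, rois, spec$target_db)
  gained <- pure$video * rep(g, each = n_frames)
  bl <- bleach_component(spec$bf, n_frames, spec$fps, spec$bleach)
  F_ <- rep(spec$bf, each = n_frames) + gained + bl + noise
  n_clip <- sum(F_ < 0)
  frames <- pmax(F_, 0)
  video <- new_video(frames, spec$fps)
  truth <- new_trace_set(roi_means_raw(gained, rois), spec$fps,
                         pure$timing)
  out <- list(video = video, rois = rois, mask = spec$mask, bf = spec$bf,
              gain = g, timing = pure$timing, truth = truth,
              peak = pure$peak,
              components = list(bf = spec$bf, signal = gained, bleach = bl,
                                noise = noise))
  attr(out, "n_clipped") <- n_clip
  class(out) <- "sim_video"
  out
}

## ROI means of a raw T x H x W array (no video wrapper, no clipping).
roi_means_raw <- function(frames, rois) {
  ids <- sort(unique(rois$labels[rois$labels > 0]))
  T_ <- dim(frames)[1]
  flat <- matrix(frames, nrow = T_)
  out <- matrix(0, length(ids), T_)
  for (i in seq_along(ids))
    out[i, ] <- rowMeans(flat[, which(rois$labels == ids[i]), drop = FALSE])
  out
}

#' @export
print.sim_video <- function(x, ...) {
  cat(sprintf("sim_video: %s, %d ROIs, %d clipped px\n",
              class(x$video), x$rois$n_in + x$rois$n_out,
              attr(x, "n_clipped")))
  invisible(x)
}

#' Stimulated / blank video pair for blank-subtraction baselines
#'
#' The blank shares the spec but has no signal term and an independent
#' noise seed; it is rescaled so its global mean exceeds the stimulated
#' video's pre-onset global mean by exactly `drift_fraction`
#' (default 0.3 %), emulating the slow bleaching drift between
#' consecutively recorded videos.
#'
#' @param spec A [video_sim_spec()].
#' @param drift_fraction Relative global-mean increase of the blank.
#' @return List with `stimulated` (a `sim_video`) and `blank` (a
#'   `video`).
#' @export
gen_blank_pair <- function(spec, drift_fraction = 0.003) {
  stim <- compose_video(spec)
  n_frames <- round(spec$duration * spec$fps)
  noise_b <- sim_noise_video(spec$lam, n_frames,
                             seed = spec$seed + 7777L,
                             shape = c(spec$H, spec$W))
  bl <- bleach_component(spec$bf, n_frames, spec$fps, spec$bleach)
  blank_raw <- rep(spec$bf, each = n_frames) + bl + noise_b
  pre <- (seq_len(n_frames) - 1) / spec$fps < stim$timing$t_onset
  target_mean <- mean(stim$video$frames[pre, , ]) * (1 + drift_fraction)
  blank_raw <- blank_raw * (target_mean / mean(blank_raw))
  list(stimulated = stim, blank = new_video(pmax(blank_raw, 0), spec$fps))
}
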