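## Synthetic 1-D source signals and noisy observation stacks: the inputs of
## the signal-processing simulations that every BSS method is benchmarked on.

new_source_signal <- function(values, kind, timing, fps) {
  structure(list(values = as.numeric(values), kind = kind,
                 timing = timing, fps = fps),
            class = "source_signal")
}

#' @export
print.source_signal <- function(x, ...) {
  cat(sprintf("source_signal (%s): %d samples @ %g fps, active [%g, %g] s\n",
              x$kind, length(x$values), x$fps,
              x$timing$t_onset, x$timing$t_end))
  invisible(x)
}

#' Action-potential surrogate signal
#'
#' Generates an inverted (negative-going, as seen by a voltage-sensitive
#' dye) action-potential-like transient: a two-frame upstroke to peak
#' amplitude -1 followed by a biexponential repolarization shaped so that
#' the durations at 25 % and 75 % repolarization match `apd25` / `apd75`.
#' The waveform is exactly zero outside the active interval
#' `[t_onset, t_onset + active]`.
#'
#' @param fps Frame rate (Hz).
#' @param duration Total record duration (s); default 5.
#' @param t_onset Upstroke start time (s); default 2.5.
#' @param active Active-interval length (s); default 0.3, i.e. the signal
#'   has returned to baseline by 2.8 s.
#' @param apd25,apd75 Target durations (s) at 25 % / 75 % repolarization,
#'   measured from onset.  Defaults 0.035 and 0.120 mimic a short rabbit
#'   ventricular action potential.
#' @return A `source_signal` object (fields `values`, `kind`, `timing`,
#'   `fps`).
#' @examples
#' ap <- gen_ap(fps = 100)
#' range(ap$values)
#' @export
gen_ap <- function(fps, duration = 5, t_onset = 2.5, active = 0.3,
                   apd25 = 0.035, apd75 = 0.120) {
  stopifnot(is_num(fps), fps > 0)
  t_up <- 2 / fps  # upstroke: 2 frames
  if (!(t_up < apd25 && apd25 < apd75 && apd75 < active))
    stopf("infeasible AP timing: need 2/fps < apd25 < apd75 < active")
  timing <- signal_timing(t_onset, t_onset + active, duration)

  ## Repolarization: rho(tau) = (r(tau) - r(Tr)) / (1 - r(Tr)) with
  ## r(tau) = a exp(-tau/tau1) + (1-a) exp(-tau/tau2); rho(0) = 1,
  ## rho(Tr) = 0.  Solve (tau1, tau2) so the 75 %/25 % levels are crossed
  ## at apd25/apd75 (measured from onset; repolarization starts at the
  ## peak, t_up after onset).
  Tr <- active - t_up
  rho <- function(tau, th) {
    a <- stats::plogis(th[3])
    r <- function(u) a * exp(-u / th[1]) + (1 - a) * exp(-u / th[2])
    (r(tau) - r(Tr)) / (1 - r(Tr))
  }
  obj <- function(par) {
    th <- c(exp(par[1:2]), par[3])
    (rho(apd25 - t_up, th) - 0.75)^2 + (rho(apd75 - t_up, th) - 0.25)^2
  }
  fit <- stats::optim(c(log(c(apd25, apd75)), 0), obj,
                      control = list(maxit = 5000, reltol = 1e-15))
  if (fit$value > 1e-10)
    stopf("AP surrogate shape solve failed (residual %.3g)", fit$value)
  th <- c(exp(fit$par[1:2]), fit$par[3])

  n <- round(duration * fps)
  t <- (seq_len(n) - 1) / fps
  v <- numeric(n)
  i_on <- round(t_onset * fps) + 1L       # frame at t_onset
  i_pk <- i_on + 2L                       # peak, 2 frames later
  if (i_pk <= n) {
    v[i_on + 1L] <- -0.5
    v[i_pk] <- -1
    post <- which(t > t[i_pk] & t < timing$t_end)
    v[post] <- -pmax(0, rho(t[post] - t[i_pk], th))
  }
  new_source_signal(v, "AP", timing, fps)
}

#' Step (electroporation-like) source signal
#'
#' A persistent step: zero before `t_onset`, `amplitude` from `t_onset`
#' to the end of the record.  Mimics the optical signature of a cell
#' membrane electroporated by a strong field pulse.
#'
#' @inheritParams gen_ap
#' @param amplitude Step amplitude (A.U., sign preserved); default -1
#'   (fluorescence drops on depolarization).
#' @return A `source_signal` object.
#' @export
gen_step <- function(fps, duration = 5, t_onset = 2.5, amplitude = -1) {
  stopifnot(is_num(fps), fps > 0, is_num(amplitude))
  if (amplitude == 0) stopf("step amplitude must be non-zero")
  timing <- signal_timing(t_onset, duration, duration)
  n <- round(duration * fps)
  t <- (seq_len(n) - 1) / fps
  v <- ifelse(t >= t_onset, amplitude, 0)
  new_source_signal(v, "step", timing, fps)
}

#' Zero-mean Poisson shot noise
#'
#' Draws `n` i.i.d. Poisson(`lam`) counts and subtracts `lam`, giving an
#' approximately zero-mean noise vector with variance `lam` — the photon
#' shot-noise model used throughout the simulations (default
#' `lam = 225`, i.e. noise SD 15 A.U.).
#'
#' @param n Number of samples.
#' @param lam Poisson rate (counts); must be > 0.
#' @param seed Integer seed; the draw is reproducible under a fixed seed.
#' @return Numeric vector of length `n`.
#' @export
gen_shot_noise <- function(n, lam = 225, seed = 0L) {
  stopifnot(is_count(n), is_num(lam), lam > 0)
  with_seed(seed, stats::rpois(n, lam) - lam)
}

#' Signal-to-noise ratio (classical power definition)
#'
#' `SNR = mean(|x_i|^2) / sigma_noise^2`, with the mean taken over the
#' full record (active plus silence intervals).
#'
#' @param signal Numeric vector or `source_signal`.
#' @param sigma_noise Noise standard deviation (> 0).
#' @return List with `ratio` (linear) and `db` (`10 log10(ratio)`).
#' @export
snr <- function(signal, sigma_noise) {
  x <- if (inherits(signal, "source_signal")) signal$values else signal
  stopifnot(is.numeric(x), all(is.finite(x)), is_num(sigma_noise))
  if (sigma_noise <= 0) stopf("undefined SNR: sigma_noise must be > 0")
  ratio <- mean(x^2) / sigma_noise^2
  list(ratio = ratio, db = 10 * log10(ratio))
}

#' Gain that scales a signal to a target SNR
#'
#' Returns the scalar `g` such that `snr(g * signal, sigma_noise)`
#' equals `target_db` (noise power held constant, signal power varied).
#'
#' @inheritParams snr
#' @param target_db Target SNR in dB.
#' @return The gain `g` (scalar).
#' @export
scale_to_snr <- function(signal, sigma_noise, target_db) {
  x <- if (inherits(signal, "source_signal")) signal$values else signal
  stopifnot(is.numeric(x), is_num(sigma_noise), sigma_noise > 0,
            is_num(target_db))
  p <- mean(x^2)
  if (p == 0) stopf("cannot scale an identically zero signal")
  sqrt(10^(target_db / 10) * sigma_noise^2 / p)
}

#' Random exponential-drift (photobleaching) parameters
#'
#' Draws per-observation `(A, B, C)` for the contaminating exponential
#' `A exp(-B t) + C` from Gaussians: `A ~ N(2 sigma, (0.2 * 2 sigma)^2)`,
#' `B ~ N(0.3 s^-1, 0.05^2)`, `C ~ N(0, sigma^2 / 4)`, truncated to
#' `A > 0`, `B > 0`.  Scales the drift to the shot-noise amplitude so
#' correction is non-trivial.
#'
#' @param n Number of observations.
#' @param sigma_noise Noise SD the drift amplitude is referenced to.
#' @param seed Integer seed.
#' @param A_mean,A_cv,B_mean,B_sd,C_sd Distribution parameters.
#' @return Data frame with columns `A`, `B`, `C` (one row per observation).
#' @export
random_bleach_params <- function(n, sigma_noise = 15, seed = 0L,
                                 A_mean = 2 * sigma_noise, A_cv = 0.2,
                                 B_mean = 0.3, B_sd = 0.05,
                                 C_sd = sigma_noise / 2) {
  stopifnot(is_count(n))
  with_seed(seed, {
    A <- abs(stats::rnorm(n, A_mean, A_cv * A_mean))
    B <- abs(stats::rnorm(n, B_mean, B_sd))
    C <- stats::rnorm(n, 0, C_sd)
    data.frame(A = A, B = B, C = C)
  })
}

#' Assemble noisy observations of a source signal
#'
#' Builds the n-row observation matrix of the signal-processing
#' simulations: each row is `g * signal + noise_i` (plus an optional
#' per-row exponential drift `A_i exp(-B_i t) + C_i` mimicking
#' photobleaching), with independent zero-mean Poisson shot noises and
#' `g` chosen so each row's SNR equals `target_db`.
#'
#' @param signal A `source_signal`.
#' @param n Number of observations (>= 2 for BSS use).
#' @param target_db Target SNR per observation (dB).
#' @param lam Poisson rate of the shot noise (default 225).
#' @param seed Master seed; per-observation noise seeds are derived from
#'   it, so `(seed, n)` fully determines the dataset.
#' @param bleach Optional data frame with columns `A`, `B`, `C` (one row
#'   per observation) as produced by [random_bleach_params()].
#' @return A `trace_set`: list with `traces` (n x T matrix), `fps`,
#'   `timing`, `n`, and the scaling `gain` applied to the source.
#' @export
make_observations <- function(signal, n, target_db, lam = 225, seed = 0L,
                              bleach = NULL) {
  stopifnot(inherits(signal, "source_signal"), is_count(n))
  g <- scale_to_snr(signal, sqrt(lam), target_db)
  T_ <- length(signal$values)
  t <- (seq_len(T_) - 1) / signal$fps
  seeds <- derive_seeds(seed, n)
  traces <- matrix(0, n, T_)
  for (i in seq_len(n)) {
    row <- g * signal$values + gen_shot_noise(T_, lam, seeds[i])
    if (!is.null(bleach))
      row <- row + bleach$A[i] * exp(-bleach$B[i] * t) + bleach$C[i]
    traces[i, ] <- row
  }
  new_trace_set(traces, signal$fps, signal$timing, gain = g)
}

#' Construct a trace set from a matrix of ROI time courses
#'
#' @param traces n x T matrix (one row per ROI / observation).
#' @param fps Frame rate (Hz).
#' @param timing Optional [signal_timing()].
#' @param gain Optional scalar gain applied to the generating source.
#' @return A `trace_set` object.
#' @export
new_trace_set <- function(traces, fps, timing, gain = NA_real_) {
  stopifnot(is.matrix(traces))
  structure(list(traces = traces, fps = fps, timing = timing,
                 n = nrow(traces), gain = gain),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d traces x %d frames @ %g fps\n",
              x$n, ncol(x$traces), x$fps))
  invisible(x)
}
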