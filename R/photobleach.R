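## Photobleaching models and their removal.  Four decaying models are
## supported; the *_STEP variants embed the (known-onset) persistent signal
## as a unit-step term so the whole record can be used for fitting (FDPC).
##
##   exp           A exp(-B t) + C
##   exp_step      A exp(-B t) + C - E u(t - t_onset)
##   exp_lin       A exp(-B t) + C - D t
##   exp_lin_step  A exp(-B t) + C - D t - E u(t - t_onset)
##
## Input-window schemes: SBPC fits on data before onset only; DBPC on all
## silence intervals (before onset and after signal end); FDPC on the whole
## record with a step-bearing model.

BLEACH_MODELS <- c("exp", "exp_step", "exp_lin", "exp_lin_step")

model_has_step <- function(model) grepl("step", model)
model_has_lin  <- function(model) grepl("lin", model)

#' Evaluate a photobleaching model
#'
#' @param fit A `bleach_fit` object (or a list with fields `model`,
#'   `pars`, `t_onset`).
#' @param t Time vector (s).
#' @param include_step If `FALSE` the `-E u(t - t_onset)` term is
#'   omitted; this is the curve actually subtracted from data, since the
#'   step term models the biological signal, not the bleaching.
#' @return Model values at `t`.
#' @export
eval_bleach <- function(fit, t, include_step = TRUE) {
  p <- fit$pars
  y <- p[["A"]] * exp(-p[["B"]] * t) + p[["C"]]
  if (model_has_lin(fit$model)) y <- y - p[["D"]] * t
  if (model_has_step(fit$model) && include_step)
    y <- y - p[["E"]] * as.numeric(t >= fit$t_onset)
  y
}

bleach_fit_window <- function(timing, fps, n_frames, mode,
                              onset_guard = 0.05) {
  t <- (seq_len(n_frames) - 1) / fps
  guard <- 2 / fps  # exclude the 2 frames straddling onset
  switch(mode,
    SBPC = which(t < timing$t_onset - guard),
    DBPC = which(t < timing$t_onset - guard | t > timing$t_end + guard),
    ## FDPC sees the whole record except a short post-onset guard, where
    ## charging transients that the step model cannot represent live
    FDPC = which(t < timing$t_onset |
                   t >= timing$t_onset + onset_guard),
    stopf("unknown bleach-correction mode '%s'", mode))
}

#' Fit a photobleaching model to one trace
#'
#' Non-linear least squares (Levenberg-Marquardt) on the input window
#' selected by `mode`:
#' * `SBPC` — data strictly before signal onset;
#' * `DBPC` — all silence intervals (requires a post-event silence
#'   window, i.e. a transitory signal);
#' * `FDPC` — the entire record, with a step term at the known onset
#'   absorbing the persistent signal.
#'
#' Starting values are data-driven (`A0 = first - last`,
#' `B0 = 1/duration`, `C0 = last`, `D0 = 0`, `E0 = -(post-onset median -
#' pre-onset median)`); `B` is constrained to `[0, 50] /s`.  Up to 5
#' restarts with jittered `B0` are attempted on non-convergence.
#'
#' @param trace Numeric vector (one ROI mean over time).
#' @param timing A [signal_timing()] object.
#' @param fps Frame rate (Hz).
#' @param mode One of `"SBPC"`, `"DBPC"`, `"FDPC"`.
#' @param model One of `"exp"`, `"exp_step"`, `"exp_lin"`,
#'   `"exp_lin_step"`.  Defaults to `"exp_step"` for FDPC and `"exp"`
#'   otherwise.  FDPC requires a step-bearing model.
#' @param onset_guard Seconds excluded right after onset in FDPC mode
#'   (default 0.05 s), shielding the fit from charging transients the
#'   step term cannot represent.
#' @return A `bleach_fit`: `model`, `pars` (named vector), `mode`,
#'   `t_onset`, `fit_window`, `converged`, `rms`.
#' @export
fit_bleach <- function(trace, timing, fps, mode = c("DBPC", "SBPC", "FDPC"),
                       model = NULL, onset_guard = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(trace), all(is.finite(trace)))
  n <- length(trace)
  if (is.null(model)) model <- if (mode == "FDPC") "exp_step" else "exp"
  model <- match.arg(model, BLEACH_MODELS)
  if (mode == "FDPC" && !model_has_step(model))
    stopf("FDPC requires a step-bearing model (got '%s')", model)
  if (mode != "FDPC" && model_has_step(model))
    stopf("step-bearing models are only meaningful under FDPC")
  if (mode == "DBPC" && timing$t_end + 2 / fps >= (n - 1) / fps)
    stopf("DBPC requires a silence window after the signal end")

  win <- bleach_fit_window(timing, fps, n, mode, onset_guard)
  t_all <- (seq_len(n) - 1) / fps
  tw <- t_all[win]; yw <- trace[win]

  par_names <- c("A", "B", "C",
                 if (model_has_lin(model)) "D",
                 if (model_has_step(model)) "E")
  if (length(win) <= length(par_names))
    stopf("fit window (%d samples) shorter than parameter count (%d)",
          length(win), length(par_names))

  ## Only B enters non-linearly: profile it on a grid, solving the
  ## linear parameters (A, C, D, E) by least squares at each B, and use
  ## the grid optimum to start the Levenberg-Marquardt polish.  The
  ## grid-global start avoids the biased local optima a single
  ## data-driven start can fall into at low SNR.
  design <- function(B) {
    cbind(A = exp(-B * tw), C = rep(1, length(tw)),
          D = if (model_has_lin(model)) -tw,
          E = if (model_has_step(model))
            -as.numeric(tw >= timing$t_onset))
  }
  duration <- t_all[n] - t_all[1] + 1 / fps
  grid <- exp(seq(log(0.05 / duration), log(50), length.out = 30))
  best_grid <- NULL
  for (B in grid) {
    X <- design(B)
    qx <- qr(X)
    if (qx$rank < ncol(X)) next
    cf <- qr.coef(qx, yw)   # named by design column, original order
    dev <- sum((yw - X %*% cf)^2)
    if (is.null(best_grid) || dev < best_grid$dev)
      best_grid <- list(dev = dev, B = B, cf = cf)
  }
  if (is.null(best_grid))
    stopf("photobleaching fit failed (%s, %s): degenerate design", mode,
          model)
  start <- stats::setNames(numeric(length(par_names)), par_names)
  start[["A"]] <- best_grid$cf[["A"]]
  start[["B"]] <- best_grid$B
  start[["C"]] <- best_grid$cf[["C"]]
  if (model_has_lin(model)) start[["D"]] <- best_grid$cf[["D"]]
  if (model_has_step(model)) start[["E"]] <- best_grid$cf[["E"]]
  lower <- stats::setNames(rep(-Inf, length(par_names)), par_names)
  upper <- stats::setNames(rep(Inf, length(par_names)), par_names)
  lower[["B"]] <- 0; upper[["B"]] <- 50

  resid_fn <- function(p) {
    fit <- list(model = model, pars = as.list(p), t_onset = timing$t_onset)
    yw - eval_bleach(fit, tw, include_step = TRUE)
  }

  best <- NULL
  for (try in 0:5) {
    st <- start
    if (try > 0)
      st[["B"]] <- with_seed(try, abs(start[["B"]] * stats::runif(1, 0.1, 10)))
    out <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(out)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
    if (out$info %in% 1:4 && out$deviance <= best_grid$dev) break
  }
  if (is.null(best))
    stopf("photobleaching fit failed to converge (%s, %s)", mode, model)

  pars <- stats::setNames(as.numeric(best$par), par_names)
  full <- c(A = NA_real_, B = NA_real_, C = NA_real_, D = 0, E = 0)
  full[par_names] <- pars
  structure(list(model = model, pars = as.list(full), mode = mode,
                 t_onset = timing$t_onset, fit_window = win,
                 converged = best$info %in% 1:4,
                 rms = sqrt(best$deviance / length(win))),
            class = "bleach_fit")
}

#' @export
print.bleach_fit <- function(x, ...) {
  p <- unlist(x$pars)
  cat(sprintf("bleach_fit [%s/%s]: %s; rms %.4g; %s\n", x$mode, x$model,
              paste(sprintf("%s=%.4g", names(p), p), collapse = " "),
              x$rms, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Remove a fitted photobleaching curve from a trace
#'
#' Subtracts the step-free model curve, so a persistent signal embedded
#' in an FDPC fit survives the correction.
#'
#' @inheritParams eval_bleach
#' @param trace Numeric vector.
#' @param fps Frame rate (Hz).
#' @return Corrected trace (same length).
#' @export
correct_bleach <- function(trace, fit, fps) {
  t <- (seq_along(trace) - 1) / fps
  trace - eval_bleach(fit, t, include_step = FALSE)
}
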