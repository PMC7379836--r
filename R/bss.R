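## Blind source separation of ROI traces: PCA (orthogonal rotation by SVD)
## and FastICA (fixed-point, deflation, logcosh contrast), plus the
## wavelet-augmented variants wPCA/wICA that hard-threshold the selected
## source before the inverse transformation.

BSS_METHODS <- c("ICA", "PCA", "wICA", "wPCA")

#' Decompose ROI traces into sources
#'
#' Rows of `traces$traces` are the n observations (ROI means over time);
#' they are mean-centered and decomposed into `m <= n` sources.  PCA uses
#' the singular value decomposition; ICA whitens to `m` principal
#' components and then runs a fixed-point FastICA (logcosh
#' non-linearity, deflation, tolerance `1e-6`, at most 1000 iterations,
#' seeded so results are reproducible).  `wPCA` / `wICA` decompose
#' identically to their base method; the wavelet step happens in
#' [reconstruct()].
#'
#' @param traces A `trace_set` (see [make_observations()]) or an n x T
#'   matrix.
#' @param method One of `"ICA"`, `"PCA"`, `"wICA"`, `"wPCA"`.
#' @param m Number of components to keep (default 1).
#' @param seed Seed for the ICA initial rotation.
#' @return A `bss_decomposition`: `method`, `m`, `sources` (m x T),
#'   `mixing` (n x m), `offsets` (length n), `fps`, `timing`,
#'   `selected` (filled by [auto_select()]).
#' @export
decompose <- function(traces, method = c("ICA", "PCA", "wICA", "wPCA"),
                      m = 1L, seed = 0L) {
  method <- match.arg(method)
  fps <- NULL; timing <- NULL
  if (inherits(traces, "trace_set")) {
    fps <- traces$fps; timing <- traces$timing
    X <- traces$traces
  } else X <- as.matrix(traces)
  n <- nrow(X); T_ <- ncol(X)
  if (n < 2) stopf("BSS needs at least 2 observations (got %d)", n)
  if (m > n) stopf("m (%d) cannot exceed the number of observations (%d)", m, n)
  if (any(apply(X, 1, stats::sd) == 0))
    stopf("constant (zero-variance) trace among the observations")

  offsets <- rowMeans(X)
  Xc <- X - offsets
  sv <- svd(Xc)

  if (method %in% c("PCA", "wPCA")) {
    sources <- t(sv$v[, seq_len(m), drop = FALSE] *
                   rep(sv$d[seq_len(m)], each = T_))
    mixing <- sv$u[, seq_len(m), drop = FALSE]
  } else {
    ## whiten to m dims: Z (m x T) with Z Z^T / T = I
    d <- sv$d[seq_len(m)]
    if (any(d < 1e-12 * sv$d[1]))
      stopf("whitening failed: rank of the observations is below m")
    Z <- sqrt(T_) * t(sv$v[, seq_len(m), drop = FALSE])
    W <- fastica_deflation(Z, seed = seed)
    sources <- W %*% Z
    ## mixing maps sources back to centered observations (least squares)
    mixing <- Xc %*% t(sources) %*% solve(sources %*% t(sources))
  }
  structure(list(method = method, m = m, sources = sources,
                 mixing = mixing, offsets = offsets, fps = fps,
                 timing = timing, selected = NULL, seed = seed),
            class = "bss_decomposition")
}

## Fixed-point FastICA with deflation on whitened data Z (m x T).
## Non-convergence of a component yields a warning and the best iterate.
fastica_deflation <- function(Z, seed = 0L, max_iter = 1000L, tol = 1e-6) {
  m <- nrow(Z); T_ <- ncol(Z)
  W <- matrix(0, m, m)
  init <- with_seed(seed, matrix(stats::rnorm(m * m), m, m))
  for (comp in seq_len(m)) {
    w <- init[, comp]
    w <- w / sqrt(sum(w^2))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      wx <- drop(crossprod(w, Z))          # 1 x T projections
      gwx <- tanh(wx)
      w_new <- Z %*% gwx / T_ - mean(1 - gwx^2) * w
      ## deflation: orthogonalize against previously extracted rows
      if (comp > 1) {
        Wp <- W[seq_len(comp - 1), , drop = FALSE]
        w_new <- w_new - t(Wp) %*% (Wp %*% w_new)
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- abs(abs(sum(w_new * w)) - 1)
      w <- drop(w_new)
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warnf("FastICA component %d did not converge in %d iterations", comp,
            max_iter)
    W[comp, ] <- w
  }
  W
}

#' @export
print.bss_decomposition <- function(x, ...) {
  cat(sprintf("bss_decomposition: %s, m = %d, n = %d, T = %d%s\n",
              x$method, x$m, nrow(x$mixing), ncol(x$sources),
              if (!is.null(x$selected))
                paste0(", selected = {", paste(x$selected, collapse = ","), "}")
              else ""))
  invisible(x)
}

#' Automatic signal-source selection
#'
#' Chooses the source with the highest energy inside the signal active
#' interval.  Sources are variance-normalized first, so PCA's scale
#' hierarchy does not simply pick the first principal component.  Ties
#' go to the lowest index (with a warning).
#'
#' @param decomp A [decompose()] result.
#' @param timing Optional [signal_timing()]; defaults to the timing
#'   stored in the decomposition.
#' @param n_select Number of sources to select (default 1).
#' @return The decomposition with `selected` set.
#' @export
auto_select <- function(decomp, timing = decomp$timing, n_select = 1L) {
  stopifnot(inherits(decomp, "bss_decomposition"))
  if (is.null(timing)) stopf("auto_select needs signal timing")
  if (decomp$m == 1L) { decomp$selected <- 1L; return(decomp) }
  act <- active_frames(timing, decomp$fps, ncol(decomp$sources))
  energy <- apply(decomp$sources, 1, function(s) {
    s <- s / stats::sd(s)
    sum(s[act]^2)
  })
  ord <- order(-energy, seq_along(energy))
  if (decomp$m > 1 && length(unique(round(energy, 9))) < decomp$m &&
      isTRUE(all.equal(energy[ord[1]], energy[ord[2]])))
    warnf("tied source energies; selecting the lowest index")
  decomp$selected <- sort(ord[seq_len(n_select)])
  decomp
}

#' Rebuild filtered traces from selected sources
#'
#' Applies the inverse transformation using only the selected sources;
#' for `wPCA`/`wICA` the selected sources are wavelet hard-threshold
#' denoised first ([wavelet_denoise()]).  Row means removed before
#' decomposition are restored, so outputs stay in A.U.
#'
#' @param decomp A [decompose()] result.
#' @param selected Indices of sources to keep; defaults to
#'   `decomp$selected` (or all sources if none were selected).
#' @param wavelet Wavelet name for the w-variants; default `"dmey"` for
#'   transitory signals and `"Haar"` is conventional for steps — pass
#'   explicitly, default here is `"haar"`.
#' @return A `trace_set` of filtered traces (n x T).
#' @export
reconstruct <- function(decomp, selected = NULL, wavelet = "haar") {
  stopifnot(inherits(decomp, "bss_decomposition"))
  if (is.null(selected)) selected <- decomp$selected
  if (is.null(selected)) selected <- seq_len(decomp$m)
  if (length(selected) == 0) stopf("empty source selection")
  if (!all(selected %in% seq_len(decomp$m)))
    stopf("selected indices outside 1..m")
  S <- decomp$sources[selected, , drop = FALSE]
  if (decomp$method %in% c("wICA", "wPCA"))
    for (k in seq_len(nrow(S)))
      S[k, ] <- wavelet_denoise(S[k, ], wavelet)
  filt <- decomp$mixing[, selected, drop = FALSE] %*% S + decomp$offsets
  new_trace_set(filt, decomp$fps %||% NA_real_, decomp$timing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Center a trace's baseline at zero
#'
#' Subtracts the median of the silence-interval samples, so the silence
#' median of the result is exactly zero.  Idempotent.
#'
#' @param trace Numeric vector.
#' @param timing A [signal_timing()].
#' @param fps Frame rate (Hz).
#' @return Centered trace.
#' @export
center_baseline <- function(trace, timing, fps) {
  sil <- silence_frames(timing, fps, length(trace))
  if (length(sil) == 0) stopf("no silence samples to center on")
  trace - stats::median(trace[sil])
}
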