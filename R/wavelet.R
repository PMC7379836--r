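## Decimated 1-D discrete wavelet transform with hard thresholding.
##
## Implemented as a periodized orthogonal pyramid on a signal padded by
## symmetric reflection to the next power of two; the inverse transform is
## exact (transpose of an orthogonal operator) and is truncated back to
## the original length.  Only orthogonal filter banks are supported.

## Standard 62-tap FIR approximation of the Discrete Meyer scaling filter
## (the usual 'dmey' filter table).
DMEY_LO <- c(
  0.0, -1.009999956941423e-12, 8.519459636796214e-09, -1.111944952595278e-08,
  -1.0798819539621958e-08, 6.066975741351135e-08, -1.0866516536735883e-07,
  8.200680650386481e-08, 1.1783004497663934e-07, -5.506340565252278e-07,
  1.1307947017916706e-06, -1.489549216497156e-06, 7.367572885903746e-07,
  3.20544191334478e-06, -1.6312699734552807e-05, 6.554305930575149e-05,
  -0.0006011502343516092, -0.002704672124643725, 0.002202534100911002,
  0.006045814097323304, -0.006387718318497156, -0.011061496392513451,
  0.015270015130934803, 0.017423434103729693, -0.03213079399021176,
  -0.024348745906078023, 0.0637390243228016, 0.030655091960824263,
  -0.13284520043622938, -0.035087555656258346, 0.44459300275757724,
  0.7445855923188063, 0.44459300275757724, -0.035087555656258346,
  -0.13284520043622938, 0.030655091960824263, 0.0637390243228016,
  -0.024348745906078023, -0.03213079399021176, 0.017423434103729693,
  0.015270015130934803, -0.011061496392513451, -0.006387718318497156,
  0.006045814097323304, 0.002202534100911002, -0.002704672124643725,
  -0.0006011502343516092, 6.554305930575149e-05, -1.6312699734552807e-05,
  3.20544191334478e-06, 7.367572885903746e-07, -1.489549216497156e-06,
  1.1307947017916706e-06, -5.506340565252278e-07, 1.1783004497663934e-07,
  8.200680650386481e-08, -1.0866516536735883e-07, 6.066975741351135e-08,
  -1.0798819539621958e-08, -1.111944952595278e-08, 8.519459636796214e-09,
  -1.009999956941423e-12)

wavelet_filter <- function(wavelet) {
  lo <- switch(tolower(wavelet),
    haar = c(1, 1) / sqrt(2),
    dmey = DMEY_LO,
    stopf("unknown wavelet '%s' (supported: haar, dmey)", wavelet))
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)  # quadrature mirror filter
  list(lo = lo, hi = hi, len = L)
}

## One periodized analysis step: x (even length) -> list(a, d).
dwt_step <- function(x, f) {
  n <- length(x)
  idx <- outer(2 * (seq_len(n / 2) - 1), seq_len(f$len) - 1, `+`) %% n + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(a = as.numeric(xm %*% f$lo), d = as.numeric(xm %*% f$hi))
}

## Inverse of dwt_step (transpose of the orthogonal analysis operator).
idwt_step <- function(a, d, f) {
  n <- 2 * length(a)
  x <- numeric(n)
  for (i in seq_along(a)) {
    j <- (2 * (i - 1) + seq_len(f$len) - 1) %% n + 1
    x[j] <- x[j] + f$lo * a[i] + f$hi * d[i]
  }
  x
}

## Symmetric-reflection padding to the next power of two.
pad_pow2 <- function(x) {
  n <- length(x)
  n2 <- 2^ceiling(log2(n))
  if (n2 == n) return(list(x = x, n = n))
  ext <- c(x, rev(x))  # full symmetric period
  list(x = ext[((seq_len(n2) - 1) %% length(ext)) + 1], n = n)
}

#' Multi-level discrete wavelet transform
#'
#' Decomposes to the maximum level permitted by the (padded) signal
#' length and the filter length.  The signal is reflection-padded to a
#' power of two; coefficients refer to the padded signal.
#'
#' @param x Numeric vector (length >= 2).
#' @param wavelet `"haar"` or `"dmey"`.
#' @param max_level Optional cap on the decomposition depth.
#' @return List with `approx` (coarsest approximation), `details` (list,
#'   finest level first), `wavelet`, `n` (original length).
#' @export
dwt <- function(x, wavelet = "haar", max_level = NULL) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  f <- wavelet_filter(wavelet)
  p <- pad_pow2(x)
  lev_cap <- max(1, floor(log2(length(p$x) / (f$len - 1))))
  if (f$len == 2) lev_cap <- log2(length(p$x))  # haar can go all the way
  if (!is.null(max_level)) lev_cap <- min(lev_cap, max_level)
  a <- p$x
  details <- list()
  for (lev in seq_len(lev_cap)) {
    s <- dwt_step(a, f)
    details[[lev]] <- s$d
    a <- s$a
    if (length(a) < 2) break
  }
  structure(list(approx = a, details = details, wavelet = wavelet, n = p$n),
            class = "dwt")
}

#' Inverse multi-level discrete wavelet transform
#'
#' @param w A [dwt()] object.
#' @return Numeric vector of the original length.
#' @export
idwt <- function(w) {
  f <- wavelet_filter(w$wavelet)
  a <- w$approx
  for (lev in rev(seq_along(w$details)))
    a <- idwt_step(a, w$details[[lev]], f)
  a[seq_len(w$n)]
}

#' Universal hard threshold from the finest-level detail coefficients
#'
#' `K = sqrt(2 ln N) * sigma`, where `N` is the number of samples and
#' `sigma` the (unscaled) median absolute deviation of the
#' highest-frequency wavelet coefficient vector.
#'
#' @param d Finest-level detail coefficients.
#' @return List with `K`, `N`, `sigma`.
#' @export
wavelet_threshold <- function(d) {
  stopifnot(is.numeric(d), length(d) >= 1)
  sigma <- stats::median(abs(d - stats::median(d)))
  N <- length(d)
  list(K = sqrt(2 * log(N)) * sigma, N = N, sigma = sigma)
}

#' Wavelet hard-threshold denoising
#'
#' Multi-level DWT; detail coefficients with `|c| < K` are zeroed, with
#' the single global `K` computed from the finest detail level
#' ([wavelet_threshold()]); approximation coefficients are never
#' touched; inverse DWT restores the original length.
#'
#' @param x Numeric vector.
#' @param wavelet `"haar"` or `"dmey"`.
#' @param threshold_all_levels If `FALSE`, only the finest detail level
#'   is thresholded.
#' @return Denoised vector, same length as `x`.
#' @export
wavelet_denoise <- function(x, wavelet = "haar", threshold_all_levels = TRUE) {
  w <- dwt(x, wavelet)
  th <- wavelet_threshold(w$details[[1]])
  levs <- if (threshold_all_levels) seq_along(w$details) else 1L
  for (lev in levs) {
    d <- w$details[[lev]]
    d[abs(d) < th$K] <- 0
    w$details[[lev]] <- d
  }
  out <- idwt(w)
  attr(out, "threshold") <- th
  out
}
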