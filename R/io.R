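## TIFF stack / mask / trace-table I/O and run configuration.

#' Construct a video from a T x H x W intensity array
#'
#' @param frames T x H x W array of finite, non-negative intensities
#'   (A.U.).
#' @param fps Frame rate (Hz).
#' @return A `video` object.
#' @export
new_video <- function(frames, fps) {
  stopifnot(is.array(frames), length(dim(frames)) == 3, is_num(fps), fps > 0)
  if (any(!is.finite(frames)) || any(frames < 0))
    stopf("video intensities must be finite and non-negative")
  structure(list(frames = frames, fps = fps), class = "video")
}

#' @export
print.video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("video: %d frames of %d x %d @ %g fps (%.3g s)\n",
              d[1], d[2], d[3], x$fps, d[1] / x$fps))
  invisible(x)
}

#' Read a grayscale TIFF stack as a video
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param fps Frame rate (Hz) to attach to the video.
#' @return A `video` object: `frames` (T x H x W array, intensities
#'   preserved bit-exactly for integer TIFFs) and `fps`.
#' @export
read_video <- function(path, fps) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) == 3 && dim(pages[[i]])[3] > 1)
      stopf("grayscale required: page %d of %s has %d channels", i, path,
            dim(pages[[i]])[3])
    if (length(dim(pages[[i]])) == 3) pages[[i]] <- pages[[i]][, , 1]
  }
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1))))
    stopf("inconsistent page dimensions in %s", path)
  frames <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  new_video(frames, fps)
}

#' Write a video as a 16-bit grayscale TIFF stack
#'
#' Intensities must lie in `[0, 65535]`; integer-valued stacks round-trip
#' bit-exactly through [read_video()].
#'
#' @param video A `video` object.
#' @param path Output path.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "video"))
  f <- video$frames
  if (max(f) > 65535) stopf("intensities exceed the 16-bit range")
  pages <- lapply(seq_len(dim(f)[1]), function(i)
    round(f[i, , ]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Construct a binary cell mask
#'
#' @param pixels H x W matrix; non-zero entries are foreground.
#' @return A `mask` object.
#' @export
new_mask <- function(pixels) {
  stopifnot(is.matrix(pixels))
  pixels <- pixels != 0
  if (!any(pixels)) stopf("empty mask: no foreground pixels")
  structure(list(pixels = pixels), class = "mask")
}

#' @export
print.mask <- function(x, ...) {
  cat(sprintf("mask: %d x %d, %d foreground px\n", nrow(x$pixels),
              ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Read a binary TIFF cell mask
#'
#' Any non-zero value maps to foreground; more than two distinct values
#' or a shape mismatch with the associated video is an error.
#'
#' @param path Path to a binary TIFF.
#' @param shape Optional `c(H, W)` that the mask must match.
#' @return A `mask` object (logical `pixels` matrix).
#' @export
read_mask <- function(path, shape = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1) stopf("grayscale required for masks: %s", path)
    img <- img[, , 1]
  }
  vals <- unique(as.vector(img))
  if (length(vals) > 2)
    stopf("mask %s is not binary (%d distinct values)", path, length(vals))
  if (!is.null(shape) && !identical(dim(img), as.integer(shape)))
    stopf("shape mismatch: mask is %dx%d, expected %dx%d",
          nrow(img), ncol(img), shape[1], shape[2])
  new_mask(img)
}

#' Write a mask as a binary TIFF
#'
#' @param mask A `mask` object or logical matrix.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  px <- if (inherits(mask, "mask")) mask$pixels else mask != 0
  tiff::writeTIFF(matrix(as.numeric(px), nrow(px)), path,
                  bits.per.sample = 8, compression = "none")
  invisible(path)
}

#' Write ROI traces to CSV
#'
#' One row per frame: a `time` column (s, frame `k` at `(k-1)/fps`) and
#' one column per ROI.  Values are written with full precision (15
#' significant digits).
#'
#' @param traces A `trace_set`.
#' @param path Output path.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  if (any(!is.finite(traces$traces))) stopf("non-finite trace")
  T_ <- ncol(traces$traces)
  df <- data.frame(time = (seq_len(T_) - 1) / traces$fps,
                   t(traces$traces))
  names(df) <- c("time", paste0("roi", seq_len(traces$n)))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ROI traces written by [write_traces()]
#'
#' @param path CSV path.
#' @param timing Optional [signal_timing()] to attach.
#' @return A `trace_set` (fps recovered from the time column).
#' @export
read_traces <- function(path, timing = NULL) {
  df <- utils::read.csv(path)
  fps <- 1 / stats::median(diff(df$time))
  new_trace_set(unname(t(as.matrix(df[, -1, drop = FALSE]))), fps, timing)
}

#' Run configuration for the pipeline
#'
#' Bundles the tunable parameters of a full run with their defaults and
#' validates the ROI-count constraints (`n_out >= 2`, `n_in >= 4` and
#' even).
#'
#' @param n_in Number of inner ROIs (default 16).
#' @param n_out Number of outer ROIs (default 16).
#' @param transitory Is the signal transitory (AP-like, `TRUE`) or
#'   persistent (electroporation step, `FALSE`)?
#' @param t_onset,t_end Signal timing in seconds, or `NA` for automatic
#'   detection.
#' @param m Number of BSS components (default 1).
#' @param method BSS method (default `"ICA"`).
#' @param wavelet Wavelet for the w-variants (default `"haar"`).
#' @param selection `"auto"` or an integer vector of source indices.
#' @param bleach_correction Apply photobleaching correction (default
#'   `TRUE`).
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(n_in = 16L, n_out = 16L, transitory = TRUE,
                       t_onset = NA, t_end = NA, m = 1L,
                       method = c("ICA", "PCA", "wICA", "wPCA"),
                       wavelet = "haar", selection = "auto",
                       bleach_correction = TRUE, seed = 0L) {
  method <- match.arg(method)
  if (!is_count(n_out, 2)) stopf("n_ROIs_out must be >= 2")
  if (!is_count(n_in, 4) || n_in %% 2 != 0)
    stopf("n_ROIs_in must be even and >= 4")
  if (!is_count(m)) stopf("m must be a positive integer")
  if (!is.na(t_onset) && !is.na(t_end) && !(0 <= t_onset && t_onset < t_end))
    stopf("need 0 <= t_onset < t_end")
  stopifnot(is_flag(transitory), is_flag(bleach_correction))
  structure(list(n_in = as.integer(n_in), n_out = as.integer(n_out),
                 transitory = transitory, t_onset = t_onset, t_end = t_end,
                 m = as.integer(m), method = method, wavelet = wavelet,
                 selection = selection,
                 bleach_correction = bleach_correction,
                 seed = as.integer(seed)),
            class = "run_config")
}
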