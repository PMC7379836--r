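## Morphological Equal-area Standardized Segmentation (MESS): divide a
## single-component cell mask into n_in inner + n_out outer quasi-equal-area
## ROIs that spring at standardized locations regardless of cell
## orientation.
##
## Conventions used throughout: pixel (r, c) is 1-based row-major; label 0
## is background; angles are degrees; the alignment angle is the major-axis
## angle measured from the vertical.

new_roi_set <- function(labels, inner_ids, outer_ids, angle) {
  structure(list(labels = labels, inner_ids = as.integer(inner_ids),
                 outer_ids = as.integer(outer_ids),
                 n_in = length(inner_ids), n_out = length(outer_ids),
                 alignment_angle = angle),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set: %d outer + %d inner ROIs on %d x %d (angle %.1f deg)\n",
              x$n_out, x$n_in, nrow(x$labels), ncol(x$labels),
              x$alignment_angle))
  invisible(x)
}

#' Automatic cell mask from a fluorescence video
#'
#' Otsu threshold on the temporal-mean frame, followed by binary closing,
#' hole filling and largest-connected-component selection.
#'
#' @param video A `video` object.
#' @return A `mask`.
#' @export
make_mask <- function(video) {
  stopifnot(inherits(video, "video"))
  avg <- apply(video$frames, c(2, 3), mean)
  rng <- range(avg)
  if (diff(rng) <= 0) stopf("no cell detected: uniform video")
  norm <- (avg - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  bw <- norm > th
  if (!any(bw) || all(bw)) stopf("no cell detected")
  bw <- EBImage::closing(bw, EBImage::makeBrush(3, "box"))
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0) stopf("no cell detected")
  new_mask(lab == which.max(sizes))
}

## ---- rotation helpers ------------------------------------------------

## Orientation of the major principal axis from central second moments,
## in degrees from the x (column) axis, y pointing down.
mask_orientation <- function(px) {
  idx <- which(px, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  xc <- mean(x); yc <- mean(y)
  mu20 <- mean((x - xc)^2); mu02 <- mean((y - yc)^2)
  mu11 <- mean((x - xc) * (y - yc))
  if (abs(mu20 - mu02) < 1e-9 && abs(mu11) < 1e-9) return(NA_real_)  # disk
  0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
}

rot_out_dim <- function(dim_in, phi_deg) {
  a <- abs(phi_deg * pi / 180)
  H <- dim_in[1]; W <- dim_in[2]
  c(ceiling(H * abs(cos(a)) + W * abs(sin(a))),
    ceiling(W * abs(cos(a)) + H * abs(sin(a)))) + 1L
}

## Rotate an integer/logical image by phi degrees (nearest neighbor,
## canvas expanded to fit).  Returns list(img, dim_in, dim_out, phi).
rotate_nn <- function(img, phi_deg) {
  mode_in <- if (is.logical(img)) "logical" else "integer"
  dim_in <- dim(img)
  dim_out <- rot_out_dim(dim_in, phi_deg)
  a <- phi_deg * pi / 180
  cin <- (dim_in + 1) / 2; cout <- (dim_out + 1) / 2
  grid <- expand.grid(r = seq_len(dim_out[1]), c = seq_len(dim_out[2]))
  ## inverse map: output (r, c) -> input coordinates
  dx <- grid$c - cout[2]; dy <- grid$r - cout[1]
  xs <- round(cos(a) * dx + sin(a) * dy + cin[2])
  ys <- round(-sin(a) * dx + cos(a) * dy + cin[1])
  ok <- xs >= 1 & xs <= dim_in[2] & ys >= 1 & ys <= dim_in[1]
  out <- matrix(0L, dim_out[1], dim_out[2])
  out[cbind(grid$r[ok], grid$c[ok])] <- img[cbind(ys[ok], xs[ok])]
  if (mode_in == "logical") out <- out != 0L
  list(img = out, dim_in = dim_in, dim_out = dim_out, phi = phi_deg)
}

## Forward map: input pixels (r, c) -> (row, col) in the rotated frame.
rotate_forward <- function(r, c, rot) {
  a <- rot$phi * pi / 180
  cin <- (rot$dim_in + 1) / 2; cout <- (rot$dim_out + 1) / 2
  dx <- c - cin[2]; dy <- r - cin[1]
  list(r = round(sin(a) * dx + cos(a) * dy + cout[1]),
       c = round(cos(a) * dx - sin(a) * dy + cout[2]))
}

#' Align a mask so its major axis is vertical
#'
#' The orientation is estimated from central second moments; rotation
#' uses nearest-neighbor interpolation to preserve binarity.  A disk
#' (undefined orientation) gets angle 0 by convention.
#'
#' @param mask A `mask`.
#' @return List with `aligned` (a `mask`), `angle` (degrees of the major
#'   axis from vertical in the original image) and `rot` (the rotation
#'   record needed to map pixels back).
#' @export
align_mask <- function(mask) {
  stopifnot(inherits(mask, "mask"))
  theta <- mask_orientation(mask$pixels)
  angle <- if (is.na(theta)) 0 else {
    av <- theta - 90
    if (av > 90) av <- av - 180
    if (av <= -90) av <- av + 180
    av
  }
  rot <- rotate_nn(mask$pixels, -angle)
  ## rotation can split off stray pixels; keep the largest component
  lab <- EBImage::bwlabel(rot$img)
  sizes <- tabulate(lab[lab > 0])
  rot$img <- EBImage::fillHull(lab == which.max(sizes))
  list(aligned = new_mask(rot$img), angle = angle, rot = rot)
}

## ---- inner/outer split -----------------------------------------------

## 3x3 square erosion; padded so border-touching foreground still erodes
## (EBImage replicates the border, which would freeze an all-TRUE mask).
erode3 <- function(px) {
  pad <- matrix(FALSE, nrow(px) + 2, ncol(px) + 2)
  pad[2:(nrow(px) + 1), 2:(ncol(px) + 1)] <- px
  er <- EBImage::erode(pad, EBImage::makeBrush(3, "box")) > 0
  er[2:(nrow(px) + 1), 2:(ncol(px) + 1)]
}

## Ordered closed contour of the largest object, as (row, col) vertices.
## The object is padded away from the image border first: border-touching
## objects break the contour tracer.
ordered_contour <- function(px) {
  pad <- matrix(FALSE, nrow(px) + 2, ncol(px) + 2)
  pad[2:(nrow(px) + 1), 2:(ncol(px) + 1)] <- px
  ct <- EBImage::ocontour(EBImage::Image(pad * 1))
  ct <- ct[[which.max(vapply(ct, nrow, integer(1)))]]
  ## EBImage uses (x = dim1 index, y = dim2 index), 0-based -> 1-based,
  ## minus the 1-px padding
  cbind(r = ct[, 1], c = ct[, 2])
}

## Enforce traversal that is counter-clockwise on screen (y down), i.e.
## negative shoelace area in (x = col, y = row) coordinates.
orient_ccw_screen <- function(ct) {
  x <- ct[, "c"]; y <- ct[, "r"]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (area2 > 0) ct[rev(seq_len(nrow(ct))), , drop = FALSE] else ct
}

#' Split an aligned mask into inner and outer regions
#'
#' Sequential 3x3 morphological erosions until the inner area first
#' drops to at most `n_in / (n_in + n_out)` of the total area; the mid
#' contour comes from half that erosion count (`floor(n/2)`).
#'
#' @param aligned A `mask`, already vertically aligned.
#' @param n_in,n_out ROI counts.
#' @return A `contour_triplet`: ordered `outer`/`mid`/`inner` contours
#'   (counter-clockwise on screen), `n_erosions`, and the `aligned`,
#'   `mid_mask`, `inner_mask` pixel sets.
#' @export
split_inner_outer <- function(aligned, n_in, n_out) {
  stopifnot(inherits(aligned, "mask"))
  px <- aligned$pixels
  target <- n_in / (n_in + n_out) * sum(px)
  inner <- px
  n_er <- 0L
  while (sum(inner) > target) {
    nxt <- erode3(inner)
    if (!any(nxt)) stopf("mask too small for %d + %d ROIs", n_in, n_out)
    inner <- nxt
    n_er <- n_er + 1L
  }
  if (n_er == 0L) stopf("mask too small: inner region already at target")
  if (sum(inner) < n_in)
    stopf("mask too small: inner region (%d px) cannot host %d ROIs",
          sum(inner), n_in)
  mid <- px
  for (i in seq_len(n_er %/% 2)) mid <- erode3(mid)
  structure(list(
    outer = orient_ccw_screen(ordered_contour(px)),
    mid = orient_ccw_screen(ordered_contour(mid)),
    inner = orient_ccw_screen(ordered_contour(inner)),
    n_erosions = n_er, aligned = px, mid_mask = mid, inner_mask = inner),
    class = "contour_triplet")
}

## Rotate a closed contour so it starts at the point in the middle of the
## mask in y and furthest right in x.
start_at_right_middle <- function(ct, px) {
  rows <- range(which(rowSums(px) > 0))
  rc <- mean(rows)
  drow <- abs(ct[, "r"] - rc)
  cand <- which(drow <= min(drow) + 0.5)
  s <- cand[which.max(ct[cand, "c"])]
  if (s > 1) ct <- rbind(ct[s:nrow(ct), , drop = FALSE],
                         ct[1:(s - 1), , drop = FALSE])
  ct
}

#' Divide the outer band into n_out ROIs
#'
#' The mid contour is arc-length parameterized and cut into `n_out`
#' equal-length segments starting from the right-middle starting point,
#' traversed counter-clockwise on screen.  Each outer-band pixel joins
#' the ROI of the nearest mid-contour segment (ties to the earlier
#' segment), so the band is tiled exactly.
#'
#' @param triplet A [split_inner_outer()] result.
#' @param n_out Number of outer ROIs.
#' @return Integer label image (1..n_out on the band, 0 elsewhere).
#' @export
divide_outer <- function(triplet, n_out) {
  band <- triplet$aligned & !triplet$inner_mask
  mid <- start_at_right_middle(triplet$mid, triplet$aligned)
  nv <- nrow(mid)
  seg_len <- sqrt(rowSums((mid - mid[c(2:nv, 1), ])^2))
  arc <- c(0, cumsum(seg_len))[seq_len(nv)]  # arc position of each vertex
  L <- sum(seg_len)
  ## segment id of each mid vertex: k-th segment covers [k-1, k) * L/n_out
  seg_id <- pmin(floor(arc / (L / n_out)) + 1, n_out)

  idx <- which(band, arr.ind = TRUE)
  labels <- matrix(0L, nrow(band), ncol(band))
  ## nearest mid vertex (ties -> earlier arc position), chunked to bound
  ## the distance-matrix memory
  for (blk in split(seq_len(nrow(idx)),
                    ceiling(seq_len(nrow(idx)) / 4000))) {
    d2 <- outer(idx[blk, 1], mid[, "r"], `-`)^2 +
      outer(idx[blk, 2], mid[, "c"], `-`)^2
    nearest <- max.col(-d2, ties.method = "first")
    labels[idx[blk, , drop = FALSE]] <- seg_id[nearest]
  }
  labels
}

#' Divide the inner region into n_in ROIs
#'
#' Top and bottom ROIs are defined first by a row sweep accumulating one
#' ROI's worth of area from each end; the remaining central area is
#' halved by a vertical line and each half-column is cut top-to-bottom
#' into `(n_in - 2) / 2` equal-area ROIs.  Labels: 1 = top, then the
#' right half top-to-bottom, then bottom, then the left half
#' bottom-to-top.
#'
#' @param inner_mask Logical matrix of the inner region.
#' @param n_in Number of inner ROIs (even, >= 4).
#' @return Integer label image (1..n_in on the inner region, 0 elsewhere).
#' @export
divide_inner <- function(inner_mask, n_in) {
  A <- sum(inner_mask)
  if (A < n_in) stopf("inner region (%d px) smaller than n_in = %d", A, n_in)
  target <- A / n_in
  labels <- matrix(0L, nrow(inner_mask), ncol(inner_mask))
  rows <- which(rowSums(inner_mask) > 0)
  counts <- rowSums(inner_mask)

  ## top ROI: first rows until one target area is reached
  cum <- cumsum(counts[rows])
  top_rows <- rows[seq_len(which(cum >= target)[1])]
  ## bottom ROI
  cumb <- cumsum(rev(counts[rows]))
  bot_rows <- rev(rows)[seq_len(which(cumb >= target)[1])]
  if (max(top_rows) >= min(bot_rows))
    stopf("inner region too small: top and bottom ROIs overlap")
  for (r in top_rows) labels[r, inner_mask[r, ]] <- 1L
  k_half <- (n_in - 2L) %/% 2L
  bot_label <- 2L + k_half
  for (r in bot_rows) labels[r, inner_mask[r, ]] <- bot_label

  ## central region, halved by a vertical line at the balanced column
  central <- inner_mask & labels == 0L
  colcum <- cumsum(colSums(central))
  c_split <- which(colcum >= colcum[length(colcum)] / 2)[1]
  halves <- list(right = central & col(central) > c_split,
                 left = central & col(central) <= c_split)
  base <- c(right = 1L, left = 2L + k_half)  # label offsets
  for (side in names(halves)) {
    h <- halves[[side]]
    hrows <- which(rowSums(h) > 0)
    if (side == "left") hrows <- rev(hrows)  # bottom-to-top
    hc <- cumsum(rowSums(h)[hrows])
    ht <- hc[length(hc)] / k_half
    for (j in seq_along(hrows)) {
      roi <- min(k_half, floor((hc[j] - 1e-9) / ht) + 1)
      r <- hrows[j]
      labels[r, h[r, ]] <- base[[side]] + roi
    }
  }
  ## guard: every label non-empty
  if (length(setdiff(seq_len(n_in), unique(labels[labels > 0]))) > 0)
    stopf("inner region too small to host %d non-empty ROIs", n_in)
  labels
}

## Fill unlabeled mask pixels from the nearest labeled neighbor, walking
## inside the mask (approximate geodesic; deterministic: lowest label wins
## among equally near neighbors).
fill_slivers <- function(labels, mask_px) {
  while (any(mask_px & labels == 0L)) {
    todo <- which(mask_px & labels == 0L, arr.ind = TRUE)
    assigned <- FALSE
    H <- nrow(labels); W <- ncol(labels)
    newlab <- integer(nrow(todo))
    for (i in seq_len(nrow(todo))) {
      r <- todo[i, 1]; c <- todo[i, 2]
      nb <- labels[cbind(pmax(1, pmin(H, r + c(-1, -1, -1, 0, 0, 1, 1, 1))),
                         pmax(1, pmin(W, c + c(-1, 0, 1, -1, 1, -1, 0, 1))))]
      nb <- nb[nb > 0]
      if (length(nb)) { newlab[i] <- min(nb); assigned <- TRUE }
    }
    if (!assigned) {  # isolated pixels: nearest labeled pixel overall
      lab_idx <- which(labels > 0, arr.ind = TRUE)
      for (i in seq_len(nrow(todo))) {
        d2 <- (lab_idx[, 1] - todo[i, 1])^2 + (lab_idx[, 2] - todo[i, 2])^2
        newlab[i] <- labels[lab_idx[which.min(d2), , drop = FALSE]]
      }
    }
    keep <- newlab > 0
    labels[todo[keep, , drop = FALSE]] <- newlab[keep]
  }
  labels
}

#' MESS: segment a cell mask into standardized equal-area ROIs
#'
#' Full sequence: vertical alignment, inner/outer split by sequential
#' erosions, outer-band and inner-region division, outer numbering
#' shifted so ROI 1 sits at the top of the aligned cell, rotation back
#' to the original orientation, and sliver fill so the labels tile the
#' mask exactly.  Outer ROIs take labels `1..n_out`, inner ROIs
#' `n_out+1..n_out+n_in`.
#'
#' @param mask A `mask`.
#' @param n_in,n_out Inner / outer ROI counts (`n_in` even and >= 4,
#'   `n_out >= 2`).
#' @return A `roi_set` in the original image orientation.
#' @examples
#' m <- ellipse_mask(61, 121, 25, 55)
#' rs <- mess(m, 16, 16)
#' table(rs$labels > 0)
#' @export
mess <- function(mask, n_in = 16L, n_out = 16L) {
  if (!is_count(n_out, 2)) stopf("n_ROIs_out must be >= 2")
  if (!is_count(n_in, 4) || n_in %% 2 != 0)
    stopf("n_ROIs_in must be even and >= 4")
  n_in <- as.integer(n_in); n_out <- as.integer(n_out)
  al <- align_mask(mask)
  tri <- split_inner_outer(al$aligned, n_in, n_out)
  outer_lab <- divide_outer(tri, n_out)
  inner_lab <- divide_inner(tri$inner_mask, n_in)

  ## shift outer numbering so ROI #1 starts at the top of the aligned
  ## cell: the segment whose arc start is nearest (cyclically) to the mid
  ## contour's apex.  Anchoring on arc position keeps the numbering
  ## stable under the pixel jitter that rotation introduces.
  mid <- start_at_right_middle(tri$mid, tri$aligned)
  nv <- nrow(mid)
  seg_len <- sqrt(rowSums((mid - mid[c(2:nv, 1), ])^2))
  arc <- c(0, cumsum(seg_len))[seq_len(nv)]
  L <- sum(seg_len)
  s_apex <- arc[which.min(mid[, "r"])]
  starts <- (seq_len(n_out) - 1) * L / n_out
  dist_cyc <- pmin(abs(starts - s_apex), L - abs(starts - s_apex))
  shift <- which.min(dist_cyc) - 1L
  outer_new <- ((seq_len(n_out) - 1L - shift) %% n_out) + 1L
  aligned_lab <- matrix(0L, nrow(outer_lab), ncol(outer_lab))
  for (k in seq_len(n_out)) aligned_lab[outer_lab == k] <- outer_new[k]
  aligned_lab[inner_lab > 0] <- inner_lab[inner_lab > 0] + n_out

  ## rotate labels back: look up each original mask pixel in the aligned
  ## frame; unresolved pixels are filled from the nearest ROI
  orig <- which(mask$pixels, arr.ind = TRUE)
  fw <- rotate_forward(orig[, 1], orig[, 2], al$rot)
  ok <- fw$r >= 1 & fw$r <= nrow(aligned_lab) &
    fw$c >= 1 & fw$c <= ncol(aligned_lab)
  labels <- matrix(0L, nrow(mask$pixels), ncol(mask$pixels))
  labels[orig[ok, , drop = FALSE]] <-
    aligned_lab[cbind(fw$r[ok], fw$c[ok])]
  labels <- fill_slivers(labels, mask$pixels)
  labels[!mask$pixels] <- 0L
  storage.mode(labels) <- "integer"

  ids <- seq_len(n_in + n_out)
  missing <- setdiff(ids, unique(labels[labels > 0]))
  if (length(missing))
    stopf("MESS produced empty ROI(s): %s", paste(missing, collapse = ", "))
  new_roi_set(labels, inner_ids = n_out + seq_len(n_in),
              outer_ids = seq_len(n_out), angle = al$angle)
}

#' Filled-ellipse binary mask (synthetic test/demo geometry)
#'
#' @param H,W Image size.
#' @param ry,rx Semi-axes in pixels (rows / cols).
#' @param angle Rotation of the ellipse (degrees from vertical major
#'   axis).
#' @param center Optional `c(row, col)` center.
#' @return A `mask`.
#' @export
ellipse_mask <- function(H, W, ry, rx, angle = 0, center = c((H + 1) / 2,
                                                             (W + 1) / 2)) {
  a <- angle * pi / 180
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  dy <- g$r - center[1]; dx <- g$c - center[2]
  u <- cos(a) * dy - sin(a) * dx   # along the (tilted) major axis
  v <- sin(a) * dy + cos(a) * dx
  px <- matrix((u / ry)^2 + (v / rx)^2 <= 1, H, W)
  new_mask(px)
}

#' Extract ROI-mean time courses from a video
#'
#' @param video A `video`.
#' @param rois A `roi_set`.
#' @param timing Optional [signal_timing()] to attach.
#' @return A `trace_set` with one row per ROI (label order).
#' @export
roi_means <- function(video, rois, timing = NULL) {
  stopifnot(inherits(video, "video"), inherits(rois, "roi_set"))
  ids <- sort(unique(rois$labels[rois$labels > 0]))
  T_ <- dim(video$frames)[1]
  flat <- matrix(video$frames, nrow = T_)  # T x (H*W)
  traces <- matrix(0, length(ids), T_)
  for (i in seq_along(ids))
    traces[i, ] <- rowMeans(flat[, which(rois$labels == ids[i]),
                                 drop = FALSE])
  new_trace_set(traces, video$fps, timing)
}
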