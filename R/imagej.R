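## ImageJ ROI container support: binary ".roi" files (the ROI Manager's
## on-disk format) and ".zip" sets.  Reading uses R's internal unzip;
## writing emits a store-only (uncompressed) ZIP, so no external zip tool
## is needed.  Supported ROI kinds: rectangle, oval, polygon, freehand and
## traced outlines; anything else raises an error naming the kind.

IJ_ROI_TYPES <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L,
                  freeline = 4L, polyline = 5L, noroi = 6L, freehand = 7L,
                  traced = 8L, angle = 9L, point = 10L)

read_be_short <- function(raw, off) {  # 0-based offset, unsigned
  as.integer(raw[off + 1]) * 256L + as.integer(raw[off + 2])
}

## Parse one .roi byte blob -> list(type, top, left, bottom, right, x, y)
## with x/y absolute 0-based pixel-corner coordinates (polygon kinds only).
parse_imagej_roi <- function(raw) {
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stopf("not an ImageJ ROI file (missing 'Iout' magic)")
  type <- as.integer(raw[7])
  top <- read_be_short(raw, 8); left <- read_be_short(raw, 10)
  bottom <- read_be_short(raw, 12); right <- read_be_short(raw, 14)
  n <- read_be_short(raw, 16)
  kind <- names(IJ_ROI_TYPES)[match(type, IJ_ROI_TYPES)]
  if (is.na(kind)) kind <- sprintf("type %d", type)
  if (!kind %in% c("polygon", "rect", "oval", "freehand", "traced"))
    stopf("unsupported ImageJ ROI kind: %s", kind)
  out <- list(type = kind, top = top, left = left, bottom = bottom,
              right = right)
  if (kind %in% c("polygon", "freehand", "traced")) {
    if (n < 3) stopf("polygon ROI with fewer than 3 vertices")
    xs <- vapply(seq_len(n) - 1L,
                 function(i) read_be_short(raw, 64 + 2 * i), integer(1))
    ys <- vapply(seq_len(n) - 1L,
                 function(i) read_be_short(raw, 64 + 2 * n + 2 * i),
                 integer(1))
    out$x <- xs + left
    out$y <- ys + top
  }
  out
}

## Even-odd point-in-polygon (ray casting) for points (px, py).
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    if (any(cross)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      flip <- cross & (px < xint)
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

## Rasterize a parsed ROI into a logical H x W matrix: a pixel belongs to
## the ROI iff its center lies inside the shape (even-odd rule).
rasterize_roi <- function(roi, shape) {
  H <- shape[1]; W <- shape[2]
  m <- matrix(FALSE, H, W)
  if (roi$type == "rect") {
    rows <- seq.int(roi$top + 1L, min(roi$bottom, H))
    cols <- seq.int(roi$left + 1L, min(roi$right, W))
    m[rows, cols] <- TRUE
  } else if (roi$type == "oval") {
    rx <- (roi$right - roi$left) / 2; ry <- (roi$bottom - roi$top) / 2
    cx <- roi$left + rx; cy <- roi$top + ry
    for (r in seq_len(H)) {
      y <- r - 0.5
      dx2 <- 1 - ((y - cy) / ry)^2
      if (dx2 > 0) {
        x <- seq_len(W) - 0.5
        m[r, abs(x - cx) <= rx * sqrt(dx2)] <- TRUE
      }
    }
  } else {
    rows <- seq.int(max(1L, roi$top), min(H, roi$bottom + 1L))
    cols <- seq.int(max(1L, roi$left), min(W, roi$right + 1L))
    grid <- expand.grid(r = rows, c = cols)
    inside <- points_in_polygon(grid$c - 0.5, grid$r - 0.5, roi$x, roi$y)
    m[cbind(grid$r[inside], grid$c[inside])] <- TRUE
  }
  m
}

#' Import ImageJ ROIs as a labeled ROI set
#'
#' Reads a single `.roi` file or a `.zip` set (ROI Manager export) and
#' rasterizes the ROIs into a label image, one label per ROI in file
#' order.  Pixels claimed by several ROIs go to the lowest label (a
#' warning is emitted).
#'
#' @param path `.roi` or `.zip` path.
#' @param shape Target image shape `c(H, W)`.
#' @return A `roi_set` whose labels follow file order; `inner_ids` is
#'   empty and `outer_ids` holds all labels (imported ROIs carry no
#'   inner/outer split).
#' @export
import_imagej_rois <- function(path, shape) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    listing <- utils::unzip(path, list = TRUE)
    names <- listing$Name[grepl("\\.roi$", listing$Name, ignore.case = TRUE)]
    if (length(names) == 0) stopf("no .roi entries in %s", path)
    tmp <- tempfile("ijrois"); dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    utils::unzip(path, files = names, exdir = tmp)
    blobs <- lapply(file.path(tmp, names), function(f)
      readBin(f, "raw", file.info(f)$size))
  } else {
    blobs <- list(readBin(path, "raw", file.info(path)$size))
  }
  labels <- matrix(0L, shape[1], shape[2])
  overlap <- FALSE
  for (i in seq_along(blobs)) {
    px <- rasterize_roi(parse_imagej_roi(blobs[[i]]), shape)
    if (any(px & labels != 0L)) overlap <- TRUE
    px <- px & labels == 0L
    labels[px] <- i
  }
  if (overlap)
    warnf("overlapping ROIs: contested pixels assigned to the lowest label")
  new_roi_set(labels, inner_ids = integer(0),
              outer_ids = seq_along(blobs), angle = 0)
}

## ---- export ----------------------------------------------------------

## Trace the boundary of a pixel set as closed loops of grid-corner
## vertices (pixel (r, c), 1-based, spans corners (c-1, r-1)..(c, r)).
trace_pixel_boundary <- function(px) {
  idx <- which(px, arr.ind = TRUE)
  H <- nrow(px); W <- ncol(px)
  inset <- function(r, c) r >= 1 & r <= H & c >= 1 & c <= W & px[cbind(r, c)]
  r <- idx[, 1]; c <- idx[, 2]
  edges <- rbind(
    ## directed edges around each pixel, clockwise in screen coords,
    ## emitted only where the neighbor is outside the set
    cbind(c - 1, r - 1, c, r - 1)[!inset(r - 1, c), , drop = FALSE],  # top
    cbind(c, r - 1, c, r)[!inset(r, c + 1), , drop = FALSE],          # right
    cbind(c, r, c - 1, r)[!inset(r + 1, c), , drop = FALSE],          # bottom
    cbind(c - 1, r, c - 1, r - 1)[!inset(r, c - 1), , drop = FALSE])  # left
  key <- function(x, y) paste(x, y)
  from <- key(edges[, 1], edges[, 2])
  used <- rep(FALSE, nrow(edges))
  lookup <- split(seq_len(nrow(edges)), from)
  loops <- list()
  while (any(!used)) {
    e <- which(!used)[1]
    loop_x <- edges[e, 1]; loop_y <- edges[e, 2]
    cur <- e
    repeat {
      used[cur] <- TRUE
      vx <- edges[cur, 3]; vy <- edges[cur, 4]
      loop_x <- c(loop_x, vx); loop_y <- c(loop_y, vy)
      cand <- lookup[[key(vx, vy)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      if (length(cand) > 1) {
        ## pinch vertex: prefer the sharpest right turn to keep loops simple
        dx <- edges[cur, 3] - edges[cur, 1]; dy <- edges[cur, 4] - edges[cur, 2]
        turn <- vapply(cand, function(k) {
          ex <- edges[k, 3] - edges[k, 1]; ey <- edges[k, 4] - edges[k, 2]
          atan2(dx * ey - dy * ex, dx * ex + dy * ey)
        }, numeric(1))
        cand <- cand[order(turn)][1]
      }
      cur <- cand[1]
    }
    ## drop the duplicated closing vertex; merge collinear runs
    loop_x <- loop_x[-length(loop_x)]; loop_y <- loop_y[-length(loop_y)]
    keep <- rep(TRUE, length(loop_x))
    n <- length(loop_x)
    for (i in seq_len(n)) {
      p <- if (i == 1) n else i - 1
      nx <- if (i == n) 1 else i + 1
      v1x <- loop_x[i] - loop_x[p]; v1y <- loop_y[i] - loop_y[p]
      v2x <- loop_x[nx] - loop_x[i]; v2y <- loop_y[nx] - loop_y[i]
      if (v1x * v2y - v1y * v2x == 0) keep[i] <- FALSE
    }
    loops[[length(loops) + 1]] <- cbind(x = loop_x[keep], y = loop_y[keep])
  }
  loops
}

write_be_short <- function(v) {
  v <- as.integer(v)
  as.raw(c(v %/% 256L %% 256L, v %% 256L))
}

## Serialize one polygon (corner coordinates) as ImageJ .roi bytes.
encode_imagej_polygon <- function(xy) {
  x <- as.integer(xy[, 1]); y <- as.integer(xy[, 2])
  left <- min(x); top <- min(y)
  header <- raw(64)
  header[1:4] <- charToRaw("Iout")
  header[5:6] <- write_be_short(227L)            # version
  header[7] <- as.raw(IJ_ROI_TYPES[["polygon"]])
  header[9:10] <- write_be_short(top)
  header[11:12] <- write_be_short(left)
  header[13:14] <- write_be_short(max(y))
  header[15:16] <- write_be_short(max(x))
  header[17:18] <- write_be_short(length(x))
  c(header,
    unlist(lapply(x - left, write_be_short)),
    unlist(lapply(y - top, write_be_short)))
}

#' Export a ROI set as an ImageJ-compatible ROI zip
#'
#' Each label's pixel-boundary polygon is written as a polygon `.roi`
#' entry (named `0001.roi`, `0002.roi`, ... in label order) inside a
#' store-only ZIP.  Re-importing with [import_imagej_rois()] reproduces
#' the label image exactly for hole-free ROIs; a ROI whose pixel set has
#' several boundary loops (holes) triggers a warning and only its outer
#' loop is written.
#'
#' @param rois A `roi_set`.
#' @param path Output `.zip` path.
#' @export
export_imagej_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  ids <- sort(unique(rois$labels[rois$labels != 0]))
  entries <- lapply(ids, function(id) {
    loops <- trace_pixel_boundary(rois$labels == id)
    if (length(loops) > 1) {
      warnf("ROI %d has %d boundary loops; writing the longest only",
            id, length(loops))
      loops <- loops[order(-vapply(loops, nrow, integer(1)))]
    }
    encode_imagej_polygon(loops[[1]])
  })
  names(entries) <- sprintf("%04d.roi", ids)
  write_store_zip(entries, path)
  invisible(path)
}

## ---- minimal store-only ZIP writer -----------------------------------

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  for (n in 0:255) {
    cc <- n
    for (k in 1:8)
      cc <- if (bitwAnd(cc, 1L) != 0L)
        bitwXor(poly, bitwShiftR(cc, 1L)) else bitwShiftR(cc, 1L)
    tab[n + 1] <- cc
  }
  tab
})

crc32 <- function(bytes) {
  cc <- -1L
  for (b in as.integer(bytes))
    cc <- bitwXor(bitwShiftR(cc, 8L),
                  crc32_table[bitwAnd(bitwXor(cc, b), 255L) + 1L])
  bitwXor(cc, -1L)
}

le_bytes <- function(v, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
    if (v < 0) v <- v + 2^(8 * (n - i))  # signed crc -> unsigned bytes
  }
  out
}

write_store_zip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    name <- charToRaw(names(entries)[i])
    crc <- crc32(data)
    local_hdr <- c(le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0, 2),
                   le_bytes(0, 2), le_bytes(0, 2), le_bytes(0x21, 2),
                   le_bytes(crc, 4), le_bytes(length(data), 4),
                   le_bytes(length(data), 4), le_bytes(length(name), 2),
                   le_bytes(0, 2))
    offsets[i] <- pos
    writeBin(c(local_hdr, name, data), con)
    pos <- pos + length(local_hdr) + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    data <- entries[[i]]
    name <- charToRaw(names(entries)[i])
    crc <- crc32(data)
    cd <- c(le_bytes(0x02014b50, 4), le_bytes(20, 2), le_bytes(20, 2),
            le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2), le_bytes(0x21, 2),
            le_bytes(crc, 4), le_bytes(length(data), 4),
            le_bytes(length(data), 4), le_bytes(length(name), 2),
            le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(0, 4), le_bytes(offsets[i], 4))
    writeBin(c(cd, name), con)
    pos <- pos + length(cd) + length(name)
  }
  eocd <- c(le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(length(entries), 2), le_bytes(length(entries), 2),
            le_bytes(pos - cd_start, 4), le_bytes(cd_start, 4),
            le_bytes(0, 2))
  writeBin(eocd, con)
  invisible(path)
}
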