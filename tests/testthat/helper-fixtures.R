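## Shared fixture builders: everything is generated in code at test time.

## Small horizontal ellipse mask (the standard desk-scale cell geometry).
fix_ellipse <- function(H = 61, W = 121, ry = 25, rx = 55, angle = 0)
  ellipse_mask(H, W, ry, rx, angle)

## Synthetic noisy-cell video: bright ellipse on dark background + shot
## noise, used for mask auto-generation tests.
fix_cell_video <- function(H = 64, W = 64, n_frames = 5, fg = 400, bg = 100,
                           seed = 1) {
  m <- ellipse_mask(H, W, round(0.35 * H), round(0.2 * W))
  base <- matrix(bg, H, W)
  base[m$pixels] <- fg
  frames <- array(0, c(n_frames, H, W))
  set.seed(seed)
  for (t in seq_len(n_frames))
    frames[t, , ] <- rpois(H * W, as.vector(base))
  list(video = new_video(frames, 50), truth = m)
}

## Mean per-label Jaccard between two label images.
label_jaccard <- function(a, b, ids) {
  mean(vapply(ids, function(k) {
    ak <- a == k; bk <- b == k
    sum(ak & bk) / max(1L, sum(ak | bk))
  }, numeric(1)))
}
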