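test_that("ICA recovers the AP source from noisy observations", {
  ap <- gen_ap(100)
  obs <- make_observations(ap, 30, -10, seed = 5)
  dec <- auto_select(decompose(obs, "ICA", 1, seed = 5))
  filt <- reconstruct(dec)
  act <- active_frames(ap$timing, 100, 500)
  r <- mean(apply(filt$traces, 1, function(x) cor(x[act], ap$values[act])))
  expect_gt(r, 0.9)
  ## silence-interval power strongly reduced by discarding noise sources
  sil <- silence_frames(ap$timing, 100, 500)
  p_in <- mean(obs$traces[, sil]^2)
  p_out <- mean(filt$traces[, sil]^2)
  expect_lt(p_out / p_in, 0.10)
})

test_that("PCA with m = n is the identity and degenerate inputs error", {
  set.seed(6)
  X <- matrix(rnorm(8 * 100), 8, 100)
  dec <- decompose(X, "PCA", 8)
  rec <- reconstruct(dec, 1:8)
  expect_equal(rec$traces, X, tolerance = 1e-8)

  ## two noise-free copies of one signal -> single PCA source, r = 1
  s <- sin(seq(0, 6 * pi, length.out = 200))
  two <- rbind(s, s) + 0.5
  d1 <- decompose(two, "PCA", 1)
  expect_equal(abs(cor(d1$sources[1, ], s)), 1, tolerance = 1e-10)

  expect_error(decompose(X, "PCA", 9), "m")
  expect_error(decompose(rbind(rep(1, 50), rnorm(50)), "PCA", 1),
               "zero-variance")
  expect_error(decompose(X[1, , drop = FALSE], "PCA", 1), "2 observations")
})

test_that("auto-selection picks the source with active-interval energy", {
  tm <- signal_timing(2.5, 5, 5)
  set.seed(7)
  n <- 150
  sig <- c(rep(0, 250), rep(4, 250))
  S <- rbind(rnorm(500), sig + rnorm(500, 0, 0.1), rnorm(500))
  A <- matrix(rnorm(9), 3, 3)
  dec <- structure(list(method = "PCA", m = 3, sources = S, mixing = A,
                        offsets = rep(0, 3), fps = 100, timing = tm,
                        selected = NULL), class = "bss_decomposition")
  expect_equal(auto_select(dec)$selected, 2L)
  ## m = 1 trivially selects the only source
  d1 <- decompose(matrix(rnorm(200), 2, 100), "PCA", 1)
  d1$fps <- 100; d1$timing <- tm
  expect_equal(auto_select(d1)$selected, 1L)
})

test_that("reconstruction is invariant to source sign/scale ambiguity", {
  obs <- make_observations(gen_ap(100), 10, -5, seed = 8)
  dec <- decompose(obs, "PCA", 3)
  rec1 <- reconstruct(dec, 1:3)
  dec$sources[2, ] <- -2 * dec$sources[2, ]
  dec$mixing[, 2] <- -dec$mixing[, 2] / 2
  rec2 <- reconstruct(dec, 1:3)
  expect_equal(rec1$traces, rec2$traces, tolerance = 1e-10)
})

test_that("ICA is deterministic under a fixed seed", {
  obs <- make_observations(gen_ap(100), 12, -10, seed = 9)
  d1 <- decompose(obs, "ICA", 2, seed = 11)
  d2 <- decompose(obs, "ICA", 2, seed = 11)
  expect_identical(d1$sources, d2$sources)
  expect_identical(d1$mixing, d2$mixing)
})

test_that("baseline centering zeroes the silence median and is idempotent", {
  tm <- signal_timing(2.5, 2.8, 5)
  expect_equal(center_baseline(rep(3.7, 500), tm, 100), rep(0, 500))
  set.seed(10)
  x <- rnorm(500) + 3.2
  y <- center_baseline(x, tm, 100)
  sil <- silence_frames(tm, 100, 500)
  expect_equal(median(y[sil]), 0)
  expect_equal(center_baseline(y, tm, 100), y)
  expect_error(center_baseline(x, signal_timing(0, 5, 5), 100), "silence")
})

test_that("filtering error shrinks as SNR grows", {
  ap <- gen_ap(100)
  err_at <- function(db) {
    mean(sapply(1:4, function(s) {
      obs <- make_observations(ap, 30, db, seed = 100 * db + s)
      dec <- auto_select(decompose(obs, "ICA", 1, seed = s))
      filt <- reconstruct(dec)
      true_amp <- obs$gain * max(abs(ap$values))
      mean(abs(sapply(1:30, function(j) {
        tr <- center_baseline(filt$traces[j, ], ap$timing, 100)
        e_r_amp(max(abs(tr[active_frames(ap$timing, 100, 500)])), true_amp)
      })))
    }))
  }
  e <- c(err_at(-15), err_at(-5), err_at(5))
  expect_gt(e[1], e[3])

  ## errors grow when too many components are kept (past m = 3)
  obs <- make_observations(ap, 30, -10, seed = 12)
  err_m <- sapply(c(2, 10, 25), function(m) {
    dec <- auto_select(decompose(obs, "PCA", m))
    filt <- reconstruct(dec, 1:m)
    true_amp <- obs$gain * max(abs(ap$values))
    mean(abs(sapply(1:30, function(j) {
      tr <- center_baseline(filt$traces[j, ], ap$timing, 100)
      e_r_amp(max(abs(tr[active_frames(ap$timing, 100, 500)])), true_amp)
    })))
  })
  expect_lt(err_m[1], err_m[3])
})

test_that("two-component electroporation structure survives m=3 selection", {
  ## synthetic construction: persistent step + brief charging peak with
  ## ROI-dependent loadings, at ~4 dB
  fps <- 100; T_ <- 500
  t <- (0:(T_ - 1)) / fps
  tm <- signal_timing(2.5, 5, 5)
  step <- as.numeric(t >= 2.5)
  peak <- ifelse(t >= 2.5, exp(-(t - 2.5) / 0.0167), 0)
  set.seed(13)
  n <- 32
  ## per-ROI loadings mirroring the spheroid field: unit step, charging
  ## peaks up to ~3x the step with both polarities; every ROI scaled to
  ## its own ~4 dB full-record SNR
  a_peak <- runif(n, 1, 3) * sign(runif(n, -1, 1))
  truth <- outer(rep(1, n), step) + outer(a_peak, peak)
  for (j in 1:n) truth[j, ] <- truth[j, ] * scale_to_snr(truth[j, ], 15, 4)
  noise <- t(sapply(1:n, function(j) gen_shot_noise(T_, 225, seed = j)))
  obs <- metroidr:::new_trace_set(truth + noise, fps, tm)
  dec <- decompose(obs, "PCA", 3)
  filt <- reconstruct(dec, 1:2)
  pk_err <- st_err <- numeric(n)
  for (j in 1:n) {
    tr <- center_baseline(filt$traces[j, ], tm, fps)
    tmj <- trace_metrics(tr, truth[j, ], tm, fps)
    pk_err[j] <- tmj$peak_e_r_amp
    st_err[j] <- tmj$stationary_e_r_amp
  }
  expect_lt(mean(abs(pk_err)), 0.15)
  expect_lt(mean(abs(st_err)), 0.15)
})
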