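test_that("AP surrogate honors timing, peak placement and APDs", {
  fps <- 100
  ap <- gen_ap(fps)
  t <- (seq_along(ap$values) - 1) / fps
  expect_true(all(ap$values[t < 2.5 | t > 2.8] == 0))
  expect_true(all(ap$values <= 0))
  expect_equal(which.min(ap$values), round(2.5 * fps) + 3)  # 2-frame upstroke
  ## oracle: threshold-crossing search for the APDs
  pk <- which.min(ap$values)
  apd <- function(q) {
    i <- which(t > t[pk] & ap$values >= -(1 - q))[1]
    t[i] - 2.5
  }
  expect_lt(abs(apd(0.25) - 0.035), 1 / fps + 1e-9)
  expect_lt(abs(apd(0.75) - 0.120), 1 / fps + 1e-9)
  expect_error(gen_ap(50), "infeasible")
})

test_that("step signal is exact in onset sample count and sign", {
  s <- gen_step(50, amplitude = 1)
  expect_equal(sum(s$values == 0), round(2.5 * 50))
  expect_true(all(s$values[126:250] == 1))
  expect_equal(gen_step(50, amplitude = -2)$values[200], -2)
  expect_equal(gen_step(50)$timing$t_end, 5)
  expect_error(gen_step(50, amplitude = 0), "non-zero")
})

test_that("shot noise is zero-mean, variance lambda, seeded and independent", {
  x <- gen_shot_noise(1e5, 225, seed = 3)
  expect_lt(abs(mean(x)), 0.3)
  expect_lt(abs(var(x) - 225) / 225, 0.02)
  expect_identical(x, gen_shot_noise(1e5, 225, seed = 3))
  ## skewness of Poisson(225) is 1/15
  y <- gen_shot_noise(1e6, 225, seed = 4)
  skew <- mean(y^3) / sd(y)^3
  expect_lt(abs(skew - 1 / 15), 0.02)
  ## independence across derived seeds: mean |r| over several pairs
  ## stays at the 1/sqrt(T) floor
  s <- metroidr:::derive_seeds(1, 10)
  rs <- sapply(1:5, function(k) {
    a <- gen_shot_noise(1e4, 225, s[2 * k - 1])
    b <- gen_shot_noise(1e4, 225, s[2 * k])
    abs(cor(a, b))
  })
  expect_lt(mean(rs), 0.02)
})

test_that("SNR follows the power definition and gain scaling is exact", {
  expect_equal(snr(rep(2, 100), 2)$ratio, 1)
  expect_equal(snr(rep(2, 100), 2)$db, 0)
  expect_equal(snr(rep(0, 10), 1)$ratio, 0)
  x <- rnorm(200)
  expect_equal(snr(3 * x, 2)$ratio, 9 * snr(x, 2)$ratio)
  expect_error(snr(x, 0), "sigma_noise")

  g <- scale_to_snr(x, 15, -10)
  expect_equal(snr(g * x, 15)$db, -10, tolerance = 1e-9)
  expect_equal(mean((scale_to_snr(x, 15, -10) * x)^2), 22.5,
               tolerance = 1e-9)
  expect_equal(scale_to_snr(x / sqrt(mean(x^2)), 1, 0), 1)
  ## down-scale then re-scale to the original SNR recovers the amplitude
  g1 <- scale_to_snr(x, 15, -15)
  g2 <- scale_to_snr(g1 * x, 15, snr(x, 15)$db)
  expect_equal(g1 * g2, 1, tolerance = 1e-9)
  expect_error(scale_to_snr(rep(0, 5), 1, 0), "zero")
})

test_that("observation stacks hit the target SNR and bleach drift", {
  ap <- gen_ap(100)
  obs <- make_observations(ap, 30, -10, seed = 2)
  sil <- silence_frames(ap$timing, 100, 500)
  vs <- apply(obs$traces[, sil], 1, var)
  expect_lt(abs(mean(vs) - 225) / 225, 0.05)
  ## realized SNR near target (Monte-Carlo, averaged over rows)
  realized <- 10 * log10(mean((obs$gain * ap$values)^2) / mean(vs))
  expect_lt(abs(realized - (-10)), 0.5)

  ## near-noise-free limit reproduces the scaled source
  quiet <- make_observations(ap, 2, -10, lam = 1e-9, seed = 1)
  expect_lt(max(abs(quiet$traces[1, ] - quiet$gain * ap$values)), 1e-3)

  ## mean drift of a bleached observation matches the integral of the
  ## exponential term
  bl <- data.frame(A = 30, B = 0.4, C = 2)
  one <- make_observations(ap, 1, -10, lam = 1e-9, seed = 1, bleach = bl)
  drift <- mean(one$traces[1, ] - quiet$gain * ap$values)
  expected <- bl$A * (1 - exp(-bl$B * 5)) / (bl$B * 5) + bl$C
  expect_lt(abs(drift - expected), 0.05)

  ## reproducibility: seed + n fully determine the dataset
  expect_identical(make_observations(ap, 5, -10, seed = 9)$traces,
                   make_observations(ap, 5, -10, seed = 9)$traces)
})
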