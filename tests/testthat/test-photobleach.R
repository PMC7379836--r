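test_that("bleach models evaluate correctly", {
  f <- list(model = "exp", pars = list(A = 0, B = 1, C = 7, D = 0, E = 0),
            t_onset = 2.5)
  expect_equal(eval_bleach(f, 0:4), rep(7, 5))
  f$pars$A <- 100; f$pars$B <- 0.5; f$pars$C <- 10
  expect_equal(eval_bleach(f, 2), 100 * exp(-1) + 10)
  ## step term inert before onset and removable
  fs <- f; fs$model <- "exp_step"; fs$pars$E <- 3
  t <- seq(0, 5, by = 0.1)
  expect_equal(eval_bleach(fs, t[t < 2.5]), eval_bleach(f, t[t < 2.5]))
  expect_equal(eval_bleach(fs, 4, include_step = FALSE), eval_bleach(f, 4))
  expect_equal(eval_bleach(fs, 4), eval_bleach(f, 4) - 3)
})

test_that("all four models recover generating parameters on noiseless data", {
  fps <- 100
  t <- (0:499) / fps
  tm_ap <- signal_timing(2.5, 2.8, 5)
  tm_st <- signal_timing(2.5, 5, 5)
  gen <- list(A = 50, B = 0.4, C = 5, D = 1.2, E = 20)
  cases <- list(
    list(y = gen$A * exp(-gen$B * t) + gen$C,
         mode = "DBPC", model = "exp", tm = tm_ap, pars = c("A", "B", "C")),
    list(y = gen$A * exp(-gen$B * t) + gen$C - gen$D * t,
         mode = "DBPC", model = "exp_lin", tm = tm_ap,
         pars = c("A", "B", "C", "D")),
    list(y = gen$A * exp(-gen$B * t) + gen$C - gen$E * (t >= 2.5),
         mode = "FDPC", model = "exp_step", tm = tm_st,
         pars = c("A", "B", "C", "E")),
    list(y = gen$A * exp(-gen$B * t) + gen$C - gen$D * t -
           gen$E * (t >= 2.5),
         mode = "FDPC", model = "exp_lin_step", tm = tm_st,
         pars = c("A", "B", "C", "D", "E")))
  for (cs in cases) {
    f <- fit_bleach(cs$y, cs$tm, fps, cs$mode, cs$model)
    expect_true(f$converged)
    for (p in cs$pars)
      expect_lt(abs(f$pars[[p]] - gen[[p]]) / abs(gen[[p]]), 1e-6)
    ## correcting the pure curve with its own fit leaves the embedded step
    corr <- correct_bleach(cs$y, f, fps)
    resid <- corr - if (grepl("step", cs$model)) -gen$E * (t >= 2.5) else 0
    expect_lt(max(abs(resid)), 1e-6)
  }
  ## SBPC on the pre-onset window also recovers the exponential
  fsb <- fit_bleach(gen$A * exp(-gen$B * t) + gen$C, tm_ap, fps, "SBPC")
  expect_lt(abs(fsb$pars$B - gen$B) / gen$B, 1e-6)
})

test_that("correction preserves signal and FDPC preserves the step", {
  fps <- 100
  ap <- gen_ap(fps)
  t <- (0:499) / fps
  y <- 10 * ap$values + 40 * exp(-0.3 * t) + 6
  f <- fit_bleach(y, ap$timing, fps, "DBPC", "exp")
  corr <- correct_bleach(y, f, fps)
  expect_gt(cor(corr, 10 * ap$values), 0.99)

  stp <- gen_step(fps, amplitude = -20)
  ys <- stp$values + 40 * exp(-0.3 * t) + 6
  fs <- fit_bleach(ys, stp$timing, fps, "FDPC", "exp_step")
  expect_lt(abs(fs$pars$E - 20) / 20, 0.01)
  corr_s <- correct_bleach(ys, fs, fps)
  expect_lt(abs((median(corr_s[t >= 2.5]) - median(corr_s[t < 2.5])) + 20),
            0.1)
})

test_that("window/mode misuse raises informative errors", {
  fps <- 100
  tm_st <- signal_timing(2.5, 5, 5)
  y <- exp(-0.3 * (0:499) / fps)
  expect_error(fit_bleach(y, tm_st, fps, "DBPC"), "silence window")
  expect_error(fit_bleach(y, tm_st, fps, "FDPC", "exp"), "step-bearing")
  expect_error(fit_bleach(y, signal_timing(2.5, 2.8, 5), fps, "SBPC",
                          "exp_step"), "FDPC")
  short <- signal_timing(0.03, 2.8, 5)
  expect_error(fit_bleach(y, short, fps, "SBPC"), "shorter")
})

test_that("SBPC degrades parameter recovery relative to DBPC at -10 dB", {
  fps <- 100
  ap <- gen_ap(fps)
  t <- (0:499) / fps
  err <- sapply(1:50, function(s) {
    bl <- random_bleach_params(1, 15, seed = s)
    obs <- make_observations(ap, 1, -10, seed = s, bleach = bl)
    y <- obs$traces[1, ]
    rel <- function(f) mean(abs(c(f$pars$A - bl$A, f$pars$B - bl$B,
                                  f$pars$C - bl$C) /
                                  c(bl$A, bl$B, max(abs(bl$C), 1))))
    c(SBPC = rel(fit_bleach(y, ap$timing, fps, "SBPC")),
      DBPC = rel(fit_bleach(y, ap$timing, fps, "DBPC")))
  })
  expect_gt(mean(err["SBPC", ]), mean(err["DBPC", ]))
})
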