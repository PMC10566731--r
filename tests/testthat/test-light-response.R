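test_that("the light-response curve behaves at its landmarks", {
  expect_identical(jassby_platt(0, 32.44, 0.16), 0)
  # saturation: far beyond Ek the curve sits on the plateau
  expect_lt(abs(jassby_platt(100 * 32.44 / 0.16, 32.44, 0.16) - 32.44),
            1e-6)
  # at E = Ek the response is pmax * tanh(1)
  expect_equal(jassby_platt(210.97, 32.44, 0.1538), 32.44 * tanh(1),
               tolerance = 1e-3)
  expect_equal(32.44 * tanh(1), 24.71, tolerance = 1e-3)
  # monotone nondecreasing
  p <- jassby_platt(seq(0, 500, by = 5), 20, 0.1)
  expect_true(all(diff(p) >= 0))
  expect_error(jassby_platt(-1, 10, 0.1), "non-negative")
  expect_error(jassby_platt(10, 0, 0.1), "pmax")
})

test_that("saturation irradiance is pmax/alpha, from fits or numbers", {
  expect_equal(saturation_irradiance(32.44, 0.1538), 210.92,
               tolerance = 1e-4)
  expect_equal(saturation_irradiance(20.54, 0.1007), 203.97,
               tolerance = 1e-3)
  expect_identical(saturation_irradiance(1, 1), 1)
  expect_error(saturation_irradiance(10, 0), "alpha = 0")
  P <- jassby_platt(light_steps[-1], 30, 0.15)
  f <- fit_light_curve(light_steps[-1], P)
  expect_equal(saturation_irradiance(f), coef(f)[["pmax"]] / coef(f)[["alpha"]])
  expect_equal(saturation_irradiance(f), f$e_k)
})

test_that("noiseless data are recovered to high precision", {
  E <- light_steps
  P <- jassby_platt(E, 32.44, 0.16)
  f <- fit_light_curve(E, P)   # dark step dropped by default
  expect_lt(abs(coef(f)[["pmax"]] - 32.44) / 32.44, 1e-4)
  expect_lt(abs(coef(f)[["alpha"]] - 0.16) / 0.16, 1e-4)
  expect_true(f$converged)
  expect_true(f$saturating)
  expect_lt(f$rss, 1e-8)
})

test_that("Nelder-Mead matches or beats a dense brute-force grid", {
  set.seed(31)
  for (rep in 1:3) {
    E <- light_steps[-1]
    P <- jassby_platt(E, 25, 0.14) + rnorm(length(E), 0, 2)
    f <- fit_light_curve(E, P)
    rss <- function(pm, al) sum((P - pm * tanh(al * E / pm))^2)
    pm_grid <- seq(0.25, 4, length.out = 200) * coef(f)[["pmax"]]
    al_grid <- seq(0.25, 4, length.out = 200) * coef(f)[["alpha"]]
    grid_min <- min(outer(pm_grid, al_grid,
                          Vectorize(function(pm, al) rss(pm, al))))
    expect_lte(f$rss, grid_min + 1e-6)
  }
})

test_that("fits are scale-equivariant in the response", {
  set.seed(5)
  E <- light_steps[-1]
  P <- jassby_platt(E, 18, 0.12) + rnorm(length(E), 0, 0.5)
  f1 <- fit_light_curve(E, P)
  f2 <- fit_light_curve(E, 10 * P)
  expect_equal(coef(f2)[["pmax"]] / coef(f1)[["pmax"]], 10,
               tolerance = 1e-4)
  expect_equal(coef(f2)[["alpha"]] / coef(f1)[["alpha"]], 10,
               tolerance = 1e-4)
  expect_equal(f2$e_k, f1$e_k, tolerance = 1e-4)
})

test_that("pmax recovery is accurate at low noise and degrades with noise", {
  E <- light_steps
  err_at <- function(noise_frac, n = 120, seed) {
    set.seed(seed)
    median(replicate(n, {
      P <- jassby_platt(E, 32.44, 0.16) +
        rnorm(length(E), 0, noise_frac * 32.44)
      abs(coef(fit_light_curve(E, P))[["pmax"]] - 32.44) / 32.44
    }))
  }
  expect_lt(err_at(0.02, seed = 61), 0.05)
  expect_lt(err_at(0.02, seed = 62), err_at(0.10, seed = 62))
})

test_that("degenerate fit inputs are rejected or flagged", {
  expect_error(fit_light_curve(c(26, 86, 156), c(0, 0, 0)), "degenerate")
  expect_error(fit_light_curve(c(26, 86), c(1, 2)), "3 distinct")
  P <- jassby_platt(light_steps[-1], 30, 0.15) + c(1, -1, 2, -2, 1)
  f <- fit_light_curve(light_steps[-1], P, maxit = 1)
  expect_false(f$converged)       # flagged, parameters still returned
  expect_length(coef(f), 2)
})

test_that("dark-offset fits recover a known respiration offset", {
  E <- light_steps
  P <- jassby_platt(E, 30, 0.15) - 4
  f <- fit_light_curve(E, P, dark_offset = TRUE)
  expect_equal(coef(f)[["pmax"]], 30, tolerance = 1e-3)
  expect_equal(coef(f)[["rd"]], 4, tolerance = 1e-3)
  expect_equal(predict(f, 0), -4, tolerance = 1e-3)
})

test_that("Welch from summaries matches the closed-form computation", {
  w <- welch_from_summary(32.44, 3.58, 5, 20.54, 1.96, 5)
  v <- 3.58^2 + 1.96^2
  expect_equal(unname(w$statistic), (20.54 - 32.44) / sqrt(v),
               tolerance = 1e-12)
  expect_equal(unname(w$parameter),
               v^2 / (3.58^4 / 4 + 1.96^4 / 4), tolerance = 1e-12)
  # an arbitrary hand-computed case
  w2 <- welch_from_summary(10, 2, 4, 16, 3, 6)
  expect_equal(unname(w2$statistic), 6 / sqrt(13), tolerance = 1e-12)
  expect_equal(unname(w2$parameter), 169 / (16 / 3 + 81 / 5),
               tolerance = 1e-12)
  # equal means
  w3 <- welch_from_summary(5, 1, 4, 5, 2, 4)
  expect_identical(unname(w3$statistic), 0)
  expect_identical(w3$p.value, 1)
  expect_error(welch_from_summary(1, 0, 5, 1, 0, 5), "zero variance")
  expect_error(welch_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("Welch from samples equals the summary route and base t.test", {
  set.seed(13)
  for (i in 1:5) {
    x1 <- rnorm(5, 30, 8); x2 <- rnorm(7, 21, 4)
    ws <- welch_from_samples(x1, x2)
    wm <- welch_from_summary(mean(x1), sd(x1) / sqrt(5), 5,
                             mean(x2), sd(x2) / sqrt(7), 7)
    expect_equal(unname(ws$statistic), unname(wm$statistic),
                 tolerance = 1e-10)
    tt <- t.test(x2, x1)   # independent cross-check
    expect_equal(unname(ws$statistic), unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(unname(ws$parameter), unname(tt$parameter),
                 tolerance = 1e-10)
    expect_equal(ws$p.value, tt$p.value, tolerance = 1e-10)
  }
  x <- c(1, 2, 3)
  expect_equal(unname(welch_from_samples(x, x)$statistic), 0)
  expect_error(welch_from_samples(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Welch p-values are uniform under the null", {
  set.seed(17)
  p <- replicate(2000,
                 welch_from_samples(rnorm(5), rnorm(5))$p.value)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("Welch df lies between min(n)-1 and n1+n2-2", {
  set.seed(19)
  for (i in 1:50) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    w <- welch_from_samples(rnorm(n1), rnorm(n2, 1))
    expect_gte(unname(w$parameter), min(n1, n2) - 1 - 1e-9)
    expect_lte(unname(w$parameter), n1 + n2 - 2 + 1e-9)
  }
})
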