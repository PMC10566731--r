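test_that("the shipped treatment parameter table is complete", {
  tf <- default_treatment_fits()
  expect_equal(nrow(tf), 16)
  expect_setequal(unique(tf$variable), c("do", "dic", "ph", "omega"))
  expect_setequal(unique(tf$flow_L_min), c(0.5, 1.4))
  expect_true(all(tf$pmax > 0 & tf$alpha > 0))
})

test_that("per-density rate reproduces the direct tanh evaluation", {
  m <- amelioration_model()
  r <- per_density_rate(m, 250, 0.5, "future", "dic")
  expect_equal(r, 25.79 * tanh(0.17 * 250 / 25.79) * (30 / 150),
               tolerance = 1e-12)
  expect_lt(abs(r - 4.5) / 4.5, 0.10)   # the headline kelp-bed figure
  expect_identical(per_density_rate(m, 0, 0.5, "future", "dic"), 0)
})

test_that("flow interpolation is exact at endpoints and linear between", {
  m <- amelioration_model()
  E <- c(50, 150, 250)
  lo <- per_density_rate(m, E, 0.5, "ambient", "do")
  hi <- per_density_rate(m, E, 1.4, "ambient", "do")
  expect_equal(lo, jassby_platt(E, 32.44, 0.16) / 5, tolerance = 1e-12)
  expect_equal(hi, jassby_platt(E, 20.54, 0.10) / 5, tolerance = 1e-12)
  mid <- per_density_rate(m, E, 0.95, "ambient", "do")
  expect_equal(mid, (lo + hi) / 2, tolerance = 1e-12)
  expect_warning(per_density_rate(m, 100, 2.0, "ambient", "do"), "clamped")
  expect_error(per_density_rate(m, 100, 2.0, "ambient", "do",
                                strict = TRUE), "outside")
})

test_that("bulk change scales the per-density rate by biomass density", {
  expect_identical(predict_bulk_change(4.5, 5e6, 1e6), 22.5)
  expect_identical(predict_bulk_change(4.5, 0, 1e6), 0)
  expect_equal(predict_bulk_change(4.5, 2 * 5e6, 1e6),
               2 * predict_bulk_change(4.5, 5e6, 1e6))
  expect_error(predict_bulk_change(1, -1, 10), "biomass")
})

test_that("background translation moves pH and omega the right way", {
  r0 <- apply_to_background(0, 2200, 2100, 11, 30)
  expect_equal(r0$pH_after, r0$pH_before, tolerance = 1e-9)
  r <- apply_to_background(22.5, 2200, 2100, 11, 30)
  expect_gt(r$pH_after, r$pH_before)
  expect_gt(r$d_omega, 0)
  expect_equal(r$after$DIC_umol_kg, 2200 - 22.5 / 1.024, tolerance = 1e-6)
  expect_equal(r$after$TA_umol_kg, 2100)   # alkalinity untouched
})

test_that("fresh/dry weight conversion applies the printed regression", {
  expect_equal(fw_to_dw(100), 0.1187 * 100 - 0.0086, tolerance = 1e-12)
  expect_equal(fw_to_dw(100), 11.8614, tolerance = 1e-6)
  expect_identical(fw_to_dw(0), 0)
  x <- c(1, 10, 150)
  expect_equal(dw_to_fw(fw_to_dw(x)), x, tolerance = 1e-12)
})

test_that("the amelioration threshold inverts the net light response", {
  m <- amelioration_model()
  expect_identical(amelioration_threshold(m, 0.5, "future", "dic", 0), 0)
  # at an endpoint flow, offset pmax*tanh(1) is crossed exactly at Ek
  ek <- 25.79 / 0.17
  es <- amelioration_threshold(m, 0.5, "future", "dic",
                               25.79 * tanh(1))
  expect_equal(es, ek, tolerance = 1e-2)
  # arbitrary offset: the threshold zeroes the net rate (dense grid check)
  off <- 7.3
  es2 <- amelioration_threshold(m, 0.9, "ambient", "do", off)
  w <- (0.9 - 0.5) / (1.4 - 0.5)
  net <- function(E) (1 - w) * jassby_platt(E, 32.44, 0.16) +
    w * jassby_platt(E, 20.54, 0.10) - off
  expect_lt(abs(net(es2)), 1e-2)
  grid <- seq(0, 1000, by = 0.05)
  first_pos <- grid[which(net(grid) >= 0)[1]]
  expect_lt(abs(es2 - first_pos), 0.06)
  expect_error(amelioration_threshold(m, 0.5, "future", "dic", 50),
               "never positive")
})

test_that("the rate surface is monotone in irradiance and scenario-ordered", {
  m <- amelioration_model()
  g1 <- surface_grid(m, "future", "dic", E_grid = 120, flow_grid = 0.8)
  expect_equal(g1$rate, per_density_rate(m, 120, 0.8, "future", "dic"))
  g <- surface_grid(m, "future", "dic", E_grid = seq(0, 260, by = 10),
                    flow_grid = c(0.5, 0.95, 1.4))
  for (fl in unique(g$flow_L_min))
    expect_true(all(diff(g$rate[g$flow_L_min == fl]) >= 0))
  # endpoint row equals the endpoint curve
  lo <- g[g$flow_L_min == 0.5, ]
  expect_equal(lo$rate,
               jassby_platt(lo$irradiance, 25.79, 0.17) / 5,
               tolerance = 1e-12)
  # at saturating light the future scenario outpaces ambient for DIC
  for (fl in c(0.5, 1.4))
    expect_gt(per_density_rate(m, 250, fl, "future", "dic"),
              per_density_rate(m, 250, fl, "ambient", "dic"))
})

test_that("predictions are linear in biomass density throughout", {
  m <- amelioration_model()
  p1 <- predict(m, irradiance = 200, flow = 0.7, scenario = "future",
                variable = "dic", biomass_fw = 1e6, volume_L = 1e6)
  p2 <- predict(m, irradiance = 200, flow = 0.7, scenario = "future",
                variable = "dic", biomass_fw = 3e6, volume_L = 1e6)
  expect_equal(p2$bulk_delta, 3 * p1$bulk_delta, tolerance = 1e-12)
  expect_equal(p1$per_density_rate, p2$per_density_rate)
})

test_that("predict with a background state returns the pH pair", {
  m <- amelioration_model()
  p <- predict(m, irradiance = 250, flow = 0.5, scenario = "future",
               variable = "dic", biomass_fw = 5e6, volume_L = 1e6,
               background = list(DIC = 2200, TA = 2100,
                                 temperature = 11, salinity = 30))
  expect_true(all(c("pH_before", "pH_after", "d_omega") %in% names(p)))
  expect_gt(p$pH_after, p$pH_before)
})

test_that("residence time converts flow and volume", {
  expect_equal(residence_time(0.5), 60)
  expect_equal(residence_time(1.4), 30 / 1.4)
  expect_error(residence_time(0), "positive")
})

test_that("treatment summaries from tank fits drive the model directly", {
  cfg <- noiseless_exp2(seed = 4)
  td <- tank_deltas(generate_tank_experiment(cfg))
  fits <- rbind(fit_tank_curves(td, "do")$summary,
                fit_tank_curves(td, "dic")$summary)
  m <- amelioration_model(fits, biomass_fw = 150, volume_L = 30)
  r <- per_density_rate(m, 250, 0.5, "future", "dic")
  expect_equal(r, 25.79 * tanh(0.17 * 250 / 25.79) / 5, tolerance = 1e-3)
})
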