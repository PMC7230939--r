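test_that("equal wall concentrations give a uniform field", {
  field <- solve_steady(device_mask_dx2(), transport_params(), c_left = 1, c_right = 1)
  expect_lt(max(abs(field$values[field$mask$inside] - 1)), 1e-9)
})

test_that("straight channel reproduces the linear pure-diffusion solution", {
  mask <- straight_channel_mask(length = 90, width = 36, dx = 1)
  field <- solve_steady(mask, transport_params())
  prof <- extract_axial_profile(field, 1)
  expect_lt(max(abs(prof$c_norm - prof$x_um / 90)), 1e-9)
  mid <- stats::approx(prof$x_um, prof$c_norm, xout = 45)$y
  expect_equal(mid, 0.5, tolerance = 1e-6)
})

test_that("straight channel reproduces the exponential advection solution", {
  L <- 90
  D <- 135
  for (Pe in c(-1.5, 2)) {
    mask <- straight_channel_mask(length = L, width = 36, dx = 0.5)
    field <- solve_steady(mask, transport_params(D = D, u_channel = Pe * D / L))
    prof <- extract_axial_profile(field, 1)
    analytic <- (exp(Pe * prof$x_um / L) - 1) / (exp(Pe) - 1)
    expect_lt(max(abs(prof$c_norm - analytic)), 0.005)
  }
})

test_that("steady device field obeys the maximum principle and balances wall fluxes", {
  field <- steady_dx2()
  vals <- field$values[field$mask$inside]
  expect_gte(min(vals), -1e-9)
  expect_lte(max(vals), 1 + 1e-9)
  fx <- boundary_fluxes(field)
  expect_lt(abs(sum(fx)) / max(abs(fx)), 0.005)
})

test_that("axial profile is monotone with most of the drop across the channel", {
  prof <- extract_axial_profile(steady_dx2(), 4)
  expect_true(all(diff(prof$c_norm) > -1e-9))
  c_at <- function(x) stats::approx(prof$x_um, prof$c_norm, xout = x)$y
  expect_gt(c_at(240) - c_at(150), 0.4)
  expect_error(extract_axial_profile(steady_dx2(), 9), "out of range")
})

test_that("gradient regions split the channel span into thirds with hand-checked ranges", {
  g <- device_geometry()
  reg <- partition_regions(linear_profile(0.25, 0.80), g)
  expect_identical(reg$label, c("L", "M", "H"))
  expect_equal(reg$x_min, c(150, 180, 210))
  expect_equal(reg$x_max, c(180, 210, 240))
  expect_equal(reg$c_min, c(0.25, 0.25 + 0.55 / 3, 0.25 + 1.1 / 3), tolerance = 1e-9)
  expect_equal(reg$c_max, c(0.25 + 0.55 / 3, 0.25 + 1.1 / 3, 0.80), tolerance = 1e-9)

  flat <- linear_profile(0.5, 0.5)
  rf <- partition_regions(flat, g)
  expect_equal(rf$c_min, rf$c_max)

  short <- linear_profile(x = seq(150, 200, by = 1))
  expect_error(partition_regions(short, g), "cover")
})

test_that("linearity R2 is exact for a line and rejects degenerate windows", {
  prof <- linear_profile(0.2, 0.9)
  expect_equal(linearity_r2(prof, c(150, 240)), 1, tolerance = 1e-12)
  expect_error(linearity_r2(prof, c(150, 151)), "fewer than 3")
})

test_that("rmse matches hand computations and is symmetric", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(1, 4)), sqrt(2))
  a <- c(0.1, 0.5, 0.9)
  b <- c(0.2, 0.4, 1.0)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_error(rmse(1:3, 1:2), "length mismatch")
})

test_that("transient evolution holds the steady fixed point and balances mass per step", {
  mask <- device_mask_dx2()
  steady <- steady_dx2()
  series <- solve_transient(mask, transport_params(), t_end = 20, dt = 5, field0 = steady)
  drift <- max(abs(
    series$final$values[mask$inside] - steady$values[mask$inside]
  ))
  expect_lt(drift, 1e-8)

  grow <- solve_transient(mask, transport_params(), t_end = 60, dt = 5)
  rel <- abs(grow$mass$d_total - grow$mass$influx_dt) /
    max(abs(grow$mass$influx_dt))
  expect_lt(max(rel), 1e-3)
})

test_that("time to steady self-converges under dt refinement", {
  mask <- device_mask_dx2()
  t_coarse <- time_to_steady(mask, transport_params(), dt = 8, t_max = 4000)$t
  t_fine <- time_to_steady(mask, transport_params(), dt = 4, t_max = 4000)$t
  expect_lt(abs(t_coarse - t_fine) / t_fine, 0.05)
})

test_that("off-balance flow ratios bend the gradient away from linearity monotonically", {
  sweep <- sweep_ratio(c(0.5, 1, 1.5, 2, 3), grid = grid_spec(dx = 2))
  r2 <- setNames(sweep$r_squared, sweep$R)
  expect_equal(unname(which.max(r2)), which(sweep$R == 1))
  dep <- abs(r2 - 1)
  expect_true(all(diff(dep[c("1", "1.5", "2", "3")]) > 0))
  expect_gt(dep[["0.5"]], dep[["1"]])
})
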