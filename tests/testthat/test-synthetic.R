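test_that("the generator is reproducible from its seed", {
  cfg <- generator_config(seed = 42, n_tracks = 50, fission_base_hazard = 0.2)
  ex1 <- generate_tracks(cfg)
  ex2 <- generate_tracks(cfg)
  expect_identical(ex1$tracks, ex2$tracks)
  expect_identical(ex1$truth$events, ex2$truth$events)
  ex3 <- generate_tracks(generator_config(seed = 43, n_tracks = 50))
  expect_false(identical(ex1$tracks, ex3$tracks))
})

test_that("near-degenerate heading concentration drives DR to one", {
  cfg <- generator_config(
    seed = 2, n_tracks = 100,
    class_probs = c(SINGLE = 0, SMALL = 1, LARGE = 0),
    kappa = c(SINGLE = 0, SMALL = 1e6, LARGE = 1e6)
  )
  ex <- generate_tracks(cfg)
  expect_gt(as.numeric(directionality(ex$tracks)), 0.99)
})

test_that("calibration reproduces targets and rejects infeasible ones", {
  flat <- calibrate_generator(lt = 10, dr = 0)
  expect_identical(flat$kappa, 0)

  cal <- calibrate_generator(lt = 17.7, dr = 0.72, dn = 10.1, n_pilot = 5000, seed = 1)
  expect_equal(cal$step_mean, 2.2125)
  expect_gte(cal$pilot_dr, 0.70)
  expect_lte(cal$pilot_dr, 0.74)

  expect_error(calibrate_generator(lt = 5, dr = 0.5, dn = 6), "infeasible")
  expect_error(calibrate_generator(lt = 5, dr = 1.5), "<= 1")
})

test_that("class proportions follow the configured weights", {
  cfg <- generator_config(seed = 7, n_tracks = 500)
  ex <- generate_tracks(cfg)
  counts <- table(ex$truth$root_class)
  p_small <- cfg$class_probs[["SMALL"]]
  expect_lt(
    abs(counts[["SMALL"]] - 500 * p_small),
    3 * sqrt(500 * p_small * (1 - p_small))
  )
})

test_that("intensity profiles add calibrated, clipped gaussian noise", {
  field <- steady_dx2()
  clean <- extract_axial_profile(field, 4)
  same <- generate_intensity_profile(field, 4, noise_sd = 0, seed = 1)
  expect_equal(same$c_norm, clean$c_norm)
  expect_true(nrow(clean) >= 100)

  errs <- vapply(1:20, function(s) {
    noisy <- generate_intensity_profile(field, 4, noise_sd = 0.01, seed = s)
    rmse(noisy$c_norm, clean$c_norm)
  }, numeric(1))
  expect_gte(mean(errs), 0.007)
  expect_lte(mean(errs), 0.013)
  expect_true(all(errs >= 0 & errs <= 0.02))

  e_small <- rmse(generate_intensity_profile(field, 4, noise_sd = 0.005, seed = 3)$c_norm, clean$c_norm)
  e_big <- rmse(generate_intensity_profile(field, 4, noise_sd = 0.02, seed = 3)$c_norm, clean$c_norm)
  expect_lt(e_small, e_big)
})

test_that("detect_fission_events recovers every generated event exactly", {
  cfg <- generator_config(
    seed = 13, n_tracks = 80,
    class_probs = c(SINGLE = 0.1, SMALL = 0.4, LARGE = 0.5),
    fission_base_hazard = 0.4
  )
  ex <- generate_tracks(cfg)
  truth <- ex$truth$events
  found <- detect_fission_events(ex$tracks)
  expect_gt(nrow(truth), 0)
  expect_equal(nrow(found), nrow(truth))
  key <- function(df) paste(df$parent_id, df$t_h, df$parent_size, df$child_sizes)
  expect_setequal(key(found), key(truth))
  expect_equal(found$x_um, truth$x_um, tolerance = 1e-9)
})

test_that("calibrated defaults recover the per-class migration statistics", {
  # targets: per-class mean total path length, net displacement and DR with
  # their reported SEs; the generated means must sit within 2 SE
  targets <- list(
    SMALL = c(lt = 17.7, lt_se = 1.83, dn = 10.1, dn_se = 0.99, dr = 0.72, dr_se = 0.15),
    LARGE = c(lt = 14.2, lt_se = 2.94, dn = 4.44, dn_se = 2.01, dr = 0.79, dr_se = 0.22)
  )
  sums <- lapply(1:10, function(seed) {
    summarize_by_class(generate_tracks(generator_config(seed = seed, n_tracks = 300))$tracks)
  })
  pool <- function(cl, col) {
    mean(vapply(sums, function(s) s[[col]][s$class == cl], numeric(1)))
  }
  for (cl in names(targets)) {
    tg <- targets[[cl]]
    expect_lt(abs(pool(cl, "lt_mean") - tg[["lt"]]), 2 * tg[["lt_se"]])
    expect_lt(abs(pool(cl, "dn_mean") - tg[["dn"]]), 2 * tg[["dn_se"]])
    expect_lt(abs(pool(cl, "dr_mean") - tg[["dr"]]), 2 * tg[["dr_se"]])
  }
  # singles: sub-cell-diameter movement, negligible directionality
  expect_lt(pool("SINGLE", "lt_mean"), 4)
  expect_lt(abs(pool("SINGLE", "dr_mean")), 0.31)
})
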