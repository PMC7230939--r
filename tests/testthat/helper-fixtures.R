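# Shared fixtures. Expensive solves are cached per test run; everything is
# built in code, nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# default device rasterized at a coarse-but-resolving grid (fast solves)
device_mask_dx2 <- function() {
  cached("mask_dx2", build_domain_mask(device_geometry(), grid_spec(dx = 2)))
}

steady_dx2 <- function() {
  cached("steady_dx2", solve_steady(device_mask_dx2(), transport_params()))
}

# full-resolution field used by the acceptance checks
device_mask_dx1 <- function() {
  cached("mask_dx1", build_domain_mask(device_geometry(), grid_spec(dx = 1)))
}

steady_dx1 <- function() {
  cached("steady_dx1", solve_steady(device_mask_dx1(), transport_params()))
}

steady_dx05 <- function() {
  cached(
    "steady_dx05",
    solve_steady(
      build_domain_mask(device_geometry(), grid_spec(dx = 0.5)),
      transport_params()
    )
  )
}

fission_calibration <- function() {
  cached("fission_cal", calibrate_fission(field = steady_dx1(), seed = 1))
}

# hand-built track table: one row per point, native columns
make_track <- function(id, xy, sizes, t = seq_len(nrow(xy)) - 1, parent = NA_character_) {
  data.frame(
    track_id = id, parent_id = parent, frame = seq_along(t), t_h = t,
    x_um = xy[, 1], y_um = xy[, 2], size = sizes
  )
}

# an analytic linear axial profile across the default channel span
linear_profile <- function(c0 = 0.25, c1 = 0.80, x = seq(150, 240, by = 1)) {
  structure(
    data.frame(x_um = x, c_norm = c0 + (c1 - c0) * (x - 150) / 90),
    class = c("axial_profile", "data.frame")
  )
}
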