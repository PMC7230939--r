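#' Device geometry of the micro-optic-stalk chip
#'
#' Plan-view layout of the two-reservoir gradient device: a sink reservoir
#' (eye-imaginal-disc side, left), a source reservoir (brain-lobe side,
#' right), and an array of `n_channels` tapered microchannels joining their
#' inner faces. All lengths are in micrometres. The x axis originates at the
#' outer (left) wall of the sink reservoir and increases toward the source;
#' under the defaults the sink spans x in \[0, 150\], the channels
#' \[150, 240\] and the source \[240, 390\].
#'
#' Channel widths taper linearly from `channel_width_eid` at the sink face to
#' `channel_width_bl` at the source face. The channel array is centred on the
#' reservoir face; it must fit, i.e.
#' `n_channels * max(widths) + (n_channels - 1) * channel_spacing <=
#' reservoir_length`, otherwise a layout error is raised. The default
#' reservoir length equals the exact span of the default 8-channel array
#' (541 um), the smallest face that hosts it.
#'
#' @param reservoir_width Reservoir extent along x (um).
#' @param reservoir_length Reservoir extent along y, the face hosting the
#'   channel array (um).
#' @param reservoir_height Reservoir depth (um); becomes the thickness of the
#'   depth-averaged transport model in the reservoirs.
#' @param n_channels Number of microchannels (>= 1).
#' @param channel_length Channel length along x (um).
#' @param channel_width_bl Channel width at the source (brain-lobe) face (um).
#' @param channel_width_eid Channel width at the sink (eye-disc) face (um).
#' @param channel_height Channel depth (um).
#' @param channel_spacing Edge-to-edge gap between adjacent channels (um).
#' @return An object of class `device_geometry`.
#' @examples
#' geom <- device_geometry()
#' geom
#' @export
device_geometry <- function(reservoir_width = 150,
                            reservoir_length = 541,
                            reservoir_height = 50,
                            n_channels = 8,
                            channel_length = 90,
                            channel_width_bl = 37,
                            channel_width_eid = 35,
                            channel_height = 10,
                            channel_spacing = 35) {
  g <- list(
    reservoir_width = reservoir_width,
    reservoir_length = reservoir_length,
    reservoir_height = reservoir_height,
    n_channels = n_channels,
    channel_length = channel_length,
    channel_width_bl = channel_width_bl,
    channel_width_eid = channel_width_eid,
    channel_height = channel_height,
    channel_spacing = channel_spacing
  )
  class(g) <- "device_geometry"
  validate_device_geometry(g)
  g
}

validate_device_geometry <- function(g) {
  lens <- c(
    "reservoir_width", "reservoir_length", "reservoir_height",
    "channel_length", "channel_width_bl", "channel_width_eid",
    "channel_height", "channel_spacing"
  )
  for (f in lens) {
    v <- g[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("device_geometry: '", f, "' must be a single positive number", call. = FALSE)
    }
  }
  n <- g$n_channels
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop("device_geometry: 'n_channels' must be an integer >= 1", call. = FALSE)
  }
  span <- channel_array_span(g)
  if (span > g$reservoir_length + 1e-9) {
    stop(
      "device_geometry: channel array (", format(span),
      " um) does not fit on the reservoir face (", format(g$reservoir_length),
      " um)", call. = FALSE
    )
  }
  invisible(g)
}

# y-extent of the channel array, using the widest cross-section of each slot
channel_array_span <- function(g) {
  wmax <- max(g$channel_width_bl, g$channel_width_eid)
  g$n_channels * wmax + (g$n_channels - 1) * g$channel_spacing
}

# y centre of channel k, array centred on the reservoir face
channel_centers <- function(g) {
  wmax <- max(g$channel_width_bl, g$channel_width_eid)
  pitch <- wmax + g$channel_spacing
  margin <- (g$reservoir_length - channel_array_span(g)) / 2
  margin + wmax / 2 + (seq_len(g$n_channels) - 1) * pitch
}

# local channel width at axial position x (um from sink outer wall)
channel_width_at <- function(g, x) {
  x0 <- g$reservoir_width
  frac <- (x - x0) / g$channel_length
  g$channel_width_eid + (g$channel_width_bl - g$channel_width_eid) * frac
}

#' @export
print.device_geometry <- function(x, ...) {
  cat("Micro-optic-stalk device geometry (um)\n")
  cat(sprintf(
    "  reservoirs : %g x %g, depth %g (sink left, source right)\n",
    x$reservoir_width, x$reservoir_length, x$reservoir_height
  ))
  cat(sprintf(
    "  channels   : %d, length %g, width %g -> %g (sink -> source face), depth %g, gap %g\n",
    x$n_channels, x$channel_length, x$channel_width_eid,
    x$channel_width_bl, x$channel_height, x$channel_spacing
  ))
  cat(sprintf(
    "  domain     : x in [0, %g], y in [0, %g]\n",
    2 * x$reservoir_width + x$channel_length, x$reservoir_length
  ))
  invisible(x)
}

#' Grid specification for rasterizing the device
#'
#' Cell-centred square grid. `dx` must resolve the channels:
#' `dx <= min(channel_width_eid, channel_spacing) / 4` is enforced at
#' rasterization time.
#'
#' @param dx Grid step (um), default 1.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(dx = 1.0) {
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0) {
    stop("grid_spec: 'dx' must be a single positive number", call. = FALSE)
  }
  structure(list(dx = dx, origin = "eid_outer_wall"), class = "grid_spec")
}

#' Rasterize the device into a computational domain mask
#'
#' Produces the boolean inside raster, the per-cell thickness map (reservoir
#' depth in reservoirs, channel depth in channels, 0 outside) and an integer
#' region labelling (0 = outside, 1 = sink/EID reservoir, 2 = source/BL
#' reservoir, 2 + k = channel k). Cells belong to a region when their centre
#' falls inside it; channel widths taper linearly along x.
#'
#' @param geometry A [device_geometry()].
#' @param grid A [grid_spec()].
#' @return An object of class `domain_mask` with elements `inside`,
#'   `thickness`, `region` (nx-by-ny matrices; rows index x, columns y),
#'   `x`, `y` (cell-centre coordinates, um), `dx`, and `geometry`.
#' @examples
#' mask <- build_domain_mask(device_geometry(), grid_spec(dx = 2))
#' mask
#' @export
build_domain_mask <- function(geometry, grid = grid_spec()) {
  stopifnot(inherits(geometry, "device_geometry"), inherits(grid, "grid_spec"))
  validate_device_geometry(geometry)
  g <- geometry
  dx <- grid$dx
  if (dx > min(g$channel_width_eid, g$channel_spacing) / 4) {
    stop(
      "build_domain_mask: dx = ", dx, " um does not resolve the channels; ",
      "need dx <= ", min(g$channel_width_eid, g$channel_spacing) / 4,
      call. = FALSE
    )
  }
  Lx <- 2 * g$reservoir_width + g$channel_length
  Ly <- g$reservoir_length
  nx <- max(1L, round(Lx / dx))
  ny <- max(1L, round(Ly / dx))
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dx

  region <- matrix(0L, nrow = nx, ncol = ny)
  x_eid <- g$reservoir_width
  x_bl <- g$reservoir_width + g$channel_length
  region[xc < x_eid, ] <- 1L
  region[xc > x_bl, ] <- 2L

  centers <- channel_centers(g)
  chan_cols <- which(xc >= x_eid & xc <= x_bl)
  for (i in chan_cols) {
    w <- channel_width_at(g, xc[i])
    for (k in seq_len(g$n_channels)) {
      rows <- abs(yc - centers[k]) <= w / 2
      region[i, rows] <- 2L + k
    }
  }

  thickness <- matrix(0, nrow = nx, ncol = ny)
  thickness[region == 1L | region == 2L] <- g$reservoir_height
  thickness[region > 2L] <- g$channel_height

  m <- structure(
    list(
      inside = region > 0L, thickness = thickness, region = region,
      x = xc, y = yc, dx = dx, geometry = g
    ),
    class = "domain_mask"
  )
  validate_domain_mask(m)
  m
}

validate_domain_mask <- function(m) {
  if (!identical(m$inside, m$thickness > 0)) {
    stop("domain_mask: thickness > 0 must coincide with inside", call. = FALSE)
  }
  # every channel must touch both reservoirs through 4-connected adjacency
  nx <- nrow(m$region)
  for (k in seq_len(m$geometry$n_channels)) {
    code <- 2L + k
    cells <- which(m$region == code, arr.ind = TRUE)
    if (nrow(cells) == 0L) {
      stop("domain_mask: channel ", k, " has no raster cells", call. = FALSE)
    }
    west <- cells[cells[, 1] > 1L, , drop = FALSE]
    east <- cells[cells[, 1] < nx, , drop = FALSE]
    touches_eid <- any(m$region[cbind(west[, 1] - 1L, west[, 2])] == 1L)
    touches_bl <- any(m$region[cbind(east[, 1] + 1L, east[, 2])] == 2L)
    if (!touches_eid || !touches_bl) {
      stop("domain_mask: channel ", k, " is not connected to both reservoirs",
        call. = FALSE
      )
    }
  }
  invisible(m)
}

#' @export
print.domain_mask <- function(x, ...) {
  cat(sprintf(
    "Domain mask: %d x %d cells at dx = %g um; %d inside (%d channel cells)\n",
    nrow(x$region), ncol(x$region), x$dx, sum(x$inside), sum(x$region > 2L)
  ))
  invisible(x)
}

#' Plan-view areas of the rasterized regions
#'
#' @param mask A `domain_mask`.
#' @return Named numeric vector of areas (um^2) for the sink reservoir,
#'   source reservoir and each channel.
#' @export
region_areas <- function(mask) {
  stopifnot(inherits(mask, "domain_mask"))
  g <- mask$geometry
  codes <- c(EID = 1L, BL = 2L)
  ch <- setNames(2L + seq_len(g$n_channels), paste0("CHANNEL_", seq_len(g$n_channels)))
  codes <- c(codes, ch)
  vapply(codes, function(code) sum(mask$region == code) * mask$dx^2, numeric(1))
}

#' A straight uniform channel domain for solver validation
#'
#' Builds a single rectangular channel of uniform thickness whose left and
#' right ends are the Dirichlet walls of the transport solver. Pure diffusion
#' across it has the exact linear solution; with a uniform axial velocity it
#' has the exponential Peclet profile, making this domain the 1D oracle for
#' the finite-volume scheme.
#'
#' @param length Channel length (um).
#' @param width Channel width (um).
#' @param height Channel depth (um).
#' @param dx Grid step (um).
#' @return A `domain_mask` whose every inside cell is channel 1.
#' @export
straight_channel_mask <- function(length = 90, width = 36, height = 10, dx = 1) {
  nx <- max(2L, round(length / dx))
  ny <- max(1L, round(width / dx))
  region <- matrix(3L, nrow = nx, ncol = ny)
  thickness <- matrix(height, nrow = nx, ncol = ny)
  g <- list(
    reservoir_width = 0, reservoir_length = width, reservoir_height = height,
    n_channels = 1L, channel_length = length, channel_width_bl = width,
    channel_width_eid = width, channel_height = height, channel_spacing = width
  )
  class(g) <- "device_geometry"
  structure(
    list(
      inside = region > 0L, thickness = thickness, region = region,
      x = (seq_len(nx) - 0.5) * dx, y = (seq_len(ny) - 0.5) * dx,
      dx = dx, geometry = g
    ),
    class = "domain_mask"
  )
}
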