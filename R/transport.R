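#' Transport parameters for the gradient device
#'
#' Physical and model parameters of the depth-averaged diffusion-advection
#' model. The solved field is always the normalized concentration C/C0; the
#' inlet concentration `C0` (ng/mL), density and viscosity are carried as
#' metadata only.
#'
#' The default diffusivity corresponds to 1.35e-10 m^2/s, the Stokes-Einstein
#' scale for a ~22 kDa protein such as FGF-8 (and for the 20 kDa dextran
#' tracer used to validate such devices); with it the channel-scale gradient
#' develops within minutes, matching the observed device behaviour.
#'
#' Unequal inlet flow rates (flow ratio `R = QR/QL != 1`) leave a small bulk
#' velocity along the channels. It is modelled as a uniform axial velocity in
#' the channel cells with channel Peclet number `Pe = pe_alpha * (R - 1)`,
#' directed from the harder-flushed reservoir toward the other (for R > 1,
#' from source to sink, i.e. along -x). `pe_alpha` is calibrated once against
#' the closed-form 1D solution so that R = 2 produces a gradient-linearity
#' R-squared inside the reported 0.94-0.99 band.
#'
#' @param D Diffusivity (um^2/s), default 135.
#' @param C0 Inlet concentration (ng/mL), metadata.
#' @param QL,QR Left/right inlet volume flow rates (uL/min).
#' @param R Optional flow ratio QR/QL; when given, overrides `QR = R * QL`.
#' @param pe_alpha Dimensionless advection coupling, default 0.7.
#' @param u_channel Optional explicit axial channel velocity (um/s);
#'   overrides the `pe_alpha` model (used mainly for validation against
#'   closed-form solutions).
#' @param rho Fluid density (kg/m^3), metadata.
#' @param mu Fluid viscosity, metadata (units as printed in device reports).
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(D = 135, C0 = 100, QL = 1, QR = 1, R = NULL,
                             pe_alpha = 0.7, u_channel = NULL,
                             rho = 1070, mu = 1.05) {
  if (!is.null(R)) {
    stopifnot(is.numeric(R), length(R) == 1L, R > 0)
    QR <- R * QL
  }
  stopifnot(D > 0, C0 > 0, QL > 0, QR > 0)
  p <- list(
    D = D, C0 = C0, QL = QL, QR = QR, R = QR / QL,
    pe_alpha = pe_alpha, u_channel = u_channel, rho = rho, mu = mu
  )
  class(p) <- "transport_params"
  p
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf(
    "Transport parameters: D = %g um^2/s, C0 = %g ng/mL, R = QR/QL = %g (pe_alpha = %g)\n",
    x$D, x$C0, x$R, x$pe_alpha
  ))
  invisible(x)
}

# axial channel velocity (um/s) implied by the flow-ratio model
channel_velocity <- function(params, geometry) {
  if (!is.null(params$u_channel)) {
    return(params$u_channel)
  }
  pe <- params$pe_alpha * (params$R - 1)
  -pe * params$D / geometry$channel_length
}

# Assemble the depth-averaged finite-volume operator on the inside cells.
# Returns A (N x N, d/dt contribution A %*% C + b in amount/s with unit dC),
# b, the cell capacities V = h*dx^2, the cell index map, and the Dirichlet
# boundary bookkeeping needed for flux audits.
assemble_operator <- function(mask, params, c_left = 0, c_right = 1) {
  inside <- mask$inside
  N <- sum(inside)
  if (N == 0L) stop("assemble_operator: empty domain", call. = FALSE)
  nx <- nrow(inside)
  ny <- ncol(inside)
  id <- matrix(0L, nx, ny)
  id[inside] <- seq_len(N)
  h <- mask$thickness
  D <- params$D
  dx <- mask$dx
  u <- channel_velocity(params, mask$geometry)
  is_chan <- mask$region > 2L

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }

  # x-faces between (i, j) and (i + 1, j)
  W <- which(inside[-nx, ] & inside[-1, ], arr.ind = FALSE)
  if (length(W)) {
    sub <- arrayInd(W, c(nx - 1L, ny))
    iP <- id[cbind(sub[, 1], sub[, 2])]
    iN <- id[cbind(sub[, 1] + 1L, sub[, 2])]
    h1 <- h[cbind(sub[, 1], sub[, 2])]
    h2 <- h[cbind(sub[, 1] + 1L, sub[, 2])]
    g <- D * 2 * h1 * h2 / (h1 + h2)
    both_chan <- is_chan[cbind(sub[, 1], sub[, 2])] &
      is_chan[cbind(sub[, 1] + 1L, sub[, 2])]
    q <- ifelse(both_chan, u * (h1 + h2) / 2 * dx, 0)
    add(iP, iP, -g - q / 2); add(iP, iN, g - q / 2)
    add(iN, iP, g + q / 2); add(iN, iN, -g + q / 2)
  }

  # y-faces between (i, j) and (i, j + 1): diffusion only (velocity is axial)
  S <- which(inside[, -ny] & inside[, -1], arr.ind = FALSE)
  if (length(S)) {
    sub <- arrayInd(S, c(nx, ny - 1L))
    iP <- id[cbind(sub[, 1], sub[, 2])]
    iN <- id[cbind(sub[, 1], sub[, 2] + 1L)]
    h1 <- h[cbind(sub[, 1], sub[, 2])]
    h2 <- h[cbind(sub[, 1], sub[, 2] + 1L)]
    g <- D * 2 * h1 * h2 / (h1 + h2)
    add(iP, iP, -g); add(iP, iN, g)
    add(iN, iP, g); add(iN, iN, -g)
  }

  b <- numeric(N)
  # Dirichlet on the two outer x walls; the face value is the wall value,
  # half-cell distance dx/2, advective face flux carried at the wall value
  left_rows <- which(inside[1, ])
  right_rows <- which(inside[nx, ])
  if (length(left_rows) == 0L || length(right_rows) == 0L) {
    stop("assemble_operator: domain does not reach both outer walls", call. = FALSE)
  }
  iL <- id[cbind(1L, left_rows)]
  hL <- h[cbind(1L, left_rows)]
  gL <- 2 * D * hL
  qL <- ifelse(is_chan[cbind(1L, left_rows)], u * hL * dx, 0)
  add(iL, iL, -gL)
  b[iL] <- b[iL] + gL * c_left + qL * c_left

  iR <- id[cbind(nx, right_rows)]
  hR <- h[cbind(nx, right_rows)]
  gR <- 2 * D * hR
  qR <- ifelse(is_chan[cbind(nx, right_rows)], u * hR * dx, 0)
  add(iR, iR, -gR)
  b[iR] <- b[iR] + gR * c_right - qR * c_right

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  V <- h[inside] * dx^2
  list(
    A = A, b = b, V = V, id = id, N = N,
    bnd = list(
      left = list(idx = iL, g = gL, q = qL, c = c_left),
      right = list(idx = iR, g = gR, q = qR, c = c_right)
    )
  )
}

# net influx (amount/s) through each Dirichlet wall for concentration vector C
wall_influx <- function(bnd, C) {
  L <- bnd$left
  R <- bnd$right
  c(
    left = sum(L$g * (L$c - C[L$idx]) + L$q * L$c),
    right = sum(R$g * (R$c - C[R$idx]) - R$q * R$c)
  )
}

field_from_vector <- function(C, mask, params, bc, op = NULL) {
  values <- matrix(NA_real_, nrow = nrow(mask$region), ncol = ncol(mask$region))
  values[mask$inside] <- C
  structure(
    list(values = values, mask = mask, params = params, bc = bc, op = op),
    class = "concentration_field"
  )
}

#' Steady-state concentration field
#'
#' Solves the depth-averaged steady transport equation
#' `div(h grad C) - h u dC/dx = 0` (thickness map `h`, uniform axial channel
#' velocity `u`) with Dirichlet conditions `C/C0 = c_left` on the sink outer
#' wall and `c_right` on the source outer wall and zero normal flux on all
#' other walls, by direct sparse factorization of the finite-volume operator.
#'
#' @param mask A [build_domain_mask()] result.
#' @param params A [transport_params()].
#' @param c_left,c_right Normalized wall concentrations (defaults 0 and 1).
#' @param rtol Relative residual tolerance; the direct solve must satisfy it
#'   or an error is raised.
#' @return An object of class `concentration_field`; `values` is the C/C0
#'   raster (NA outside the domain).
#' @examples
#' mask <- build_domain_mask(device_geometry(), grid_spec(dx = 2))
#' field <- solve_steady(mask, transport_params())
#' range(field$values, na.rm = TRUE)
#' @export
solve_steady <- function(mask, params = transport_params(),
                         c_left = 0, c_right = 1, rtol = 1e-10) {
  stopifnot(inherits(mask, "domain_mask"))
  op <- assemble_operator(mask, params, c_left, c_right)
  C <- tryCatch(
    as.numeric(Matrix::solve(op$A, -op$b)),
    error = function(e) {
      stop("solve_steady: sparse solve failed (singular or disconnected domain?): ",
        conditionMessage(e),
        call. = FALSE
      )
    }
  )
  res <- as.numeric(op$A %*% C + op$b)
  scale <- max(abs(op$b), 1e-300)
  if (max(abs(res)) / scale > rtol) {
    stop(sprintf(
      "solve_steady: residual %.3e exceeds tolerance %.3e",
      max(abs(res)) / scale, rtol
    ), call. = FALSE)
  }
  field_from_vector(C, mask, params, c(left = c_left, right = c_right), op)
}

#' @export
print.concentration_field <- function(x, ...) {
  r <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "Concentration field (C/C0): %d x %d at dx = %g um, range [%.4f, %.4f]\n",
    nrow(x$values), ncol(x$values), x$mask$dx, r[1], r[2]
  ))
  invisible(x)
}

#' @export
plot.concentration_field <- function(x, ...) {
  graphics::image(x$mask$x, x$mask$y, x$values,
    col = grDevices::hcl.colors(64, "Blue-Red"),
    xlab = "x (um)", ylab = "y (um)", useRaster = TRUE, ...
  )
  invisible(x)
}

#' Net boundary fluxes of a steady field
#'
#' Influx through the sink-side and source-side Dirichlet walls, in the
#' solver's flux units. At steady state they must balance.
#'
#' @param field A `concentration_field` from [solve_steady()].
#' @return Named vector `c(left =, right =)` of net influxes.
#' @export
boundary_fluxes <- function(field) {
  stopifnot(inherits(field, "concentration_field"), !is.null(field$op))
  wall_influx(field$op$bnd, field$values[field$mask$inside])
}

#' Transient concentration evolution
#'
#' Integrates `h dC/dt = div(h grad C) - h u dC/dx` by implicit Euler with a
#' single sparse LU factorization reused across steps. With the implicit
#' scheme `dt` controls accuracy only. The per-step mass ledger (change in
#' total dissolved amount vs. net boundary influx) is returned; for this
#' scheme the two agree to round-off.
#'
#' @param mask A `domain_mask`.
#' @param params A `transport_params`.
#' @param t_end End time (s).
#' @param dt Time step (s).
#' @param field0 Initial `concentration_field`, or NULL for C = 0 everywhere.
#' @param c_left,c_right Wall concentrations.
#' @param save_times Times (s) at which to keep full snapshots (rounded to
#'   step boundaries); the final field is always kept.
#' @return A list of class `concentration_series`: `times`, `snapshots`
#'   (list of `concentration_field`), `final`, and `mass` (data.frame with
#'   per-step `t`, `total`, `d_total`, `influx_dt`).
#' @export
solve_transient <- function(mask, params = transport_params(), t_end, dt,
                            field0 = NULL, c_left = 0, c_right = 1,
                            save_times = numeric(0)) {
  stopifnot(inherits(mask, "domain_mask"), t_end > 0, dt > 0)
  op <- assemble_operator(mask, params, c_left, c_right)
  C <- if (is.null(field0)) {
    numeric(op$N)
  } else {
    stopifnot(inherits(field0, "concentration_field"))
    field0$values[mask$inside]
  }
  M <- Matrix::Diagonal(x = op$V / dt) - op$A
  fac <- Matrix::lu(M)
  n_steps <- ceiling(t_end / dt)
  save_steps <- unique(pmin(n_steps, pmax(1L, round(save_times / dt))))
  snapshots <- list()
  times <- numeric(0)
  total <- sum(op$V * C)
  ledger <- matrix(NA_real_, nrow = n_steps, ncol = 4,
    dimnames = list(NULL, c("t", "total", "d_total", "influx_dt"))
  )
  for (s in seq_len(n_steps)) {
    rhs <- op$V / dt * C + op$b
    C <- as.numeric(Matrix::solve(fac, rhs))
    if (!all(is.finite(C))) {
      stop("solve_transient: non-finite values at step ", s,
        " (t = ", s * dt, " s)",
        call. = FALSE
      )
    }
    new_total <- sum(op$V * C)
    ledger[s, ] <- c(
      s * dt, new_total, new_total - total, sum(wall_influx(op$bnd, C)) * dt
    )
    total <- new_total
    if (s %in% save_steps) {
      snapshots[[length(snapshots) + 1L]] <- field_from_vector(C, mask, params,
        c(left = c_left, right = c_right)
      )
      times <- c(times, s * dt)
    }
  }
  final <- field_from_vector(C, mask, params, c(left = c_left, right = c_right), op)
  structure(
    list(
      times = times, snapshots = snapshots, final = final,
      mass = as.data.frame(ledger)
    ),
    class = "concentration_series"
  )
}

#' Time for the channel midpoint to approach steady state
#'
#' Starting from C = 0 everywhere, integrates the transient model and
#' reports the first time the probed location reaches `frac` of its
#' steady-state value (linearly interpolated between steps). The default
#' probe is the axial midpoint of the middle channel.
#'
#' @param mask A `domain_mask`.
#' @param params A `transport_params`.
#' @param frac Target fraction of the steady value (default 0.95).
#' @param dt Time step (s).
#' @param t_max Give up after this time (s).
#' @param probe Optional `c(x, y)` probe location (um).
#' @return List with `t` (s), `steady_value`, and `probe`.
#' @export
time_to_steady <- function(mask, params = transport_params(), frac = 0.95,
                           dt = 2, t_max = 7200, probe = NULL) {
  stopifnot(inherits(mask, "domain_mask"), frac > 0, frac < 1)
  g <- mask$geometry
  if (is.null(probe)) {
    k <- ceiling(g$n_channels / 2)
    probe <- c(
      g$reservoir_width + g$channel_length / 2,
      channel_centers(g)[k]
    )
  }
  i <- which.min(abs(mask$x - probe[1]))
  j <- which.min(abs(mask$y - probe[2]))
  if (!mask$inside[i, j]) stop("time_to_steady: probe is outside the domain", call. = FALSE)

  steady <- solve_steady(mask, params)
  target <- steady$values[i, j]
  op <- steady$op
  pid <- op$id[i, j]

  M <- Matrix::Diagonal(x = op$V / dt) - op$A
  fac <- Matrix::lu(M)
  C <- numeric(op$N)
  prev <- 0
  t <- 0
  while (t < t_max) {
    rhs <- op$V / dt * C + op$b
    C <- as.numeric(Matrix::solve(fac, rhs))
    t <- t + dt
    cur <- C[pid]
    if (cur >= frac * target) {
      # linear interpolation inside the crossing step
      t_cross <- t - dt * (cur - frac * target) / max(cur - prev, 1e-300)
      return(list(t = t_cross, steady_value = target, probe = probe))
    }
    prev <- cur
  }
  stop("time_to_steady: ", frac, " of steady not reached within ", t_max, " s",
    call. = FALSE
  )
}

#' Axial concentration profile along one channel
#'
#' Width-averaged C/C0 along a channel's centerline band, extended across
#' both reservoirs, so the profile spans the full device (x in \[0, 390\]
#' under the defaults). Inside the channel the band is the local (tapered)
#' channel width; in the reservoirs it is the width at the adjacent channel
#' mouth.
#'
#' @param field A `concentration_field`.
#' @param channel_index Channel number (1-based, bottom to top).
#' @return A data.frame of class `axial_profile` with columns `x_um`,
#'   `c_norm`.
#' @export
extract_axial_profile <- function(field, channel_index = 1) {
  stopifnot(inherits(field, "concentration_field"))
  mask <- field$mask
  g <- mask$geometry
  if (!(channel_index %in% seq_len(g$n_channels))) {
    stop("extract_axial_profile: channel_index out of range 1..", g$n_channels,
      call. = FALSE
    )
  }
  ck <- channel_centers(g)[channel_index]
  x_eid <- g$reservoir_width
  x_bl <- g$reservoir_width + g$channel_length
  xs <- mask$x
  cvals <- vapply(seq_along(xs), function(i) {
    x <- xs[i]
    w <- if (x < x_eid) {
      g$channel_width_eid
    } else if (x > x_bl) {
      g$channel_width_bl
    } else {
      channel_width_at(g, x)
    }
    rows <- which(abs(mask$y - ck) <= w / 2 & mask$inside[i, ])
    if (length(rows) == 0L) NA_real_ else mean(field$values[i, rows])
  }, numeric(1))
  keep <- !is.na(cvals)
  structure(
    data.frame(x_um = xs[keep], c_norm = cvals[keep]),
    class = c("axial_profile", "data.frame")
  )
}

#' @export
plot.axial_profile <- function(x, ...) {
  graphics::plot(x$x_um, x$c_norm,
    type = "l", xlab = "x (um)",
    ylab = "C/C0", ylim = c(0, 1), ...
  )
  invisible(x)
}

#' Partition the channel span into the three gradient regions
#'
#' Splits the channel span into thirds by position — L (low concentration,
#' sink side), M (medium), H (high, source side) — and reports each third's
#' span and the range of the profile over it (sample values plus linearly
#' interpolated values at the region edges).
#'
#' @param profile An `axial_profile` covering the channel span.
#' @param geometry The `device_geometry` the profile was extracted from.
#' @return A data.frame of class `gradient_regions` with columns `label`,
#'   `x_min`, `x_max`, `c_min`, `c_max`.
#' @export
partition_regions <- function(profile, geometry) {
  stopifnot(inherits(profile, "axial_profile") || is.data.frame(profile))
  g <- geometry
  x0 <- g$reservoir_width
  x1 <- g$reservoir_width + g$channel_length
  x <- profile$x_um
  cc <- profile$c_norm
  dx_sample <- if (length(x) > 1) max(diff(x)) else Inf
  if (min(x) > x0 + dx_sample || max(x) < x1 - dx_sample) {
    stop("partition_regions: profile does not cover the channel span [",
      x0, ", ", x1, "] um",
      call. = FALSE
    )
  }
  edges <- x0 + g$channel_length * (0:3) / 3
  out <- lapply(1:3, function(r) {
    lo <- edges[r]
    hi <- edges[r + 1]
    inner <- cc[x >= lo & x <= hi]
    at_edges <- stats::approx(x, cc, xout = c(lo, hi), rule = 2)$y
    vals <- c(inner, at_edges)
    data.frame(
      label = c("L", "M", "H")[r], x_min = lo, x_max = hi,
      c_min = min(vals), c_max = max(vals)
    )
  })
  structure(do.call(rbind, out), class = c("gradient_regions", "data.frame"))
}

#' Gradient linearity (ordinary least squares R-squared)
#'
#' R-squared of the regression of C/C0 on x over an axial window, the
#' statistic used to certify gradient linearity across the channel span.
#'
#' @param profile An `axial_profile`.
#' @param x_window Length-2 numeric window (um).
#' @return R-squared in \[0, 1\].
#' @export
linearity_r2 <- function(profile, x_window) {
  stopifnot(length(x_window) == 2L)
  sel <- profile$x_um >= min(x_window) & profile$x_um <= max(x_window)
  x <- profile$x_um[sel]
  y <- profile$c_norm[sel]
  if (length(x) < 3L) stop("linearity_r2: fewer than 3 samples in window", call. = FALSE)
  if (stats::sd(x) == 0) stop("linearity_r2: degenerate window (constant x)", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    return(1)
  }
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

#' Root-mean-square error between two profiles
#'
#' @param simulated,measured Equal-length numeric vectors (e.g. model C/C0
#'   vs. dextran-intensity estimates).
#' @return `sqrt(mean((simulated - measured)^2))`.
#' @export
rmse <- function(simulated, measured) {
  if (length(simulated) != length(measured)) {
    stop("rmse: length mismatch (", length(simulated), " vs ",
      length(measured), ")",
      call. = FALSE
    )
  }
  if (length(simulated) < 1L) stop("rmse: empty input", call. = FALSE)
  sqrt(mean((simulated - measured)^2))
}
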