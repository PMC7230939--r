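#' Von Mises random deviates
#'
#' Best-Fisher rejection sampler for the von Mises circular distribution,
#' used for the heading of each migration step. `kappa = 0` is the uniform
#' circle; large `kappa` concentrates headings at `mu`.
#'
#' @param n Number of deviates.
#' @param kappa Concentration (>= 0).
#' @param mu Mean direction (radians).
#' @return Angles in radians.
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  stopifnot(kappa >= 0)
  if (n == 0L) {
    return(numeric(0))
  }
  if (kappa < 1e-8) {
    return(stats::runif(n, -pi, pi) + mu)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- (sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1)))[acc]
    k <- length(th)
    if (k) {
      out[(got + 1L):(got + k)] <- th
      got <- got + k
    }
  }
  mu + out
}

# mean resultant length A(kappa) = I1(kappa)/I0(kappa); the step-level
# expected cosine of a von Mises heading
vm_mean_cos <- function(kappa) {
  ifelse(kappa == 0, 0,
    besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
  )
}

# unordered partitions of n into >= 2 parts, each part >= 3
partitions_min3 <- function(n) {
  res <- list()
  rec <- function(rem, mx, acc) {
    if (rem == 0L) {
      if (length(acc) >= 2L) res[[length(res) + 1L]] <<- acc
      return(invisible())
    }
    hi <- min(mx, rem)
    if (hi < 3L) {
      return(invisible())
    }
    for (p in seq(hi, 3L)) {
      if (rem - p == 0L || rem - p >= 3L) rec(rem - p, p, c(acc, p))
    }
  }
  rec(as.integer(n), as.integer(n) - 3L, integer(0))
  res
}

#' Synthetic-experiment generator configuration
#'
#' Parameters of the biased-random-walk generator that emulates the observed
#' migration structure: hourly frames over 8 h; three size classes with
#' class-specific gamma step lengths and von Mises heading concentration
#' toward the gradient (+x); concentration-gated fission of large clusters.
#'
#' Defaults emulate the reported experiment: class probabilities 0.16 / 0.65
#' / 0.21 (single cells / small / large clusters); per-frame step means equal
#' to the reported per-class total path lengths divided by the 8 steps
#' (singles 2.67/8 = 0.334 um, small 17.7/8 = 2.2125 um, large 14.2/8 =
#' 1.775 um); heading concentrations calibrated by [calibrate_generator()]
#' against the reported per-class directionality (singles kappa = 0).
#' Large-cluster fission is a per-hour Poisson hazard that switches off where
#' the local C/C0 meets or exceeds `fission_conc_cutoff`; when a
#' concentration field is attached and the cutoff is left `NULL`, the cutoff
#' resolves to the minimum concentration of the field's high-gradient (H)
#' region, so that no fission occurs anywhere in H.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_tracks Number of root tracks.
#' @param class_probs Weights for SINGLE / SMALL / LARGE root tracks;
#'   normalized to sum to 1 (the reported percentages 16/65/21 sum to 102
#'   and are used as weights).
#' @param frame_interval Hours between frames.
#' @param n_frames Frames per track (first frame at t = 0).
#' @param step_mean Named per-class mean step length (um/frame).
#' @param step_shape Gamma shape of step lengths.
#' @param kappa Named per-class von Mises concentration toward +x.
#' @param size_range Named list of integer size supports per class.
#' @param fission_base_hazard Per-hour fission hazard of large clusters
#'   below the concentration cutoff.
#' @param fission_conc_cutoff C/C0 at or above which the hazard is zero;
#'   `NULL` resolves from `field` (H-region minimum) or 0.65 without one.
#' @param field Optional `concentration_field` coupling hazard and start
#'   positions to the device.
#' @param noise_sd Gaussian noise sd for [generate_intensity_profile()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             n_tracks = 300,
                             class_probs = c(SINGLE = 0.16, SMALL = 0.65, LARGE = 0.21),
                             frame_interval = 1,
                             n_frames = 9,
                             step_mean = c(SINGLE = 2.67 / 8, SMALL = 17.7 / 8, LARGE = 14.2 / 8),
                             step_shape = 2,
                             kappa = c(SINGLE = 0, SMALL = 0.877, LARGE = 1.069),
                             size_range = list(SINGLE = 1:2, SMALL = 3:5, LARGE = 6:8),
                             fission_base_hazard = 0,
                             fission_conc_cutoff = NULL,
                             field = NULL,
                             noise_sd = 0.01) {
  stopifnot(
    sum(class_probs) > 0,
    all(class_probs >= 0),
    n_frames >= 2, frame_interval > 0,
    fission_base_hazard >= 0,
    all(step_mean > 0), step_shape > 0, all(kappa >= 0)
  )
  cls <- c("SINGLE", "SMALL", "LARGE")
  if (!all(cls %in% names(class_probs)) || !all(cls %in% names(step_mean)) ||
    !all(cls %in% names(kappa)) || !all(cls %in% names(size_range))) {
    stop("generator_config: class_probs, step_mean, kappa and size_range must be named ",
      "SINGLE/SMALL/LARGE",
      call. = FALSE
    )
  }
  class_probs <- class_probs / sum(class_probs)
  structure(
    list(
      seed = seed, n_tracks = n_tracks, class_probs = class_probs[cls],
      frame_interval = frame_interval, n_frames = n_frames,
      step_mean = step_mean[cls], step_shape = step_shape, kappa = kappa[cls],
      size_range = size_range[cls], fission_base_hazard = fission_base_hazard,
      fission_conc_cutoff = fission_conc_cutoff, field = field,
      noise_sd = noise_sd
    ),
    class = "generator_config"
  )
}

# concentration lookup C/C0(x) and resolved cutoff for the fission gate
resolve_hazard_gate <- function(config) {
  if (is.null(config$field)) {
    cutoff <- if (is.null(config$fission_conc_cutoff)) 0.65 else config$fission_conc_cutoff
    return(list(cfun = NULL, cutoff = cutoff))
  }
  field <- config$field
  g <- field$mask$geometry
  prof <- extract_axial_profile(field, ceiling(g$n_channels / 2))
  cfun <- stats::approxfun(prof$x_um, prof$c_norm, rule = 2)
  cutoff <- config$fission_conc_cutoff
  if (is.null(cutoff)) {
    regions <- partition_regions(prof, g)
    cutoff <- regions$c_min[regions$label == "H"]
  }
  list(cfun = cfun, cutoff = cutoff)
}

#' Generate a synthetic collective-migration experiment
#'
#' Draws root tracks from the configured class mix and simulates each as a
#' biased random walk (gamma step lengths, von Mises headings about +x) at
#' the configured frame interval. Large clusters carry a Poisson fission
#' hazard, switched off at and above the concentration cutoff; on fission
#' the parent track ends and its cells are partitioned uniformly at random
#' into parts of at least 3 cells, each child continuing as its own track
#' with `parent_id` set. Fully reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @return An object of class `synthetic_experiment`: list with `tracks`
#'   (a `muos_tracks` table), and `truth` (root class labels, the true
#'   fission events, the resolved concentration cutoff and the config).
#' @export
generate_tracks <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  gate <- resolve_hazard_gate(config)
  g <- if (!is.null(config$field)) config$field$mask$geometry else device_geometry()
  x_lo <- g$reservoir_width
  x_hi <- g$reservoir_width + g$channel_length
  centers <- channel_centers(g)
  dt <- config$frame_interval
  nF <- config$n_frames
  cls_names <- c("SINGLE", "SMALL", "LARGE")

  rows <- vector("list", 0L)
  events <- vector("list", 0L)

  class_of_size <- function(size) {
    if (size <= 2) "SINGLE" else if (size <= 5) "SMALL" else "LARGE"
  }
  hazard_at <- function(x) {
    if (config$fission_base_hazard == 0) {
      return(0)
    }
    cval <- if (is.null(gate$cfun)) -Inf else gate$cfun(x)
    if (cval >= gate$cutoff) 0 else config$fission_base_hazard
  }

  simulate_branch <- function(id, parent_id, frame0, pos, size) {
    frames <- frame0
    xs <- pos[1]
    ys <- pos[2]
    fr <- frame0
    while (fr < nF) {
      fr <- fr + 1L
      cl <- class_of_size(size)
      step <- stats::rgamma(1, shape = config$step_shape,
        scale = config$step_mean[[cl]] / config$step_shape
      )
      ang <- rvonmises(1, config$kappa[[cl]])
      pos <- pos + step * c(cos(ang), sin(ang))
      frames <- c(frames, fr)
      xs <- c(xs, pos[1])
      ys <- c(ys, pos[2])
      if (size > 5 && fr < nF) {
        lam <- hazard_at(pos[1])
        if (lam > 0 && stats::runif(1) < 1 - exp(-lam * dt)) {
          parts <- partitions_min3(size)
          part <- parts[[sample.int(length(parts), 1)]]
          rows[[length(rows) + 1L]] <<- data.frame(
            track_id = id, parent_id = if (is.na(parent_id)) NA_character_ else parent_id,
            frame = frames, t_h = (frames - 1) * dt, x_um = xs, y_um = ys,
            size = size
          )
          events[[length(events) + 1L]] <<- data.frame(
            parent_id = id, t_h = (fr - 1) * dt, x_um = pos[1], y_um = pos[2],
            parent_size = size,
            child_sizes = paste(sort(part, decreasing = TRUE), collapse = ",")
          )
          for (ci in seq_along(part)) {
            simulate_branch(paste0(id, ".", ci), id, fr, pos, part[ci])
          }
          return(invisible())
        }
      }
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      track_id = id, parent_id = if (is.na(parent_id)) NA_character_ else parent_id,
      frame = frames, t_h = (frames - 1) * dt, x_um = xs, y_um = ys, size = size
    )
    invisible()
  }

  root_class <- character(config$n_tracks)
  for (i in seq_len(config$n_tracks)) {
    cl <- sample(cls_names, 1, prob = config$class_probs)
    root_class[i] <- cl
    size <- if (length(config$size_range[[cl]]) == 1L) {
      config$size_range[[cl]]
    } else {
      sample(config$size_range[[cl]], 1)
    }
    k <- sample.int(g$n_channels, 1)
    w <- min(g$channel_width_eid, g$channel_width_bl)
    start <- c(
      stats::runif(1, x_lo, x_hi),
      centers[k] + stats::runif(1, -w / 4, w / 4)
    )
    simulate_branch(sprintf("T%04d", i), NA_character_, 1L, start, size)
  }

  tracks <- as_tracks(do.call(rbind, rows))
  truth_events <- if (length(events)) {
    ev <- do.call(rbind, events)
    ev <- ev[order(ev$t_h, ev$parent_id), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  } else {
    data.frame(
      parent_id = character(0), t_h = numeric(0), x_um = numeric(0),
      y_um = numeric(0), parent_size = integer(0), child_sizes = character(0)
    )
  }
  structure(
    list(
      tracks = tracks,
      truth = list(
        root_class = root_class, events = truth_events,
        conc_cutoff = gate$cutoff, config = config
      )
    ),
    class = "synthetic_experiment"
  )
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "Synthetic experiment: %d root tracks (%d after fission), %d fission events, seed %d\n",
    x$truth$config$n_tracks, length(unique(x$tracks$track_id)),
    nrow(x$truth$events), x$truth$config$seed
  ))
  invisible(x)
}

# mean DR of a pilot cohort of pure biased random walks; deterministic in
# (kappa, n_pilot, seed) so it can be root-found over kappa
pilot_dr <- function(kappa, n_steps, n_pilot, seed, step_shape = 2) {
  set.seed(seed)
  len <- stats::rgamma(n_pilot * n_steps, shape = step_shape, scale = 1 / step_shape)
  ang <- rvonmises(n_pilot * n_steps, kappa)
  dx <- matrix(len * cos(ang), n_pilot, n_steps)
  dy <- matrix(len * sin(ang), n_pilot, n_steps)
  x <- rowSums(dx)
  y <- rowSums(dy)
  r <- sqrt(x^2 + y^2)
  ok <- r > 0
  mean(x[ok] / r[ok])
}

#' Calibrate the walk generator against target migration statistics
#'
#' Sets the per-frame step mean from the target total path length
#' (`lt / (n_frames - 1)`) and finds the von Mises concentration `kappa`
#' whose pilot-simulated directionality ratio matches the target within
#' `tol`. The mean-resultant-length relation `A(kappa) = I1/I0` supplies the
#' bracket; the final value comes from pilot simulation, because DR is the
#' cosine of the *net*-displacement angle of a multi-step walk, which is
#' more concentrated than a single step.
#'
#' @param lt Target total path length (um over the experiment).
#' @param dr Target directionality ratio.
#' @param dn Optional target net displacement (um), used only to check
#'   feasibility (`dn <= lt` required).
#' @param n_frames Frames per track (default 9: hourly over 8 h).
#' @param n_pilot Pilot cohort size.
#' @param seed Seed for the pilot simulations.
#' @param tol Tolerance on the pilot DR.
#' @param step_shape Gamma shape of step lengths.
#' @return List with `step_mean`, `kappa`, and `pilot_dr` (achieved value).
#' @export
calibrate_generator <- function(lt, dr, dn = NULL, n_frames = 9,
                                n_pilot = 5000, seed = 1, tol = 0.02,
                                step_shape = 2) {
  if (abs(dr) > 1) stop("calibrate_generator: |dr| must be <= 1", call. = FALSE)
  if (!is.null(dn) && dn > lt) {
    stop("calibrate_generator: infeasible targets (dn > lt)", call. = FALSE)
  }
  n_steps <- n_frames - 1L
  step_mean <- lt / n_steps
  if (dr == 0) {
    return(list(step_mean = step_mean, kappa = 0, pilot_dr = 0))
  }
  if (dr < 0) stop("calibrate_generator: dr < 0 not supported (flip the axis)", call. = FALSE)
  # step-level concentration giving mean cos = dr; the net-angle DR exceeds
  # it, so this brackets kappa from above
  k_hi <- stats::uniroot(function(k) vm_mean_cos(k) - dr, c(1e-6, 500))$root
  f <- function(k) pilot_dr(k, n_steps, n_pilot, seed, step_shape) - dr
  lo <- k_hi / 20
  while (f(lo) > 0 && lo > 1e-6) lo <- lo / 5
  kappa <- stats::uniroot(f, c(lo, k_hi * 2), tol = 1e-3)$root
  achieved <- pilot_dr(kappa, n_steps, n_pilot, seed, step_shape)
  if (abs(achieved - dr) > tol) {
    stop(sprintf(
      "calibrate_generator: pilot DR %.3f missed target %.3f beyond tol %.3f",
      achieved, dr, tol
    ), call. = FALSE)
  }
  list(step_mean = step_mean, kappa = kappa, pilot_dr = achieved)
}

#' Calibrate the disaggregation experiment
#'
#' Finds the initial small-cluster fraction and the large-cluster fission
#' hazard such that the expected motile small-cluster fraction matches the
#' target timeline (default 42% at t = 2 h and 65% at t = 8 h). A two-state
#' expectation model (each fission converts one large cluster into two small
#' ones at rate `hazard * P(C < cutoff)`) supplies the starting point; the
#' pair is then refined by Nelder-Mead on pilot simulations run with fixed
#' seeds, so the objective is deterministic.
#'
#' @param targets Named fractions, default `c(t2 = 0.42, t8 = 0.65)`.
#' @param times Times (h) the targets refer to, default `c(2, 8)`.
#' @param field Optional `concentration_field` the experiment couples to.
#' @param n_tracks Pilot cohort size per seed.
#' @param n_seeds Pilot seeds per objective evaluation.
#' @param seed Base seed for the pilots.
#' @return List with `small_frac0`, `hazard`, `config` (a ready
#'   [generator_config()] for the mixed small/large population), and
#'   `pilot` (achieved pilot fractions).
#' @export
calibrate_fission <- function(targets = c(t2 = 0.42, t8 = 0.65),
                              times = c(2, 8), field = NULL,
                              n_tracks = 300, n_seeds = 6, seed = 1) {
  stopifnot(length(targets) == length(times), all(targets > 0 & targets < 1))
  # fraction of the channel span below the concentration cutoff
  q <- if (is.null(field)) {
    1
  } else {
    gate <- resolve_hazard_gate(generator_config(field = field))
    g <- field$mask$geometry
    xs <- seq(g$reservoir_width, g$reservoir_width + g$channel_length, length.out = 201)
    mean(gate$cfun(xs) < gate$cutoff)
  }
  f_model <- function(sigma, lam, t) {
    p <- q * (1 - exp(-lam * t))
    (sigma + 2 * (1 - sigma) * p) / (1 + (1 - sigma) * p)
  }
  obj_model <- function(par) {
    sigma <- stats::plogis(par[1])
    lam <- exp(par[2])
    sum((f_model(sigma, lam, times) - targets)^2)
  }
  st <- stats::optim(c(0, log(0.1)), obj_model, method = "Nelder-Mead")$par

  make_config <- function(sigma, lam, s) {
    generator_config(
      seed = s, n_tracks = n_tracks,
      class_probs = c(SINGLE = 0, SMALL = sigma, LARGE = 1 - sigma),
      fission_base_hazard = lam, field = field
    )
  }
  pilot_frac <- function(sigma, lam) {
    sims <- vapply(seq_len(n_seeds), function(i) {
      ex <- generate_tracks(make_config(sigma, lam, seed + i))
      tl <- timeline_fraction_small(ex$tracks, times)
      tl$fraction_small
    }, numeric(length(times)))
    rowMeans(matrix(sims, nrow = length(times)))
  }
  obj_pilot <- function(par) {
    sigma <- stats::plogis(par[1])
    lam <- exp(par[2])
    sum((pilot_frac(sigma, lam) - targets)^2)
  }
  fit <- stats::optim(st, obj_pilot,
    method = "Nelder-Mead",
    control = list(maxit = 40, reltol = 1e-3)
  )
  sigma <- stats::plogis(fit$par[1])
  lam <- exp(fit$par[2])
  list(
    small_frac0 = sigma, hazard = lam,
    config = make_config(sigma, lam, seed),
    pilot = stats::setNames(pilot_frac(sigma, lam), names(targets))
  )
}

#' Noisy axial intensity profile
#'
#' Emulates a fluorescence-intensity readout of the tracer gradient: the
#' width-averaged axial profile of a field plus i.i.d. Gaussian noise,
#' clipped to \[0, 1\].
#'
#' @param field A `concentration_field`.
#' @param channel_index Channel to read out.
#' @param noise_sd Gaussian noise standard deviation (C/C0 units).
#' @param seed Seed.
#' @return An `axial_profile` data.frame.
#' @export
generate_intensity_profile <- function(field, channel_index = 1, noise_sd = 0.01,
                                       seed = 1) {
  prof <- extract_axial_profile(field, channel_index)
  set.seed(seed)
  noisy <- prof$c_norm + stats::rnorm(nrow(prof), sd = noise_sd)
  prof$c_norm <- pmin(pmax(noisy, 0), 1)
  prof
}
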