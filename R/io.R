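#' Read a track table
#'
#' The native dialect is a CSV with columns
#' `track_id,frame,t_h,x_um,y_um,size` and optionally `parent_id`. The
#' ImageJ dialect maps Manual-Tracking exports (`Track n°, Slice n°, X, Y`)
#' into it; because those exports carry pixel and slice units, the pixel
#' size (um/px) and frame interval (h) must be given explicitly, and the
#' cluster `size` column must be present (added during manual tracking) or
#' every cluster is taken as a single cell.
#'
#' @param path CSV file path.
#' @param dialect `"native"` or `"imagej"`.
#' @param pixel_size um per pixel (ImageJ dialect, required).
#' @param frame_interval Hours per slice (ImageJ dialect, required).
#' @return A `muos_tracks` table.
#' @export
read_tracks <- function(path, dialect = c("native", "imagej"),
                        pixel_size = NULL, frame_interval = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "native") {
    need <- c("track_id", "frame", "t_h", "x_um", "y_um", "size")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("read_tracks: '", path, "' lacks required column(s): ",
        paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    bad <- which(!stats::complete.cases(df[need]))
    if (length(bad)) {
      stop("read_tracks: malformed row at line ", bad[1] + 1L, " of '", path, "'",
        call. = FALSE
      )
    }
    return(as_tracks(df))
  }
  if (is.null(pixel_size) || is.null(frame_interval)) {
    stop("read_tracks: the imagej dialect requires pixel_size (um/px) and ",
      "frame_interval (h)",
      call. = FALSE
    )
  }
  cols <- names(df)
  track_col <- grep("^Track", cols, value = TRUE)[1]
  slice_col <- grep("^Slice", cols, value = TRUE)[1]
  if (is.na(track_col) || is.na(slice_col) || !all(c("X", "Y") %in% cols)) {
    stop("read_tracks: not an ImageJ Manual Tracking export (need Track/Slice/X/Y)",
      call. = FALSE
    )
  }
  out <- data.frame(
    track_id = df[[track_col]],
    frame = df[[slice_col]],
    t_h = (df[[slice_col]] - 1) * frame_interval,
    x_um = df$X * pixel_size,
    y_um = df$Y * pixel_size,
    size = if ("size" %in% cols) df$size else 1L
  )
  as_tracks(out)
}

#' Write a track table in the native CSV dialect
#'
#' @param tracks A `muos_tracks` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(as_tracks(as.data.frame(tracks)))
  cols <- c("track_id", "parent_id", "frame", "t_h", "x_um", "y_um", "size")
  utils::write.csv(df[cols], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write device geometry as a flat key:value config
#'
#' YAML with one key per [device_geometry()] field, all lengths in um.
#'
#' @param path YAML file path.
#' @return A `device_geometry`.
#' @export
read_geometry_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(device_geometry))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("read_geometry_config: unknown key(s): ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(device_geometry, vals)
}

#' @rdname read_geometry_config
#' @param geometry A `device_geometry` to write.
#' @export
write_geometry_config <- function(geometry, path) {
  stopifnot(inherits(geometry, "device_geometry"))
  yaml::write_yaml(unclass(geometry), path)
  invisible(path)
}

#' Write an axial profile as a two-column CSV
#'
#' @param profile An `axial_profile`.
#' @param path Output path; columns `x_um,c_norm`.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[c("x_um", "c_norm")], path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Gradient-linearity sweep over inlet flow ratios
#'
#' Solves the steady field for each flow ratio and reports the channel-span
#' linearity R-squared, reproducing the device-tuning analysis: R = 1 gives
#' the most linear gradient, off-balance ratios degrade it monotonically.
#'
#' @param ratios Flow ratios QR/QL to solve.
#' @param geometry A `device_geometry`.
#' @param grid A `grid_spec`.
#' @param params Base `transport_params` (its `R` is overridden per solve).
#' @return A data.frame with columns `R` and `r_squared`.
#' @export
sweep_ratio <- function(ratios = c(0.5, 1, 1.5, 2, 3),
                        geometry = device_geometry(), grid = grid_spec(),
                        params = transport_params()) {
  mask <- build_domain_mask(geometry, grid)
  g <- geometry
  window <- c(g$reservoir_width, g$reservoir_width + g$channel_length)
  mid <- ceiling(g$n_channels / 2)
  r2 <- vapply(ratios, function(R) {
    p <- params
    p$QR <- R * p$QL
    p$R <- R
    field <- solve_steady(mask, p)
    linearity_r2(extract_axial_profile(field, mid), window)
  }, numeric(1))
  data.frame(R = ratios, r_squared = r2)
}

#' Run the full simulate / generate / analyze pipeline
#'
#' Solves the steady concentration field, generates (or reads) a track
#' table, summarizes migration by size class, detects fission events,
#' localizes them in the gradient regions, computes the small-cluster
#' timeline, and writes every artifact plus a JSON manifest with MD5
#' checksums. Identical config and seed reproduce identical checksums.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the synthetic experiment.
#' @param geometry A `device_geometry`.
#' @param grid A `grid_spec`.
#' @param params A `transport_params`.
#' @param gen_config Optional [generator_config()]; by default a
#'   fission-calibrated mixed population coupled to the solved field.
#' @param tracks_csv Optional path to an existing native-dialect track CSV;
#'   when given, no synthetic tracks are generated.
#' @param timeline_times Times (h) for the disaggregation timeline.
#' @return The manifest (named list), invisibly written to
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         geometry = device_geometry(), grid = grid_spec(),
                         params = transport_params(), gen_config = NULL,
                         tracks_csv = NULL, timeline_times = 0:8) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  field <- stage("simulate", {
    mask <- build_domain_mask(geometry, grid)
    solve_steady(mask, params)
  })
  mid <- ceiling(geometry$n_channels / 2)
  profile <- extract_axial_profile(field, mid)
  regions <- partition_regions(profile, geometry)
  write_profile(profile, file.path(out_dir, "profile.csv"))
  utils::write.csv(as.data.frame(regions), file.path(out_dir, "regions.csv"),
    row.names = FALSE, quote = FALSE
  )

  tracks <- stage("tracks", {
    if (!is.null(tracks_csv)) {
      read_tracks(tracks_csv)
    } else {
      if (is.null(gen_config)) {
        gen_config <- calibrate_fission(field = field, seed = seed)$config
      }
      gen_config$seed <- seed
      gen_config$field <- field
      ex <- generate_tracks(gen_config)
      ex$tracks
    }
  })
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))

  summary <- stage("metrics", summarize_by_class(tracks))
  utils::write.csv(as.data.frame(summary), file.path(out_dir, "summary.csv"),
    row.names = FALSE, quote = FALSE
  )

  events <- stage("disaggregation", detect_fission_events(tracks))
  by_region <- events_by_region(events, regions)
  timeline <- timeline_fraction_small(tracks, timeline_times)
  utils::write.csv(as.data.frame(events), file.path(out_dir, "events.csv"),
    row.names = FALSE, quote = FALSE
  )
  utils::write.csv(
    data.frame(region = names(by_region), n_events = as.integer(by_region)),
    file.path(out_dir, "events_by_region.csv"),
    row.names = FALSE, quote = FALSE
  )
  utils::write.csv(as.data.frame(timeline), file.path(out_dir, "timeline.csv"),
    row.names = FALSE, quote = FALSE
  )

  files <- c(
    "profile.csv", "regions.csv", "tracks.csv", "summary.csv",
    "events.csv", "events_by_region.csv", "timeline.csv"
  )
  manifest <- list(
    seed = seed,
    flow_ratio = params$R,
    dx_um = grid$dx,
    artifacts = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$artifacts) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
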