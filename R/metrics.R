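#' Track tables
#'
#' Cluster trajectories are kept in a long-format data.frame with one row per
#' tracked time point: `track_id` (character or integer), `frame` (1-based
#' integer), `t_h` (hours), `x_um`, `y_um` (um) and `size` (cell count).
#' An optional `parent_id` column links fission children to the track they
#' detached from; a child's first frame is the fission frame.
#'
#' @param df A data.frame with the columns above.
#' @return The validated table with class `muos_tracks`.
#' @export
as_tracks <- function(df) {
  need <- c("track_id", "frame", "t_h", "x_um", "y_um", "size")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("as_tracks: missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"parent_id" %in% names(df)) df$parent_id <- NA_character_
  df$track_id <- as.character(df$track_id)
  df$parent_id <- as.character(df$parent_id)
  df$parent_id[!is.na(df$parent_id) & df$parent_id == ""] <- NA_character_
  if (any(df$size < 1)) stop("as_tracks: cluster sizes must be >= 1", call. = FALSE)
  if (any(df$t_h < 0)) stop("as_tracks: times must be >= 0", call. = FALSE)
  df <- df[order(df$track_id, df$t_h), , drop = FALSE]
  rownames(df) <- NULL
  bad <- tapply(df$t_h, df$track_id, function(t) any(diff(t) <= 0))
  if (any(unlist(bad))) {
    stop("as_tracks: track times must be strictly increasing", call. = FALSE)
  }
  class(df) <- c("muos_tracks", "data.frame")
  df
}

split_tracks <- function(tracks) {
  split(as.data.frame(tracks), tracks$track_id)
}

#' Size class of a cluster
#'
#' Classes partition the positive integers: SINGLE = 1-2 cells, SMALL = 3-5
#' cells, LARGE = more than 5 cells.
#'
#' @param size Integer vector of cell counts (>= 1).
#' @return Factor with levels SINGLE < SMALL < LARGE.
#' @examples
#' classify_cluster(c(1, 4, 6))
#' @export
classify_cluster <- function(size) {
  if (any(size < 1)) stop("classify_cluster: size must be >= 1", call. = FALSE)
  cut(size,
    breaks = c(0, 2, 5, Inf),
    labels = c("SINGLE", "SMALL", "LARGE"), ordered_result = TRUE
  )
}

#' Whole-track size class
#'
#' A fissioning track can change size class between frames; the track-level
#' class is the modal per-frame class, with ties broken toward the larger
#' class (a cluster that spends half its frames large and half small is
#' summarized as large only if large frames are at least as many).
#'
#' @param track One track's data.frame (rows of a `muos_tracks` table).
#' @return A single factor level.
#' @export
track_class <- function(track) {
  cl <- classify_cluster(track$size)
  counts <- table(cl)
  lev <- levels(cl)
  best <- lev[counts == max(counts)]
  factor(best[length(best)], levels = lev, ordered = TRUE)
}

#' Total path length of a track
#'
#' Sum of Euclidean step lengths over consecutive frames (the L_T migration
#' statistic), in um.
#'
#' @param track One track's data.frame with >= 2 time-ordered points.
#' @return Path length (um).
#' @export
total_path_length <- function(track) {
  if (nrow(track) < 2L) stop("total_path_length: track needs >= 2 points", call. = FALSE)
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' Net displacement of a track
#'
#' Euclidean distance between the first and last time points (the D_N
#' migration statistic), in um.
#'
#' @param track One track's data.frame with >= 2 time-ordered points.
#' @return Net displacement (um).
#' @export
net_displacement <- function(track) {
  if (nrow(track) < 2L) stop("net_displacement: track needs >= 2 points", call. = FALSE)
  n <- nrow(track)
  sqrt((track$x_um[n] - track$x_um[1])^2 + (track$y_um[n] - track$y_um[1])^2)
}

# per-track cos(angle between the net displacement and the axis); NA when
# the track does not displace
track_cos_theta <- function(track, axis = c(1, 0)) {
  n <- nrow(track)
  v <- c(track$x_um[n] - track$x_um[1], track$y_um[n] - track$y_um[1])
  nv <- sqrt(sum(v^2))
  na <- sqrt(sum(axis^2))
  if (nv == 0) {
    return(NA_real_)
  }
  sum(v * axis) / (nv * na)
}

#' Directionality ratio of a track population
#'
#' Mean over tracks of the cosine of the angle between each track's net
#' displacement vector and the directional axis (horizontal gradient axis by
#' default): `DR = sum(cos(theta)) / n`, one angle per trajectory. Tracks
#' with zero net displacement have no defined angle; they are excluded from
#' the mean and counted in the `n_stationary` attribute.
#'
#' @param tracks A `muos_tracks` table (or list of per-track data.frames).
#' @param axis Length-2 direction vector, default `c(1, 0)` (+x, toward the
#'   source reservoir).
#' @return DR in \[-1, 1\], with attributes `n` (tracks used) and
#'   `n_stationary` (excluded).
#' @export
directionality <- function(tracks, axis = c(1, 0)) {
  trs <- if (is.data.frame(tracks)) split_tracks(tracks) else tracks
  cosines <- vapply(trs, track_cos_theta, numeric(1), axis = axis)
  ok <- !is.na(cosines)
  if (!any(ok)) stop("directionality: no track with non-zero net displacement", call. = FALSE)
  structure(mean(cosines[ok]),
    n = sum(ok), n_stationary = sum(!ok)
  )
}

se <- function(x) {
  if (length(x) < 2L) {
    return(0)
  }
  stats::sd(x) / sqrt(length(x))
}

#' Per-class migration summary
#'
#' Classifies every track (modal per-frame class, ties toward larger) and
#' reports, per size class: track count, percentage of tracks, and mean with
#' standard error of total path length, net displacement and per-track
#' directionality cosine. The SE denominator is the number of tracks in the
#' class. Tracks with zero net displacement contribute to L_T and D_N but
#' not to DR; their count is reported in `n_stationary`.
#'
#' @param tracks A `muos_tracks` table.
#' @param axis Directional axis for DR, default `c(1, 0)`.
#' @return A data.frame of class `migration_summary` with one row per size
#'   class present plus columns `class`, `n`, `percent`, `lt_mean`, `lt_se`,
#'   `dn_mean`, `dn_se`, `dr_mean`, `dr_se`, `n_stationary`.
#' @export
summarize_by_class <- function(tracks, axis = c(1, 0)) {
  trs <- split_tracks(tracks)
  if (length(trs) < 1L) stop("summarize_by_class: no tracks", call. = FALSE)
  cls <- vapply(trs, function(tr) as.character(track_class(tr)), character(1))
  lt <- vapply(trs, total_path_length, numeric(1))
  dn <- vapply(trs, net_displacement, numeric(1))
  cth <- vapply(trs, track_cos_theta, numeric(1), axis = axis)
  total <- length(trs)
  out <- lapply(c("SINGLE", "SMALL", "LARGE"), function(cl) {
    sel <- cls == cl
    if (!any(sel)) {
      return(NULL)
    }
    ct <- cth[sel]
    data.frame(
      class = cl, n = sum(sel), percent = 100 * sum(sel) / total,
      lt_mean = mean(lt[sel]), lt_se = se(lt[sel]),
      dn_mean = mean(dn[sel]), dn_se = se(dn[sel]),
      dr_mean = if (any(!is.na(ct))) mean(ct, na.rm = TRUE) else NA_real_,
      dr_se = if (any(!is.na(ct))) se(ct[!is.na(ct)]) else NA_real_,
      n_stationary = sum(is.na(ct))
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("migration_summary", "data.frame")
  res
}

#' @export
print.migration_summary <- function(x, ...) {
  cat("Per-class migration summary (mean +/- SE per track)\n")
  df <- data.frame(
    class = x$class, n = x$n, percent = sprintf("%.1f%%", x$percent),
    L_T_um = sprintf("%.2f +/- %.2f", x$lt_mean, x$lt_se),
    D_N_um = sprintf("%.2f +/- %.2f", x$dn_mean, x$dn_se),
    DR = ifelse(is.na(x$dr_mean), "--",
      sprintf("%.2f +/- %.2f", x$dr_mean, x$dr_se)
    )
  )
  print(df, row.names = FALSE)
  invisible(x)
}
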