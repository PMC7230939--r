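#' Detect cluster fission (disaggregation) events
#'
#' A fission event is a parent track ending at time t and two or more child
#' tracks (rows carrying `parent_id`) starting at the same time. Children
#' born simultaneously from the same parent are grouped into one event, and
#' cell-count conservation is enforced: the child sizes at birth must sum to
#' the parent's size at its final frame.
#'
#' @param tracks A `muos_tracks` table with parent links.
#' @return A data.frame of class `fission_events` with columns `parent_id`,
#'   `t_h`, `x_um`, `y_um`, `parent_size`, `n_children`, `child_sizes`
#'   (comma-separated), ordered by time. Zero rows when no track carries a
#'   parent link.
#' @export
detect_fission_events <- function(tracks) {
  tracks <- as_tracks(as.data.frame(tracks))
  kids <- tracks[!is.na(tracks$parent_id), , drop = FALSE]
  empty <- structure(
    data.frame(
      parent_id = character(0), t_h = numeric(0), x_um = numeric(0),
      y_um = numeric(0), parent_size = integer(0), n_children = integer(0),
      child_sizes = character(0)
    ),
    class = c("fission_events", "data.frame")
  )
  if (nrow(kids) == 0L) {
    return(empty)
  }
  births <- do.call(rbind, lapply(split(kids, kids$track_id), function(tr) tr[1, ]))
  ev <- split(births, list(births$parent_id, births$t_h), drop = TRUE)
  out <- lapply(ev, function(b) {
    pid <- b$parent_id[1]
    t <- b$t_h[1]
    parent <- tracks[tracks$track_id == pid, , drop = FALSE]
    if (nrow(parent) == 0L) {
      stop("detect_fission_events: parent track '", pid, "' not found", call. = FALSE)
    }
    plast <- parent[nrow(parent), ]
    if (abs(plast$t_h - t) > 1e-9) {
      stop("detect_fission_events: children of '", pid, "' born at t = ", t,
        " h but parent ends at t = ", plast$t_h, " h",
        call. = FALSE
      )
    }
    if (sum(b$size) != plast$size) {
      stop("detect_fission_events: cell-count conservation violated for '",
        pid, "': children sum to ", sum(b$size), " but parent size is ",
        plast$size,
        call. = FALSE
      )
    }
    if (nrow(b) < 2L) {
      stop("detect_fission_events: fission of '", pid, "' has fewer than 2 children",
        call. = FALSE
      )
    }
    data.frame(
      parent_id = pid, t_h = t, x_um = plast$x_um, y_um = plast$y_um,
      parent_size = plast$size, n_children = nrow(b),
      child_sizes = paste(sort(b$size, decreasing = TRUE), collapse = ",")
    )
  })
  res <- do.call(rbind, out)
  res <- res[order(res$t_h, res$parent_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("fission_events", "data.frame")
  res
}

#' Count fission events per gradient region
#'
#' Assigns each event to the L/M/H gradient region by its x position; events
#' outside the channel span are counted under OUTSIDE.
#'
#' @param events A `fission_events` table.
#' @param regions A `gradient_regions` table from [partition_regions()].
#' @return Named integer vector with counts for L, M, H and OUTSIDE.
#' @export
events_by_region <- function(events, regions) {
  counts <- c(L = 0L, M = 0L, H = 0L, OUTSIDE = 0L)
  if (nrow(events) == 0L) {
    return(counts)
  }
  for (x in events$x_um) {
    hit <- which(x >= regions$x_min & x <= regions$x_max)
    lab <- if (length(hit)) regions$label[hit[1]] else "OUTSIDE"
    counts[lab] <- counts[lab] + 1L
  }
  counts
}

#' Small-cluster fraction of the motile population over time
#'
#' At each requested time, finds the clusters present (a track with a point
#' at that time whose centroid is still within the channel span, when a span
#' is given), keeps the motile ones — cumulative path length up to that time
#' above `motile_threshold` (default 4 um, one cell diameter) — with current
#' size of at least 3 cells, and reports the fraction whose current size is
#' 3-5 cells (small clusters) versus more than 5 (large).
#'
#' @param tracks A `muos_tracks` table.
#' @param times Numeric vector of times (hours).
#' @param motile_threshold Cumulative path length (um) a cluster must exceed
#'   to count as motile.
#' @param x_span Optional length-2 vector; clusters whose centroid has left
#'   this axial span are dropped from the denominator.
#' @return A data.frame of class `disagg_timeline` with columns `t_h`,
#'   `fraction_small`, `n_motile`.
#' @export
timeline_fraction_small <- function(tracks, times, motile_threshold = 4,
                                    x_span = NULL) {
  trs <- split_tracks(as_tracks(as.data.frame(tracks)))
  rows <- lapply(times, function(t) {
    n_small <- 0L
    n_large <- 0L
    for (tr in trs) {
      k <- which(abs(tr$t_h - t) < 1e-9)
      if (length(k) == 0L) next
      k <- k[1]
      if (!is.null(x_span) && (tr$x_um[k] < x_span[1] || tr$x_um[k] > x_span[2])) next
      lt <- if (k == 1L) 0 else sum(sqrt(diff(tr$x_um[1:k])^2 + diff(tr$y_um[1:k])^2))
      if (lt <= motile_threshold) next
      size <- tr$size[k]
      if (size < 3) next
      if (size <= 5) n_small <- n_small + 1L else n_large <- n_large + 1L
    }
    n <- n_small + n_large
    data.frame(
      t_h = t,
      fraction_small = if (n > 0L) n_small / n else NA_real_,
      n_motile = n
    )
  })
  res <- do.call(rbind, rows)
  class(res) <- c("disagg_timeline", "data.frame")
  res
}
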