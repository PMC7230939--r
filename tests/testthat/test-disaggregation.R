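fission_family <- function(child_sizes = c(5, 3), parent_size = 8, t_split = 4) {
  parent <- make_track("P", cbind(seq(150, 150 + t_split * 2, by = 2), 10),
    sizes = rep(parent_size, t_split + 1), t = 0:t_split
  )
  kids <- lapply(seq_along(child_sizes), function(i) {
    make_track(paste0("P.", i),
      cbind(seq(150 + t_split * 2, by = 2, length.out = 9 - t_split), 10 + i),
      sizes = rep(child_sizes[i], 9 - t_split), t = t_split:8, parent = "P"
    )
  })
  as_tracks(do.call(rbind, c(list(parent), kids)))
}

test_that("a constructed 8 -> (5,3) split yields one conservation-checked event", {
  tracks <- fission_family()
  ev <- detect_fission_events(tracks)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$parent_id, "P")
  expect_equal(ev$t_h, 4)
  expect_equal(ev$parent_size, 8)
  expect_equal(ev$child_sizes, "5,3")
  expect_equal(ev$x_um, 158)
})

test_that("conservation violations and missing links are handled", {
  bad <- fission_family(child_sizes = c(5, 2))
  expect_error(detect_fission_events(bad), "conservation")

  no_links <- generate_tracks(generator_config(seed = 3, n_tracks = 40))$tracks
  expect_identical(nrow(detect_fission_events(no_links)), 0L)
})

test_that("zero hazard produces zero events", {
  ex <- generate_tracks(generator_config(seed = 5, n_tracks = 60, fission_base_hazard = 0))
  expect_identical(nrow(ex$truth$events), 0L)
  expect_identical(nrow(detect_fission_events(ex$tracks)), 0L)
})

test_that("events are assigned to gradient regions by axial position", {
  regions <- partition_regions(linear_profile(), device_geometry())
  ev <- structure(
    data.frame(
      parent_id = c("a", "b", "c"), t_h = c(2, 3, 4),
      x_um = c(160, 225, 100), y_um = c(0, 0, 0),
      parent_size = c(8, 8, 8), n_children = c(2L, 2L, 2L),
      child_sizes = c("5,3", "4,4", "5,3")
    ),
    class = c("fission_events", "data.frame")
  )
  counts <- events_by_region(ev, regions)
  expect_equal(counts[["L"]], 1L)
  expect_equal(counts[["H"]], 1L)
  expect_equal(counts[["OUTSIDE"]], 1L)
  expect_equal(sum(counts), nrow(ev))
})

test_that("timeline reports all-small populations as fraction one", {
  trs <- do.call(rbind, lapply(1:6, function(i) {
    make_track(paste0("t", i), cbind(seq(160, 184, by = 3) + i, i), sizes = rep(4, 9), t = 0:8)
  }))
  tl <- timeline_fraction_small(as_tracks(trs), times = 2:8)
  expect_true(all(tl$fraction_small == 1))
  expect_true(all(tl$n_motile == 6))
})

test_that("clusters below the motility threshold are excluded", {
  creep <- make_track("c", cbind(seq(0, 0.8, by = 0.1), 0), sizes = rep(4, 9), t = 0:8)
  tl <- timeline_fraction_small(as_tracks(creep), times = c(8))
  expect_equal(tl$n_motile, 0L)
  expect_true(is.na(tl$fraction_small))
})

test_that("fraction small is non-decreasing in expectation under positive hazard", {
  curves <- sapply(1:20, function(seed) {
    cfg <- generator_config(
      seed = seed, n_tracks = 100,
      class_probs = c(SINGLE = 0, SMALL = 0.3, LARGE = 0.7),
      fission_base_hazard = 0.3
    )
    timeline_fraction_small(generate_tracks(cfg)$tracks, times = 2:8)$fraction_small
  })
  mean_curve <- rowMeans(curves)
  expect_true(all(diff(mean_curve) > -0.01))
  expect_gt(mean_curve[length(mean_curve)], mean_curve[1])
})

test_that("cell counts are conserved across whole fission chains", {
  cfg <- generator_config(
    seed = 9, n_tracks = 50,
    class_probs = c(SINGLE = 0, SMALL = 0, LARGE = 1),
    fission_base_hazard = 0.5
  )
  ex <- generate_tracks(cfg)
  tracks <- ex$tracks
  expect_gt(nrow(ex$truth$events), 0)
  first_sizes <- tapply(tracks$size, tracks$track_id, function(s) s[1])
  ids <- names(first_sizes)
  roots <- ids[!grepl(".", ids, fixed = TRUE)]
  children_of <- function(id) ids[startsWith(ids, paste0(id, ".")) &
    nchar(gsub("[^.]", "", ids)) == nchar(gsub("[^.]", "", id)) + 1]
  leaf_sum <- function(id) {
    kids <- children_of(id)
    if (length(kids) == 0) {
      return(first_sizes[[id]])
    }
    sum(vapply(kids, leaf_sum, numeric(1)))
  }
  for (r in roots) {
    expect_equal(leaf_sum(r), first_sizes[[r]])
  }
})
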