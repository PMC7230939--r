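test_that("cluster size classes partition the positive integers", {
  expect_equal(as.character(classify_cluster(c(1, 2, 3, 4, 5, 6, 40))),
    c("SINGLE", "SINGLE", "SMALL", "SMALL", "SMALL", "LARGE", "LARGE"))
  expect_error(classify_cluster(0), ">= 1")
})

test_that("whole-track class is the modal frame class with ties toward larger", {
  tr_small <- make_track("a", cbind(0:2, 0), sizes = c(8, 4, 4))
  expect_equal(as.character(track_class(tr_small)), "SMALL")
  tr_tie <- make_track("b", cbind(0:3, 0), sizes = c(8, 8, 4, 4))
  expect_equal(as.character(track_class(tr_tie)), "LARGE")
})

test_that("path length and net displacement match hand computations", {
  tr <- make_track("t", rbind(c(0, 0), c(3, 0), c(3, 4)), sizes = rep(4, 3))
  expect_equal(total_path_length(tr), 7)
  expect_equal(net_displacement(tr), 5)

  still <- make_track("s", rbind(c(1, 1), c(1, 1), c(1, 1)), sizes = rep(2, 3))
  expect_equal(total_path_length(still), 0)

  loop <- make_track("l", rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 0)), sizes = rep(4, 4))
  expect_equal(net_displacement(loop), 0)

  straight <- make_track("r", cbind(c(0, 2, 7), 0), sizes = rep(4, 3))
  expect_equal(total_path_length(straight), net_displacement(straight))

  expect_error(total_path_length(tr[1, ]), ">= 2 points")
})

test_that("directionality uses one net-displacement angle per track", {
  along_x <- lapply(1:3, function(i) {
    make_track(paste0("x", i), rbind(c(0, i), c(10, i + 0.5), c(20, i)), sizes = rep(4, 3))
  })
  expect_equal(as.numeric(directionality(along_x)), 1)

  compass <- lapply(list(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)), function(d) {
    make_track(paste(d, collapse = ","), rbind(c(0, 0), 10 * rbind(d)), sizes = c(4, 4))
  })
  expect_equal(as.numeric(directionality(compass)), 0, tolerance = 1e-12)
  # axis flip negates, rigid translation leaves DR unchanged
  expect_equal(
    as.numeric(directionality(along_x, axis = c(-1, 0))),
    -as.numeric(directionality(along_x))
  )
  shifted <- lapply(along_x, function(tr) {
    tr$x_um <- tr$x_um + 100
    tr$y_um <- tr$y_um - 50
    tr
  })
  expect_equal(
    as.numeric(directionality(shifted)),
    as.numeric(directionality(along_x))
  )
})

test_that("stationary tracks are excluded from DR and counted", {
  trs <- list(
    make_track("m", rbind(c(0, 0), c(5, 0)), sizes = c(4, 4)),
    make_track("s", rbind(c(0, 0), c(0, 0), c(0, 0)), sizes = rep(4, 3))
  )
  dr <- directionality(trs)
  expect_equal(as.numeric(dr), 1)
  expect_equal(attr(dr, "n_stationary"), 1L)
  only_still <- trs[2]
  expect_error(directionality(only_still), "no track")
})

test_that("per-class summary reports counts, percentages and SEs", {
  trs <- rbind(
    make_track("s1", rbind(c(0, 0), c(1, 0)), sizes = c(1, 1)),
    make_track("m1", rbind(c(0, 0), c(5, 0)), sizes = c(4, 4)),
    make_track("l1", rbind(c(0, 0), c(3, 0)), sizes = c(7, 7))
  )
  sm <- summarize_by_class(as_tracks(trs))
  expect_equal(sm$percent, rep(100 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(sm$percent), 100)

  # identical tracks -> zero dispersion
  same <- do.call(rbind, lapply(1:5, function(i) {
    make_track(paste0("t", i), rbind(c(0, 0), c(3, 4)), sizes = c(4, 4))
  }))
  ss <- summarize_by_class(as_tracks(same))
  expect_equal(ss$lt_se, 0)
  expect_equal(ss$dn_se, 0)
  expect_equal(ss$dr_se, 0)
  expect_equal(ss$lt_mean, 5)
})

test_that("summary is invariant under track-list permutation", {
  ex <- generate_tracks(generator_config(seed = 11, n_tracks = 60))
  sm1 <- summarize_by_class(ex$tracks)
  shuffled <- ex$tracks[sample(nrow(ex$tracks)), ]
  sm2 <- summarize_by_class(as_tracks(shuffled))
  expect_equal(sm1, sm2)
})

test_that("L_T >= D_N >= 0 and |DR| <= 1 hold across generated experiments", {
  for (seed in 1:5) {
    ex <- generate_tracks(generator_config(seed = seed, n_tracks = 80))
    trs <- split(as.data.frame(ex$tracks), ex$tracks$track_id)
    trs <- trs[vapply(trs, nrow, integer(1)) >= 2]
    lt <- vapply(trs, total_path_length, numeric(1))
    dn <- vapply(trs, net_displacement, numeric(1))
    expect_true(all(lt >= dn - 1e-12))
    expect_true(all(dn >= 0))
    expect_lte(abs(as.numeric(directionality(trs))), 1)
  }
})
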