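test_that("polar_to_rect applies the literal conversion", {
  expect_equal(polar_to_rect(c(1, 2, 3, 0, 123)), c(1, 2, 3, 0, 0))
  expect_equal(polar_to_rect(c(0, 0, 0, 100, 0)), c(0, 0, 0, 100, 0))
  p <- polar_to_rect(c(358943, 3936899, 615.4, 572, 195))
  expect_equal(p[4:5], c(-552.51, -148.04), tolerance = 1e-2)
  # compass convention measures clockwise from north
  expect_equal(polar_to_rect(c(0, 0, 0, 10, 90), "compass")[4:5], c(10, 0))
})

test_that("predict_bear adds the VHF offset to the receiver position", {
  expect_equal(predict_bear(c(5, 7, 0, 0, 33)), c(5, 7))
  expect_equal(predict_bear(c(0, 0, 0, 10, 90)), c(0, 10))
  b <- predict_bear(c(358943, 3936899, 615.4, 572, 195))
  expect_equal(b, c(358390.49, 3936750.96), tolerance = 1e-2)
  # within the printed rounding of the worked reading
  expect_lt(sqrt(sum((b - c(358391, 3936750))^2)), 1.2)
})

test_that("range codes decode per the distance-code table", {
  expect_equal(range_code_to_m(c(2, 3, 4, 5, 6)), c(1500, 1000, 750, 500, 375))
  expect_equal(range_code_to_m(5), 500)
  expect_error(range_code_to_m(7), "unknown range code")
})

test_that("the tracking sheaf has the right shape and commutes", {
  sh <- build_tracking_sheaf(printed_geocoder_fx())
  expect_length(sh$complex$faces, 9)
  fk <- tracking_faces()
  expect_equal(sh$stalks[[fk[["B"]]]]$dim, 2L)
  expect_equal(sh$stalks[[fk[["H"]]]]$dim, 3L)
  expect_equal(sh$stalks[["R"]]$dim, 5L)
  expect_equal(sh$stalks[["T"]]$kind, "text")
  samples <- list(V = list(c(35.6, -82.6, 2019)),
                  R = list(c(358943, 3936899, 615.4, 572, 195)),
                  G = list(c(358391, 3936750, 581)))
  expect_equal(nrow(verify_commutativity(sh, samples)), 0)
})

test_that("the printed worked section is consistent to within its rounding", {
  sh <- build_tracking_sheaf(printed_geocoder_fx())
  rep_ <- consistency_radius(sh, printed_assignment_fx())
  fk <- tracking_faces()
  expect_lte(rep_$spreads[[fk[["B"]]]], 0.6)
  for (lbl in c("X", "Y", "Z", "H"))
    expect_lt(rep_$spreads[[fk[[lbl]]]], 1e-6)
})

test_that("interleaving carries the last observation forward", {
  s1 <- data.frame(time = c(0, 10), payload = I(list(1, 2)))
  s2 <- data.frame(time = 5, payload = I(list(100)))
  tl <- interleave(list(A = s1, B = s2))
  expect_equal(tl$time, c(0, 5, 10))
  expect_equal(vapply(tl$values, function(v) v$A, 0), c(1, 1, 2))
  expect_null(tl$values[[1]]$B)  # before B's first reading
  expect_equal(tl$values[[2]]$B, 100)
  expect_equal(tl$values[[3]]$B, 100)
  expect_equal(unname(tl$fresh[, "A"]), c(TRUE, FALSE, TRUE))
  expect_error(interleave(list(A = data.frame(time = c(5, 1),
                                              payload = I(list(1, 2))))),
               "sorted")
})

test_that("a single stream interleaves to itself and grids resample", {
  s <- data.frame(time = c(0, 7, 13), payload = I(list(1, 2, 3)))
  tl <- interleave(list(A = s))
  expect_equal(tl$time, c(0, 7, 13))
  tg <- interleave(list(A = s), grid = 5)
  expect_equal(tg$time, c(0, 5, 10))
  expect_equal(vapply(tg$values, function(v) v$A, 0), c(1, 1, 2))
})

test_that("session streams interleave on the union of reading times", {
  sess <- simulate_session(session_params(duration_s = 1800, seed = 9))
  tl <- interleave(sess$streams)
  all_times <- sort(unique(unlist(lapply(sess$streams, `[[`, "time"))))
  expect_equal(tl$time, all_times)
  # collar values persist at most one collar period
  g_fresh <- which(tl$fresh[, "G"])
  expect_lte(max(diff(tl$time[g_fresh])), 900)
})

test_that("a noise-free stationary session is a global section everywhere", {
  p <- session_params(duration_s = 1800, collar_gps_sd = 0, receiver_gps_sd = 0,
                      vehicle_gps_sd = 0, elev_sd = 0, vhf_range_sd = 0,
                      vhf_bearing_sd = 0, human_walk_sd = 0, bear_walk_sd = 0,
                      stationary = TRUE, seed = 4)
  sess <- simulate_session(p, geocoder = exact_geocoder())
  sh <- build_tracking_sheaf(exact_geocoder())
  series <- suppressWarnings(radius_series(interleave(sess$streams), sh, "full"))
  expect_gt(nrow(series), 0)
  expect_lt(max(series$radius), 1e-6)
})

test_that("bear radius is half the collar-to-VHF-prediction distance", {
  sess <- simulate_session(session_params(duration_s = 1800, seed = 12))
  sh <- build_tracking_sheaf(grid_geocoder(100))
  tl <- interleave(sess$streams)
  series <- suppressWarnings(radius_series(tl, sh, "bear"))
  i <- nrow(series)
  t_i <- series$time[i]
  v <- tl$values[[which(tl$time == t_i)]]
  d <- sqrt(sum((predict_bear(v$R) - v$G[1:2])^2))
  expect_equal(series$radius[i], d / 2, tolerance = 1e-9)
})

test_that("the full-system radius is the max of the subsystem radii", {
  sess <- simulate_session(session_params(duration_s = 1800, seed = 13))
  sh <- build_tracking_sheaf(grid_geocoder(100))
  tl <- interleave(sess$streams)
  full <- suppressWarnings(radius_series(tl, sh, "full"))
  human <- suppressWarnings(radius_series(tl, sh, "human"))
  bear <- suppressWarnings(radius_series(tl, sh, "bear"))
  common <- Reduce(intersect, list(full$time, human$time, bear$time))
  expect_gt(length(common), 0)
  fi <- match(common, full$time); hi <- match(common, human$time)
  bi <- match(common, bear$time)
  expect_equal(full$radius[fi], pmax(human$radius[hi], bear$radius[bi]))
})

test_that("timestamps missing a sensor are skipped with a warning", {
  sess <- simulate_session(session_params(duration_s = 1800, seed = 14))
  streams <- sess$streams
  streams$G <- streams$G[streams$G$time > 900, , drop = FALSE]
  sh <- build_tracking_sheaf(grid_geocoder(100))
  expect_warning(series <- radius_series(interleave(streams), sh, "full"),
                 "skipped")
  expect_true(all(series$time >= min(streams$G$time)))
})

test_that("scaling the VHF range error scales the median bear radius", {
  base <- session_params(duration_s = 7200, vhf_bearing_sd = 0,
                         vhf_range_sd = 100, collar_gps_sd = 0,
                         receiver_gps_sd = 0, human_walk_sd = 0,
                         bear_walk_sd = 0, stationary = TRUE, seed = 21)
  doubled <- base; doubled$vhf_range_sd <- 200
  sh <- build_tracking_sheaf(grid_geocoder(100))
  med <- function(p) {
    tl <- interleave(simulate_session(p, exact_geocoder())$streams)
    stats::median(suppressWarnings(radius_series(tl, sh, "bear"))$radius)
  }
  m1 <- med(base); m2 <- med(doubled)
  expect_equal(m2 / m1, 2, tolerance = 1e-6)  # same seed, scaled noise
})
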