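test_that("observation matrices subset the fixed five-row pattern", {
  full <- observation_matrix(c("vehicle_gps", "vhf_gps", "street_sign",
                               "bear_gps", "vhf"))
  expect_equal(unname(full$schematic),
               rbind(c(0, 1), c(0, 1), c(0, 1), c(1, 0), c(-1, 1)))
  vhf <- observation_matrix("vhf")
  expect_equal(unname(vhf$schematic), rbind(c(-1, 1)))
  two <- observation_matrix(c("bear_gps", "vehicle_gps"))
  expect_equal(rownames(two$schematic), c("vehicle_gps", "bear_gps"))
  expect_equal(unname(two$schematic), rbind(c(0, 1), c(1, 0)))
  # planar expansion doubles every row and column
  expect_equal(dim(full$H), c(10, 4))
  expect_equal(unname(full$H[9:10, ]),
               rbind(c(-1, 0, 1, 0), c(0, -1, 0, 1)))
  expect_error(observation_matrix(character(0)), "nonempty")
  expect_error(observation_matrix("sonar"), "unknown")
})

test_that("the full observation pattern matches the sheaf incidence up to sign", {
  sh <- build_tracking_sheaf(grid_geocoder(100))
  incidence <- sheaf_incidence_pattern(sh)
  full <- observation_matrix(c("vehicle_gps", "vhf_gps", "street_sign",
                               "bear_gps", "vhf"))$schematic
  expect_equal(unname(full), unname(incidence))
  expect_equal(rownames(full), rownames(incidence))
})

test_that("a forecast-only step leaves the mean and grows the covariance", {
  spec <- dlm_spec(c(bear_state = 1, human_state = 2, bear_gps = 5,
                     vhf_gps = 5, vehicle_gps = 5, street_sign = 5, vhf = 5))
  s0 <- kf_init(c(0, 0, 10, 10), var = 4, time = 0)
  stp <- kf_step(s0, 10, NULL, NULL, spec)
  expect_equal(stp$state$mean, c(0, 0, 10, 10))
  expect_equal(diag(stp$state$cov), c(4 + 10, 4 + 10, 4 + 40, 4 + 40))
  expect_equal(stp$logdens, 0)
})

test_that("a single-sensor update matches the scalar Bayesian closed form", {
  spec <- dlm_spec(c(bear_state = 1, human_state = 1, bear_gps = 3,
                     vhf_gps = 1, vehicle_gps = 1, street_sign = 1, vhf = 1))
  s0 <- kf_init(c(2, 2, 0, 0), var = 7, time = 0)
  y <- c(bear_gps.E = 10, bear_gps.N = -4)
  stp <- kf_step(s0, 5, observation_matrix("bear_gps"), y, spec)
  R <- 7 + 1 * 5              # prior var + process var
  post <- function(prior, obs) (9 * prior + R * obs) / (R + 9)
  expect_equal(stp$state$mean[1], post(2, 10))
  expect_equal(stp$state$mean[2], post(2, -4))
  expect_equal(stp$state$mean[3:4], c(0, 0))  # human unobserved
  expect_equal(diag(stp$state$cov)[1], R * 9 / (R + 9))
})

test_that("a near-noiseless sensor pins the observed coordinates", {
  spec <- dlm_spec(c(bear_state = 1, human_state = 1, bear_gps = 1e-6,
                     vhf_gps = 1, vehicle_gps = 1, street_sign = 1, vhf = 1))
  s0 <- kf_init(c(0, 0, 0, 0), var = 100, time = 0)
  stp <- kf_step(s0, 1, observation_matrix("bear_gps"),
                 c(bear_gps.E = 55, bear_gps.N = -7), spec)
  expect_equal(stp$state$mean[1:2], c(55, -7), tolerance = 1e-6)
})

test_that("the filter tracks noise-free synthetic data with tiny sigma", {
  truth <- dlm_spec(c(bear_state = 0, human_state = 0, bear_gps = 0,
                      vhf_gps = 0, vehicle_gps = 0, street_sign = 0, vhf = 0))
  sched <- data.frame(time = rep(seq(0, 600, 60), each = 2),
                      sensor = c("bear_gps", "vehicle_gps"))
  set.seed(2)
  sim <- simulate_dlm(truth, sched, start = c(100, 200, 300, 400))
  run_spec <- dlm_spec(c(bear_state = 0.1, human_state = 0.1, bear_gps = 1e-3,
                         vhf_gps = 1e-3, vehicle_gps = 1e-3, street_sign = 1e-3,
                         vhf = 1e-3))
  out <- kf_filter(sim$events, run_spec)
  last <- nrow(out$estimates)
  expect_lt(abs(out$estimates$bearE[last] - 100), 1e-3)
  expect_lt(abs(out$estimates$humanN[last] - 400), 1e-3)
})

test_that("uncertainty bands contract when the bear collar reports", {
  spec <- dlm_spec(c(bear_state = 0.5, human_state = 3, bear_gps = 15,
                     vhf_gps = 8, vehicle_gps = 12, street_sign = 28, vhf = 150))
  set.seed(8)
  sim <- simulate_dlm(spec, dlm_schedule_fx(), start = c(0, 0, 900, 600))
  out <- kf_filter(sim$events, spec)
  est <- out$estimates
  collar_times <- vapply(sim$events, function(ev)
    if ("bear_gps" %in% ev$sensors) ev$time else NA_real_, 0)
  collar_idx <- which(est$time %in% collar_times[!is.na(collar_times)])
  collar_idx <- collar_idx[collar_idx > 1]
  expect_true(all(est$band.bear[collar_idx] < est$band.bear[collar_idx - 1]))
})

test_that("covariances stay symmetric positive semidefinite while filtering", {
  spec <- dlm_spec(c(bear_state = 0.5, human_state = 3, bear_gps = 15,
                     vhf_gps = 8, vehicle_gps = 12, street_sign = 28, vhf = 150))
  set.seed(9)
  sim <- simulate_dlm(spec, dlm_schedule_fx(), start = c(0, 0, 900, 600))
  state <- kf_init(c(0, 0, 900, 600), var = 1e6,
                   time = sim$events[[1]]$time)
  for (ev in sim$events) {
    stp <- kf_step(state, ev$time, observation_matrix(ev$sensors),
                   ev$y[rownames(observation_matrix(ev$sensors)$H)], spec)
    state <- stp$state
    expect_equal(state$cov, t(state$cov))
    expect_gte(min(eigen(state$cov, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-9)
  }
})

test_that("the recursive likelihood equals the joint Gaussian closed form", {
  spec <- dlm_spec(c(bear_state = 0.7, human_state = 2, bear_gps = 10,
                     vhf_gps = 4, vehicle_gps = 6, street_sign = 20, vhf = 80))
  sched <- data.frame(
    time = c(0, 30, 60, 90, 120, 150, 180, 210, 240, 270,
             300, 330, 360, 390, 420, 450, 480, 510, 540, 570),
    sensor = rep(c("vehicle_gps", "bear_gps", "vhf", "vhf_gps", "street_sign"), 4))
  set.seed(10)
  sim <- simulate_dlm(spec, sched, start = c(50, -20, 0, 30))
  prior <- kf_init(c(50, -20, 0, 30), var = 1e4, time = 0)
  kf_ll <- kf_filter(sim$events, spec, prior = prior)$loglik
  joint_ll <- joint_loglik_fx(sim$events, spec,
                              prior_mean = c(50, -20, 0, 30),
                              prior_var = 1e4, t0 = 0)
  expect_equal(kf_ll, joint_ll, tolerance = 1e-6)
})

test_that("pooled likelihood is invariant to session order", {
  spec <- dlm_spec(c(bear_state = 0.5, human_state = 2, bear_gps = 10,
                     vhf_gps = 4, vehicle_gps = 6, street_sign = 20, vhf = 80))
  set.seed(11)
  sessions <- lapply(1:3, function(i)
    simulate_dlm(spec, dlm_schedule_fx(), start = c(0, 0, 900, 600))$events)
  ll <- function(sess) sum(vapply(sess, function(s)
    kf_filter(s, spec)$loglik, 0))
  expect_equal(ll(sessions), ll(rev(sessions)))
})

test_that("average log-likelihood peaks at the generating parameters", {
  truth <- dlm_spec(c(bear_state = 0.5, human_state = 2, bear_gps = 10,
                      vhf_gps = 4, vehicle_gps = 6, street_sign = 20, vhf = 80))
  perturbed <- dlm_spec(truth$sigma * 2.5)
  set.seed(12)
  diffs <- vapply(1:5, function(i) {
    sim <- simulate_dlm(truth, dlm_schedule_fx(), start = c(0, 0, 900, 600))
    kf_filter(sim$events, truth)$loglik -
      kf_filter(sim$events, perturbed)$loglik
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("the stationary-collar constraint pins the bear-state SD at zero", {
  truth <- dlm_spec(c(bear_state = 0, human_state = 2, bear_gps = 10,
                      vhf_gps = 4, vehicle_gps = 6, street_sign = 20, vhf = 80))
  sched <- data.frame(time = rep(seq(0, 1200, 120), each = 2),
                      sensor = c("bear_gps", "vehicle_gps"))
  set.seed(13)
  sess <- simulate_dlm(truth, sched, start = c(0, 0, 500, 500))$events
  fit <- mle_variances(sess, fix_bear_state = TRUE,
                       control = list(maxit = 400, reltol = 1e-5),
                       restarts = 0)
  expect_identical(unname(fit$sigma["bear_state"]), 0)
  expect_true(all(fit$sigma[c("bear_gps", "vehicle_gps")] > 0))
})
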