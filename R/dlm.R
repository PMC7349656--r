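#' Comparison dynamic linear model
#'
#' A random-walk state-space model over the four planar state variables
#' (bear easting/northing, human easting/northing).  Five observation
#' forms — vehicle ("truck") GPS, the receiver's own GPS ("vhf_gps"), the
#' street-sign/text position, the bear-collar GPS, and the VHF relative
#' reading (human minus bear) — are stacked into a time-varying observation
#' matrix, subsetted to whichever sensors actually report at each instant.
#' A Kalman filter provides location estimates with uncertainty bands and
#' the prediction-error decomposition of the likelihood, which a numerical
#' optimizer maximizes over the seven standard deviations, optionally
#' pooled across sessions.
#'
#' @name dlm_kalman
NULL

dlm_sensors <- c("vehicle_gps", "vhf_gps", "street_sign", "bear_gps", "vhf")
dlm_sigma_names <- c("bear_state", "human_state",
                     "bear_gps", "vhf_gps", "vehicle_gps", "street_sign", "vhf")

#' Specify the DLM's variance parameters
#'
#' @param sigma named numeric of seven nonnegative standard deviations in
#'   meters: `bear_state` and `human_state` (random-walk impetus per
#'   square-root second: process variance grows as `sigma^2 * dt`) and the
#'   five observation errors `bear_gps`, `vhf_gps`, `vehicle_gps`,
#'   `street_sign`, `vhf`
#' @return a `dlm_spec`
#' @export
dlm_spec <- function(sigma) {
  stopifnot(is.numeric(sigma))
  missing <- setdiff(dlm_sigma_names, names(sigma))
  if (length(missing)) stop("missing sigma: ", paste(missing, collapse = ","))
  if (any(sigma < 0)) stop("standard deviations must be >= 0")
  structure(list(sigma = sigma[dlm_sigma_names]), class = "dlm_spec")
}

schematic_rows <- function() {
  # 1-D pattern over state (bear, human); VHF row is human - bear
  rbind(vehicle_gps = c(0, 1),
        vhf_gps     = c(0, 1),
        street_sign = c(0, 1),
        bear_gps    = c(1, 0),
        vhf         = c(-1, 1))
}

#' Observation matrix for a set of available sensors
#'
#' Rows appear in the fixed order vehicle GPS, VHF-unit GPS, street sign,
#' bear GPS, VHF, restricted to the available subset.  The 1-D schematic
#' (state = (bear, human)) is returned alongside the planar matrix actually
#' used by the filter, in which every schematic row is expanded to an
#' easting row and a northing row (Kronecker product with the 2x2 identity;
#' state = (bearE, bearN, humanE, humanN)).
#'
#' @param available character vector, subset of
#'   `c("vehicle_gps", "vhf_gps", "street_sign", "bear_gps", "vhf")`
#' @return an `observation_block`: list with `sensors`, `schematic`, `H`
#' @export
observation_matrix <- function(available) {
  if (length(available) == 0L) stop("'available' must be a nonempty sensor subset")
  bad <- setdiff(available, dlm_sensors)
  if (length(bad)) stop("unknown sensors: ", paste(bad, collapse = ","))
  sel <- dlm_sensors[dlm_sensors %in% available]
  schem <- schematic_rows()[sel, , drop = FALSE]
  H <- kronecker(schem, diag(2))
  rownames(H) <- paste(rep(sel, each = 2), c("E", "N"), sep = ".")
  colnames(H) <- c("bearE", "bearN", "humanE", "humanN")
  structure(list(sensors = sel, schematic = schem, H = H),
            class = "observation_block")
}

obs_cov <- function(block, spec) {
  diag(rep(spec$sigma[block$sensors]^2, each = 2),
       nrow = 2 * length(block$sensors))
}

process_cov <- function(spec, dt) {
  diag(rep(spec$sigma[c("bear_state", "human_state")]^2 * dt, each = 2))
}

#' Initialize the filter state
#'
#' @param mean numeric length-4 `(bearE, bearN, humanE, humanN)`
#' @param var diffuse prior variance (m^2) on each coordinate, or a full
#'   4x4 covariance
#' @param time prior timestamp (seconds)
#' @return a `kf_state`
#' @export
kf_init <- function(mean, var = 1e6, time = 0) {
  cov <- if (is.matrix(var)) var else diag(var, 4)
  structure(list(mean = as.numeric(mean), cov = cov, time = time),
            class = "kf_state")
}

#' One Kalman forecast/update step
#'
#' Forecast: the state transition is the identity, so the mean carries over
#' and the covariance grows by the process covariance `W = diag(sigma_state^2
#' * dt)`.  Update (when an observation is present): innovation
#' `e = y - H theta`, gain `K = R H' (V + H R H')^{-1}`, mean `+= K e`,
#' covariance `R - K H R` (symmetrized).  With no observation only the
#' forecast is applied.
#'
#' @param state a `kf_state`
#' @param t observation time (seconds, > `state$time` unless equal-time
#'   observations are stacked)
#' @param block an `observation_block`, or `NULL` for forecast-only
#' @param y numeric observation vector matching `block$H`'s rows
#' @param spec a `dlm_spec`
#' @return list with `state` (updated `kf_state`), `e` (prediction error,
#'   `NULL` if no observation) and `logdens` (step log-density, 0 if none)
#' @export
kf_step <- function(state, t, block, y, spec) {
  dt <- t - state$time
  if (dt < 0) stop("observations must be processed in time order")
  R <- state$cov + process_cov(spec, dt)
  mean <- state$mean
  if (is.null(block)) {
    return(list(state = kf_init(mean, R, t), e = NULL, logdens = 0))
  }
  H <- block$H
  if (length(y) != nrow(H)) stop("y has length ", length(y),
                                 " but H has ", nrow(H), " rows")
  V <- obs_cov(block, spec)
  S <- V + H %*% R %*% t(H)
  S <- (S + t(S)) / 2
  e <- as.numeric(y - H %*% mean)
  ch <- tryCatch(chol(S), error = function(err)
    stop("singular innovation covariance; give every available sensor a ",
         "positive observation SD"))
  Sinv_e <- backsolve(ch, forwardsolve(t(ch), e))
  K <- R %*% t(H) %*% chol2inv(ch)
  mean <- mean + as.numeric(K %*% e)
  cov <- R - K %*% H %*% R
  cov <- (cov + t(cov)) / 2
  logdens <- -0.5 * (length(e) * log(2 * pi) +
                       2 * sum(log(diag(ch))) + sum(e * Sinv_e))
  list(state = kf_init(mean, cov, t), e = e, logdens = logdens)
}

default_prior <- function(events) {
  bear <- NULL; human <- NULL
  for (ev in events) {
    if (is.null(bear) && "bear_gps" %in% ev$sensors)
      bear <- ev$y[paste0("bear_gps.", c("E", "N"))]
    hs <- intersect(c("vehicle_gps", "vhf_gps", "street_sign"), ev$sensors)
    if (is.null(human) && length(hs))
      human <- ev$y[paste0(hs[1], ".", c("E", "N"))]
    if (!is.null(bear) && !is.null(human)) break
  }
  if (is.null(bear)) bear <- c(0, 0)
  if (is.null(human)) human <- c(0, 0)
  kf_init(c(bear, human), var = 1e6,
          time = min(vapply(events, `[[`, 0, "time")))
}

#' Run the Kalman filter over an observation sequence
#'
#' @param events list of observation events, each a list with `time`
#'   (seconds), `sensors` (character subset of the five forms) and `y`
#'   (named numeric: `<sensor>.E`, `<sensor>.N` per available sensor)
#' @param spec a `dlm_spec`
#' @param prior a `kf_state`, or `NULL` to start from the first available
#'   position readings with a diffuse (1e6 m^2) covariance
#' @return a `kf_output`: list with `estimates` (data.frame of per-event
#'   state means, SDs and 2-SD band half-widths), `loglik` (sum of step
#'   log-densities) and `errors` (list of per-step prediction errors)
#' @export
kf_filter <- function(events, spec, prior = NULL) {
  stopifnot(length(events) > 0)
  times <- vapply(events, `[[`, 0, "time")
  if (is.unsorted(times)) stop("events must be time-sorted")
  state <- if (is.null(prior)) default_prior(events) else prior
  n <- length(events)
  est <- matrix(NA_real_, n, 8,
                dimnames = list(NULL, c("bearE", "bearN", "humanE", "humanN",
                                        "sd.bearE", "sd.bearN",
                                        "sd.humanE", "sd.humanN")))
  loglik <- 0
  errors <- vector("list", n)
  block_cache <- new.env(parent = emptyenv())
  get_block <- function(sensors) {
    key <- paste(sensors, collapse = ",")
    if (!exists(key, envir = block_cache))
      assign(key, observation_matrix(sensors), envir = block_cache)
    get(key, envir = block_cache)
  }
  for (i in seq_len(n)) {
    ev <- events[[i]]
    block <- if (length(ev$sensors)) get_block(ev$sensors) else NULL
    y <- if (is.null(block)) NULL else {
      want <- rownames(block$H)
      yy <- ev$y[want]
      if (anyNA(yy)) stop("event at t=", ev$time, " missing components: ",
                          paste(want[is.na(yy)], collapse = ","))
      as.numeric(yy)
    }
    stp <- kf_step(state, ev$time, block, y, spec)
    state <- stp$state
    loglik <- loglik + stp$logdens
    errors[[i]] <- stp$e
    est[i, 1:4] <- state$mean
    est[i, 5:8] <- sqrt(pmax(diag(state$cov), 0))
  }
  estimates <- data.frame(time = times, est)
  estimates$band.bear <- 2 * sqrt(estimates$sd.bearE^2 + estimates$sd.bearN^2)
  estimates$band.human <- 2 * sqrt(estimates$sd.humanE^2 + estimates$sd.humanN^2)
  structure(list(estimates = estimates, loglik = loglik, errors = errors,
                 final = state),
            class = "kf_output")
}

#' Simulate observation events directly from the DLM
#'
#' Draws the bear and human tracks as Gaussian random walks with variance
#' proportional to elapsed time, then generates the scheduled observations
#' with their sensor noise.  Used for parameter-recovery experiments.
#'
#' @param spec a `dlm_spec` (the truth)
#' @param schedule data.frame with columns `time` and `sensor`; several rows
#'   may share a time
#' @param start numeric length-4 initial state
#' @return list with `events` (as consumed by [kf_filter()]) and `truth`
#'   (data.frame of states at every scheduled time)
#' @export
simulate_dlm <- function(spec, schedule, start = c(0, 0, 0, 0)) {
  stopifnot(all(c("time", "sensor") %in% names(schedule)))
  schedule <- schedule[order(schedule$time), , drop = FALSE]
  tt <- sort(unique(schedule$time))
  theta <- matrix(NA_real_, length(tt), 4)
  cur <- start
  prev_t <- tt[1]
  for (i in seq_along(tt)) {
    dt <- tt[i] - prev_t
    if (dt > 0)
      cur <- cur + stats::rnorm(4, 0,
        rep(spec$sigma[c("bear_state", "human_state")], each = 2) * sqrt(dt))
    theta[i, ] <- cur
    prev_t <- tt[i]
  }
  events <- vector("list", length(tt))
  for (i in seq_along(tt)) {
    sensors <- dlm_sensors[dlm_sensors %in% schedule$sensor[schedule$time == tt[i]]]
    th <- theta[i, ]
    y <- numeric(0)
    for (s in sensors) {
      base <- switch(s,
                     vehicle_gps = th[3:4], vhf_gps = th[3:4],
                     street_sign = th[3:4], bear_gps = th[1:2],
                     vhf = th[3:4] - th[1:2])
      obs <- base + stats::rnorm(2, 0, spec$sigma[s])
      names(obs) <- paste0(s, ".", c("E", "N"))
      y <- c(y, obs)
    }
    events[[i]] <- list(time = tt[i], sensors = sensors, y = y)
  }
  truth <- data.frame(time = tt, bearE = theta[, 1], bearN = theta[, 2],
                      humanE = theta[, 3], humanN = theta[, 4])
  list(events = events, truth = truth)
}

# Precompute per-event matrices and per-session priors so repeated
# likelihood evaluations inside the optimizer skip all name matching.
prep_session <- function(events) {
  block_cache <- new.env(parent = emptyenv())
  prepped <- lapply(events, function(ev) {
    key <- paste(ev$sensors, collapse = ",")
    if (!exists(key, envir = block_cache))
      assign(key, observation_matrix(ev$sensors), envir = block_cache)
    block <- get(key, envir = block_cache)
    y <- ev$y[rownames(block$H)]
    if (anyNA(y)) stop("event at t=", ev$time, " missing observation components")
    list(time = ev$time, H = block$H, sensors = block$sensors,
         y = as.numeric(y), k = length(y))
  })
  prior <- default_prior(events)
  list(events = prepped, prior_mean = prior$mean, t0 = prior$time)
}

kf_loglik_prepped <- function(prep, spec, prior_var = 1e6) {
  sig <- spec$sigma
  wdiag <- rep(sig[c("bear_state", "human_state")]^2, each = 2)
  mean <- prep$prior_mean
  cov <- diag(prior_var, 4)
  prev_t <- prep$t0
  ll <- 0
  for (ev in prep$events) {
    dt <- ev$time - prev_t
    prev_t <- ev$time
    diag(cov) <- diag(cov) + wdiag * dt
    H <- ev$H
    HR <- H %*% cov
    S <- HR %*% t(H)
    diag(S) <- diag(S) + rep(sig[ev$sensors]^2, each = 2)
    ch <- chol(S)
    e <- ev$y - as.numeric(H %*% mean)
    Sinv_e <- backsolve(ch, forwardsolve(t(ch), e))
    K <- t(HR) %*% chol2inv(ch)
    mean <- mean + as.numeric(K %*% e)
    cov <- cov - K %*% HR
    cov <- (cov + t(cov)) / 2
    ll <- ll - 0.5 * (ev$k * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(e * Sinv_e))
  }
  ll
}

#' Maximum-likelihood estimation of the DLM's standard deviations
#'
#' Maximizes the (optionally pooled) prediction-error log-likelihood over
#' the logarithms of the standard deviations with Nelder-Mead.  Sessions
#' are filtered independently and their log-likelihoods summed; the
#' stationary-collar constraint pins the bear-state SD to zero (the collar
#' did not move), removing it from the optimization.
#'
#' @param sessions a single event list or a list of event lists
#' @param init named numeric of starting standard deviations (defaults to
#'   10 m for every component)
#' @param fix_bear_state logical: pin `bear_state` to 0
#' @param control passed to [stats::optim()] (Nelder-Mead); `maxit`
#'   defaults to 2000
#' @param restarts number of times the optimizer is restarted from its last
#'   optimum (a fresh simplex often escapes premature collapse); restarting
#'   stops early once an extra run improves the log-likelihood by < 0.01
#' @return list with `sigma` (estimated SDs, meters), `loglik`,
#'   `convergence` (0 = converged) and `optim` (the raw optimizer result)
#' @export
mle_variances <- function(sessions, init = NULL, fix_bear_state = FALSE,
                          control = list(), restarts = 2) {
  if (!is.null(sessions[[1]]$time)) sessions <- list(sessions)
  if (is.null(init)) init <- stats::setNames(rep(10, 7), dlm_sigma_names)
  init <- init[dlm_sigma_names]
  free <- if (fix_bear_state) setdiff(dlm_sigma_names, "bear_state") else dlm_sigma_names
  make_spec <- function(logs) {
    sig <- stats::setNames(numeric(7), dlm_sigma_names)
    sig[free] <- exp(logs)
    dlm_spec(sig)
  }
  preps <- lapply(sessions, prep_session)
  negll <- function(logs) {
    spec <- make_spec(logs)
    tot <- 0
    for (prep in preps) {
      ll <- tryCatch(kf_loglik_prepped(prep, spec), error = function(e) -Inf)
      if (!is.finite(ll)) return(1e12)
      tot <- tot + ll
    }
    -tot
  }
  if (is.null(control$maxit)) control$maxit <- 2000
  opt <- stats::optim(log(init[free]), negll, method = "Nelder-Mead",
                      control = control)
  for (r in seq_len(restarts)) {
    opt2 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = control)
    improved <- opt$value - opt2$value
    if (opt2$value < opt$value) opt <- opt2
    if (improved < 0.01) break
  }
  sigma <- stats::setNames(numeric(7), dlm_sigma_names)
  sigma[free] <- exp(opt$par)
  if (opt$convergence != 0)
    warning("optimizer did not report convergence (code ", opt$convergence,
            "); returning best iterate")
  list(sigma = sigma, loglik = -opt$value, convergence = opt$convergence,
       optim = opt)
}

#' Structural correspondence between the DLM and the tracking sheaf
#'
#' The full observation-row pattern must equal the sensor-target incidence
#' of the tracking complex up to sign: each human-position sensor
#' contributes a (0, 1) row, the collar GPS a (1, 0) row, and the VHF
#' reading the signed difference row (-1, +1).  Returns the incidence
#' pattern derived from the complex for comparison with
#' `observation_matrix(dlm_sensors)$schematic`.
#'
#' @param sh the tracking `sheaf` (only its complex is used)
#' @return numeric matrix with the same row names as the full schematic
#' @export
sheaf_incidence_pattern <- function(sh) {
  fk <- tracking_faces()
  H_face <- sh$complex$faces[[fk[["H"]]]]
  B_face <- sh$complex$faces[[fk[["B"]]]]
  vertex_for <- c(vehicle_gps = "V", vhf_gps = "R", street_sign = "T",
                  bear_gps = "G", vhf = "R")
  rows <- t(vapply(dlm_sensors, function(s) {
    v <- vertex_for[[s]]
    if (s == "vhf") {
      # the VHF reading relates both targets: human minus bear
      stopifnot(v %in% B_face, v %in% H_face)
      c(-1, 1)
    } else if (s == "bear_gps") {
      stopifnot(v %in% B_face)
      c(1, 0)
    } else {
      stopifnot(v %in% H_face)
      c(0, 1)
    }
  }, numeric(2)))
  colnames(rows) <- c("bear", "human")
  rows
}
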