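#' Synthetic tracking sessions
#'
#' Generates two-hour urban tracking sessions with the study's structure:
#' 16 receiver stops spaced 5-7 min apart, collar GPS fixes every 15 min,
#' a vehicle GPS log every ~10 s, and a free-text report at every stop.
#' Bear and human move as planar Gaussian random walks with per-step
#' variance proportional to elapsed time (the bear frozen for stationary
#' "dummy" collars); the human can optionally drift toward the bear, the
#' mechanism behind the decreasing-radius trend when VHF error grows with
#' range.  VHF error is applied in polar coordinates (range and bearing
#' separately) because that is the physical measurement.
#'
#' @name synthetic_data
NULL

#' Session parameters
#'
#' @param duration_s session length (default 7200 s)
#' @param n_stops number of receiver stops (default 16)
#' @param stop_spacing_s range of stop spacings, seconds (default 300-420)
#' @param collar_period_s collar GPS period (default 900 s)
#' @param vehicle_period_s vehicle GPS period (default 10 s)
#' @param collar_gps_sd,receiver_gps_sd,vehicle_gps_sd horizontal GPS noise
#'   SDs, meters (defaults 15, 5, 5: typical wildlife-collar vs handheld
#'   receiver accuracy)
#' @param elev_sd elevation noise SD, meters (default 5)
#' @param vhf_range_sd VHF range error SD, meters (default 100)
#' @param vhf_bearing_sd VHF bearing error SD, degrees (default 5)
#' @param range_proportional logical: scale both VHF error SDs by
#'   range / 1000 m, so readings degrade with distance (default FALSE)
#' @param human_walk_sd,bear_walk_sd random-walk impetus SDs, m per sqrt
#'   second (defaults 3 and 0.3: a searching vehicle covers far more ground
#'   than a resting bear)
#' @param approach_speed m/s drift of the human toward the bear (default 0)
#' @param start_human,start_bear initial UTM positions (meters); defaults
#'   place them ~900 m apart in zone 17
#' @param elev_m terrain elevation (default 600 m)
#' @param stationary logical: dummy collar, bear frozen (default FALSE)
#' @param quantize_range logical: log VHF range as the nearest distance
#'   code instead of meters (default FALSE)
#' @param zone,hemisphere UTM zone of the study area
#' @param seed integer RNG seed
#' @return a `session_params` list
#' @export
session_params <- function(duration_s = 7200, n_stops = 16,
                           stop_spacing_s = c(300, 420),
                           collar_period_s = 900, vehicle_period_s = 10,
                           collar_gps_sd = 15, receiver_gps_sd = 5,
                           vehicle_gps_sd = 5, elev_sd = 5,
                           vhf_range_sd = 100, vhf_bearing_sd = 5,
                           range_proportional = FALSE,
                           human_walk_sd = 3, bear_walk_sd = 0.3,
                           approach_speed = 0,
                           start_human = c(358000, 3936000),
                           start_bear = c(358700, 3936600),
                           elev_m = 600,
                           stationary = FALSE, quantize_range = FALSE,
                           zone = 17, hemisphere = "north", seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$duration_s > 0, p$collar_period_s > 0, p$vehicle_period_s > 0,
            all(p$stop_spacing_s > 0))
  sds <- c(p$collar_gps_sd, p$receiver_gps_sd, p$vehicle_gps_sd, p$elev_sd,
           p$vhf_range_sd, p$vhf_bearing_sd, p$human_walk_sd, p$bear_walk_sd)
  stopifnot(all(sds >= 0))
  structure(p, class = "session_params")
}

walk_track <- function(times, start, sd, drift_target = NULL, speed = 0) {
  n <- length(times)
  pos <- matrix(NA_real_, n, 2)
  cur <- start
  for (i in seq_len(n)) {
    if (i > 1L) {
      dt <- times[i] - times[i - 1L]
      step <- stats::rnorm(2, 0, sd * sqrt(dt))
      if (!is.null(drift_target) && speed > 0) {
        d <- drift_target(times[i - 1L]) - cur
        dist <- sqrt(sum(d^2))
        if (dist > 1e-9) step <- step + d / dist * min(speed * dt, dist)
      }
      cur <- cur + step
    }
    pos[i, ] <- cur
  }
  pos
}

nearest_range_code <- function(range_m) {
  codes <- c(2, 3, 4, 5, 6)
  meters <- c(1500, 1000, 750, 500, 375)
  codes[which.min(abs(meters - range_m))]
}

#' Simulate a tracking session
#'
#' Returns the three sensor stream data.frames in the dialects the CSV
#' readers consume (vehicle: `time, lat, lon, altitude_ft`; collar:
#' `time, utm_e, utm_n, elev_m, hdop, fix_type`; receiver: `time, utm_e,
#' utm_n, elev_m, bearing_deg, range_m` or `range_code`, `text`), plus the
#' noise-free ground-truth tracks for recovery tests.  Bearings are logged
#' in the mathematical convention (degrees from the easting axis).  The RNG
#' state is restored on exit; identical parameters give identical output.
#'
#' @param params a `session_params`
#' @param geocoder geocoder used to produce the text reports (default
#'   `grid_geocoder(100)`); its `address` function must be non-NULL
#' @return list with `vehicle`, `collar`, `receiver` data.frames, `streams`
#'   (the named V/R/T/G list ready for [interleave()]) and `truth`
#' @export
simulate_session <- function(params = session_params(),
                             geocoder = grid_geocoder(100)) {
  stopifnot(inherits(params, "session_params"))
  if (is.null(geocoder$address))
    stop("geocoder must provide an address() function for simulation")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  # schedules
  gaps <- stats::runif(params$n_stops - 1L,
                       params$stop_spacing_s[1], params$stop_spacing_s[2])
  stop_times <- round(cumsum(c(60, gaps)))
  stop_times <- stop_times[stop_times <= params$duration_s]
  vehicle_times <- seq(0, params$duration_s, by = params$vehicle_period_s)
  collar_times <- seq(0, params$duration_s, by = params$collar_period_s)
  all_times <- sort(unique(c(vehicle_times, collar_times, stop_times)))

  bear_sd <- if (params$stationary) 0 else params$bear_walk_sd
  bear_pos <- walk_track(all_times, params$start_bear, bear_sd)
  bear_at <- function(t) bear_pos[findInterval(t, all_times), ]
  human_pos <- walk_track(all_times, params$start_human, params$human_walk_sd,
                          drift_target = bear_at, speed = params$approach_speed)
  idx <- function(t) match(t, all_times)

  # collar stream: bear + GPS noise
  gi <- idx(collar_times)
  collar <- data.frame(
    time = collar_times,
    utm_e = bear_pos[gi, 1] + stats::rnorm(length(gi), 0, params$collar_gps_sd),
    utm_n = bear_pos[gi, 2] + stats::rnorm(length(gi), 0, params$collar_gps_sd),
    elev_m = params$elev_m + stats::rnorm(length(gi), 0, params$elev_sd),
    hdop = round(stats::runif(length(gi), 0.8, 2.5), 1),
    fix_type = "3D")

  # vehicle stream: human + GPS noise, re-expressed as lat/long/ft
  vi <- idx(vehicle_times)
  ve <- human_pos[vi, 1] + stats::rnorm(length(vi), 0, params$vehicle_gps_sd)
  vn <- human_pos[vi, 2] + stats::rnorm(length(vi), 0, params$vehicle_gps_sd)
  vz <- params$elev_m + stats::rnorm(length(vi), 0, params$elev_sd)
  ll <- t(vapply(seq_along(vi), function(i)
    utm_to_latlon(ve[i], vn[i], params$zone, params$hemisphere), numeric(2)))
  vehicle <- data.frame(time = vehicle_times, lat = ll[, 1], lon = ll[, 2],
                        altitude_ft = vz / 0.3048)

  # receiver stream: human + GPS noise, plus VHF polar reading to the bear
  si <- idx(stop_times)
  re <- human_pos[si, 1] + stats::rnorm(length(si), 0, params$receiver_gps_sd)
  rn <- human_pos[si, 2] + stats::rnorm(length(si), 0, params$receiver_gps_sd)
  rz <- params$elev_m + stats::rnorm(length(si), 0, params$elev_sd)
  d <- bear_pos[si, , drop = FALSE] - human_pos[si, , drop = FALSE]
  true_range <- sqrt(rowSums(d^2))
  true_bearing <- (atan2(d[, 2], d[, 1]) * 180 / pi) %% 360
  scale <- if (params$range_proportional) true_range / 1000 else rep(1, length(si))
  range_obs <- pmax(true_range + stats::rnorm(length(si), 0,
                                              params$vhf_range_sd * scale), 0)
  bearing_obs <- (true_bearing + stats::rnorm(length(si), 0,
                                              params$vhf_bearing_sd * scale)) %% 360
  text <- vapply(seq_along(si), function(i)
    geocoder$address(c(human_pos[si[i], ], params$elev_m)), "")
  receiver <- data.frame(time = stop_times, utm_e = re, utm_n = rn,
                         elev_m = rz, bearing_deg = bearing_obs,
                         stringsAsFactors = FALSE)
  if (params$quantize_range) {
    receiver$range_code <- vapply(range_obs, nearest_range_code, 0)
    range_for_stalk <- range_code_to_m(receiver$range_code)
  } else {
    receiver$range_m <- range_obs
    range_for_stalk <- range_obs
  }
  receiver$text <- text

  streams <- list(
    V = data.frame(time = vehicle$time,
                   payload = I(lapply(seq_len(nrow(vehicle)), function(i)
                     c(vehicle$lat[i], vehicle$lon[i], vehicle$altitude_ft[i])))),
    R = data.frame(time = receiver$time,
                   payload = I(lapply(seq_len(nrow(receiver)), function(i)
                     c(receiver$utm_e[i], receiver$utm_n[i], receiver$elev_m[i],
                       range_for_stalk[i], receiver$bearing_deg[i])))),
    T = data.frame(time = receiver$time,
                   payload = I(as.list(receiver$text))),
    G = data.frame(time = collar$time,
                   payload = I(lapply(seq_len(nrow(collar)), function(i)
                     c(collar$utm_e[i], collar$utm_n[i], collar$elev_m[i]))))
  )

  truth <- data.frame(time = all_times,
                      bearE = bear_pos[, 1], bearN = bear_pos[, 2],
                      humanE = human_pos[, 1], humanN = human_pos[, 2])
  list(vehicle = vehicle, collar = collar, receiver = receiver,
       streams = streams, truth = truth)
}
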