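#' The four-sensor bear/human tracking sheaf
#'
#' Four sensors observe two targets: the vehicle GPS (`V`), the receiver's
#' handheld GPS + VHF range/bearing (`R`) and the free-text report (`T`)
#' locate the human; the bear-collar GPS (`G`) and the VHF reading locate
#' the bear.  The complex is the downward closure of the human triangle
#' `{R,T,V}` and the bear edge `{G,R}`.  Restriction maps register every
#' reading into UTM meters: lat/long/ft conversion for `V`, geocoding for
#' `T`, coordinate projections for `R` and `G`, and polar-to-rectangular
#' conversion plus vector addition for the VHF prediction of the bear.
#'
#' @name bear_model
NULL

#' Named faces of the tracking complex
#'
#' Conventional labels for the five non-vertex faces: `B = {G,R}` (bear),
#' `X = {T,V}`, `Y = {R,V}`, `Z = {R,T}` (human pairs) and `H = {R,T,V}`
#' (human triangle).
#'
#' @return named character vector label -> face key
#' @export
tracking_faces <- function() {
  c(B = face_key(c("G", "R")),
    X = face_key(c("T", "V")),
    Y = face_key(c("R", "V")),
    Z = face_key(c("R", "T")),
    H = face_key(c("R", "T", "V")))
}

#' Convert a receiver reading from polar to rectangular offsets
#'
#' Maps `(x, y, z, r, theta)` to `(x, y, z, r cos(theta), r sin(theta))`:
#' the receiver position and elevation pass through unchanged, the VHF
#' range/bearing becomes an (easting, northing) offset.  By default the
#' bearing is treated as a mathematical angle from the easting axis, the
#' convention under which the worked coordinates in the source data check
#' out to ~1 m; `convention = "compass"` instead measures clockwise from
#' north.
#'
#' @param p numeric length-5: `(easting, northing, elev_m, range_m, bearing_deg)`
#' @param convention `"math"` or `"compass"`
#' @return numeric length-5 with the last two entries the rectangular offsets
#' @export
polar_to_rect <- function(p, convention = c("math", "compass")) {
  convention <- match.arg(convention)
  th <- p[5] * pi / 180
  off <- if (convention == "math") c(p[4] * cos(th), p[4] * sin(th))
         else c(p[4] * sin(th), p[4] * cos(th))
  c(p[1], p[2], p[3], off[1], off[2])
}

#' Predict the bear position from a receiver reading
#'
#' Adds the rectangular VHF offset to the receiver's own position.
#'
#' @inheritParams polar_to_rect
#' @return numeric `c(easting, northing)` of the predicted bear position
#' @export
predict_bear <- function(p, convention = "math") {
  q <- polar_to_rect(p, convention)
  c(q[1] + q[4], q[2] + q[5])
}

#' Build the tracking sheaf
#'
#' @param geocoder a `geocoder` used for the text vertex's restrictions
#' @param zone UTM zone used to register the vehicle's lat/long readings
#' @param hemisphere `"north"` or `"south"`
#' @param bearing_convention `"math"` (default) or `"compass"`; see
#'   [polar_to_rect()]
#' @return a `sheaf` on the 9-face tracking complex; stalks are R^3 on the
#'   vertices `G`, `V` and all human faces, text on `T`, R^5 on `R` and R^2
#'   on the bear edge (elevation is dropped where the VHF reading carries
#'   none)
#' @export
build_tracking_sheaf <- function(geocoder, zone = 17, hemisphere = "north",
                                 bearing_convention = "math") {
  stopifnot(inherits(geocoder, "geocoder"))
  cx <- build_complex(list(c("R", "T", "V"), c("G", "R")))
  fk <- tracking_faces()
  stalks <- list()
  stalks[["G"]] <- stalk_euclidean(3)
  stalks[["V"]] <- stalk_euclidean(3)
  stalks[["T"]] <- stalk_text()
  stalks[["R"]] <- stalk_euclidean(5)
  stalks[[fk[["B"]]]] <- stalk_euclidean(2)
  for (lbl in c("X", "Y", "Z", "H")) stalks[[fk[[lbl]]]] <- stalk_euclidean(3)

  v_to_utm <- function(p) latlonft_to_utm(p[1], p[2], p[3],
                                          zone = zone, hemisphere = hemisphere)
  t_geocode <- function(text) {
    v <- geocoder$geocode(text)
    if (is.null(v))
      stop("geocoder failed on text reading: ", text, call. = FALSE)
    v
  }
  r_proj3 <- function(p) p[1:3]
  r_to_b <- function(p) predict_bear(p, convention = bearing_convention)
  g_to_b <- function(p) p[1:2]

  restrictions <- list()
  restrictions[[restr_key("V", fk[["X"]])]] <- v_to_utm
  restrictions[[restr_key("V", fk[["Y"]])]] <- v_to_utm
  restrictions[[restr_key("T", fk[["X"]])]] <- t_geocode
  restrictions[[restr_key("T", fk[["Z"]])]] <- t_geocode
  restrictions[[restr_key("R", fk[["Y"]])]] <- r_proj3
  restrictions[[restr_key("R", fk[["Z"]])]] <- r_proj3
  restrictions[[restr_key("R", fk[["B"]])]] <- r_to_b
  restrictions[[restr_key("G", fk[["B"]])]] <- g_to_b
  for (lbl in c("X", "Y", "Z"))
    restrictions[[restr_key(fk[[lbl]], fk[["H"]])]] <- identity

  sheaf(cx, stalks, restrictions)
}

#' Decode VHF range codes to meters
#'
#' Approximate distances were logged as integer codes; the decoding is
#' code 2 = 1500 m, 3 = 1000 m, 4 = 750 m, 5 = 500 m, 6 = 375 m.
#'
#' @param code integer vector with values in 2..6
#' @return numeric vector of ranges in meters
#' @export
range_code_to_m <- function(code) {
  map <- c(`2` = 1500, `3` = 1000, `4` = 750, `5` = 500, `6` = 375)
  out <- map[as.character(code)]
  if (anyNA(out)) stop("unknown range code(s): ",
                       paste(code[is.na(out)], collapse = ","))
  unname(out)
}

#' Interleave per-sensor streams into a tracking timeline
#'
#' Sensors report on different clocks; readings are aligned by
#' last-observation-carried-forward.  With `grid = NULL` the timeline runs
#' at the union of all reading times (event-driven); with a numeric `grid`
#' it is resampled at that fixed step.  Before a sensor's first reading its
#' vertex is unassigned.
#'
#' @param streams named list of per-sensor data.frames, each with a `time`
#'   column (seconds, sorted) and a `payload` list-column or the sensor's
#'   payload columns; names are vertex labels (`V`, `R`, `T`, `G`)
#' @param grid `NULL` or a fixed resampling step in seconds
#' @return a `tracking_timeline`: list with `time` (numeric vector),
#'   `values` (per-timestamp named list of payloads) and `fresh` (logical
#'   matrix timestamps x sensors: whether the value was recorded at that
#'   instant or carried forward)
#' @export
interleave <- function(streams, grid = NULL) {
  stopifnot(length(streams) > 0, !is.null(names(streams)))
  payloads <- lapply(streams, function(df) {
    if (is.null(df$time)) stop("each stream needs a 'time' column")
    if (is.unsorted(df$time)) stop("stream times must be sorted")
    if (!is.null(df$payload)) df$payload
    else lapply(seq_len(nrow(df)), function(i)
      unlist(df[i, setdiff(names(df), "time"), drop = FALSE], use.names = FALSE))
  })
  times_by <- lapply(streams, `[[`, "time")
  tt <- if (is.null(grid)) sort(unique(unlist(times_by)))
        else {
          rng <- range(unlist(times_by))
          seq(rng[1], rng[2], by = grid)
        }
  sensors <- names(streams)
  fresh <- matrix(FALSE, length(tt), length(sensors),
                  dimnames = list(NULL, sensors))
  values <- vector("list", length(tt))
  for (i in seq_along(tt)) {
    v <- list()
    for (s in sensors) {
      k <- findInterval(tt[i], times_by[[s]])
      if (k >= 1L) {
        v[[s]] <- payloads[[s]][[k]]
        fresh[i, s] <- times_by[[s]][k] == tt[i]
      }
    }
    values[[i]] <- v
  }
  structure(list(time = tt, values = values, fresh = fresh),
            class = "tracking_timeline")
}

#' @export
print.tracking_timeline <- function(x, ...) {
  cat("Tracking timeline:", length(x$time), "timestamps over",
      diff(range(x$time)), "s; sensors:",
      paste(colnames(x$fresh), collapse = ","), "\n")
  invisible(x)
}

subsystem_faces <- function(subsystem = c("full", "human", "bear")) {
  subsystem <- match.arg(subsystem)
  fk <- tracking_faces()
  switch(subsystem,
         full = unname(fk),
         human = unname(fk[c("X", "Y", "Z", "H")]),
         bear = unname(fk["B"]))
}

#' Consistency-radius time series over a timeline
#'
#' For each timestamp with all required vertices assigned, computes the
#' per-face spreads and their maximum over the chosen subsystem: `full`
#' uses all five non-vertex faces, `human` the triangle and its edges,
#' `bear` the collar/VHF edge.  Timestamps lacking a required vertex (e.g.,
#' before a sensor's first reading, or a geocoder failure on the text
#' vertex) are skipped with a warning.
#'
#' @param timeline a `tracking_timeline`
#' @param sh the tracking `sheaf`
#' @param subsystem `"full"`, `"human"` or `"bear"`
#' @return data.frame with `time`, `radius` and one spread column per face
#' @export
radius_series <- function(timeline, sh, subsystem = c("full", "human", "bear")) {
  subsystem <- match.arg(subsystem)
  fks <- subsystem_faces(subsystem)
  need <- sort(unique(unlist(lapply(fks, key_to_face))))
  rows <- list()
  skipped <- 0L
  for (i in seq_along(timeline$time)) {
    a <- timeline$values[[i]]
    if (!all(need %in% names(a))) { skipped <- skipped + 1L; next }
    rep_ <- tryCatch(consistency_radius(sh, a, faces = fks),
                     error = function(e) NULL)
    if (is.null(rep_)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <-
      c(time = timeline$time[i], radius = rep_$radius, rep_$spreads)
  }
  if (skipped > 0L)
    warning(skipped, " timestamp(s) skipped: missing or unregistrable vertex data")
  if (!length(rows))
    return(data.frame(time = numeric(0), radius = numeric(0)))
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Theil-Sen slope of a time series
#'
#' Median of all pairwise slopes; a robust trend estimate used to summarize
#' whether the consistency radius rises or falls over a session.
#'
#' @param x,y numeric vectors of equal length (>= 2)
#' @return scalar slope
#' @export
theil_sen_slope <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0
  stats::median(dy[keep] / dx[keep])
}
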