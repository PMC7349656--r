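#' Sensor CSV readers and result writers
#'
#' Three sensor dialects are supported: the vehicle log
#' (`time, lat, lon, altitude_ft`), the collar log
#' (`time, utm_e, utm_n, elev_m` plus optional quality metadata such as
#' `hdop`/`fix_type`, preserved but unused) and the receiver-stop log
#' (`time, utm_e, utm_n, elev_m, bearing_deg`, one of `range_m` or
#' `range_code`, and `text`).  Coordinates are stored as
#' (easting, northing); units are meters after ingestion; range codes are
#' decoded on read.
#'
#' @name io_cli
NULL

sensor_dialects <- list(
  vehicle = c("time", "lat", "lon", "altitude_ft"),
  collar = c("time", "utm_e", "utm_n", "elev_m"),
  receiver = c("time", "utm_e", "utm_n", "elev_m", "bearing_deg")
)

#' Read a sensor CSV
#'
#' Rows are sorted by time (with a notice when the file was out of order);
#' rows with unparseable required fields are dropped with a warning giving
#' the count.  Receiver files may log the approximate VHF distance either
#' as `range_m` or as a `range_code` column decoded via
#' [range_code_to_m()].
#'
#' @param path file path
#' @param kind `"vehicle"`, `"collar"` or `"receiver"`
#' @return data.frame in the standard column layout (receiver output always
#'   carries `range_m`); extra columns are preserved
#' @export
read_sensor_csv <- function(path, kind = c("vehicle", "collar", "receiver")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- sensor_dialects[[kind]]
  if (kind == "receiver") {
    if (!("range_m" %in% names(df) || "range_code" %in% names(df)))
      stop("receiver file needs a 'range_m' or 'range_code' column")
    if (!"text" %in% names(df)) stop("missing required column: text")
  }
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing required column: ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty sensor file: ", path)
    if (kind == "receiver" && !"range_m" %in% names(df)) df$range_m <- numeric(0)
    return(df)
  }
  num_cols <- setdiff(need, "time")
  for (cl in c("time", num_cols)) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  ok <- stats::complete.cases(df[, need, drop = FALSE])
  if (any(!ok)) {
    warning(sum(!ok), " unparseable row(s) skipped in ", path)
    df <- df[ok, , drop = FALSE]
  }
  if (is.unsorted(df$time)) {
    message("rows in ", path, " were out of time order; sorted")
    df <- df[order(df$time), , drop = FALSE]
  }
  if (kind == "receiver" && !"range_m" %in% names(df))
    df$range_m <- range_code_to_m(df$range_code)
  rownames(df) <- NULL
  df
}

#' Build interleaving-ready streams from the three sensor files
#'
#' The receiver file carries both the `R` payload (position, elevation,
#' range, bearing) and the `T` text reports.
#'
#' @param vehicle,collar,receiver data.frames as returned by
#'   [read_sensor_csv()]
#' @return named list of V/R/T/G streams for [interleave()]
#' @export
sensor_streams <- function(vehicle, collar, receiver) {
  list(
    V = data.frame(time = vehicle$time, payload = I(lapply(
      seq_len(nrow(vehicle)), function(i)
        c(vehicle$lat[i], vehicle$lon[i], vehicle$altitude_ft[i])))),
    R = data.frame(time = receiver$time, payload = I(lapply(
      seq_len(nrow(receiver)), function(i)
        c(receiver$utm_e[i], receiver$utm_n[i], receiver$elev_m[i],
          receiver$range_m[i], receiver$bearing_deg[i])))),
    T = data.frame(time = receiver$time, payload = I(as.list(receiver$text))),
    G = data.frame(time = collar$time, payload = I(lapply(
      seq_len(nrow(collar)), function(i)
        c(collar$utm_e[i], collar$utm_n[i], collar$elev_m[i]))))
  )
}

#' Write / read a consistency filtration as CSV
#'
#' Columns `epsilon`, `new_faces`, `cover`, `rank` and `measure` mirror the
#' filtration table; the measure is written both as a `p/q` fraction and as
#' a decimal, faces separated by spaces and cover sets by `;`.
#'
#' @param steps a `consistency_filtration`
#' @param path output file
#' @export
write_filtration <- function(steps, path) {
  stopifnot(inherits(steps, "consistency_filtration"), length(steps) > 0)
  df <- data.frame(
    epsilon = vapply(steps, `[[`, 0, "epsilon"),
    new_faces = vapply(steps, function(s) paste(s$new_faces, collapse = " "), ""),
    cover = vapply(steps, function(s)
      paste(vapply(s$cover$sets, face_key, ""), collapse = ";"), ""),
    rank = vapply(steps, `[[`, 0L, "rank"),
    measure_fraction = vapply(steps, `[[`, "", "fraction"),
    measure = vapply(steps, `[[`, 0, "measure"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_filtration
#' @param n number of vertices of the underlying complex (needed to rebuild
#'   cover objects on read)
#' @export
read_filtration <- function(path, n) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  steps <- lapply(seq_len(nrow(df)), function(i) {
    sets <- lapply(strsplit(df$cover[i], ";", fixed = TRUE)[[1]], key_to_face)
    cov <- structure(list(sets = canon_cover(sets), n = n), class = "vertex_cover")
    list(epsilon = df$epsilon[i],
         new_faces = if (nzchar(df$new_faces[i]))
           strsplit(df$new_faces[i], " ", fixed = TRUE)[[1]] else character(0),
         cover = cov, rank = df$rank[i], measure = df$measure[i],
         fraction = df$measure_fraction[i])
  })
  structure(steps, class = "consistency_filtration")
}

#' Write a consistency-radius time series as CSV
#'
#' @param series data.frame from [radius_series()]
#' @param path output file
#' @export
write_radius_series <- function(series, path) {
  stopifnot(is.data.frame(series), nrow(series) > 0)
  utils::write.csv(series, path, row.names = FALSE)
  invisible(series)
}

#' Export tracks and per-timestamp radius as GeoJSON
#'
#' Writes a FeatureCollection of Point features in UTM coordinates with
#' time and radius properties.
#'
#' @param series data.frame with `time` and `radius`
#' @param positions matrix/data.frame of easting, northing rows aligned
#'   with `series`
#' @param path output file
#' @export
write_geojson_radius <- function(series, positions, path) {
  stopifnot(nrow(series) == nrow(positions))
  features <- lapply(seq_len(nrow(series)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(positions[i, 1], positions[i, 2])),
         properties = list(time = series$time[i], radius = series$radius[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

builtin_restrictions <- c("identity", "projection", "utm_from_latlon_ft",
                          "polar_to_rect_then_add", "geocode")

#' Read and validate a run configuration
#'
#' YAML (or JSON) with the sheaf definition (top faces, restriction-map
#' names, bearing convention, UTM zone), per-sensor file paths, interleave
#' grid, subsystem, DLM initial SDs and seed.  Unknown restriction-map
#' names are rejected before any computation.
#'
#' @param path config file
#' @return validated config list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$restrictions)) {
    unknown <- setdiff(unlist(cfg$restrictions), builtin_restrictions)
    if (length(unknown))
      stop("unknown restriction-map name(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$bearing_convention) &&
      !cfg$bearing_convention %in% c("math", "compass"))
    stop("bearing_convention must be 'math' or 'compass'")
  if (is.null(cfg$zone)) cfg$zone <- 17
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}
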