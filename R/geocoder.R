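#' Offline geocoders
#'
#' The text sensor reports a free-text location; before any spread can be
#' computed it must be registered into UTM meters.  A geocoder is a pair of
#' deterministic functions: `geocode(text)` returning
#' `c(easting, northing, elev_m)` or `NULL` on failure, and (for synthetic
#' data) `address(point)` producing a text string for a position.  All
#' built-in geocoders are offline; a live service can be wrapped in the same
#' contract.
#'
#' @name geocoders
NULL

new_geocoder <- function(geocode, address = NULL, label = "geocoder") {
  structure(list(geocode = geocode, address = address, label = label),
            class = "geocoder")
}

#' @export
print.geocoder <- function(x, ...) {
  cat("<geocoder:", x$label, ">\n"); invisible(x)
}

#' Grid geocoder: addresses are cells of a square grid
#'
#' Synthetic "street corner" addresses name a grid cell; geocoding returns
#' the cell center, so any point geocodes to within `cell_size * sqrt(2) / 2`
#' of its true position.  Malformed addresses fail (return `NULL`), which
#' exercises the unassignable-text-vertex path.
#'
#' @param cell_size cell edge length in meters (> 0)
#' @return a `geocoder`
#' @export
grid_geocoder <- function(cell_size) {
  stopifnot(cell_size > 0)
  new_geocoder(
    geocode = function(text) {
      m <- regmatches(text, regexec(
        "^cell (-?[0-9]+) (-?[0-9]+) elev (-?[0-9.]+)$", text))[[1]]
      if (length(m) != 4L) return(NULL)
      i <- as.numeric(m[2]); jj <- as.numeric(m[3]); elev <- as.numeric(m[4])
      c((i + 0.5) * cell_size, (jj + 0.5) * cell_size, elev)
    },
    address = function(p) {
      sprintf("cell %d %d elev %s",
              floor(p[1] / cell_size), floor(p[2] / cell_size),
              format(round(p[3], 1)))
    },
    label = sprintf("grid(%g m)", cell_size)
  )
}

#' Exact geocoder: addresses carry full-precision coordinates
#'
#' Round-trips positions exactly; used for noise-free end-to-end checks.
#' @return a `geocoder`
#' @export
exact_geocoder <- function() {
  new_geocoder(
    geocode = function(text) {
      m <- regmatches(text, regexec(
        "^loc (-?[0-9.]+) (-?[0-9.]+) (-?[0-9.]+)$", text))[[1]]
      if (length(m) != 4L) return(NULL)
      as.numeric(m[2:4])
    },
    address = function(p) sprintf("loc %.6f %.6f %.6f", p[1], p[2], p[3]),
    label = "exact"
  )
}

#' Lookup-table geocoder
#'
#' @param table named list: address string -> numeric
#'   `c(easting, northing, elev_m)`
#' @return a `geocoder`
#' @export
table_geocoder <- function(table) {
  new_geocoder(
    geocode = function(text) {
      v <- table[[text]]
      if (is.null(v)) NULL else as.numeric(v)
    },
    address = NULL,
    label = sprintf("table(%d entries)", length(table))
  )
}
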