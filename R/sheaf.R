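#' Sheaves of metric-space data on a simplicial complex
#'
#' A sheaf attaches a stalk (value space) to every face and a restriction
#' map to every inclusion of faces.  Restrictions are supplied for covering
#' pairs (face -> coface with one more vertex); longer inclusions are
#' composed along a deterministic chain and cached, which is valid because
#' the composition law makes all chains agree.
#'
#' @name sheaf_core
NULL

#' Stalk space descriptors
#'
#' @param d dimension (>= 1); coordinates are meters after registration
#' @return a `stalk_space` object
#' @export
stalk_euclidean <- function(d) {
  stopifnot(d >= 1)
  structure(list(kind = "euclidean", dim = as.integer(d)), class = "stalk_space")
}

#' @rdname stalk_euclidean
#' @export
stalk_text <- function() {
  structure(list(kind = "text", dim = NA_integer_), class = "stalk_space")
}

restr_key <- function(from, to) paste(from, to, sep = " -> ")

#' Construct a sheaf on a simplicial complex
#'
#' @param complex a `simplicial_complex`
#' @param stalks named list (by face key) of `stalk_space` objects; one per face
#' @param restrictions named list of functions, one per covering pair, named
#'   `"<from key> -> <to key>"`; each maps a stalk value of `from` to one of `to`
#' @return a `sheaf` object
#' @export
sheaf <- function(complex, stalks, restrictions) {
  stopifnot(inherits(complex, "simplicial_complex"))
  missing_stalks <- setdiff(names(complex$faces), names(stalks))
  if (length(missing_stalks))
    stop("missing stalks for faces: ", paste(missing_stalks, collapse = ", "))
  ap <- attachment_pairs(complex)
  want <- restr_key(ap$from, ap$to)
  missing_r <- setdiff(want, names(restrictions))
  if (length(missing_r))
    stop("missing restriction maps for covering pairs: ",
         paste(missing_r, collapse = ", "))
  structure(
    list(complex = complex, stalks = stalks, restrictions = restrictions,
         cache = new.env(parent = emptyenv())),
    class = "sheaf"
  )
}

#' @export
print.sheaf <- function(x, ...) {
  cat("Sheaf on ")
  print(x$complex)
  dims <- vapply(x$stalks, function(s)
    if (s$kind == "text") "text" else paste0("R^", s$dim), "")
  cat("Stalks:", paste(names(dims), dims, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Restriction map between two nested faces
#'
#' Composites for multi-step inclusions are built by chaining covering-pair
#' maps through the lexicographically smallest intermediate vertex, and cached.
#'
#' @param sh a `sheaf`
#' @param from,to face keys with `from` a subset of `to`
#' @return a function stalk(from) -> stalk(to)
#' @export
restriction_map <- function(sh, from, to) {
  if (from == to) return(identity)
  key <- restr_key(from, to)
  if (!is.null(sh$restrictions[[key]])) return(sh$restrictions[[key]])
  if (exists(key, envir = sh$cache)) return(get(key, envir = sh$cache))
  fv <- key_to_face(from); tv <- key_to_face(to)
  if (!all(fv %in% tv))
    stop("no inclusion ", from, " -> ", to)
  mid <- face_key(c(fv, setdiff(tv, fv)[1L]))
  f1 <- restriction_map(sh, from, mid)
  f2 <- restriction_map(sh, mid, to)
  fn <- function(x) f2(f1(x))
  assign(key, fn, envir = sh$cache)
  fn
}

#' Check the composition law on sample data
#'
#' For every chain vertex -> delta -> lambda the two-step composite must
#' match the direct restriction.  This is a test utility, not a runtime gate.
#'
#' @param sh a `sheaf`
#' @param sample_points named list (by vertex) of stalk values, or a list of
#'   such values per vertex
#' @param tol numeric tolerance in stalk units (meters)
#' @return data.frame of violating triples (zero rows when the sheaf commutes)
#' @export
verify_commutativity <- function(sh, sample_points, tol = 1e-6) {
  cx <- sh$complex
  bad <- list()
  for (w in cx$vertices) {
    pts <- sample_points[[w]]
    if (is.null(pts)) next
    if (!is.list(pts)) pts <- list(pts)
    ups <- names(star(cx, w))
    for (dk in ups) {
      if (dk == w) next
      for (lk in ups) {
        if (lk == dk || lk == w) next
        dv <- key_to_face(dk); lv <- key_to_face(lk)
        if (!all(dv %in% lv)) next
        direct <- restriction_map(sh, w, lk)
        two_step_a <- restriction_map(sh, w, dk)
        two_step_b <- restriction_map(sh, dk, lk)
        for (x in pts) {
          d1 <- direct(x)
          d2 <- two_step_b(two_step_a(x))
          if (is.numeric(d1) && is.numeric(d2)) {
            if (max(abs(d1 - d2)) > tol)
              bad[[length(bad) + 1L]] <-
                data.frame(vertex = w, via = dk, to = lk,
                           max_diff = max(abs(d1 - d2)))
          } else if (!identical(d1, d2)) {
            bad[[length(bad) + 1L]] <-
              data.frame(vertex = w, via = dk, to = lk, max_diff = NA_real_)
          }
        }
      }
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(vertex = character(0), via = character(0),
                  to = character(0), max_diff = numeric(0))
}

#' Images of a face's vertex values under restriction
#'
#' @param sh a `sheaf`
#' @param a a vertex assignment: named list (by vertex) of stalk values
#' @param face a non-vertex face (character vector or face key)
#' @return matrix with one row per vertex of `face` (rownames = vertices),
#'   the restricted values in the face's stalk
#' @export
restricted_values <- function(sh, a, face) {
  fv <- if (length(face) == 1L && grepl("|", face, fixed = TRUE))
    key_to_face(face) else sort(as.character(face))
  fk <- face_key(fv)
  if (length(fv) < 2L) stop("face must be non-vertex")
  vals <- lapply(fv, function(w) {
    if (is.null(a[[w]]))
      stop("vertex ", w, " is not assigned")
    v <- restriction_map(sh, w, fk)(a[[w]])
    if (!is.numeric(v))
      stop("restricted value at vertex ", w, " on face {",
           paste(fv, collapse = ","),
           "} is not numeric; register text readings through a geocoder first")
    v
  })
  m <- do.call(rbind, vals)
  rownames(m) <- fv
  m
}

#' Spread of a point multiset
#'
#' The root-mean-square deviation from the multiset mean,
#' \eqn{\hat\sigma(Y) = \sqrt{\frac{1}{|Y|}\sum_{y\in Y} \|y-\mu_Y\|^2}},
#' in the units of the points (meters).  For two points it is half their
#' distance.
#'
#' @param points numeric matrix, one row per point (a vector is one point)
#' @return nonnegative scalar
#' @examples
#' spread(rbind(c(0, 0), c(3, 0), c(6, 0)))  # sqrt(6)
#' @export
spread <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  if (!is.numeric(points) || anyNA(points))
    stop("spread needs finite numeric points")
  mu <- colMeans(points)
  dev <- sweep(points, 2L, mu)
  sqrt(mean(rowSums(dev^2)))
}

#' Consistency radius of a vertex assignment
#'
#' The per-face spread of the restricted vertex values, and its maximum:
#' the smallest tolerance at which the data extend to a pseudosection.
#'
#' @param sh a `sheaf` whose non-vertex stalks are euclidean
#' @param a vertex assignment (named list by vertex)
#' @param faces optional character vector of face keys to restrict attention
#'   to (default: all non-vertex faces)
#' @return a `spread_report`: list with `spreads` (named numeric, meters)
#'   and `radius` (their maximum)
#' @export
consistency_radius <- function(sh, a, faces = NULL) {
  nv <- names(complex_faces(sh$complex, min_dim = 1L))
  if (!is.null(faces)) {
    unknown <- setdiff(faces, nv)
    if (length(unknown)) stop("not non-vertex faces: ", paste(unknown, collapse = ","))
    nv <- faces
  }
  spreads <- vapply(nv, function(fk) spread(restricted_values(sh, a, fk)), 0)
  structure(list(spreads = spreads, radius = if (length(spreads)) max(spreads) else 0),
            class = "spread_report")
}

#' @export
print.spread_report <- function(x, ...) {
  cat("Consistency radius:", format(x$radius), "m\n")
  print(round(x$spreads, 3))
  invisible(x)
}

#' Extend a vertex assignment to all faces
#'
#' Each non-vertex face receives the mean of its restricted vertex values.
#' The result is a pseudosection at epsilon equal to the consistency radius.
#'
#' @inheritParams consistency_radius
#' @return full assignment: named list over all face keys
#' @export
extend_assignment <- function(sh, a) {
  full <- list()
  for (w in sh$complex$vertices) {
    if (is.null(a[[w]])) stop("vertex ", w, " is not assigned")
    full[[w]] <- a[[w]]
  }
  for (fk in names(complex_faces(sh$complex, min_dim = 1L)))
    full[[fk]] <- colMeans(restricted_values(sh, a, fk))
  full
}

#' Consistency structures
#'
#' A per-face boolean agreement test replacing strict equality: the
#' `standard` mode tests exact equality (within `tol`); the `epsilon` mode
#' accepts a face when the spread of the compared values is at most `epsilon`.
#'
#' @param sh a `sheaf`
#' @param mode `"standard"` or `"epsilon"`
#' @param epsilon tolerance in meters (epsilon mode)
#' @param tol numeric equality tolerance for the standard mode
#' @return a `consistency_structure`
#' @export
consistency_structure <- function(sh, mode = c("standard", "epsilon"),
                                  epsilon = 0, tol = 1e-6) {
  mode <- match.arg(mode)
  test <- if (mode == "standard") {
    function(points) {
      if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
      all(apply(points, 2L, function(col) max(col) - min(col) <= tol))
    }
  } else {
    function(points) spread(points) <= epsilon
  }
  structure(list(sheaf = sh, mode = mode, epsilon = epsilon, tol = tol,
                 test = test),
            class = "consistency_structure")
}

#' Test whether a full assignment is a pseudosection
#'
#' Both defining conditions are checked on every non-vertex face: (i) the
#' restricted vertex multiset passes the face's agreement test, and (ii) so
#' does every multiset obtained by replacing one restricted vertex value
#' with the value assigned to the face itself.
#'
#' @param cs a `consistency_structure`
#' @param a full assignment (all faces assigned)
#' @return logical
#' @export
is_pseudosection <- function(cs, a) {
  sh <- cs$sheaf
  for (fk in names(complex_faces(sh$complex, min_dim = 1L))) {
    if (is.null(a[[fk]])) stop("face ", fk, " is not assigned")
    z <- restricted_values(sh, a, fk)
    if (!cs$test(z)) return(FALSE)
    for (j in seq_len(nrow(z))) {
      zj <- z
      zj[j, ] <- a[[fk]]
      if (!cs$test(zj)) return(FALSE)
    }
  }
  TRUE
}
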