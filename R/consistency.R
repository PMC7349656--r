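#' Maximal consistent covers, cover measures, and the consistency filtration
#'
#' Given a per-face consistency verdict, there is a unique full antichain of
#' vertex subsets whose induced subcomplexes are consistent and maximal; the
#' union of the stars of these subcomplexes covers the whole complex.  The
#' antichain is measured by the rank of its order ideal in the Boolean
#' lattice, normalized so that the coarsest cover (all sensors agreeing)
#' scores 1.  Sweeping the tolerance epsilon from 0 to the consistency
#' radius yields the consistency filtration.
#'
#' @name consistency
NULL

# is the induced subcomplex of W consistent, given consistent face keys?
consistent_on <- function(complex, W, consistent_keys) {
  for (fk in names(complex_faces(complex, min_dim = 1L))) {
    f <- complex$faces[[fk]]
    if (all(f %in% W) && !(fk %in% consistent_keys)) return(FALSE)
  }
  TRUE
}

all_subsets <- function(x) {
  n <- length(x)
  out <- vector("list", 2^n)
  idx <- 1L
  for (m in 0:n) {
    if (m == 0L) { out[[idx]] <- character(0); idx <- idx + 1L; next }
    for (s in utils::combn(x, m, simplify = FALSE)) {
      out[[idx]] <- s; idx <- idx + 1L
    }
  }
  out
}

drop_dominated <- function(sets) {
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i == j || !keep[i] || !keep[j]) next
      if (all(sets[[i]] %in% sets[[j]]) &&
          (length(sets[[i]]) < length(sets[[j]]) || j < i))
        keep[i] <- FALSE
    }
  }
  sets[keep]
}

cover_bruteforce <- function(complex, consistent_keys) {
  U <- complex$vertices
  cand <- Filter(function(W) length(W) > 0L &&
                   consistent_on(complex, W, consistent_keys),
                 all_subsets(U))
  drop_dominated(cand)
}

cover_recursive <- function(complex, consistent_keys, face_order = NULL) {
  U <- complex$vertices
  nv_keys <- names(complex_faces(complex, min_dim = 1L))
  if (is.null(face_order)) face_order <- sort(nv_keys)
  memo <- new.env(parent = emptyenv())
  first_bad <- function(W) {
    k <- face_key(W)
    if (exists(k, envir = memo)) return(get(k, envir = memo))
    bad <- NA_character_
    for (fk in face_order) {
      f <- complex$faces[[fk]]
      if (all(f %in% W) && !(fk %in% consistent_keys)) { bad <- fk; break }
    }
    assign(k, bad, envir = memo)
    bad
  }
  active <- list(sort(U))
  finished <- list()
  seen <- new.env(parent = emptyenv())
  while (length(active)) {
    W <- active[[1L]]; active <- active[-1L]
    bad <- first_bad(W)
    if (is.na(bad)) { finished[[length(finished) + 1L]] <- W; next }
    for (v in key_to_face(bad)) {
      Wi <- setdiff(W, v)
      if (!length(Wi)) next
      k <- face_key(Wi)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        active[[length(active) + 1L]] <- Wi
      }
    }
  }
  drop_dominated(finished)
}

canon_cover <- function(sets) {
  sets <- lapply(sets, function(s) sort(s))
  sets[order(vapply(sets, face_key, ""))]
}

#' The unique maximal-consistent-subcomplex cover
#'
#' @param complex a `simplicial_complex`
#' @param consistent character vector of face keys (or list of faces) judged
#'   consistent; vertices are always consistent and need not be listed
#' @param method `"auto"` (brute force up to 15 vertices), `"bruteforce"`,
#'   or `"recursive"` (the constructive split-on-inconsistent-face recursion
#'   with memoization; provably the same answer by uniqueness)
#' @param face_order optional permutation of non-vertex face keys used by the
#'   recursive method's face selection (the result is order-invariant)
#' @return a `vertex_cover`: list with `sets` (list of sorted vertex subsets,
#'   a full antichain) and `n` (number of vertices)
#' @export
maximal_consistent_covers <- function(complex, consistent = character(0),
                                      method = c("auto", "bruteforce", "recursive"),
                                      face_order = NULL) {
  method <- match.arg(method)
  if (is.list(consistent)) consistent <- vapply(consistent, face_key, "")
  n <- length(complex$vertices)
  sets <- if (method == "recursive" ||
              (method == "auto" && n > 15L))
    cover_recursive(complex, consistent, face_order)
  else cover_bruteforce(complex, consistent)
  structure(list(sets = canon_cover(sets), n = n), class = "vertex_cover")
}

#' @export
print.vertex_cover <- function(x, ...) {
  cat("{", paste(vapply(x$sets, function(s)
    paste0("{", paste(s, collapse = ","), "}"), ""), collapse = ", "), "}\n")
  invisible(x)
}

cover_ideal_keys <- function(cover) {
  keys <- ""  # empty set
  for (W in cover$sets)
    keys <- union(keys, vapply(all_subsets(W), face_key, ""))
  keys
}

#' Rank measure of a vertex cover
#'
#' The cover is an antichain in the Boolean lattice on the vertex set; its
#' order ideal (all subsets of its members, including the empty set and all
#' singletons) has a cardinality whose excess over n+1 is the rank.  The
#' measure normalizes by the maximum rank `2^n - (n+1)`.
#'
#' @param cover a `vertex_cover` (must be full: union of sets = all vertices)
#' @return list with `rank` (integer), `max_rank`, `measure` (rank/max_rank)
#'   and `fraction` (a `"p/q"` string)
#' @export
cover_measure <- function(cover) {
  n <- cover$n
  U_size <- length(unique(unlist(cover$sets)))
  if (U_size != n)
    stop("cover is not full: its union has ", U_size, " of ", n, " vertices")
  ideal <- cover_ideal_keys(cover)
  rank <- length(ideal) - (n + 1L)
  max_rank <- 2L^n - (n + 1L)
  list(rank = rank, max_rank = max_rank,
       measure = rank / max_rank,
       fraction = if (rank == max_rank) "1" else paste0(rank, "/", max_rank))
}

#' Consistency filtration from per-face spreads
#'
#' Sweeps epsilon through 0 and each distinct positive spread value (ties
#' grouped at one landmark).  Each step records the faces that become
#' consistent, the maximal-consistent cover at that tolerance, and its rank
#' measure.  The final landmark is the consistency radius and its measure
#' is 1.
#'
#' @param complex a `simplicial_complex`
#' @param face_spreads named numeric: spread (meters) per non-vertex face key
#' @param method passed to [maximal_consistent_covers()]
#' @return a `consistency_filtration`: list of steps, each with `epsilon`,
#'   `new_faces`, `cover`, `rank`, `measure`, `fraction`
#' @export
consistency_filtration <- function(complex, face_spreads,
                                   method = c("auto", "bruteforce", "recursive")) {
  method <- match.arg(method)
  nv <- names(complex_faces(complex, min_dim = 1L))
  missing <- setdiff(nv, names(face_spreads))
  if (length(missing))
    stop("no spread given for faces: ", paste(missing, collapse = ", "))
  sp <- face_spreads[nv]
  if (any(!is.finite(sp)) || any(sp < 0)) stop("spreads must be finite and >= 0")
  landmarks <- c(0, sort(unique(sp[sp > 0])))
  steps <- vector("list", length(landmarks))
  prev_consistent <- character(0)
  for (i in seq_along(landmarks)) {
    eps <- landmarks[i]
    consistent <- names(sp)[sp <= eps]
    cov <- maximal_consistent_covers(complex, consistent, method = method)
    m <- cover_measure(cov)
    steps[[i]] <- list(epsilon = eps,
                       new_faces = setdiff(consistent, prev_consistent),
                       cover = cov, rank = m$rank, measure = m$measure,
                       fraction = m$fraction)
    prev_consistent <- consistent
  }
  structure(steps, class = "consistency_filtration")
}

#' Wrapper: filtration of a sheaf-valued vertex assignment
#'
#' Computes per-face spreads with [consistency_radius()] and runs
#' [consistency_filtration()].
#'
#' @param sh a `sheaf`
#' @param a vertex assignment
#' @param ... passed to [consistency_filtration()]
#' @export
assignment_filtration <- function(sh, a, ...) {
  rep_ <- consistency_radius(sh, a)
  consistency_filtration(sh$complex, rep_$spreads, ...)
}

#' @export
print.consistency_filtration <- function(x, ...) {
  cat(sprintf("%-9s %-18s %-34s %s\n", "epsilon", "new faces", "cover", "measure"))
  for (s in x) {
    cov <- paste(vapply(s$cover$sets, function(w)
      paste0("{", paste(w, collapse = ","), "}"), ""), collapse = " ")
    cat(sprintf("%-9s %-18s %-34s %s\n", format(round(s$epsilon, 2)),
                paste(s$new_faces, collapse = " "), cov, s$fraction))
  }
  invisible(x)
}
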