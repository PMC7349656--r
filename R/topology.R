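#' Abstract simplicial complexes over a finite sensor set
#'
#' A simplicial complex records which groups of sensors observe a common
#' quantity: vertices are sensors, higher faces are multi-way interactions.
#' Faces are canonicalized as alphabetically sorted character vectors, and
#' keyed internally as the vertices joined by `"|"`, so that set equality,
#' deterministic iteration order and reproducible cover computations are all
#' well defined.
#'
#' @name topology
NULL

face_key <- function(vertices) paste(sort(unique(as.character(vertices))), collapse = "|")

key_to_face <- function(key) strsplit(key, "|", fixed = TRUE)[[1]]

#' Build the downward closure of a set of top faces
#'
#' @param top_faces list of character vectors, each a nonempty set of vertex
#'   (sensor) identifiers.  The complex is the collection of all nonempty
#'   subsets of these sets.
#' @return an object of class `simplicial_complex` with elements
#'   `vertices` (sorted character vector, the base set),
#'   `faces` (named list of sorted character vectors, keyed by face key) and
#'   `top_faces` (the maximal faces).
#' @examples
#' cx <- build_complex(list(c("V", "R", "T"), c("R", "G")))
#' length(cx$faces)  # 9
#' @export
build_complex <- function(top_faces) {
  if (!is.list(top_faces) || length(top_faces) == 0L)
    stop("'top_faces' must be a nonempty list of vertex sets")
  if (any(vapply(top_faces, length, 1L) == 0L))
    stop("empty face in 'top_faces': every face needs at least one vertex")
  faces <- new.env(parent = emptyenv())
  for (tf in top_faces) {
    tf <- sort(unique(as.character(tf)))
    n <- length(tf)
    for (m in seq_len(n)) {
      combs <- utils::combn(tf, m, simplify = FALSE)
      for (s in combs) assign(face_key(s), s, envir = faces)
    }
  }
  keys <- sort(ls(faces))
  fl <- lapply(keys, function(k) get(k, envir = faces))
  names(fl) <- keys
  vertices <- sort(unique(unlist(fl)))
  # maximal faces: not a proper subset of any other face
  is_top <- vapply(keys, function(k) {
    f <- fl[[k]]
    !any(vapply(fl, function(g) length(g) > length(f) && all(f %in% g), TRUE))
  }, TRUE)
  structure(
    list(vertices = vertices, faces = fl, top_faces = unname(fl[is_top])),
    class = "simplicial_complex"
  )
}

#' @export
print.simplicial_complex <- function(x, ...) {
  cat("Simplicial complex on", length(x$vertices), "vertices {",
      paste(x$vertices, collapse = ","), "} with", length(x$faces), "faces\n")
  cat("Top faces:", paste(vapply(x$top_faces, face_key, ""), collapse = "  "), "\n")
  invisible(x)
}

has_face <- function(complex, face) face_key(face) %in% names(complex$faces)

face_dim <- function(face) length(face) - 1L

#' Faces of a complex, optionally filtered by dimension
#' @param complex a `simplicial_complex`
#' @param min_dim keep faces of dimension >= `min_dim`
#' @return named list of faces
#' @export
complex_faces <- function(complex, min_dim = 0L) {
  Filter(function(f) face_dim(f) >= min_dim, complex$faces)
}

#' Star of a face: all faces containing it
#'
#' @param complex a `simplicial_complex`
#' @param face character vector of vertices; must be a face of `complex`
#' @return named list of faces `rho` with `face` a subset of `rho`
#'   (including `face` itself)
#' @export
star <- function(complex, face) {
  face <- sort(unique(as.character(face)))
  if (!has_face(complex, face))
    stop("face {", paste(face, collapse = ","), "} is not in the complex")
  Filter(function(g) all(face %in% g), complex$faces)
}

#' Subcomplex induced by a vertex subset
#'
#' @param complex a `simplicial_complex`
#' @param W character vector, a subset of the base set
#' @return the `simplicial_complex` of exactly those faces contained in `W`
#'   (downward closure is automatic).  `W` may induce an empty complex only
#'   if it is empty; vertices of the result are the members of `W` that are
#'   vertices of `complex`.
#' @export
induced_subcomplex <- function(complex, W) {
  W <- sort(unique(as.character(W)))
  if (!all(W %in% complex$vertices))
    stop("W contains non-vertices: ",
         paste(setdiff(W, complex$vertices), collapse = ","))
  fl <- Filter(function(f) all(f %in% W), complex$faces)
  keys <- names(fl)
  is_top <- vapply(keys, function(k) {
    f <- fl[[k]]
    !any(vapply(fl, function(g) length(g) > length(f) && all(f %in% g), TRUE))
  }, TRUE)
  structure(
    list(vertices = sort(unique(unlist(fl))),
         faces = fl, top_faces = unname(fl[is_top])),
    class = "simplicial_complex"
  )
}

#' Covering pairs of the attachment diagram
#'
#' The attachment diagram links each face to the cofaces with exactly one
#' more vertex.  It is derived on demand rather than stored.
#'
#' @param complex a `simplicial_complex`
#' @return data.frame with columns `from`, `to` (face keys), one row per
#'   covering pair
#' @export
attachment_pairs <- function(complex) {
  keys <- names(complex$faces)
  out_from <- character(0); out_to <- character(0)
  for (k in keys) {
    f <- complex$faces[[k]]
    for (k2 in keys) {
      g <- complex$faces[[k2]]
      if (length(g) == length(f) + 1L && all(f %in% g)) {
        out_from <- c(out_from, k); out_to <- c(out_to, k2)
      }
    }
  }
  data.frame(from = out_from, to = out_to, stringsAsFactors = FALSE)
}
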