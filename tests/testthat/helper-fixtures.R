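# Shared fixtures and independent oracles, all built in code.

fkey <- function(v) paste(sort(v), collapse = "|")
rkey <- function(from, to) paste(from, to, sep = " -> ")

tracking_complex_fx <- function() build_complex(list(c("R", "T", "V"), c("G", "R")))

# The worked filtration's per-face spreads (meters), keyed by face.
table4_spreads_fx <- function() {
  fk <- tracking_faces()
  stats::setNames(c(9.48, 15.90, 18.42, 20.35, 464.50),
                  fk[c("Y", "Z", "H", "X", "B")])
}

printed_geocoder_fx <- function() {
  table_geocoder(list(
    "Intersection of Victoria Rd and Meadow Rd" = c(358943, 3936899, 615.4)))
}

# The worked global section: receiver, collar and text readings as printed;
# the vehicle lat/long generated by inverse projection of the registered
# position so the registration round-trips.
printed_assignment_fx <- function() {
  ll <- utm_to_latlon(358943, 3936899, 17)
  list(V = c(ll[["lat"]], ll[["lon"]], 615.4 / 0.3048),
       R = c(358943, 3936899, 615.4, 572, 195),
       T = "Intersection of Victoria Rd and Meadow Rd",
       G = c(358391, 3936750, 581))
}

# A sheaf with identical stalks and identity restrictions everywhere.
identity_sheaf_fx <- function(top_faces, d = 1) {
  cx <- build_complex(top_faces)
  stalks <- lapply(cx$faces, function(f) stalk_euclidean(d))
  ap <- attachment_pairs(cx)
  restr <- stats::setNames(rep(list(identity), nrow(ap)), rkey(ap$from, ap$to))
  sheaf(cx, stalks, restr)
}

# Random euclidean sheaf from the shared-comparison-space family: each
# vertex carries a linear map into a common R^k; all non-vertex stalks are
# R^k with identity maps between them, so the composition law holds by
# construction.  Returns the sheaf plus a random vertex assignment.
random_sheaf_fx <- function(n_max = 5, k_max = 3) {
  n <- sample(2:n_max, 1)
  verts <- LETTERS[seq_len(n)]
  k <- sample(1:k_max, 1)
  tops <- replicate(sample(1:3, 1),
                    sample(verts, sample(2:n, 1)), simplify = FALSE)
  tops <- c(tops, as.list(setdiff(verts, unique(unlist(tops)))))
  cx <- build_complex(tops)
  dims <- stats::setNames(sample(1:3, n, replace = TRUE), verts)
  M <- lapply(dims, function(d) matrix(stats::rnorm(k * d), k, d))
  stalks <- lapply(cx$faces, function(f)
    if (length(f) == 1L) stalk_euclidean(dims[[f]]) else stalk_euclidean(k))
  ap <- attachment_pairs(cx)
  restr <- list()
  for (i in seq_len(nrow(ap))) {
    from <- ap$from[i]
    restr[[rkey(from, ap$to[i])]] <- if (from %in% verts)
      local({ Mv <- M[[from]]; function(x) as.numeric(Mv %*% x) })
    else identity
  }
  a <- lapply(dims, function(d) stats::rnorm(d, sd = 5))
  list(sheaf = sheaf(cx, stalks, restr), assignment = a)
}

# Independent consistency-radius oracle: bisection over epsilon on the
# question "does the mean extension pass both pseudosection conditions?".
radius_by_bisection_fx <- function(sh, a, tol = 1e-9) {
  ext <- extend_assignment(sh, a)
  ok <- function(eps)
    is_pseudosection(consistency_structure(sh, "epsilon", epsilon = eps), ext)
  hi <- 1
  while (!ok(hi)) hi <- hi * 2
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Random complex on up to n_max vertices plus a random consistent-face set.
random_complex_fx <- function(n_max = 6) {
  n <- sample(2:n_max, 1)
  verts <- letters[seq_len(n)]
  tops <- replicate(sample(1:4, 1),
                    sample(verts, sample(2:n, 1)), simplify = FALSE)
  tops <- c(tops, as.list(setdiff(verts, unique(unlist(tops)))))
  build_complex(tops)
}

random_consistent_fx <- function(cx, p = 0.5) {
  nv <- names(complex_faces(cx, min_dim = 1L))
  nv[stats::runif(length(nv)) < p]
}

# Independent Snyder (1987) transverse-Mercator forward formulas, WGS84.
snyder_utm_fx <- function(lat, lon, zone) {
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  phi <- lat * pi / 180
  lam0 <- (zone * 6 - 183) * pi / 180
  Nr <- a / sqrt(1 - e2 * sin(phi)^2)
  Tt <- tan(phi)^2
  Cc <- ep2 * cos(phi)^2
  A <- (lon * pi / 180 - lam0) * cos(phi)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
              (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
              (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
              (35 * e2^3 / 3072) * sin(6 * phi))
  E <- k0 * Nr * (A + (1 - Tt + Cc) * A^3 / 6 +
                    (5 - 18 * Tt + Tt^2 + 72 * Cc - 58 * ep2) * A^5 / 120) + 500000
  N <- k0 * (M + Nr * tan(phi) * (A^2 / 2 + (5 - Tt + 9 * Cc + 4 * Cc^2) * A^4 / 24 +
                                    (61 - 58 * Tt + Tt^2 + 600 * Cc - 330 * ep2) * A^6 / 720))
  c(easting = E, northing = N)
}

# Closed-form joint multivariate-normal log-likelihood of a linear-Gaussian
# state-space observation sequence (exact; independent of the Kalman
# recursion it cross-checks).
joint_loglik_fx <- function(events, spec, prior_mean, prior_var, t0) {
  Q <- diag(rep(spec$sigma[c("bear_state", "human_state")]^2, each = 2))
  blocks <- lapply(events, function(ev) observation_matrix(ev$sensors))
  Hs <- lapply(blocks, `[[`, "H")
  ys <- unlist(lapply(seq_along(events), function(i)
    as.numeric(events[[i]]$y[rownames(Hs[[i]])])))
  times <- vapply(events, `[[`, 0, "time")
  ks <- vapply(Hs, nrow, 0L)
  N <- sum(ks)
  offs <- cumsum(c(0L, ks))
  mu <- unlist(lapply(Hs, function(H) as.numeric(H %*% prior_mean)))
  Sig <- matrix(0, N, N)
  for (i in seq_along(events)) {
    for (j in seq_along(events)) {
      Cth <- diag(prior_var, 4) + Q * (min(times[i], times[j]) - t0)
      Sig[(offs[i] + 1):offs[i + 1], (offs[j] + 1):offs[j + 1]] <-
        Hs[[i]] %*% Cth %*% t(Hs[[j]])
    }
  }
  Vd <- unlist(lapply(blocks, function(b) rep(spec$sigma[b$sensors]^2, each = 2)))
  diag(Sig) <- diag(Sig) + Vd
  e <- ys - mu
  ch <- chol(Sig)
  -0.5 * (N * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(e * backsolve(ch, forwardsolve(t(ch), e))))
}

# Study-structure DLM observation schedule (vehicle GPS thinned to 120 s).
dlm_schedule_fx <- function() {
  stops <- round(cumsum(c(60, rep(330, 15))))
  rbind(data.frame(time = seq(0, 7200, 120), sensor = "vehicle_gps"),
        data.frame(time = seq(0, 7200, 900), sensor = "bear_gps"),
        data.frame(time = rep(stops, 3),
                   sensor = rep(c("vhf_gps", "street_sign", "vhf"),
                                each = length(stops))))
}
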