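# Independent brute-force oracles, written directly from the statistic
# definitions; deliberately loop-based and separate from the package's
# vectorised implementations.

bf_dist <- function(p, q, geometry = "planar") {
  if (geometry == "planar") return(sqrt(sum((p - q)^2)))
  # haversine, R = 6371 km; p, q are (lon, lat) degrees
  to_rad <- pi / 180
  dlat <- (q[2] - p[2]) * to_rad
  dlon <- (q[1] - p[1]) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(p[2] * to_rad) * cos(q[2] * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(sqrt(a))
}

bf_dc <- function(sites, clade) {
  m <- sites[sites$clade == clade, ]
  ctr <- c(mean(m$x_km), mean(m$y_km))
  mean(apply(cbind(m$x_km, m$y_km), 1, function(p) bf_dist(p, ctr)))
}

bf_dn <- function(sites, clade, nesting = unique(sites$clade)) {
  nest <- sites[sites$clade %in% nesting, ]
  ctr <- c(mean(nest$x_km), mean(nest$y_km))
  m <- sites[sites$clade == clade, ]
  mean(apply(cbind(m$x_km, m$y_km), 1, function(p) bf_dist(p, ctr)))
}

bf_mantel <- function(sites) {
  n <- nrow(sites)
  geo <- gen <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    geo <- c(geo, bf_dist(c(sites$x_km[i], sites$y_km[i]),
                          c(sites$x_km[j], sites$y_km[j])))
    gen <- c(gen, as.numeric(sites$clade[i] != sites$clade[j]))
  }
  cor(geo, gen)
}

bf_nearest_occupied <- function(x, y, state, cell_size) {
  occ <- which(state$occupancy > 0L, arr.ind = TRUE)
  best <- NULL; best_d <- Inf
  for (i in seq_len(nrow(occ))) {
    cx <- (occ[i, 2] - 0.5) * cell_size
    cy <- (occ[i, 1] - 0.5) * cell_size
    d <- sqrt((cx - x)^2 + (cy - y)^2)
    key <- c(occ[i, 1], occ[i, 2])
    if (d < best_d - 1e-12 ||
        (abs(d - best_d) <= 1e-12 &&
         (key[1] < best[1] || (key[1] == best[1] && key[2] < best[2])))) {
      best_d <- d; best <- key
    }
  }
  state$occupancy[best[1], best[2]]
}

random_sites <- function(n, n_clades = 3, seed = 1, span = 100) {
  set.seed(seed)
  labels <- CLADE_ALPHABET[seq_len(n_clades)]
  tibble::tibble(
    x_km = runif(n, 0, span), y_km = runif(n, 0, span * 0.6),
    clade = sample(labels, n, replace = TRUE)
  )
}

tiny_landscape <- function(rows = 6, cols = 12, cell_size = 5) {
  landscape(matrix(1, rows, cols), cell_size = cell_size)
}

# state with a given occupancy matrix at a given time
state_with <- function(occ, time = 0.5) {
  st <- structure(list(occupancy = occ, time = time), class = "clade_state")
  st
}
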