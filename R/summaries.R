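#' Geographic distance between points
#'
#' Planar geometry uses the Euclidean distance on km coordinates;
#' geographic geometry uses the haversine great-circle distance on WGS84
#' decimal degrees with Earth radius 6371 km.
#'
#' @param x1,y1,x2,y2 coordinates; planar: `x = x_km`, `y = y_km`;
#'   geographic: `x = lon`, `y = lat` (decimal degrees).
#' @param geometry `"planar"` or `"geographic"`.
#' @return Distances in km (vectorised).
#' @examples
#' geo_distance(0, 0, 3, 4, "planar") # 5
#' @export
geo_distance <- function(x1, y1, x2, y2,
                         geometry = c("planar", "geographic")) {
  geometry <- match.arg(geometry)
  if (geometry == "planar") {
    sqrt((x1 - x2)^2 + (y1 - y2)^2)
  } else {
    if (any(abs(c(y1, y2)) > 90) || any(abs(c(x1, x2)) > 180))
      abort("geographic coordinates out of range")
    geosphere::distHaversine(cbind(x1, y1), cbind(x2, y2), r = 6371) # km
  }
}

site_coords <- function(sites) {
  nm <- names(sites)
  planar <- all(c("x_km", "y_km") %in% nm)
  geographic <- all(c("lat", "lon") %in% nm)
  if (planar && geographic)
    abort("site table mixes planar (x_km/y_km) and geographic (lat/lon) columns")
  if (!planar && !geographic)
    abort("site table needs x_km/y_km or lat/lon columns")
  if (planar) {
    list(x = sites$x_km, y = sites$y_km, geometry = "planar")
  } else {
    list(x = sites$lon, y = sites$lat, geometry = "geographic")
  }
}

# centroid; geographic centroids go through unit vectors on the sphere
centroid_of <- function(x, y, geometry) {
  if (geometry == "planar") return(c(mean(x), mean(y)))
  lam <- x * pi / 180; phi <- y * pi / 180
  v <- c(mean(cos(phi) * cos(lam)), mean(cos(phi) * sin(lam)), mean(sin(phi)))
  if (sum(v^2) < 1e-12) abort("degenerate geographic centroid")
  c(atan2(v[2], v[1]) * 180 / pi,
    atan2(v[3], sqrt(v[1]^2 + v[2]^2)) * 180 / pi)
}

#' Clade distance Dc
#'
#' The nested-clade-analysis clade distance: the mean geographic distance
#' of a clade's individuals from the clade's own geographic centre (the
#' coordinate centroid of its members). Dc measures how widespread a clade
#' is; a single-individual clade has Dc = 0.
#'
#' @param sites site table (one row per individual) with a `clade` column
#'   and either planar (`x_km`, `y_km`) or geographic (`lat`, `lon`)
#'   coordinates.
#' @param clade clade label, must be present in `sites`.
#' @return Dc in km.
#' @export
clade_distance <- function(sites, clade) {
  cc <- site_coords(sites)
  member <- sites$clade == clade
  if (!any(member)) abort(paste0("clade not present in sites: ", clade))
  ctr <- centroid_of(cc$x[member], cc$y[member], cc$geometry)
  mean(geo_distance(cc$x[member], cc$y[member], ctr[1], ctr[2], cc$geometry))
}

#' Nested clade distance Dn
#'
#' The mean geographic distance of a clade's individuals from the
#' geographic centre of all individuals in the nesting set. Dn relative to
#' Dc captures how far a clade sits from the range of the group it is
#' nested in. With the default nesting (the full sample) the nesting
#' centre is the centroid of every sampled individual.
#'
#' @inheritParams clade_distance
#' @param nesting character vector of clade labels forming the nesting
#'   set; must contain `clade`. Default: every clade in `sites`.
#' @return Dn in km.
#' @export
nested_clade_distance <- function(sites, clade,
                                  nesting = unique(sites$clade)) {
  if (!clade %in% nesting) abort("clade must belong to its nesting set")
  missing_n <- setdiff(nesting, sites$clade)
  if (length(missing_n))
    abort(paste0("nesting clade(s) absent: ", paste(missing_n, collapse = ", ")))
  cc <- site_coords(sites)
  member <- sites$clade == clade
  if (!any(member)) abort(paste0("clade not present in sites: ", clade))
  in_nest <- sites$clade %in% nesting
  ctr <- centroid_of(cc$x[in_nest], cc$y[in_nest], cc$geometry)
  mean(geo_distance(cc$x[member], cc$y[member], ctr[1], ctr[2], cc$geometry))
}

#' Spatial autocorrelation between clade identity and geography
#'
#' Default (`method = "mantel"`): the Mantel correlation, i.e. the Pearson
#' correlation between the upper triangles of the pairwise geographic
#' distance matrix and the pairwise genetic distance matrix (0 for
#' same-clade pairs, 1 otherwise). The statistic is large when clades
#' occupy separate blocks of the landscape and small when individuals are
#' surrounded by different neighbouring clades. `method = "moran"` instead
#' averages Moran's I of each clade's presence indicator under
#' inverse-distance weights.
#'
#' @inheritParams clade_distance
#' @param method `"mantel"` (default) or `"moran"`.
#' @return The autocorrelation statistic (in `[-1, 1]`).
#' @export
spatial_autocorrelation <- function(sites, method = c("mantel", "moran")) {
  method <- match.arg(method)
  n <- nrow(sites)
  if (n < 3) abort("spatial autocorrelation needs at least 3 individuals")
  if (length(unique(sites$clade)) < 2)
    abort("spatial autocorrelation undefined: all individuals share one clade")
  cc <- site_coords(sites)
  gmat <- pairwise_geo(cc)
  if (method == "mantel") {
    ut <- upper.tri(gmat)
    gen <- outer(sites$clade, sites$clade, `!=`) * 1
    cor(gmat[ut], gen[ut])
  } else {
    w <- 1 / gmat
    diag(w) <- 0
    w[!is.finite(w)] <- 0 # coincident points carry no weight
    vals <- vapply(unique(sites$clade), function(cl) {
      ape::Moran.I(as.numeric(sites$clade == cl), w)$observed
    }, numeric(1))
    mean(vals)
  }
}

pairwise_geo <- function(cc) {
  n <- length(cc$x)
  if (cc$geometry == "planar") {
    as.matrix(stats::dist(cbind(cc$x, cc$y)))
  } else {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      d <- geo_distance(cc$x[i], cc$y[i], cc$x[j], cc$y[j], "geographic")
      m[i, j] <- d
      m[j, i] <- d
    }
    m
  }
}

#' Summary-statistic vector for ABC
#'
#' Concatenates, in a fixed layout, the clade distance Dc and nested clade
#' distance Dn of every clade in the alphabet (nesting = the full sample)
#' followed by the Mantel spatial autocorrelation. A clade absent from the
#' sample contributes 0 to its Dc/Dn slots, flagged as missing; the
#' autocorrelation of a single-clade sample is likewise encoded as 0 with
#' a missing flag. The fixed length (`2 * length(alphabet) + 1`) is what
#' makes observed and simulated vectors directly comparable.
#'
#' @inheritParams clade_distance
#' @param alphabet ordered clade labels defining the layout.
#' @return A tibble with columns `statistic`, `value`, `missing`.
#' @examples
#' sites <- tibble::tibble(x_km = c(0, 10, 40, 50), y_km = 0,
#'                         clade = c("C", "C", "F", "F"))
#' summary_vector(sites)
#' @export
summary_vector <- function(sites, alphabet = CLADE_ALPHABET) {
  if (nrow(sites) == 0) abort("empty site table")
  present <- alphabet %in% sites$clade
  dc <- dn <- numeric(length(alphabet))
  for (k in seq_along(alphabet)) {
    if (present[k]) {
      dc[k] <- clade_distance(sites, alphabet[k])
      dn[k] <- nested_clade_distance(sites, alphabet[k],
                                     nesting = intersect(alphabet, sites$clade))
    }
  }
  multi <- length(unique(sites$clade)) >= 2 && nrow(sites) >= 3
  ac <- if (multi) spatial_autocorrelation(sites) else 0
  tibble(
    statistic = c(paste0("Dc_", alphabet), paste0("Dn_", alphabet), "mantel"),
    value = c(dc, dn, ac),
    missing = c(!present, !present, !multi)
  )
}

# Fast vectorised summary computation for an ABC pool: `labels` is an
# n_sims x n_sites matrix of clade codes at fixed planar sites. Returns the
# n_sims x (2K + 1) summary matrix in summary_vector() layout. Equality
# with the per-dataset public path is asserted in the test suite.
pool_summaries <- function(labels, x, y, alphabet = CLADE_ALPHABET) {
  n_sims <- nrow(labels); n <- ncol(labels)
  K <- length(alphabet)
  d0 <- sqrt((x - mean(x))^2 + (y - mean(y))^2) # to full-sample centroid
  gmat <- as.matrix(stats::dist(cbind(x, y)))
  ut <- upper.tri(gmat)
  gsum <- sum(gmat[ut]); gss <- sum(gmat[ut]^2); n_pairs <- sum(ut)

  out <- matrix(0, n_sims, 2 * K + 1)
  nk <- matrix(0, n_sims, K)
  within_g <- matrix(0, n_sims, K) # sum of geo distances within clade pairs
  for (k in seq_len(K)) {
    I <- (labels == k) * 1
    nkk <- rowSums(I)
    nk[, k] <- nkk
    cx <- (I %*% x) / nkk
    cy <- (I %*% y) / nkk
    D <- sqrt((matrix(x, n_sims, n, byrow = TRUE) - c(cx))^2 +
              (matrix(y, n_sims, n, byrow = TRUE) - c(cy))^2)
    dc <- rowSums(I * D) / nkk
    dn <- (I %*% d0) / nkk
    dc[nkk == 0] <- 0
    dn[nkk == 0] <- 0
    out[, k] <- dc
    out[, K + k] <- dn
    within_g[, k] <- rowSums((I %*% gmat) * I) / 2
  }
  # Mantel r against the binary mismatch matrix, from sufficient statistics
  mis_pairs <- (n^2 - rowSums(nk^2)) / 2          # pairs with clade mismatch
  sxy <- gsum - rowSums(within_g)                 # sum g over mismatch pairs
  p <- mis_pairs / n_pairs
  vg <- gss / n_pairs - (gsum / n_pairs)^2
  r <- (sxy / n_pairs - (gsum / n_pairs) * p) / sqrt(vg * p * (1 - p))
  r[!is.finite(r)] <- 0
  out[, 2 * K + 1] <- r
  out
}

summary_layout <- function(alphabet = CLADE_ALPHABET) {
  c(paste0("Dc_", alphabet), paste0("Dn_", alphabet), "mantel")
}
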