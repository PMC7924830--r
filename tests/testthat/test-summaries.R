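test_that("geographic distance: closed forms and symmetry", {
  expect_equal(geo_distance(1, 2, 1, 2, "planar"), 0)
  expect_equal(geo_distance(0, 0, 3, 4, "planar"), 5)
  # quarter great circle along the equator
  expect_equal(geo_distance(0, 0, 90, 0, "geographic"), 6371 * pi / 2,
               tolerance = 1e-6)
  expect_equal(geo_distance(12, 34, 56, -7, "geographic"),
               geo_distance(56, -7, 12, 34, "geographic"))
  expect_equal(geo_distance(135.5, 34.7, 135.5, 34.7, "geographic"), 0)
  expect_error(geo_distance(0, 91, 0, 0, "geographic"), "out of range")
})

test_that("Dc: degenerate clouds and two-point symmetry", {
  one_pt <- tibble::tibble(x_km = rep(3, 4), y_km = rep(7, 4), clade = "C")
  expect_equal(clade_distance(one_pt, "C"), 0)
  two <- tibble::tibble(x_km = c(0, 10), y_km = c(0, 0), clade = "F")
  expect_equal(clade_distance(two, "F"), 5)
  expect_error(clade_distance(two, "G"), "not present")
})

test_that("Dn: equals Dc for self-nesting, 0 at the nesting centroid", {
  s <- random_sites(12, n_clades = 2, seed = 5)
  only_c <- s[s$clade == "C", ]
  expect_equal(nested_clade_distance(only_c, "C", nesting = "C"),
               clade_distance(only_c, "C"))
  # clade members sitting exactly at the full-sample centroid
  s2 <- tibble::tibble(
    x_km = c(0, 10, 5, 5), y_km = c(0, 0, 0, 0),
    clade = c("C", "C", "G", "G")
  )
  ctr <- c(mean(s2$x_km), mean(s2$y_km))
  expect_equal(ctr, c(5, 0))
  expect_equal(nested_clade_distance(s2, "G"), 0)
  expect_error(nested_clade_distance(s2, "C", nesting = "G"), "nesting")
})

test_that("Dc/Dn/Mantel match brute-force oracles on random instances", {
  for (case in 1:100) {
    n <- sample(4:25, 1)
    s <- random_sites(n, n_clades = sample(2:3, 1), seed = 1000 + case)
    s <- s[order(s$clade), ]
    present <- unique(s$clade)
    if (length(present) < 2) next
    for (cl in present) {
      expect_equal(clade_distance(s, cl), bf_dc(s, cl), tolerance = 1e-9)
      expect_equal(nested_clade_distance(s, cl), bf_dn(s, cl),
                   tolerance = 1e-9)
    }
    expect_equal(spatial_autocorrelation(s), bf_mantel(s), tolerance = 1e-9)
  }
})

test_that("Mantel statistic agrees with vegan on a random instance", {
  skip_if_not_installed("vegan")
  s <- random_sites(20, seed = 77)
  geo <- dist(cbind(s$x_km, s$y_km))
  gen <- as.dist(outer(s$clade, s$clade, `!=`) * 1)
  vg <- vegan::mantel(geo, gen, permutations = 0)
  expect_equal(spatial_autocorrelation(s), unname(vg$statistic),
               tolerance = 1e-9)
})

test_that("Mantel: block structure is positive, permutation null centres on 0", {
  blocks <- tibble::tibble(
    x_km = c(runif(10, 0, 5), runif(10, 100, 105)),
    y_km = runif(20, 0, 5),
    clade = rep(c("C", "G"), each = 10)
  )
  expect_gt(spatial_autocorrelation(blocks), 0.8)

  s <- random_sites(15, seed = 3)
  set.seed(99)
  null_stats <- replicate(1000, {
    sp <- s
    sp$clade <- sample(sp$clade)
    if (length(unique(sp$clade)) < 2) NA_real_ else spatial_autocorrelation(sp)
  })
  expect_lt(abs(mean(null_stats, na.rm = TRUE)), 0.05)

  same <- tibble::tibble(x_km = 1:5, y_km = 0, clade = "C")
  expect_error(spatial_autocorrelation(same), "one clade")
  expect_error(spatial_autocorrelation(random_sites(2, seed = 1)), "at least 3")
})

test_that("Moran's I variant stays within bounds", {
  s <- random_sites(25, seed = 8)
  mi <- spatial_autocorrelation(s, method = "moran")
  expect_true(mi >= -1 - 1e-9 && mi <= 1 + 1e-9)
})

test_that("summary vector composes the individual statistics in fixed layout", {
  s <- random_sites(18, n_clades = 3, seed = 31)
  sv <- summary_vector(s)
  expect_equal(sv$statistic,
               c("Dc_C", "Dc_F", "Dc_G", "Dn_C", "Dn_F", "Dn_G", "mantel"))
  expect_equal(nrow(sv), 2 * length(CLADE_ALPHABET) + 1)
  for (cl in c("C", "F", "G")) {
    expect_equal(sv$value[sv$statistic == paste0("Dc_", cl)],
                 clade_distance(s, cl))
    expect_equal(sv$value[sv$statistic == paste0("Dn_", cl)],
                 nested_clade_distance(s, cl))
  }
  expect_equal(sv$value[sv$statistic == "mantel"], spatial_autocorrelation(s))
  expect_false(any(sv$missing))
})

test_that("unsampled clades and single-clade samples are zero with flags", {
  s <- random_sites(10, n_clades = 1, seed = 2)
  sv <- summary_vector(s)
  expect_equal(sv$value[sv$statistic %in% c("Dc_F", "Dc_G", "Dn_F", "Dn_G")],
               rep(0, 4))
  expect_true(all(sv$missing[sv$statistic != "Dc_C" & sv$statistic != "Dn_C"]))
  expect_equal(sv$value[sv$statistic == "Dc_C"],
               sv$value[sv$statistic == "Dn_C"])
  expect_error(summary_vector(s[0, ]), "empty")
})

test_that("rigid motions leave statistics unchanged; scaling is equivariant", {
  s <- random_sites(16, seed = 13)
  rotate <- function(s, theta, dx, dy) {
    tibble::tibble(
      x_km = cos(theta) * s$x_km - sin(theta) * s$y_km + dx,
      y_km = sin(theta) * s$x_km + cos(theta) * s$y_km + dy,
      clade = s$clade
    )
  }
  for (theta in c(0.3, 1.9)) {
    sr <- rotate(s, theta, -40, 17)
    for (cl in unique(s$clade)) {
      expect_equal(clade_distance(sr, cl), clade_distance(s, cl),
                   tolerance = 1e-9)
      expect_equal(nested_clade_distance(sr, cl), nested_clade_distance(s, cl),
                   tolerance = 1e-9)
    }
    expect_equal(spatial_autocorrelation(sr), spatial_autocorrelation(s),
                 tolerance = 1e-9)
  }
  sc <- s
  sc$x_km <- s$x_km * 3.5
  sc$y_km <- s$y_km * 3.5
  expect_equal(clade_distance(sc, "C"), 3.5 * clade_distance(s, "C"))
  expect_equal(nested_clade_distance(sc, "C"),
               3.5 * nested_clade_distance(s, "C"))
  expect_equal(spatial_autocorrelation(sc), spatial_autocorrelation(s),
               tolerance = 1e-9)
})

test_that("geographic Dc/Dn use great-circle metric and spherical centroid", {
  s <- tibble::tibble(
    lon = c(130.5, 131.2, 132.0, 133.4, 134.1, 135.0),
    lat = c(33.2, 33.9, 34.4, 34.0, 33.5, 34.8),
    clade = c("C", "C", "F", "F", "G", "G")
  )
  # oracle: same definition computed from scratch on the sphere
  for (cl in c("C", "F", "G")) {
    m <- s[s$clade == cl, ]
    lam <- m$lon * pi / 180; phi <- m$lat * pi / 180
    v <- c(mean(cos(phi) * cos(lam)), mean(cos(phi) * sin(lam)), mean(sin(phi)))
    ctr <- c(atan2(v[2], v[1]), atan2(v[3], sqrt(v[1]^2 + v[2]^2))) * 180 / pi
    ora <- mean(sapply(seq_len(nrow(m)), function(i)
      bf_dist(c(m$lon[i], m$lat[i]), ctr, "geographic")))
    expect_equal(clade_distance(s, cl), ora, tolerance = 1e-6)
  }
})
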