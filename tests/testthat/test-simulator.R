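test_that("initial state saturates every habitable cell with clade C", {
  land <- tiny_landscape(10, 10)
  st <- initialize_state(land, sim_params(0.9, 0.5, 20, 0.8))
  expect_equal(st$time, 1.52)
  expect_equal(unname(clade_counts(st)), c(100L, 0L, 0L))

  mask <- matrix(0L, 10, 10)
  mask[3:5, 1:10] <- 1L
  land2 <- landscape(mask, cell_size = 5)
  st2 <- initialize_state(land2, sim_params(0.9, 0.5, 20, 0.8))
  expect_equal(sum(st2$occupancy == 1L), 30)
  expect_true(all(st2$occupancy[mask == 0L] == 0L))

  expect_error(landscape(matrix(0L, 4, 4), 5), "no habitable")
})

test_that("parameter validation enforces ordering and ranges", {
  expect_error(sim_params(1.4, 0.5, 20, 0.8), "r < t_F")
  expect_error(sim_params(0.9, 0.5, 20, 1.2), "alpha")
  expect_error(sim_params(0.9, -1, 20, 0.5), "m")
  expect_error(sim_params(0.9, 0.5, 0, 0.5), "s")
  expect_error(sim_params(0.9, 0.5, 20, 0.5, dt = 0), "dt")
})

test_that("clade introduction colonises empty cells and replaces by alpha", {
  land <- tiny_landscape(4, 8)
  p <- sim_params(0.9, 0.5, 20, 0.8)

  # empty entry cells: colonisation is certain for any alpha
  empty <- state_with(matrix(0L, 4, 8))
  set.seed(1)
  st <- introduce_clade(empty, "G", land, alpha = 0)
  expect_true(all(st$occupancy[land$entry + 1L] == 3L))

  # occupied by an older clade: alpha = 1 always takes, alpha = 0 never
  full_f <- state_with(matrix(2L, 4, 8) * land$mask)
  set.seed(1)
  st1 <- introduce_clade(full_f, "G", land, alpha = 1)
  expect_true(all(st1$occupancy[land$entry + 1L] == 3L))
  set.seed(1)
  st0 <- introduce_clade(full_f, "G", land, alpha = 0)
  expect_true(all(st0$occupancy[land$entry + 1L] == 2L))

  expect_error(introduce_clade(full_f, "Z", land, 0.5), "unknown clade")
})

test_that("dispersal kernel: degenerate at m = 0, gamma mean m * dt", {
  land <- tiny_landscape(20, 20, cell_size = 5)
  p0 <- sim_params(0.9, 0, 20, 0.8)
  set.seed(1)
  ev <- draw_dispersal(c(10L, 10L), p0, land)
  expect_equal(ev$distance, 0)
  expect_equal(c(ev$target_row, ev$target_col), c(10L, 10L))

  # sub-half-cell distances always round back to the source cell
  p <- sim_params(0.9, 0.345, 20.2, 0.8)
  set.seed(42)
  stays <- purrr::map_dfr(1:400, ~draw_dispersal(c(10L, 10L), p, land))
  short <- stays[stays$distance < land$cell_size / 2, ]
  expect_gt(nrow(short), 0)
  expect_true(all(short$target_row == 10L & short$target_col == 10L))

  # Monte-Carlo mean of the kernel equals m * dt within 3 SE
  set.seed(7)
  d <- rgamma(10000, shape = 0.345 * 1 / 20.2, scale = 20.2)
  expect_lt(abs(mean(d) - 0.345), 3 * sd(d) / sqrt(10000))
})

test_that("thinned table sampler matches the closed-form conditional gamma", {
  m <- 0.345; s <- 20.2; cell <- 5
  k <- m / s; thr <- cell / 2
  cond_mean <- k * s * (1 - pgamma(thr, k + 1, scale = s)) /
    (1 - pgamma(thr, k, scale = s))
  set.seed(11)
  x <- cladewave:::cpp_sample_conditional(50000, m, s, 1, cell)
  expect_true(all(x >= thr))
  expect_lt(abs(mean(x) - cond_mean), 3 * sd(x) / sqrt(length(x)))
  # quantiles agree with the exact conditional inverse CDF
  p_stay <- pgamma(thr, k, scale = s)
  for (q in c(0.1, 0.5, 0.9)) {
    expect_equal(unname(quantile(x, q)),
                 qgamma(p_stay + (1 - p_stay) * q, k, scale = s),
                 tolerance = 0.05)
  }
})

test_that("alpha = 0 freezes a fully occupied mosaic", {
  land <- tiny_landscape(6, 12)
  occ <- matrix(sample(c(1L, 2L), 72, replace = TRUE), 6, 12)
  st <- state_with(occ, time = 0.5)
  p <- sim_params(0.4, 1, 10, 0)
  set.seed(3)
  counts0 <- clade_counts(st)
  for (i in 1:50) st <- sim_step(st, p, land)
  expect_identical(clade_counts(st), counts0)
  expect_identical(st$occupancy, occ)
})

test_that("alpha = 1 newest-clade invasion is non-decreasing", {
  land <- tiny_landscape(8, 8)
  occ <- matrix(2L, 8, 8)
  occ[4, 4] <- 3L
  st <- state_with(occ, time = 0.5)
  p <- sim_params(0.4, 5, 10, 1) # large m: long jumps
  set.seed(9)
  g <- sum(st$occupancy == 3L)
  for (i in 1:60) {
    st <- sim_step(st, p, land)
    g_new <- sum(st$occupancy == 3L)
    expect_gte(g_new, g)
    g <- g_new
  }
})

test_that("occupation is monotone and labels stay in the alphabet", {
  land <- make_landscape(8, 16, cell_size = 5, corridor_fraction = 0.75)
  p <- sim_params(0.9, 1, 10, 0.6)
  st <- initialize_state(land, p)
  occ0 <- matrix(0L, 8, 16)
  occ0[land$entry[, 1] + 1L, 1] <- 1L # sparse start: entry column only
  st$occupancy <- occ0 * land$mask
  set.seed(5)
  occupied <- sum(st$occupancy > 0L)
  for (i in 1:80) {
    st <- sim_step(st, p, land)
    expect_true(all(st$occupancy %in% 0:3))
    expect_true(all(st$occupancy[land$mask == 0L] == 0L))
    now <- sum(st$occupancy > 0L)
    expect_gte(now, occupied)
    occupied <- now
  }
})

test_that("full simulation is deterministic given the seed", {
  land <- make_landscape(10, 20, cell_size = 5, corridor_fraction = 0.8)
  p <- sim_params(0.9, 0.5, 20, 0.8)
  a <- run_simulation(land, p, seed = 123)
  b <- run_simulation(land, p, seed = 123)
  expect_identical(a$occupancy, b$occupancy)
  expect_equal(a$time, 0)
  bad <- p
  bad$r <- 1.4 # past t_F: the schedule is invalid
  expect_error(run_simulation(land, bad, seed = 1), "t_F")
})

test_that("higher replacement rate yields larger final G range", {
  # landscape large enough that certain replacement rarely saturates it
  # (saturation at both rates would tie the comparison)
  land <- default_fixture()$landscape
  wins <- 0
  for (seed in 1:50) {
    g_lo <- clade_counts(run_simulation(land, sim_params(0.9, 0.5, 20, 0.5),
                                        seed = seed))[["G"]]
    g_hi <- clade_counts(run_simulation(land, sim_params(0.9, 0.5, 20, 0.95),
                                        seed = seed))[["G"]]
    wins <- wins + (g_hi > g_lo)
  }
  expect_gte(wins, 45) # >= 90% of paired seeds
})

test_that("immediate migration with m = 0 leaves G in entry cells only", {
  land <- tiny_landscape(6, 12)
  p <- sim_params(0.001, 0, 20, 1)
  st <- run_simulation(land, p, seed = 4)
  g_cells <- which(st$occupancy == 3L, arr.ind = TRUE) - 1L
  expect_setequal(paste(g_cells[, 1], g_cells[, 2]),
                  paste(land$entry[, 1], land$entry[, 2]))
})

test_that("site sampling matches brute-force nearest-occupied-cell search", {
  land <- tiny_landscape(8, 10, cell_size = 4)
  set.seed(21)
  occ <- matrix(sample(0:3, 80, replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.2)),
                8, 10)
  st <- state_with(occ, time = 0)
  sites <- tibble::tibble(x_km = runif(50, 0, 40), y_km = runif(50, 0, 32))
  got <- sample_sites(st, sites, land)
  for (i in 1:50) {
    expect_identical(
      got$clade[i],
      clade_label(bf_nearest_occupied(sites$x_km[i], sites$y_km[i], st,
                                      land$cell_size))
    )
  }
  # a site at the exact centre of an occupied cell takes that cell's clade
  first_occ <- which(occ > 0L, arr.ind = TRUE)[1, ]
  centre <- sample_sites(
    st,
    tibble::tibble(x_km = (first_occ[2] - 0.5) * 4,
                   y_km = (first_occ[1] - 0.5) * 4),
    land
  )
  expect_identical(centre$clade, clade_label(occ[first_occ[1], first_occ[2]]))
  expect_equal(centre$assign_km, 0)

  expect_error(sample_sites(state_with(matrix(0L, 8, 10)), sites, land),
               "no occupied")
})

test_that("uniform all-C state labels every site C", {
  land <- tiny_landscape(5, 5)
  st <- initialize_state(land, sim_params(0.9, 0.5, 20, 0.8))
  sites <- tibble::tibble(x_km = runif(10, 0, 25), y_km = runif(10, 0, 25))
  expect_true(all(sample_sites(st, sites, land)$clade == "C"))
})
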