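#' Simulation parameters for the clade-replacement model
#'
#' The model has four free parameters: `r`, the migration time of the last
#' clade (G) in Ma before present; `m`, the dispersal rate in km/Kyr; `s`,
#' the scale of the gamma dispersal kernel in km; and `alpha`, the
#' replacement rate: the probability that a migrant of a later-arriving
#' clade displaces an earlier-arriving resident on contact (arrival order
#' C, then F, then G; contests in the opposite direction fail, so
#' `alpha = 0` freezes all clade boundaries and `alpha = 0.5` is the
#' neutral reference value). The
#' schedule constants are fixed: clade F migrates at `t_F = 1.31` Ma and
#' the simulation starts from a saturated clade-C landscape at
#' `t_start = 1.52` Ma. Per occupied cell and time step `dt` (Kyr) one
#' dispersal event is drawn with distance `~ Gamma(shape = m * dt / s,
#' scale = s)`, so the mean displacement per Kyr equals `m` km, and a
#' uniform bearing.
#'
#' @param r migration time of clade G (Ma), `0 < r < t_F`.
#' @param m dispersal rate (km/Kyr), `>= 0`.
#' @param s gamma scale parameter (km), `> 0`.
#' @param alpha replacement rate in `[0, 1]`.
#' @param t_F migration time of clade F (Ma).
#' @param t_start simulation start / clade-C saturation time (Ma).
#' @param dt time step (Kyr), `> 0`.
#' @return A `sim_params` list.
#' @examples
#' sim_params(r = 0.862, m = 0.345, s = 20.2, alpha = 0.774)
#' @export
sim_params <- function(r, m, s, alpha, t_F = 1.31, t_start = 1.52, dt = 1) {
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  if (m < 0) abort("m must be >= 0")
  if (s <= 0) abort("s must be > 0")
  if (dt <= 0) abort("dt must be > 0")
  if (!(r > 0 && r < t_F && t_F < t_start))
    abort("need 0 < r < t_F < t_start")
  structure(list(r = r, m = m, s = s, alpha = alpha,
                 t_F = t_F, t_start = t_start, dt = dt),
            class = "sim_params")
}

new_state <- function(occupancy, time) {
  structure(list(occupancy = occupancy, time = time), class = "clade_state")
}

#' @export
print.clade_state <- function(x, ...) {
  counts <- clade_counts(x)
  cat(sprintf("<clade_state> t = %.4g Ma; %s\n", x$time,
              paste(names(counts), counts, sep = "=", collapse = " ")))
  invisible(x)
}

#' Per-clade occupied-cell counts of a simulation state
#' @param state a `clade_state`.
#' @param alphabet ordered clade labels.
#' @return Named integer vector of cell counts per clade.
#' @export
clade_counts <- function(state, alphabet = CLADE_ALPHABET) {
  occ <- state$occupancy
  setNames(vapply(seq_along(alphabet),
                  function(k) sum(occ == k), integer(1)), alphabet)
}

#' Tidy a simulation state into a cell table
#'
#' @param x a `clade_state`.
#' @param landscape optionally, the `clade_landscape` the state lives on;
#'   when given, empty habitable cells are included as `"EMPTY"` rows.
#' @param ... unused.
#' @return Tibble with 0-based `row`, `col` and `clade`.
#' @export
tidy.clade_state <- function(x, landscape = NULL, ...) {
  if (is.null(landscape)) {
    idx <- which(x$occupancy > 0L, arr.ind = TRUE)
  } else {
    idx <- which(landscape$mask == 1L, arr.ind = TRUE)
  }
  tibble(
    row = idx[, 1] - 1L, col = idx[, 2] - 1L,
    clade = clade_label(as.integer(x$occupancy[idx]))
  ) |> dplyr::arrange(.data$row, .data$col)
}

#' Initial simulation state: clade C everywhere
#'
#' The initial condition of the model is a universal distribution of the
#' resident clade C over every habitable cell at `t_start`.
#'
#' @param landscape a `clade_landscape`.
#' @param params a `sim_params`.
#' @return A `clade_state` at `time = t_start`.
#' @export
initialize_state <- function(landscape, params) {
  occ <- landscape$mask # 1 = clade C on habitable, 0 elsewhere
  new_state(occ, params$t_start)
}

#' Introduce a migrating clade at the entry cells
#'
#' Each entry cell is colonised with probability 1 when empty, and taken
#' over with probability `alpha` when held by an earlier-arriving clade.
#'
#' @param state a `clade_state`.
#' @param clade clade label to introduce.
#' @param landscape a `clade_landscape`.
#' @param alpha replacement probability in `[0, 1]`.
#' @param alphabet ordered clade labels.
#' @return The updated `clade_state`.
#' @export
introduce_clade <- function(state, clade, landscape, alpha,
                            alphabet = CLADE_ALPHABET) {
  code <- clade_code(clade, alphabet)
  occ <- cpp_simulate(state$occupancy, landscape$mask,
                      landscape$cell_size, 0, 1, alpha, 1, 0L,
                      0L, code, landscape$entry)
  new_state(occ, state$time)
}

#' Draw a single dispersal event
#'
#' Distance `~ Gamma(shape = m * dt / s, scale = s)` (degenerate at 0 when
#' `m = 0`), bearing uniform on `[0, 2 * pi)`; the target is the habitable
#' cell nearest the displaced point, or `NA` (off landscape) when that
#' lattice cell is not habitable.
#'
#' @param source length-2 integer `(row, col)`, 0-based.
#' @inheritParams introduce_clade
#' @param params a `sim_params`.
#' @return One-row tibble with `distance`, `bearing`, `target_row`,
#'   `target_col` (`NA` when the event falls off the landscape).
#' @export
draw_dispersal <- function(source, params, landscape) {
  cs <- landscape$cell_size
  d <- if (params$m == 0) 0 else
    rgamma(1, shape = params$m * params$dt / params$s, scale = params$s)
  theta <- runif(1, 0, 2 * pi)
  tc <- floor(source[2] + 0.5 + d * cos(theta) / cs)
  tr <- floor(source[1] + 0.5 + d * sin(theta) / cs)
  ok <- tr >= 0 && tr < nrow(landscape$mask) &&
    tc >= 0 && tc < ncol(landscape$mask) &&
    landscape$mask[tr + 1, tc + 1] == 1L
  tibble(distance = d, bearing = theta,
         target_row = if (ok) as.integer(tr) else NA_integer_,
         target_col = if (ok) as.integer(tc) else NA_integer_)
}

#' Advance the simulation by one time step
#'
#' Synchronous update: every occupied cell (read from a frozen copy of the
#' state) draws one dispersal event; a migrant reaching a cell held by an
#' earlier-arriving clade replaces the resident with probability `alpha`,
#' an empty habitable cell is colonised with probability 1, and same-clade,
#' older-onto-newer or off-landscape events are no-ops. Events are applied
#' sequentially against the live state, so conflicting arrivals resolve in
#' application order. Time decreases by `dt`.
#'
#' @inheritParams draw_dispersal
#' @param state a `clade_state`.
#' @return The updated `clade_state`.
#' @export
sim_step <- function(state, params, landscape) {
  occ <- cpp_simulate(state$occupancy, landscape$mask, landscape$cell_size,
                      params$m, params$s, params$alpha, params$dt, 1L,
                      integer(0), integer(0), landscape$entry)
  new_state(occ, state$time - params$dt / 1000)
}

#' Run the full migration-and-replacement simulation
#'
#' Starts from a clade-C-saturated landscape at `t_start`, steps `dt` at a
#' time down to the present, and introduces clade F at the step nearest
#' `t_F` and clade G at the step nearest `r`. Deterministic given
#' `(landscape, params, seed)`.
#'
#' @inheritParams draw_dispersal
#' @param seed integer RNG seed.
#' @return The final `clade_state` at `time = 0`.
#' @examples
#' land <- make_landscape(8, 16, cell_size = 5)
#' st <- run_simulation(land, sim_params(0.9, 0.5, 20, 0.8), seed = 1)
#' clade_counts(st)
#' @export
run_simulation <- function(landscape, params, seed) {
  if (params$r >= params$t_F) abort("need r < t_F")
  set.seed(seed)
  n_steps <- as.integer(round(params$t_start * 1000 / params$dt))
  step_of <- function(t_ma) {
    min(n_steps - 1L,
        max(0L, as.integer(round((params$t_start - t_ma) * 1000 / params$dt))))
  }
  intro_steps <- c(step_of(params$t_F), step_of(params$r))
  intro_clades <- clade_code(c("F", "G"))
  init <- initialize_state(landscape, params)
  occ <- cpp_simulate(init$occupancy, landscape$mask, landscape$cell_size,
                      params$m, params$s, params$alpha, params$dt, n_steps,
                      intro_steps, intro_clades, landscape$entry)
  st <- new_state(occ, 0)
  attr(st, "seed") <- seed
  st
}

#' Assign simulated clades to sampling sites
#'
#' Observation operator matching a final simulated state to a sampling
#' design: each site receives the clade of the nearest occupied cell
#' (planar distance to cell centres; ties broken by lowest `(row, col)`),
#' and the site-to-cell distance is recorded.
#'
#' @param state a final `clade_state`.
#' @param sites data frame with planar coordinates `x_km`, `y_km` (and
#'   optionally `site_id`).
#' @param landscape a `clade_landscape`.
#' @return `sites` as a tibble with `clade` and `assign_km` columns.
#' @export
sample_sites <- function(state, sites, landscape) {
  occ_idx <- which(state$occupancy > 0L, arr.ind = TRUE)
  if (nrow(occ_idx) == 0) abort("no occupied cells to sample from")
  cell_idx <- nearest_cell(sites$x_km, sites$y_km, occ_idx, landscape$cell_size)
  codes <- state$occupancy[occ_idx[cell_idx$nearest, , drop = FALSE]]
  sites <- as_tibble(sites)
  if (!"site_id" %in% names(sites)) sites$site_id <- seq_len(nrow(sites))
  sites$clade <- clade_label(as.integer(codes))
  sites$assign_km <- cell_idx$dist
  sites
}

# nearest candidate cell per site; candidates is a (n x 2) 1-based
# arr.ind matrix ordered by (row, col) as produced by which()
nearest_cell <- function(x, y, candidates, cell_size) {
  cx <- (candidates[, 2] - 0.5) * cell_size
  cy <- (candidates[, 1] - 0.5) * cell_size
  nearest <- integer(length(x))
  dist <- numeric(length(x))
  ord <- order(candidates[, 1] - 1L, candidates[, 2] - 1L) # tie preference
  for (i in seq_along(x)) {
    d2 <- (cx - x[i])^2 + (cy - y[i])^2
    best <- ord[which.min(d2[ord])]
    nearest[i] <- best
    dist[i] <- sqrt(d2[best])
  }
  list(nearest = nearest, dist = dist)
}
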