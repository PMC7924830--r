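#' Independent uniform prior ranges for the model parameters
#'
#' Priors are independent uniforms on `r` (Ma, bounded above by the fixed
#' clade-F migration time), `m` (km/Kyr), `s` (km) and `alpha`.
#'
#' @param r,m,s,alpha length-2 numeric `(lo, hi)` ranges.
#' @param t_F fixed clade-F migration time (Ma); `r` must stay below it.
#' @return A `prior_spec` list.
#' @examples
#' prior_spec()
#' @export
prior_spec <- function(r = c(0.3, 1.3), m = c(0, 2), s = c(1, 60),
                       alpha = c(0, 1), t_F = 1.31) {
  spec <- list(r = r, m = m, s = s, alpha = alpha)
  for (nm in names(spec)) {
    rng <- spec[[nm]]
    if (length(rng) != 2 || !all(is.finite(rng)) || rng[1] >= rng[2])
      abort(paste0("prior range for ", nm, " must be an ordered (lo, hi) pair"))
  }
  if (spec$r[2] >= t_F) abort("upper prior bound for r must be < t_F")
  if (spec$alpha[1] < 0 || spec$alpha[2] > 1)
    abort("alpha prior must stay within [0, 1]")
  if (spec$m[1] < 0) abort("m prior must be non-negative")
  if (spec$s[1] <= 0) abort("s prior must be positive")
  structure(c(spec, list(t_F = t_F)), class = "prior_spec")
}

#' Draw parameter sets from the prior
#'
#' @param spec a [prior_spec()].
#' @param n number of draws.
#' @param seed integer RNG seed.
#' @return Tibble with columns `r`, `m`, `s`, `alpha`.
#' @export
sample_prior <- function(spec, n, seed) {
  if (n < 1) abort("n must be >= 1")
  set.seed(seed)
  tibble(
    r = runif(n, spec$r[1], spec$r[2]),
    m = runif(n, spec$m[1], spec$m[2]),
    s = runif(n, spec$s[1], spec$s[2]),
    alpha = runif(n, spec$alpha[1], spec$alpha[2])
  )
}

#' Rejection-ABC estimation of the replacement-model parameters
#'
#' Simulates the clade-formation process once per prior draw on the same
#' landscape and sampling design as the observed data, summarises each
#' simulation with [summary_vector()] statistics, standardises every
#' summary coordinate by its median absolute deviation across the
#' simulations, and accepts the prior draws whose standardised Euclidean
#' distance to the observed summary vector falls in the smallest
#' `tolerance` quantile. Point estimates are posterior medians with
#' central 95% credible intervals; `p_neutral` is the accepted-sample
#' probability that `alpha <= 0.5`.
#'
#' @param observed_sites site table (planar `x_km`/`y_km` plus `clade`);
#'   its coordinates define the sampling design used for every simulation.
#' @param landscape the `clade_landscape` shared by all simulations.
#' @param prior a [prior_spec()].
#' @param n_sims number of prior draws / simulations.
#' @param tolerance acceptance quantile in (0, 1].
#' @param seed master integer seed; per-simulation child seeds are spawned
#'   from it by counter and recorded in the result.
#' @param t_F,t_start,dt schedule constants passed to [sim_params()].
#' @param alphabet ordered clade labels.
#' @return A `clade_abc` object; see [tidy.clade_abc()], [glance.clade_abc()],
#'   [test_neutrality()] and [posterior_report()].
#' @examples
#' \donttest{
#' land <- make_landscape(10, 24, cell_size = 5)
#' truth <- sim_params(0.9, 0.5, 20, 0.8)
#' obs <- generate_observed_dataset(land, truth, n_sites = 40, seed = 7)
#' fit <- abc_rejection(obs$sites, land, prior_spec(),
#'                      n_sims = 50, tolerance = 0.2, seed = 1)
#' glance(fit)
#' }
#' @export
abc_rejection <- function(observed_sites, landscape, prior = prior_spec(),
                          n_sims = 2000, tolerance = 0.005, seed = 1L,
                          t_F = prior$t_F, t_start = 1.52, dt = 1,
                          alphabet = CLADE_ALPHABET) {
  if (tolerance <= 0 || tolerance > 1) abort("tolerance must be in (0, 1]")
  n_acc <- ceiling(tolerance * n_sims)
  if (n_acc < 20)
    warn("fewer than 20 accepted draws: posterior quantiles will be unstable")

  cc <- site_coords(observed_sites)
  if (cc$geometry != "planar")
    abort("ABC simulations require planar site coordinates (x_km/y_km)")
  obs_tbl <- summary_vector(observed_sites, alphabet)
  obs_vec <- obs_tbl$value

  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_sims + 1L)
  draws <- sample_prior(prior, n_sims, seed = child_seeds[n_sims + 1L])

  # sampling design fixed across simulations: precompute site -> cell map
  # (every habitable cell is occupied from the start, so the nearest
  # occupied cell is the nearest habitable cell throughout)
  hab_idx <- which(landscape$mask == 1L, arr.ind = TRUE)
  site_cell <- nearest_cell(cc$x, cc$y, hab_idx, landscape$cell_size)$nearest
  cell_lin <- (hab_idx[site_cell, 2] - 1L) * nrow(landscape$mask) +
    hab_idx[site_cell, 1]

  labels <- matrix(0L, n_sims, nrow(observed_sites))
  for (i in seq_len(n_sims)) {
    p <- sim_params(draws$r[i], draws$m[i], draws$s[i], draws$alpha[i],
                    t_F = t_F, t_start = t_start, dt = dt)
    st <- run_simulation(landscape, p, seed = child_seeds[i])
    labels[i, ] <- st$occupancy[cell_lin]
  }
  sims <- pool_summaries(labels, cc$x, cc$y, alphabet)
  colnames(sims) <- summary_layout(alphabet)

  # MAD-standardised coordinates; a zero MAD with positive variance
  # (zero-inflated statistics such as Dc of an often-extinct clade) falls
  # back to the standard deviation, and only truly constant coordinates
  # are dropped
  scale <- apply(sims, 2, mad)
  sds <- apply(sims, 2, stats::sd)
  scale[scale == 0] <- sds[scale == 0]
  keep <- scale > 0
  if (!all(keep))
    warn(paste0("dropping zero-variance summary coordinate(s): ",
                paste(colnames(sims)[!keep], collapse = ", ")))
  if (!any(keep)) abort("every summary coordinate has zero variance")
  z <- sweep(sims[, keep, drop = FALSE], 2, scale[keep], `/`)
  z_obs <- obs_vec[keep] / scale[keep]
  dist <- sqrt(colSums((t(z) - z_obs)^2))

  acc_idx <- order(dist)[seq_len(n_acc)]
  accepted <- draws[acc_idx, ]
  accepted$distance <- dist[acc_idx]

  pars <- c("r", "m", "s", "alpha")
  point <- vapply(pars, function(p) median(accepted[[p]]), numeric(1))
  ci95 <- vapply(pars, function(p)
    unname(quantile(accepted[[p]], c(0.025, 0.975))), numeric(2))
  structure(list(
    accepted = as_tibble(accepted),
    draws = draws, distances = dist,
    observed = obs_tbl, sim_summaries = sims, summary_scale = scale,
    n_sims = n_sims, tolerance = tolerance,
    point = point, ci95 = ci95,
    p_neutral = mean(accepted$alpha <= 0.5),
    seed = seed, child_seeds = child_seeds,
    prior = prior,
    schedule = list(t_F = t_F, t_start = t_start, dt = dt)
  ), class = "clade_abc")
}

#' @export
print.clade_abc <- function(x, ...) {
  cat(sprintf("<clade_abc> %d simulations, tolerance %.3g (%d accepted)\n",
              x$n_sims, x$tolerance, nrow(x$accepted)))
  for (p in c("r", "m", "s", "alpha")) {
    cat(sprintf("  %-5s %.3g (%.3g-%.3g)\n", p, x$point[[p]],
                x$ci95[1, p], x$ci95[2, p]))
  }
  cat(sprintf("  P(alpha <= 0.5 | accepted) = %.3g\n", x$p_neutral))
  invisible(x)
}

#' Tidy the accepted posterior draws
#' @param x a `clade_abc` fit.
#' @param ... unused.
#' @return Tibble of accepted draws (`r`, `m`, `s`, `alpha`, `distance`).
#' @export
tidy.clade_abc <- function(x, ...) x$accepted

#' One-row summary of a rejection-ABC fit
#' @param x a `clade_abc` fit.
#' @param ... unused.
#' @return One-row tibble with posterior medians, 95% credible bounds,
#'   `p_neutral`, `n_sims`, `n_accepted` and `tolerance`.
#' @export
glance.clade_abc <- function(x, ...) {
  pars <- c("r", "m", "s", "alpha")
  est <- purrr::map(pars, function(p) {
    tibble::tibble_row(!!!setNames(
      list(x$point[[p]], x$ci95[1, p], x$ci95[2, p]),
      paste0(p, c("_median", "_lo", "_hi"))
    ))
  })
  dplyr::bind_cols(est,
                   tibble(p_neutral = x$p_neutral, n_sims = x$n_sims,
                          n_accepted = nrow(x$accepted),
                          tolerance = x$tolerance, seed = x$seed))
}

#' Test the neutral-replacement null alpha = 0.5
#'
#' Reports `p_neutral`, the accepted-sample probability that
#' `alpha <= null_value`, and rejects neutrality exactly when the central
#' 95% credible interval for `alpha` lies entirely above the null -- i.e.
#' the data support replacement beyond neutral drift.
#'
#' @param posterior a `clade_abc` fit.
#' @param null_value neutral replacement rate (default 0.5).
#' @param level credibility level of the interval (default 0.05 => 95%).
#' @return One-row tibble with `p_neutral`, the interval, and `reject`.
#' @export
test_neutrality <- function(posterior, null_value = 0.5, level = 0.05) {
  a <- posterior$accepted$alpha
  if (length(a) == 0) abort("empty posterior")
  ci <- unname(quantile(a, c(level / 2, 1 - level / 2)))
  tibble(
    null_value = null_value,
    p_neutral = mean(a <= null_value),
    alpha_median = median(a),
    ci_lo = ci[1], ci_hi = ci[2],
    reject = ci[1] > null_value
  )
}

#' Serialise / restore a posterior report
#'
#' Writes point estimates, 95% intervals, the neutrality probability and
#' the run metadata to JSON in the fixed parameter order `r, m, s, alpha`;
#' numbers round-trip losslessly.
#'
#' @param posterior a `clade_abc` fit.
#' @param path optional JSON output path; when `NULL` the report list is
#'   returned without writing.
#' @return The report as a list, invisibly when written.
#' @export
posterior_report <- function(posterior, path = NULL) {
  pars <- c("r", "m", "s", "alpha")
  report <- list(
    parameters = purrr::map(setNames(pars, pars), function(p) list(
      point = unname(posterior$point[[p]]),
      ci95 = c(posterior$ci95[1, p], posterior$ci95[2, p])
    )),
    p_neutral = posterior$p_neutral,
    n_sims = posterior$n_sims,
    tolerance = posterior$tolerance,
    seed = posterior$seed
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17))
    return(invisible(report))
  }
  report
}

#' @rdname posterior_report
#' @export
read_posterior_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
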