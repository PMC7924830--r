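#' Read a sampling-site table
#'
#' CSV with a mandatory header, one row per sampled individual. Geometry
#' is auto-detected from the coordinate columns: planar tables carry
#' `x_km`/`y_km`, geographic tables `lat`/`lon` (WGS84 decimal degrees);
#' a file carrying both conventions is rejected. Every row must have a
#' non-empty `clade` label.
#'
#' @param path CSV file path.
#' @return Tibble with `site_id`, coordinates and `clade`; the detected
#'   geometry is attached as attribute `"geometry"`.
#' @export
read_sites <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) abort("site table has no rows")
  cc <- site_coords(raw) # validates the coordinate convention
  if (is.null(raw$clade)) abort("site table needs a clade column")
  bad <- which(is.na(raw$clade) | trimws(raw$clade) == "")
  if (length(bad))
    abort(paste0("missing clade label on data line(s): ",
                 paste(bad, collapse = ", ")))
  if (cc$geometry == "geographic" &&
      (any(abs(raw$lat) > 90) || any(abs(raw$lon) > 180)))
    abort("geographic coordinates out of range")
  out <- as_tibble(raw)
  if (!"site_id" %in% names(out)) out$site_id <- seq_len(nrow(out))
  attr(out, "geometry") <- cc$geometry
  out
}

#' @rdname read_sites
#' @param sites site tibble.
#' @export
write_sites <- function(sites, path) {
  write.csv(sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the full result set of an ABC analysis
#'
#' Writes `posterior.json` (the [posterior_report()]),
#' `accepted_draws.csv`, optionally `final_state.csv` (0-based
#' `row, col, clade`) and `config_echo.yaml` with everything needed to
#' re-run the analysis, into `outdir`.
#'
#' @param posterior a `clade_abc` fit.
#' @param outdir output directory (created if absent).
#' @param state optional final `clade_state` to dump.
#' @param config optional config list echoed as YAML.
#' @param force overwrite existing files.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(posterior, outdir, state = NULL, config = NULL,
                          force = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(outdir, c("posterior.json", "accepted_draws.csv"))
  if (!is.null(state)) files <- c(files, file.path(outdir, "final_state.csv"))
  if (!is.null(config)) files <- c(files, file.path(outdir, "config_echo.yaml"))
  clash <- files[file.exists(files)]
  if (length(clash) && !force)
    abort(paste0("output exists (use force = TRUE): ",
                 paste(basename(clash), collapse = ", ")))
  posterior_report(posterior, file.path(outdir, "posterior.json"))
  write.csv(posterior$accepted, file.path(outdir, "accepted_draws.csv"),
            row.names = FALSE)
  if (!is.null(state))
    write.csv(tidy(state), file.path(outdir, "final_state.csv"),
              row.names = FALSE)
  if (!is.null(config))
    yaml::write_yaml(config, file.path(outdir, "config_echo.yaml"))
  invisible(files)
}
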