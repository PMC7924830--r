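#' Construct a habitable-lattice landscape
#'
#' A landscape is a rectangular lattice of square cells, each habitable or
#' not, with a metric cell size and an ordered set of entry cells -- the
#' cells standing for the land-bridge end through which each migration wave
#' enters. Simulation geometry is planar: the centre of cell (row, col)
#' (0-based) sits at `((col + 0.5) * cell_size, (row + 0.5) * cell_size)` km.
#'
#' @param mask integer/logical matrix; `TRUE`/`1` marks habitable cells.
#' @param cell_size cell edge length in km (> 0).
#' @param entry two-column matrix or data frame of 0-based `(row, col)`
#'   entry cells, or the string `"west"` (default) to use every habitable
#'   cell of the westernmost habitable column.
#' @return An object of class `clade_landscape`.
#' @examples
#' land <- landscape(matrix(1, 5, 8), cell_size = 10)
#' land
#' @export
landscape <- function(mask, cell_size, entry = "west") {
  mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (cell_size <= 0) abort("cell_size must be > 0")
  if (!any(mask == 1L)) abort("landscape has no habitable cells")
  if (identical(entry, "west")) {
    west_col <- min(which(colSums(mask) > 0)) # 1-based
    entry <- cbind(which(mask[, west_col] == 1L) - 1L, west_col - 1L)
  } else {
    entry <- as.matrix(entry)
    storage.mode(entry) <- "integer"
    dimnames(entry) <- NULL
  }
  if (nrow(entry) == 0) abort("landscape needs at least one entry cell")
  hab <- mask[cbind(entry[, 1] + 1L, entry[, 2] + 1L)]
  if (any(hab != 1L)) abort("every entry cell must be habitable")
  structure(
    list(mask = mask, cell_size = cell_size, entry = entry,
         geometry = "planar"),
    class = "clade_landscape"
  )
}

#' @export
print.clade_landscape <- function(x, ...) {
  cat(sprintf(
    "<clade_landscape> %d x %d lattice, %.3g km cells, %d habitable, %d entry\n",
    nrow(x$mask), ncol(x$mask), x$cell_size, sum(x$mask), nrow(x$entry)
  ))
  invisible(x)
}

#' @export
tidy.clade_landscape <- function(x, ...) {
  idx <- which(x$mask == 1L, arr.ind = TRUE)
  is_entry <- paste(idx[, 1] - 1L, idx[, 2] - 1L) %in%
    paste(x$entry[, 1], x$entry[, 2])
  tibble(
    row = idx[, 1] - 1L, col = idx[, 2] - 1L,
    x_km = (idx[, 2] - 0.5) * x$cell_size,
    y_km = (idx[, 1] - 0.5) * x$cell_size,
    entry = is_entry
  ) |> dplyr::arrange(.data$row, .data$col)
}

#' Generate a corridor-style synthetic landscape
#'
#' Builds a stylised east-west corridor: a horizontal habitable band of the
#' requested fraction of the lattice height, optionally interrupted by
#' non-habitable barrier rectangles (mimicking mountain axes) that must
#' leave the habitable region connected. With `roughness > 0`, random
#' single-cell notches are carved from the band edge (rejected whenever a
#' notch would disconnect the region or remove an entry cell).
#'
#' @param rows,cols lattice dimensions (>= 2).
#' @param cell_size cell edge length in km.
#' @param corridor_fraction habitable fraction of the lattice height,
#'   in (0, 1].
#' @param barriers list of barrier rectangles, each a list/vector with
#'   elements `row0`, `row1`, `col0`, `col1` (0-based, inclusive).
#' @param entry_side which edge holds the entry cells (only `"west"`).
#' @param roughness expected number of random edge notches.
#' @param seed integer seed for the notches (ignored when `roughness = 0`).
#' @return A `clade_landscape`.
#' @examples
#' make_landscape(10, 20, cell_size = 5, corridor_fraction = 0.6)
#' @export
make_landscape <- function(rows, cols, cell_size = 5,
                           corridor_fraction = 1, barriers = list(),
                           entry_side = "west", roughness = 0, seed = 1L) {
  if (rows < 2 || cols < 2) abort("rows and cols must be >= 2")
  if (corridor_fraction <= 0 || corridor_fraction > 1)
    abort("corridor_fraction must be in (0, 1]")
  entry_side <- match.arg(entry_side, "west")

  band <- max(1L, round(rows * corridor_fraction))
  top <- (rows - band) %/% 2L
  mask <- matrix(0L, rows, cols)
  mask[(top + 1L):(top + band), ] <- 1L

  for (b in barriers) {
    b <- as.list(b)
    r0 <- b$row0 + 1L; r1 <- b$row1 + 1L
    c0 <- b$col0 + 1L; c1 <- b$col1 + 1L
    if (r0 < 1 || c0 < 1 || r1 > rows || c1 > cols || r0 > r1 || c0 > c1)
      abort("barrier rectangle outside the lattice")
    mask[r0:r1, c0:c1] <- 0L
  }
  if (!any(mask == 1L)) abort("barriers removed every habitable cell")

  west_col <- min(which(colSums(mask) > 0))
  entry <- cbind(which(mask[, west_col] == 1L) - 1L, west_col - 1L)
  if (!connected_mask(mask))
    abort("barriers disconnect the habitable region (entry cells cut off)")

  if (roughness > 0) {
    with_local_seed <- function(expr) { # local RNG, leave global stream alone
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      expr
    }
    with_local_seed({
      edge <- which(mask == 1L, arr.ind = TRUE)
      on_edge <- edge[edge[, 1] %in% c(top + 1L, top + band), , drop = FALSE]
      n_notch <- min(nrow(on_edge), stats::rpois(1, roughness))
      if (n_notch > 0) {
        cand <- on_edge[sample.int(nrow(on_edge), n_notch), , drop = FALSE]
        for (i in seq_len(nrow(cand))) {
          trial <- mask
          trial[cand[i, 1], cand[i, 2]] <- 0L
          still_entry <- trial[cbind(entry[, 1] + 1L, entry[, 2] + 1L)] == 1L
          if (all(still_entry) && any(trial == 1L) && connected_mask(trial))
            mask <- trial
        }
      }
    })
  }

  landscape(mask, cell_size, entry = entry)
}

# flood fill from the first habitable cell; TRUE iff one component
connected_mask <- function(mask) {
  idx <- which(mask == 1L)
  if (length(idx) == 0) return(FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  start <- arrayInd(idx[1], dim(mask))
  queue <- list(c(start[1], start[2]))
  seen[start[1], start[2]] <- TRUE
  n_seen <- 1L
  while (length(queue)) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      r <- cur[1] + d[1]; c <- cur[2] + d[2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          mask[r, c] == 1L && !seen[r, c]) {
        seen[r, c] <- TRUE
        n_seen <- n_seen + 1L
        queue[[length(queue) + 1L]] <- c(r, c)
      }
    }
  }
  n_seen == length(idx)
}

#' Read / write a landscape raster
#'
#' The raster is a headerless CSV of integer codes (0 = sea or barrier,
#' 1 = habitable, 2 = habitable entry cell); the cell size travels in a
#' YAML companion file `<path>.yaml` holding `cell_size_km`.
#'
#' @param path CSV raster path.
#' @return `read_landscape()` returns a `clade_landscape`;
#'   `write_landscape()` returns `path`, invisibly.
#' @export
read_landscape <- function(path) {
  if (!file.exists(path)) abort(paste0("missing landscape raster: ", path))
  raster <- as.matrix(read.csv(path, header = FALSE))
  dimnames(raster) <- NULL
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path))
    abort(paste0("missing landscape companion file: ", meta_path))
  meta <- yaml::read_yaml(meta_path)
  entry <- which(raster == 2L, arr.ind = TRUE)
  if (nrow(entry) == 0) abort("landscape raster has no entry cells (code 2)")
  landscape(raster >= 1L, cell_size = meta$cell_size_km,
            entry = entry - 1L)
}

#' @rdname read_landscape
#' @param x a `clade_landscape`.
#' @export
write_landscape <- function(x, path) {
  raster <- x$mask
  raster[cbind(x$entry[, 1] + 1L, x$entry[, 2] + 1L)] <- 2L
  write.table(raster, path, sep = ",", row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(cell_size_km = x$cell_size), paste0(path, ".yaml"))
  invisible(path)
}
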