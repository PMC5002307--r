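# Rasterization of firing activity into arena-wide rate maps.

new_rate_map <- function(grid, visits, resolution, extent) {
  structure(list(grid = grid, visits = visits,
                 resolution = resolution, extent = extent),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf(
    "<rate map: %d x %d bins at %g m, %d visited, max rate %s>\n",
    nrow(x$grid), ncol(x$grid), x$resolution, sum(x$visits > 0),
    format(suppressWarnings(max(x$grid, na.rm = TRUE)), digits = 3)))
  invisible(x)
}

# Map positions to (row, col) bin indices. Row 1 is the southmost y bin,
# column 1 the westmost x bin; points exactly on the far boundary fall in
# the last bin.
bin_index <- function(x, y, resolution, extent) {
  nx <- ceiling(extent[1] / resolution)
  ny <- ceiling(extent[2] / resolution)
  ix <- pmin(floor(x / resolution) + 1L, nx)
  iy <- pmin(floor(y / resolution) + 1L, ny)
  list(ix = ix, iy = iy, nx = nx, ny = ny)
}

#' Rasterize one cell's firing along a trajectory into a rate map
#'
#' Evaluates the cell's firing rate at every trajectory step and bins the
#' rates on a regular grid over the arena (row = y bin from south,
#' col = x bin from west). Each visited bin holds the mean rate over the
#' trajectory points that fell in it. Bins the trajectory never entered
#' are `NA`, never zero: "not visited" must not be conflated with "not
#' firing" when measuring field areas.
#'
#' @param cell a `place_cell`.
#' @param trajectory a `trajectory` data.frame.
#' @param percepts list of `place_code`s, one per trajectory step
#'   (aligned by position).
#' @param params a [firing_params()].
#' @param resolution bin side in metres (> 0); default 0.5 m.
#' @param arena the [arena()]; defaults to the trajectory's arena
#'   attribute.
#' @param weight_mode passed to [firing_rate()].
#' @return A `rate_map` with fields `grid` (mean rates, `NA` where
#'   unvisited), `visits` (per-bin counts), `resolution`, `extent`.
#' @export
rasterize_cell <- function(cell, trajectory, percepts, params,
                           resolution = 0.5, arena = attr(trajectory, "arena"),
                           weight_mode = c("current", "matched")) {
  resolution <- check_number(resolution, "resolution",
                             lower = 0, strict_lower = TRUE)
  weight_mode <- match.arg(weight_mode)
  stopifnot(nrow(trajectory) == length(percepts))
  rates <- vapply(percepts, firing_rate, numeric(1),
                  cell = cell, params = params, weight_mode = weight_mode)
  rasterize_values(rates, trajectory, resolution,
                   extent = c(arena$width, arena$height))
}

# Shared binning: mean of `values` per visited bin.
rasterize_values <- function(values, trajectory, resolution, extent) {
  b <- bin_index(trajectory$x, trajectory$y, resolution, extent)
  flat <- (b$iy - 1L) * b$nx + b$ix
  visits <- matrix(tabulate(flat, b$nx * b$ny), nrow = b$ny, ncol = b$nx,
                   byrow = TRUE)
  sums <- matrix(0, nrow = b$ny, ncol = b$nx)
  agg <- rowsum(values, group = flat)
  flat_idx <- as.integer(rownames(agg))
  iy <- (flat_idx - 1L) %/% b$nx + 1L
  ix <- (flat_idx - 1L) %% b$nx + 1L
  sums[cbind(iy, ix)] <- agg[, 1]
  grid <- sums / ifelse(visits > 0, visits, NA)
  new_rate_map(grid, visits, resolution, extent)
}

#' Combine per-cell rate maps into a population map
#'
#' The population map shows the overlap of all firing fields: each bin
#' holds the maximum rate across cells (the strongest responder at that
#' location). All maps must share the same grid geometry.
#'
#' @param rate_maps a list of `rate_map`s (at least one).
#' @return A `rate_map`.
#' @export
population_map <- function(rate_maps) {
  stopifnot(length(rate_maps) >= 1)
  ref <- rate_maps[[1]]
  for (m in rate_maps) {
    if (!identical(dim(m$grid), dim(ref$grid)) ||
        m$resolution != ref$resolution) {
      stop("rate maps have mismatched grid geometry", call. = FALSE)
    }
  }
  grids <- lapply(rate_maps, `[[`, "grid")
  combined <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE), grids)
  # pmax(NA, NA, na.rm = TRUE) is NA, so never-visited bins stay flagged
  visits <- Reduce(`+`, lapply(rate_maps, `[[`, "visits"))
  new_rate_map(combined, visits, ref$resolution, ref$extent)
}

#' Firing-field area and coverage of a rate map
#'
#' A bin belongs to the field when its rate is at least `rate_threshold`.
#' The field area is the number of such bins times the bin area; coverage
#' is their fraction among visited bins. Unvisited bins are excluded from
#' both.
#'
#' @param map a `rate_map`.
#' @param rate_threshold rate in \[0, 1\]; a natural choice is the FRT.
#' @return A list with `field_area_m2` and `coverage_fraction`.
#' @export
field_metrics <- function(map, rate_threshold) {
  rate_threshold <- check_number(rate_threshold, "rate_threshold",
                                 lower = 0, upper = 1)
  visited <- map$visits > 0 & !is.na(map$grid)
  n_visited <- sum(visited)
  n_field <- sum(map$grid[visited] >= rate_threshold)
  list(field_area_m2 = n_field * map$resolution^2,
       coverage_fraction = if (n_visited > 0) n_field / n_visited else NA_real_)
}

#' Write and read rate maps as annotated CSV
#'
#' Text format: three comment lines (`# resolution_m=...`,
#' `# extent_m=...,...`, `# unvisited=NA`) followed by the grid as a CSV
#' matrix, row 1 = southmost bin row, unvisited bins written as `NA`.
#' Visit counts are not serialized; on reading, bins that are `NA` are
#' marked unvisited.
#'
#' @param map a `rate_map`.
#' @param path file path.
#' @return `write_rate_map` returns `path` invisibly; `read_rate_map`
#'   returns a `rate_map`.
#' @export
write_rate_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# resolution_m=%.17g", map$resolution),
    sprintf("# extent_m=%.17g,%.17g", map$extent[1], map$extent[2]),
    "# unvisited=NA"
  ), con)
  utils::write.table(map$grid, con, sep = ",", na = "NA",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_map
#' @export
read_rate_map <- function(path) {
  hdr <- readLines(path, n = 3)
  get_val <- function(key) sub(sprintf("^# %s=", key), "", grep(
    sprintf("^# %s=", key), hdr, value = TRUE))
  resolution <- as.numeric(get_val("resolution_m"))
  extent <- as.numeric(strsplit(get_val("extent_m"), ",")[[1]])
  grid <- as.matrix(utils::read.table(path, sep = ",", skip = 3,
                                      na.strings = "NA"))
  dimnames(grid) <- NULL
  new_rate_map(grid, visits = ifelse(is.na(grid), 0L, 1L),
               resolution = resolution, extent = extent)
}

#' Plot a rate map
#'
#' Convenience rendering: image of the grid in arena coordinates (low
#' rates dark blue, high rates dark red), optionally with the trajectory
#' overlaid.
#'
#' @param x a `rate_map`.
#' @param trajectory optional `trajectory` to overlay.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.rate_map <- function(x, trajectory = NULL, main = "firing rate", ...) {
  nx <- ncol(x$grid)
  ny <- nrow(x$grid)
  xs <- (seq_len(nx) - 0.5) * x$resolution
  ys <- (seq_len(ny) - 0.5) * x$resolution
  pal <- grDevices::hcl.colors(64, "RdYlBu", rev = TRUE)
  graphics::image(xs, ys, t(x$grid), zlim = c(0, 1), col = pal,
                  xlab = "x (m)", ylab = "y (m)", main = main,
                  useRaster = TRUE, asp = 1, ...)
  if (!is.null(trajectory)) {
    graphics::lines(trajectory$x, trajectory$y, col = "black", lwd = 0.3)
  }
  invisible(x)
}
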