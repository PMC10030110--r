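#' Gridded terrain height field
#'
#' A node-registered rectangular grid of surface heights for a running track.
#' Rows of `heights` run along the track (longitudinal `y` axis), columns run
#' across it (lateral `x` axis); `z` is up. All units are metres.
#'
#' @param heights numeric matrix of heights (m), rows along the track
#' @param resolution grid spacing (m); a scalar or `c(dy, dx)`
#' @param origin world coordinates `c(x0, y0)` of the `heights[1, 1]` node
#' @return an object of class `terrain_field` with elements `heights`,
#'   `resolution` (length 2, `c(dy, dx)`), `origin`, `track_length`,
#'   `track_width`
#' @export
terrain_field <- function(heights, resolution, origin = c(0, 0)) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) {
    stop("terrain heights must all be finite")
  }
  resolution <- as.numeric(resolution)
  if (length(resolution) == 1L) resolution <- c(resolution, resolution)
  if (length(resolution) != 2L || any(resolution <= 0)) {
    stop("grid resolution must be positive (scalar or c(dy, dx))")
  }
  structure(
    list(
      heights = heights,
      resolution = resolution,
      origin = as.numeric(origin),
      track_length = (nrow(heights) - 1L) * resolution[1L],
      track_width = (ncol(heights) - 1L) * resolution[2L]
    ),
    class = "terrain_field"
  )
}

#' @export
print.terrain_field <- function(x, ...) {
  cat(sprintf(
    "<terrain_field> %.2f m x %.2f m, %d x %d nodes at (%.3g, %.3g) m\n",
    x$track_length, x$track_width, nrow(x$heights), ncol(x$heights),
    x$resolution[1L], x$resolution[2L]
  ))
  cat(sprintf(
    "  height range [%.1f, %.1f] mm\n",
    1e3 * min(x$heights), 1e3 * max(x$heights)
  ))
  invisible(x)
}

# world coordinates of grid nodes
field_y <- function(field) {
  field$origin[2L] + (seq_len(nrow(field$heights)) - 1L) * field$resolution[1L]
}
field_x <- function(field) {
  field$origin[1L] + (seq_len(ncol(field$heights)) - 1L) * field$resolution[2L]
}

#' Interpolate terrain height at world coordinates
#'
#' Nearest-node lookup, clamped to the grid edges.
#'
#' @param field a [terrain_field()]
#' @param x,y world coordinates (m), recycled to a common length
#' @return numeric vector of heights (m)
#' @export
terrain_height_at <- function(field, x, y) {
  iy <- pmin(pmax(round((y - field$origin[2L]) / field$resolution[1L]) + 1L, 1L),
             nrow(field$heights))
  ix <- pmin(pmax(round((x - field$origin[1L]) / field$resolution[2L]) + 1L, 1L),
             ncol(field$heights))
  field$heights[cbind(iy, ix)]
}

#' Write a terrain field to disk
#'
#' The grid is stored as a comma-delimited numeric matrix at full double
#' precision, with a JSON sidecar (`<path>.json`) holding the resolution,
#' origin, and units, so that write/load round-trips are bit exact.
#'
#' @param field a [terrain_field()]
#' @param path output path for the delimited grid
#' @return `path`, invisibly
#' @export
write_terrain <- function(field, path) {
  lines <- apply(field$heights, 1L, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = ",")
  })
  writeLines(lines, path)
  meta <- list(
    resolution = field$resolution,
    origin = field$origin,
    units = "m"
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a terrain field from disk
#'
#' Reads a whitespace- or comma-delimited rectangular numeric matrix plus its
#' JSON metadata sidecar.
#'
#' @param path path to the delimited grid; metadata is read from
#'   `<path>.json`
#' @param mean_subtract subtract the grid mean from all heights?
#' @return a [terrain_field()]
#' @export
load_terrain <- function(path, mean_subtract = FALSE) {
  if (!file.exists(path)) stop("terrain grid file not found: ", path)
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("terrain metadata sidecar not found: ", meta_path)
  dt <- data.table::fread(path, header = FALSE)
  h <- as.matrix(dt)
  if (!is.numeric(h)) {
    bad <- which(!vapply(dt, is.numeric, logical(1L)))[1L]
    stop("terrain grid is not numeric (first bad column: ", bad, ")")
  }
  if (anyNA(h)) {
    bad_row <- which(rowSums(is.na(h)) > 0)[1L]
    stop("terrain grid contains missing values (first bad row: ", bad_row, ")")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$resolution)) stop("terrain metadata lacks 'resolution'")
  dimnames(h) <- NULL
  if (mean_subtract) h <- h - mean(h)
  terrain_field(h, resolution = meta$resolution,
                origin = meta$origin %||% c(0, 0))
}

#' Height statistics of a rear-foot sized terrain patch
#'
#' Computes the median and interquartile range of all grid nodes inside an
#' axis-aligned rectangular patch. The IQR of heights within a rear-foot
#' sized patch is the per-patch unevenness measure used throughout the
#' foot-placement analyses. Quantiles use linear interpolation between order
#' statistics (R's default type 7), consistently with every other quantile
#' in the package.
#'
#' @param field a [terrain_field()]
#' @param center patch centre `c(x, y)` (m)
#' @param patch_size patch extent `c(width, length)` (m); default 95 mm
#'   square, half the 190 mm foot length
#' @return a list of class `patch_stats` with `center`, `h_iqr`, `h_median`,
#'   `patch_size`, `n_nodes`, and `clipped` (TRUE when the patch overhung
#'   the track edge and was clipped)
#' @export
patch_stats <- function(field, center, patch_size = c(0.095, 0.095)) {
  if (length(patch_size) == 1L) patch_size <- c(patch_size, patch_size)
  xs <- field_x(field)
  ys <- field_y(field)
  x_lo <- center[1L] - patch_size[1L] / 2
  x_hi <- center[1L] + patch_size[1L] / 2
  y_lo <- center[2L] - patch_size[2L] / 2
  y_hi <- center[2L] + patch_size[2L] / 2
  jx <- which(xs >= x_lo - 1e-12 & xs <= x_hi + 1e-12)
  iy <- which(ys >= y_lo - 1e-12 & ys <= y_hi + 1e-12)
  if (length(jx) == 0L || length(iy) == 0L) {
    stop("patch lies fully outside the terrain field")
  }
  clipped <- x_lo < min(xs) - 1e-12 || x_hi > max(xs) + 1e-12 ||
    y_lo < min(ys) - 1e-12 || y_hi > max(ys) + 1e-12
  vals <- field$heights[iy, jx]
  q <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(
    list(
      center = as.numeric(center),
      h_iqr = q[3L] - q[1L],
      h_median = q[2L],
      patch_size = patch_size,
      n_nodes = length(vals),
      clipped = clipped
    ),
    class = "patch_stats"
  )
}

#' Precompute patch statistics at every grid node
#'
#' Sliding-window median and IQR with the window clipped at the grid edges,
#' identical to evaluating [patch_stats()] centred on each node. Used as a
#' lookup table by the stepping models so that 100,000-step walks evaluate
#' patch unevenness in constant time per candidate.
#'
#' @param field a [terrain_field()]
#' @param patch_size patch extent `c(width, length)` (m)
#' @return list with matrices `median` and `iqr` shaped like `field$heights`
#' @export
patch_lookup <- function(field, patch_size = c(0.095, 0.095)) {
  if (length(patch_size) == 1L) patch_size <- c(patch_size, patch_size)
  hy <- floor(patch_size[2L] / 2 / field$resolution[1L] + 1e-9)
  hx <- floor(patch_size[1L] / 2 / field$resolution[2L] + 1e-9)
  out <- patch_window_stats_cpp(field$heights, as.integer(hy), as.integer(hx))
  out$patch_size <- patch_size
  out
}

# alternating local extrema of a 1D signal; returns data.frame(idx, type)
# with type +1 for maxima, -1 for minima; consecutive same-type extrema are
# collapsed keeping the more extreme one
find_alternating_extrema <- function(h) {
  d <- diff(h)
  s <- sign(d)
  # carry the previous non-zero slope sign through plateaus
  nz <- s != 0
  if (!any(nz)) return(data.frame(idx = integer(), type = integer()))
  s <- s[nz]
  pos <- which(nz)
  chg <- which(diff(s) != 0)
  if (length(chg) == 0L) return(data.frame(idx = integer(), type = integer()))
  idx <- pos[chg] + 1L              # sample where slope sign flips
  type <- ifelse(s[chg] > 0, 1L, -1L)  # rising-then-falling = maximum
  # enforce alternation, keep the more extreme of same-type neighbours
  keep_idx <- idx[1L]
  keep_type <- type[1L]
  for (k in seq_along(idx)[-1L]) {
    last <- length(keep_idx)
    if (type[k] == keep_type[last]) {
      better <- if (type[k] > 0) h[idx[k]] > h[keep_idx[last]] else h[idx[k]] < h[keep_idx[last]]
      if (better) keep_idx[last] <- idx[k]
    } else {
      keep_idx <- c(keep_idx, idx[k])
      keep_type <- c(keep_type, type[k])
    }
  }
  data.frame(idx = keep_idx, type = keep_type)
}

#' Terrain amplitude and wavelength statistics
#'
#' Measures peak-to-valley height differences (amplitude) and peak-to-peak
#' longitudinal separations (wavelength) along longitudinal transects of the
#' field. Each transect is lightly smoothed with a moving average (20 mm
#' window by default) before locating alternating local maxima and minima;
#' amplitudes are absolute height differences of consecutive alternating
#' extrema and wavelengths are distances between consecutive maxima. Results
#' are pooled over all transects.
#'
#' @param field a [terrain_field()]
#' @param smooth_window moving-average window (m) applied before extremum
#'   detection
#' @param transect_stride evaluate every `transect_stride`-th lateral column
#' @return a list of class `terrain_stats` with `amplitude_mean`,
#'   `amplitude_sd`, `wavelength_mean`, `wavelength_sd`, `n_amplitudes`,
#'   `n_wavelengths`, and `flat` (TRUE when no extrema were found)
#' @export
measure_amplitude_wavelength <- function(field, smooth_window = 0.02,
                                         transect_stride = 1L) {
  dy <- field$resolution[1L]
  k <- max(1L, round(smooth_window / dy))
  cols <- seq(1L, ncol(field$heights), by = as.integer(transect_stride))
  amps <- vector("list", length(cols))
  wls <- vector("list", length(cols))
  for (ci in seq_along(cols)) {
    h <- moving_average(field$heights[, cols[ci]], k)
    ext <- find_alternating_extrema(h)
    if (nrow(ext) >= 2L) {
      amps[[ci]] <- abs(diff(h[ext$idx]))
      pk <- ext$idx[ext$type > 0]
      if (length(pk) >= 2L) wls[[ci]] <- diff(pk) * dy
    }
  }
  amps <- unlist(amps)
  wls <- unlist(wls)
  flat <- length(amps) == 0L
  structure(
    list(
      amplitude_mean = if (flat) 0 else mean(amps),
      amplitude_sd = if (flat) 0 else sd(amps),
      wavelength_mean = if (length(wls)) mean(wls) else NaN,
      wavelength_sd = if (length(wls) > 1L) sd(wls) else NaN,
      n_amplitudes = length(amps),
      n_wavelengths = length(wls),
      flat = flat
    ),
    class = "terrain_stats"
  )
}

#' @export
print.terrain_stats <- function(x, ...) {
  cat(sprintf(
    "<terrain_stats> amplitude %.1f +/- %.1f mm, wavelength %.0f +/- %.0f mm\n",
    1e3 * x$amplitude_mean, 1e3 * x$amplitude_sd,
    1e3 * x$wavelength_mean, 1e3 * x$wavelength_sd
  ))
  invisible(x)
}

#' Divide a terrain region into foot-placement cells
#'
#' Tiles the analysed region with cells one foot length long (along the
#' track) and half a foot length wide (across it), with half-open
#' `[start, end)` boundaries. Rows index position along the track (`i`),
#' columns position across it (`j`). Per-cell terrain height medians and
#' IQRs are attached.
#'
#' @param field a [terrain_field()]
#' @param foot_length foot length (m); cells are `foot_length` x
#'   `foot_length / 2`
#' @param region analysed region as `list(x = c(lo, hi), y = c(lo, hi))`;
#'   defaults to the full field
#' @return an object of class `cell_grid`
#' @export
build_cell_grid <- function(field, foot_length = 0.19, region = NULL) {
  if (foot_length <= 0) stop("foot_length must be positive")
  cell_length <- foot_length
  cell_width <- foot_length / 2
  if (cell_width > field$track_width) {
    stop("cell width exceeds track width; foot_length too large for this field")
  }
  region <- region %||% list(
    x = range(field_x(field)),
    y = range(field_y(field))
  )
  n_rows <- floor(diff(region$y) / cell_length + 1e-9)
  n_cols <- floor(diff(region$x) / cell_width + 1e-9)
  if (n_rows < 1L || n_cols < 1L) stop("region smaller than a single cell")
  xs <- field_x(field)
  ys <- field_y(field)
  iy <- floor((ys - region$y[1L]) / cell_length + 1e-9) + 1L
  jx <- floor((xs - region$x[1L]) / cell_width + 1e-9) + 1L
  ok_y <- which(iy >= 1L & iy <= n_rows)
  ok_x <- which(jx >= 1L & jx <= n_cols)
  h_median <- matrix(NA_real_, n_rows, n_cols)
  h_iqr <- matrix(NA_real_, n_rows, n_cols)
  for (j in unique(jx[ok_x])) {
    colsel <- ok_x[jx[ok_x] == j]
    sub <- field$heights[ok_y, colsel, drop = FALSE]
    grp <- iy[ok_y]
    med <- tapply(as.vector(sub), rep(grp, times = length(colsel)),
                  quantile, probs = 0.5, names = FALSE)
    q1 <- tapply(as.vector(sub), rep(grp, times = length(colsel)),
                 quantile, probs = 0.25, names = FALSE)
    q3 <- tapply(as.vector(sub), rep(grp, times = length(colsel)),
                 quantile, probs = 0.75, names = FALSE)
    rows <- as.integer(names(med))
    h_median[rows, j] <- med
    h_iqr[rows, j] <- q3 - q1
  }
  structure(
    list(
      cell_length = cell_length,
      cell_width = cell_width,
      origin = c(region$x[1L], region$y[1L]),
      n_rows = n_rows,
      n_cols = n_cols,
      counts = matrix(0L, n_rows, n_cols),
      h_median = h_median,
      h_iqr = h_iqr
    ),
    class = "cell_grid"
  )
}

#' Assign world coordinates to foot-placement cells
#'
#' Half-open `[start, end)` cell boundaries, so a point on a boundary belongs
#' to exactly one cell. Points outside the tiled region get `NA` indices.
#'
#' @param grid a [build_cell_grid()] result
#' @param x,y world coordinates (m)
#' @return data.frame with integer columns `i` (along track) and `j` (across)
#' @export
assign_cells <- function(grid, x, y) {
  i <- floor((y - grid$origin[2L]) / grid$cell_length + 1e-9) + 1L
  j <- floor((x - grid$origin[1L]) / grid$cell_width + 1e-9) + 1L
  i[i < 1L | i > grid$n_rows] <- NA_integer_
  j[j < 1L | j > grid$n_cols] <- NA_integer_
  data.frame(i = i, j = j)
}
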