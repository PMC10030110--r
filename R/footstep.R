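# Blind and terrain-directed foot-placement models and the foot-placement
# index.

#' Sample a zero-centred von Mises distribution
#'
#' Best-Fisher rejection sampling of vM(kappa, mu = 0) on (-pi, pi]. No
#' installed package provides a von Mises sampler, so this small primitive
#' is implemented here.
#'
#' @param n number of draws
#' @param kappa concentration parameter (> 0)
#' @return numeric vector of angles in (-pi, pi]
#' @export
rvonmises <- function(n, kappa = 1) {
  if (kappa <= 0) stop("kappa must be positive")
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0L)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 32L)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1)))
  }
  out[seq_len(n)]
}

# von Mises noise mapped linearly so the base of support equals `support`
vm_support_noise <- function(n, kappa, support) {
  rvonmises(n, kappa) * support / (2 * pi)
}

#' Blind (uniform random) footstep sampling
#'
#' The null model of footstep selection: rear-foot sized patches are
#' sampled uniformly at random over the analysed region and their height
#' statistics recorded. Patch statistics are looked up at the nearest grid
#' node from a precomputed sliding-window table.
#'
#' @param field a [terrain_field()]
#' @param n number of samples
#' @param patch_size patch extent (m), scalar or `c(width, length)`
#' @param seed integer seed
#' @param region analysed region `list(x = c(lo, hi), y = c(lo, hi))`;
#'   defaults to the full field
#' @param lookup optional precomputed [patch_lookup()] table
#' @return data.frame with columns `x`, `y`, `h_iqr`, `h_median`
#' @export
blind_sample <- function(field, n, patch_size = 0.095, seed = 1L,
                         region = NULL, lookup = NULL) {
  if (n < 1L) stop("n must be at least 1")
  region <- region %||% list(x = range(field_x(field)),
                             y = range(field_y(field)))
  if (diff(region$x) <= 0 || diff(region$y) <= 0) {
    stop("analysed region is smaller than a patch")
  }
  lookup <- lookup %||% patch_lookup(field, patch_size)
  with_seed(seed, {
    x <- runif(n, region$x[1L], region$x[2L])
    y <- runif(n, region$y[1L], region$y[2L])
    iy <- pmin(pmax(round((y - field$origin[2L]) / field$resolution[1L]) + 1L, 1L),
               nrow(field$heights))
    ix <- pmin(pmax(round((x - field$origin[1L]) / field$resolution[2L]) + 1L, 1L),
               ncol(field$heights))
    idx <- cbind(iy, ix)
    data.frame(x = x, y = y,
               h_iqr = lookup$iqr[idx], h_median = lookup$median[idx])
  })
}

#' Configuration of the directed foot-placement walk
#'
#' Defaults take the step statistics of the measured gait: step length
#' 128 %LL with SD 6 %LL and step width 4.2 %LL with SD 2.8 %LL of a
#' 0.89 m leg.
#'
#' @param step_length,step_length_sd open-loop step length and search
#'   half-extent (m)
#' @param step_width,step_width_sd open-loop step width and search
#'   half-extent (m)
#' @param kappa von Mises concentration of the noise process
#' @param substeps half-number of search sub-steps per axis; the search
#'   grid has `2 * substeps + 1` candidates per axis (sub-step size
#'   sigma/substeps)
#' @param patch_size rear-foot patch extent (m)
#' @param n_steps number of simulated steps
#' @param seed integer seed
#' @return an object of class `directed_walk_config`
#' @export
directed_walk_config <- function(step_length = 1.28 * 0.89,
                                 step_length_sd = 0.06 * 0.89,
                                 step_width = 0.042 * 0.89,
                                 step_width_sd = 0.028 * 0.89,
                                 kappa = 1, substeps = 10L,
                                 patch_size = 0.095,
                                 n_steps = 100000L, seed = 1L) {
  stopifnot(step_length > 0, step_length_sd > 0, step_width_sd > 0,
            kappa > 0, substeps >= 1L, n_steps >= 1L)
  structure(
    list(step_length = step_length, step_length_sd = step_length_sd,
         step_width = step_width, step_width_sd = step_width_sd,
         kappa = kappa, substeps = as.integer(substeps),
         patch_size = patch_size, n_steps = as.integer(n_steps),
         seed = as.integer(seed)),
    class = "directed_walk_config"
  )
}

#' Directed (terrain-minimizing) foot-placement walk
#'
#' Markov-chain model of a runner who aims each step at the most level
#' nearby patch. Each step has three stages: an open-loop target one mean
#' step length ahead and one mean step width to the alternating side; a
#' minimization stage that scans a rear-foot sized window over the search
#' rectangle (half-extents one step-length SD longitudinally and one
#' step-width SD laterally, sub-steps of a tenth of each SD, endpoints
#' included) and picks the candidate with the lowest patch height IQR (ties
#' broken in favour of the candidate nearest the open-loop target, then the
#' lexicographically smallest (y, x)); and a noise stage that
#' perturbs the pick with zero-centred von Mises noise scaled so the base
#' of support equals the respective SD. When the open-loop target would
#' leave the track, the lateral position resets to the track centre and the
#' direction of travel reverses.
#'
#' @param field a [terrain_field()]
#' @param cfg a [directed_walk_config()]
#' @param start optional start position `c(x, y)`; defaults to the track
#'   centre, one step length from the near end
#' @param lookup optional precomputed [patch_lookup()] table
#' @param noise apply the von Mises noise stage? Disabling it isolates the
#'   open-loop and minimization stages
#' @return data.frame of class `step_sequence`: one row per step with the
#'   landing position, direction flag `j`, landing-patch `h_iqr` and
#'   `h_median`, per-step `step_length` (|dy|) and `step_width` (|dx|), and
#'   a `reset` flag marking turnarounds
#' @export
directed_walk <- function(field, cfg, start = NULL, lookup = NULL,
                          noise = TRUE) {
  lookup <- lookup %||% patch_lookup(field, cfg$patch_size)
  xs <- field_x(field); ys <- field_y(field)
  x_bounds <- range(xs); y_bounds <- range(ys)
  y_margin <- cfg$patch_size / 2
  y_lo <- y_bounds[1L] + y_margin; y_hi <- y_bounds[2L] - y_margin
  x_center <- mean(x_bounds)
  start <- start %||% c(x_center, y_lo + cfg$step_length)
  n <- cfg$n_steps
  dx_grid <- seq(-cfg$step_width_sd, cfg$step_width_sd,
                 length.out = 2L * cfg$substeps + 1L)
  dy_grid <- seq(-cfg$step_length_sd, cfg$step_length_sd,
                 length.out = 2L * cfg$substeps + 1L)
  # candidate order: y-major ascending then x, so which.min's first-minimum
  # rule implements the lexicographic (y, x) tie-break
  cand_dx <- rep(dx_grid, times = length(dy_grid))
  cand_dy <- rep(dy_grid, each = length(dx_grid))
  res_y <- field$resolution[1L]; res_x <- field$resolution[2L]
  ny <- nrow(field$heights); nx <- ncol(field$heights)
  out_x <- numeric(n); out_y <- numeric(n)
  out_j <- integer(n); out_reset <- logical(n)
  out_iqr <- numeric(n); out_med <- numeric(n)
  out_sgn <- numeric(n)
  with_seed(cfg$seed, {
    eta_x <- if (noise) vm_support_noise(n, cfg$kappa, cfg$step_width_sd) else numeric(n)
    eta_y <- if (noise) vm_support_noise(n, cfg$kappa, cfg$step_length_sd) else numeric(n)
    x <- start[1L]; y <- start[2L]
    j <- 0L
    for (i in seq_len(n)) {
      sgn_w <- if ((i - 1L) %% 2L == 0L) 1 else -1   # (-1)^i alternation
      x_hat <- x + sgn_w * cfg$step_width
      y_hat <- y + (if (j == 0L) 1 else -1) * cfg$step_length
      reset <- y_hat > y_hi || y_hat < y_lo
      if (reset) {
        x <- x_center
        j <- 1L - j
        x_hat <- x + sgn_w * cfg$step_width
        y_hat <- y + (if (j == 0L) 1 else -1) * cfg$step_length
      }
      cx <- pmin(pmax(x_hat + cand_dx, x_bounds[1L]), x_bounds[2L])
      cy <- pmin(pmax(y_hat + cand_dy, y_bounds[1L]), y_bounds[2L])
      iy <- pmin(pmax(round((cy - field$origin[2L]) / res_y) + 1L, 1L), ny)
      ix <- pmin(pmax(round((cx - field$origin[1L]) / res_x) + 1L, 1L), nx)
      vals <- lookup$iqr[iy + (ix - 1L) * ny]
      best <- which.min(vals)
      # ties: prefer the candidate closest to the open-loop target (so a
      # featureless field reproduces the open-loop gait), then the
      # lexicographically smallest (y, x)
      tied <- which(vals == vals[best])
      if (length(tied) > 1L) {
        best <- tied[order(abs(cand_dy[tied]), abs(cand_dx[tied]),
                           cand_dy[tied], cand_dx[tied])[1L]]
      }
      x_new <- cx[best] + eta_x[i]
      y_new <- cy[best] + eta_y[i]
      x_new <- min(max(x_new, x_bounds[1L]), x_bounds[2L])
      y_new <- min(max(y_new, y_bounds[1L]), y_bounds[2L])
      li_y <- min(max(round((y_new - field$origin[2L]) / res_y) + 1L, 1L), ny)
      li_x <- min(max(round((x_new - field$origin[1L]) / res_x) + 1L, 1L), nx)
      out_x[i] <- x_new; out_y[i] <- y_new
      out_j[i] <- j; out_reset[i] <- reset; out_sgn[i] <- sgn_w
      out_iqr[i] <- lookup$iqr[li_y + (li_x - 1L) * ny]
      out_med[i] <- lookup$median[li_y + (li_x - 1L) * ny]
      x <- x_new; y <- y_new
    }
  })
  out <- data.frame(
    step = seq_len(n), x = out_x, y = out_y, j = out_j,
    h_iqr = out_iqr, h_median = out_med,
    step_length = c(NA, abs(diff(out_y))),
    # signed lateral displacement in the alternation frame: its mean is the
    # model's step width without the folding bias of |dx|
    step_width = c(NA, diff(out_x) * out_sgn[-1L]),
    reset = out_reset
  )
  # displacement-based stats are undefined across a turnaround reset
  out$step_length[which(out$reset)] <- NA
  out$step_width[which(out$reset)] <- NA
  class(out) <- c("step_sequence", "data.frame")
  out
}

#' Foot placement index over a cell grid
#'
#' Normalized landing counts: `p[i, j] = f[i, j] / S`, where `f` is the
#' number of heel landings in the cell and `S` is the mean total count over
#' all step-length-sized neighbourhoods (windows of consecutive cell rows
#' spanning one step length, as wide as the track) that contain row `i`.
#' Perfectly periodic stepping gives p = 1 on stepped cells and 0
#' elsewhere; uniform random stepping gives p approximately equal to the
#' reciprocal of the number of cells in a step-length-sized box.
#'
#' @param grid a [build_cell_grid()] result
#' @param footsteps data.frame with heel landing coordinates `x`, `y` (m)
#' @param step_length neighbourhood length (m)
#' @return list of class `placement_index_map` with matrices `p` and
#'   `counts`, the per-row normalizer `S`, `window_rows`, and the input
#'   `step_length`; cells in rows not covered by any fully-contained
#'   window have `p = NA`
#' @export
foot_placement_index <- function(grid, footsteps, step_length) {
  W <- max(1L, round(step_length / grid$cell_length))
  if (step_length < grid$cell_length) {
    stop("step length is smaller than one cell; index undefined")
  }
  if (W > grid$n_rows) stop("grid shorter than one step-length window")
  cells <- assign_cells(grid, footsteps$x, footsteps$y)
  ok <- !is.na(cells$i) & !is.na(cells$j)
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  if (any(ok)) {
    tab <- table(factor(cells$i[ok], levels = seq_len(grid$n_rows)),
                 factor(cells$j[ok], levels = seq_len(grid$n_cols)))
    counts <- matrix(as.integer(tab), grid$n_rows, grid$n_cols)
  }
  row_tot <- rowSums(counts)
  n_win <- grid$n_rows - W + 1L
  win_tot <- vapply(seq_len(n_win), function(w) sum(row_tot[w:(w + W - 1L)]), 0)
  S <- rep(NA_real_, grid$n_rows)
  for (i in seq_len(grid$n_rows)) {
    w_lo <- max(1L, i - W + 1L); w_hi <- min(i, n_win)
    if (w_lo <= w_hi) S[i] <- mean(win_tot[w_lo:w_hi])
  }
  p <- counts / S   # recycles S down the rows
  p[!is.finite(p)] <- NA
  structure(
    list(p = p, counts = counts, S = S, window_rows = W,
         step_length = step_length, n_footsteps = sum(ok),
         grid = grid),
    class = "placement_index_map"
  )
}

#' Compare blind, directed, and observed stepping
#'
#' Aligns the landing-patch unevenness distributions and step statistics of
#' the three footstep sources: the blind uniform sampler, the directed
#' walk, and a table of observed footsteps.
#'
#' @param field a [terrain_field()]
#' @param observed data.frame with observed heel landings `x`, `y`, and
#'   optionally `step_length` and `step_width`
#' @param cfg a [directed_walk_config()]
#' @param n_blind number of blind samples
#' @param seed integer seed (for the blind sampler; the directed walk uses
#'   `cfg$seed`)
#' @return list with `summary` (one row per scheme) and `samples` (named
#'   list of per-scheme h_iqr vectors, for histograms)
#' @export
compare_schemes <- function(field, observed, cfg, n_blind = 10000L,
                            seed = 1L) {
  lookup <- patch_lookup(field, cfg$patch_size)
  blind <- blind_sample(field, n_blind, cfg$patch_size, seed = seed,
                        lookup = lookup)
  directed <- directed_walk(field, cfg, lookup = lookup)
  iy <- pmin(pmax(round((observed$y - field$origin[2L]) / field$resolution[1L]) + 1L, 1L),
             nrow(field$heights))
  ix <- pmin(pmax(round((observed$x - field$origin[1L]) / field$resolution[2L]) + 1L, 1L),
             ncol(field$heights))
  obs_iqr <- lookup$iqr[cbind(iy, ix)]
  row_for <- function(scheme, iqr, sl, sw) {
    data.frame(
      scheme = scheme, n = length(iqr),
      h_iqr_mean = mean(iqr), h_iqr_median = median(iqr),
      h_iqr_sd = sd(iqr),
      step_length_mean = mean(sl, na.rm = TRUE),
      step_length_sd = sd(sl, na.rm = TRUE),
      step_width_mean = mean(sw, na.rm = TRUE),
      step_width_sd = sd(sw, na.rm = TRUE)
    )
  }
  summary <- rbind(
    row_for("blind", blind$h_iqr, NA_real_, NA_real_),
    row_for("directed", directed$h_iqr,
            directed$step_length, directed$step_width),
    row_for("observed", obs_iqr,
            observed$step_length %||% NA_real_,
            observed$step_width %||% NA_real_)
  )
  list(summary = summary,
       samples = list(blind = blind$h_iqr, directed = directed$h_iqr,
                      observed = obs_iqr))
}
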