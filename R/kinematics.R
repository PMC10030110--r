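# Gait-event detection and per-step kinematics from marker trajectories.

#' Align the track frame to the direction of running
#'
#' Rotates all markers about the vertical axis so that the average CoM path
#' is parallel to the y axis, correcting small angular misalignments between
#' the capture frame and the track's long axis.
#'
#' @param ms a [marker_set()]
#' @param max_angle largest admissible correction (rad); larger estimates
#'   are clamped with a warning
#' @return the rotated `marker_set`, with the applied rotation (rad) in
#'   attribute `rotation`
#' @export
align_track_frame <- function(ms, max_angle = 5 * pi / 180) {
  com <- com_trajectory(ms)
  dxy <- apply(com[, 1:2], 2L, function(v) diff(range(v)))
  if (max(dxy) < 0.5) stop("CoM trajectory too short to estimate track direction")
  # principal horizontal direction of the CoM path
  xy <- sweep(com[, 1:2], 2L, colMeans(com[, 1:2]))
  ev <- eigen(crossprod(xy) / nrow(xy), symmetric = TRUE)$vectors[, 1L]
  ang <- atan2(ev[1L], ev[2L])   # angle of principal axis from +y
  if (ang > pi / 2) ang <- ang - pi
  if (ang < -pi / 2) ang <- ang + pi
  if (abs(ang) > max_angle) {
    warning(sprintf("track alignment of %.1f deg clamped to %.1f deg",
                    ang * 180 / pi, sign(ang) * max_angle * 180 / pi))
    ang <- sign(ang) * max_angle
  }
  # the estimated path angle is atan2(d_x, d_y) = -alpha for a path tilted
  # counterclockwise by alpha, so a counterclockwise rotation by `ang`
  # realigns the path with +y; `ang` is the applied correction
  ca <- cos(ang); sa <- sin(ang)
  rot <- function(m) {
    out <- m
    out[, 1L] <- ca * m[, 1L] - sa * m[, 2L]
    out[, 2L] <- sa * m[, 1L] + ca * m[, 2L]
    out
  }
  out <- ms
  out$markers <- lapply(ms$markers, rot)
  attr(out, "rotation") <- ang
  out
}

#' Detect stance phases from the heel marker
#'
#' A stance is a contiguous interval in which the heel height is no more
#' than `height_tol` above its standing height and the low-pass-filtered
#' heel forward speed is below `v_thresh` (the heel forward-speed minimum
#' criterion); the interval boundaries are then refined on unfiltered
#' one-sided speed differences so that the touchdown is the first at-rest
#' frame. The height tolerance (15 mm by default) accommodates landing on
#' local peaks of the uneven terrain; valleys are always below the bound.
#'
#' With a bilateral marker set (roles `heel_l` and `heel_r`), stances are
#' detected per foot and merged in time order; a unilateral set with a
#' single `heel` role is also accepted.
#'
#' @param ms a [marker_set()] with `heel` or `heel_l`/`heel_r` markers and
#'   their standing heights
#' @param height_tol admissible height above standing heel height (m)
#' @param v_thresh heel forward-speed threshold (m/s) on the filtered speed
#' @param lp_cutoff low-pass cutoff (Hz) for the speed signal
#' @param min_gap minimum separation between touchdowns of one foot (s)
#' @param min_stance shortest accepted stance (s)
#' @return data.frame with columns `t_td`, `t_lo` (s) and `foot`; zero rows
#'   (with a warning) when no stance is found
#' @export
detect_stance_events <- function(ms, height_tol = 0.015, v_thresh = 0.5,
                                 lp_cutoff = 10, min_gap = 0.3,
                                 min_stance = 0.05) {
  roles <- if ("heel" %in% names(ms$markers)) "heel" else c("heel_l", "heel_r")
  if (!all(roles %in% names(ms$markers))) {
    stop("marker set lacks heel markers ('heel' or 'heel_l'/'heel_r')")
  }
  per_heel <- lapply(roles, function(role) {
    ev <- detect_stance_one(ms, role, height_tol, v_thresh, lp_cutoff,
                            min_gap, min_stance)
    if (nrow(ev)) ev$foot <- sub("heel_?", "", role)
    ev
  })
  out <- do.call(rbind, per_heel[vapply(per_heel, nrow, 0L) > 0])
  if (is.null(out) || nrow(out) == 0L) {
    warning("no stance phases detected")
    return(data.frame(t_td = numeric(), t_lo = numeric(),
                      foot = character()))
  }
  out[order(out$t_td), , drop = FALSE]
}

detect_stance_one <- function(ms, role, height_tol, v_thresh, lp_cutoff,
                              min_gap, min_stance) {
  heel <- ms$markers[[role]]
  z0 <- ms$standing_heights[[role]]
  dt <- 1 / ms$rate
  n <- nrow(heel)
  vy <- grad_uniform(heel[, 2L], dt)
  speed <- abs(vy)
  # one-sided speeds: forward difference flags the first planted frame,
  # backward difference the last
  dstep <- abs(diff(heel[, 2L])) / dt
  speed_fwd <- c(dstep, Inf)
  speed_bwd <- c(Inf, dstep)
  bf <- signal::butter(2, lp_cutoff / (ms$rate / 2), type = "low")
  speed_f <- as.numeric(signal::filtfilt(bf, speed))
  height_ok <- heel[, 3L] - z0 <= height_tol
  cand <- height_ok & speed_f < v_thresh
  runs <- true_runs(cand)
  if (nrow(runs) == 0L) {
    return(data.frame(t_td = numeric(), t_lo = numeric()))
  }
  # refine boundaries on raw one-sided speeds: expand while the heel is at
  # rest, shrink past frames where it still moves
  raw_tol <- v_thresh / 4
  refine <- function(s, e) {
    while (s > 1L && speed_fwd[s - 1L] < raw_tol && height_ok[s - 1L]) s <- s - 1L
    while (s < e && speed_fwd[s] >= raw_tol) s <- s + 1L
    while (e < n && speed_bwd[e + 1L] < raw_tol && height_ok[e + 1L]) e <- e + 1L
    while (e > s && speed_bwd[e] >= raw_tol) e <- e - 1L
    c(s, e)
  }
  bounds <- t(apply(runs, 1L, function(r) refine(r[1L], r[2L])))
  dur <- (bounds[, 2L] - bounds[, 1L]) * dt
  bounds <- bounds[dur >= min_stance, , drop = FALSE]
  if (nrow(bounds) == 0L) {
    return(data.frame(t_td = numeric(), t_lo = numeric()))
  }
  # merge refinements that collapsed onto the same stance
  keep <- c(TRUE, diff(bounds[, 1L]) * dt >= min_gap)
  bounds <- bounds[keep, , drop = FALSE]
  # sub-frame touchdown: extrapolate the pre-touchdown approach velocity to
  # the moment the heel reaches its planted position
  t_td <- ms$t[bounds[, 1L]]
  for (r in seq_len(nrow(bounds))) {
    s <- bounds[r, 1L]
    if (s >= 3L) {
      v_pre <- (heel[s - 1L, 2L] - heel[s - 2L, 2L]) / dt
      if (abs(v_pre) > raw_tol) {
        frac <- (heel[s, 2L] - heel[s - 1L, 2L]) / (v_pre * dt)
        if (is.finite(frac) && frac > 0 && frac < 1) {
          t_td[r] <- ms$t[s - 1L] + frac * dt
        }
      }
    }
  }
  data.frame(t_td = t_td, t_lo = ms$t[bounds[, 2L]])
}

#' Landing velocity from a pre-touchdown cubic fit
#'
#' Fits a cubic polynomial per axis to a trajectory over the window before
#' touchdown and returns the analytic derivative evaluated at the moment
#' just prior to touchdown.
#'
#' @param t sample times (s)
#' @param xyz n x 3 trajectory matrix (m)
#' @param t_td touchdown time (s)
#' @param window fit window length (s) ending at `t_td`
#' @return named velocity vector `c(x, y, z)` (m/s)
#' @export
landing_velocity <- function(t, xyz, t_td, window = 0.1) {
  sel <- which(t >= t_td - window & t < t_td)
  if (length(sel) < 4L) stop("need at least 4 samples in the pre-touchdown window")
  tt <- t[sel] - t_td   # centre so the derivative is evaluated at 0
  v <- vapply(1:3, function(a) {
    fit <- lm(xyz[sel, a] ~ tt + I(tt^2) + I(tt^3))
    unname(coef(fit)[2L])
  }, 0)
  names(v) <- c("x", "y", "z")
  v
}

# total-least-squares line fit in the horizontal plane; returns point p0 and
# unit direction u
fit_line_2d <- function(xy) {
  p0 <- colMeans(xy)
  d <- sweep(xy, 2L, p0)
  u <- eigen(crossprod(d) / nrow(d), symmetric = TRUE)$vectors[, 1L]
  list(p0 = p0, u = u / sqrt(sum(u^2)))
}

dist_to_line <- function(p, line) {
  d <- p - line$p0
  abs(d[1L] * line$u[2L] - d[2L] * line$u[1L])
}

#' Per-step kinematic measures
#'
#' Computes every per-step measure from the marker data and detected stance
#' events: step length and duration (CoM travel between consecutive
#' touchdowns), CoM speed, step width (twice the nearest approach of the
#' stance heel to the horizontal-plane regression line of the stance-phase
#' CoM), virtual leg length and leg angle at touchdown, heel and CoM
#' landing velocities from pre-touchdown cubic fits, leg retraction rate,
#' and dimensionless forward foot speed. Fore-aft quantities are expressed
#' in the direction-of-travel frame so back-and-forth runs pool. Steps that
#' span a turnaround (direction change or stretched step interval) are
#' flagged `is_turn` and excluded from traversal meanders.
#'
#' @param ms a [marker_set()]
#' @param events data.frame from [detect_stance_events()]
#' @param subject a [subject_params()]
#' @return data.frame of class `step_series`, one row per step, with the
#'   per-traversal meander table in attribute `meander`
#' @export
per_step_metrics <- function(ms, events, subject) {
  if (nrow(events) < 2L) stop("need at least two stance events")
  com <- com_trajectory(ms)
  heel_for <- function(k) {
    foot <- if ("foot" %in% names(events)) events$foot[k] else ""
    role <- if (foot %in% c("l", "r")) paste0("heel_", foot) else "heel"
    ms$markers[[role]]
  }
  t <- ms$t
  g <- subject$g
  ll <- subject$leg_length
  n <- nrow(events) - 1L
  interp_row <- function(m, tt) {
    vapply(1:3, function(a) approx(t, m[, a], xout = tt, rule = 2L)$y, 0)
  }
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    td <- events$t_td[k]; lo <- events$t_lo[k]; td_next <- events$t_td[k + 1L]
    heel <- heel_for(k)
    stance_sel <- which(t >= td & t <= lo)
    heel_pos <- apply(heel[stance_sel, , drop = FALSE], 2L, median)
    com_td <- interp_row(com, td)
    com_next <- interp_row(com, td_next)
    delta <- com_next - com_td
    d_step <- sqrt(sum(delta[1:2]^2))
    t_step <- td_next - td
    dirn <- sign(delta[2L])
    if (dirn == 0) dirn <- 1
    line <- fit_line_2d(com[stance_sel, 1:2, drop = FALSE])
    width <- 2 * dist_to_line(heel_pos[1:2], line)
    l_vec <- com_td - heel_pos          # heel -> CoM at touchdown
    l_len <- sqrt(sum(l_vec^2))
    horiz <- sqrt(sum(l_vec[1:2]^2))
    theta <- atan2(horiz, l_vec[3L]) *
      sign(dirn * (heel_pos[2L] - com_td[2L]))   # + when heel is ahead
    v_heel <- landing_velocity(t, heel, td)
    v_com <- landing_velocity(t, com, td)
    v_rel <- v_heel - v_com
    l_hat <- l_vec / l_len
    v_perp <- v_rel - sum(v_rel * l_hat) * l_hat
    rows[[k]] <- data.frame(
      step = k, t_td = td, t_lo = lo, direction = dirn,
      step_length = d_step, step_duration = t_step,
      com_speed = d_step / t_step,
      step_width = width,
      virtual_leg_length = l_len,
      leg_angle = theta,
      heel_x = heel_pos[1L], heel_y = heel_pos[2L], heel_z = heel_pos[3L],
      v_heel_x = v_heel[1L], v_heel_y = v_heel[2L], v_heel_z = v_heel[3L],
      v_com_x = v_com[1L], v_com_y = v_com[2L], v_com_z = v_com[3L],
      retraction_rate = sqrt(sum(v_perp^2)) / l_len,
      fwd_foot_speed = dirn * v_heel[2L],
      fwd_foot_speed_froude = dirn * v_heel[2L] / sqrt(g * ll)
    )
  }
  series <- do.call(rbind, rows)
  med_dt <- median(series$step_duration)
  chg <- diff(sign(series$direction)) != 0
  # a turnaround contaminates the step ending at the direction change and
  # the one starting from the planted turn stance
  series$is_turn <- c(chg, FALSE) | c(FALSE, chg) |
    series$step_duration > 1.5 * med_dt
  # meander per traversal: excess CoM path length over its straight-line fit
  trav_id <- cumsum(c(1L, diff(series$direction) != 0))
  meanders <- lapply(split(seq_len(nrow(series)), trav_id), function(idx) {
    if (length(idx) < 3L) return(NULL)
    sel <- which(t >= series$t_td[idx[1L]] & t <= series$t_td[idx[length(idx)]])
    xy <- com[sel, 1:2, drop = FALSE]
    d <- sum(sqrt(rowSums(diff(xy)^2)))
    line <- fit_line_2d(xy)
    proj <- as.numeric(sweep(xy, 2L, line$p0) %*% line$u)
    d0 <- diff(range(proj))
    data.frame(traversal = trav_id[idx[1L]],
               direction = series$direction[idx[1L]],
               n_steps = length(idx), meander = (d - d0) / d0)
  })
  meanders <- do.call(rbind, meanders)
  if (is.null(meanders)) {
    warning("no traversal long enough for a meander estimate")
  }
  attr(series, "meander") <- meanders
  class(series) <- c("step_series", "data.frame")
  series
}

#' Trial-level summary of step measures
#'
#' Mean/SD and median/IQR of each per-step measure, in dimensional units and
#' the standard nondimensional forms: lengths in percent leg length (%LL)
#' and speeds in Froude units (divided by `sqrt(g * leg_length)`).
#'
#' @param series a [per_step_metrics()] result
#' @param subject a [subject_params()]
#' @param drop_turns exclude turnaround steps?
#' @return data.frame with one row per (measure, unit) pair
#' @export
trial_summary <- function(series, subject, drop_turns = TRUE) {
  if (nrow(series) < 2L) stop("need at least two steps to summarize a trial")
  if (drop_turns) series <- series[!series$is_turn, , drop = FALSE]
  ll <- subject$leg_length
  sqrtgl <- sqrt(subject$g * ll)
  take <- function(measure, values, unit) {
    data.frame(
      measure = measure, unit = unit, n = sum(is.finite(values)),
      mean = mean(values), sd = sd(values),
      median = median(values), iqr = unname(diff(quantile(values, c(0.25, 0.75))))
    )
  }
  out <- rbind(
    take("step_length", series$step_length, "m"),
    take("step_length", 100 * series$step_length / ll, "%LL"),
    take("step_width", series$step_width, "m"),
    take("step_width", 100 * series$step_width / ll, "%LL"),
    take("com_speed", series$com_speed, "m/s"),
    take("com_speed", series$com_speed / sqrtgl, "froude"),
    take("virtual_leg_length", 100 * series$virtual_leg_length / ll, "%LL"),
    take("leg_angle", series$leg_angle, "rad"),
    take("fwd_foot_speed", series$fwd_foot_speed_froude, "froude"),
    take("retraction_rate", series$retraction_rate, "rad/s")
  )
  meander <- attr(series, "meander")
  if (!is.null(meander) && nrow(meander) > 0L) {
    out <- rbind(out, take("meander", meander$meander, "1"))
  }
  rownames(out) <- NULL
  out
}
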