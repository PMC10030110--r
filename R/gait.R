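#' Gait specification for synthetic running trials
#'
#' Defaults emulate the study conditions: back-and-forth shuttle running at
#' about 3.2 m/s for a 66.1 kg, 0.89 m leg-length runner, heel-strike gait
#' with step length 128 %LL (SD 6 %LL), step width 4.2 %LL (SD 2.8 %LL),
#' touchdown leg angle 0.20 rad, dimensionless forward foot landing speed
#' 0.37 Froude, and a braking impulse equal to 6 % of the aerial forward
#' momentum.
#'
#' @param speed mean CoM forward speed (m/s)
#' @param step_length,step_length_sd step length mean and SD (m)
#' @param step_width,step_width_sd step width mean and SD (m)
#' @param duty_factor stance time over stride time
#' @param leg_length leg length (m)
#' @param body_mass body mass (kg)
#' @param foot_length foot length (m)
#' @param touchdown_leg_angle touchdown leg angle (rad)
#' @param virtual_leg_frac touchdown heel-to-CoM distance over leg length
#' @param fwd_foot_speed_froude,fwd_foot_speed_sd forward foot landing speed
#'   mean and SD (Froude units)
#' @param braking_fraction target braking impulse as a fraction of aerial
#'   forward momentum
#' @param com_landing_speed vertical CoM landing speed, positive down (m/s)
#' @param turn_dwell time spent planted at each turnaround (s)
#' @param g gravitational acceleration (m/s^2)
#' @param seed integer seed
#' @return an object of class `gait_spec`
#' @export
gait_spec <- function(speed = 3.2,
                      step_length = 1.28 * 0.89, step_length_sd = 0.06 * 0.89,
                      step_width = 0.042 * 0.89, step_width_sd = 0.028 * 0.89,
                      duty_factor = 0.30,
                      leg_length = 0.89, body_mass = 66.1, foot_length = 0.19,
                      touchdown_leg_angle = 0.20, virtual_leg_frac = 1.20,
                      fwd_foot_speed_froude = 0.37, fwd_foot_speed_sd = 0.12,
                      braking_fraction = 0.06,
                      com_landing_speed = 0.7,
                      turn_dwell = 0.5, g = 9.81, seed = 1L) {
  if (duty_factor <= 0 || duty_factor >= 1) stop("duty factor must lie in (0, 1)")
  if (step_length_sd < 0 || step_width_sd < 0 || fwd_foot_speed_sd < 0) {
    stop("spread parameters must be non-negative")
  }
  structure(
    list(
      speed = speed,
      step_length = step_length, step_length_sd = step_length_sd,
      step_width = step_width, step_width_sd = step_width_sd,
      duty_factor = duty_factor,
      leg_length = leg_length, body_mass = body_mass,
      foot_length = foot_length,
      touchdown_leg_angle = touchdown_leg_angle,
      virtual_leg_frac = virtual_leg_frac,
      fwd_foot_speed_froude = fwd_foot_speed_froude,
      fwd_foot_speed_sd = fwd_foot_speed_sd,
      braking_fraction = braking_fraction,
      com_landing_speed = com_landing_speed,
      turn_dwell = turn_dwell, g = g, seed = as.integer(seed)
    ),
    class = "gait_spec"
  )
}

#' Subject parameters
#'
#' @param body_mass body mass (kg)
#' @param leg_length greater trochanter to lateral malleolus distance (m)
#' @param foot_length heel-to-toe marker distance (m)
#' @param ankle_height malleolus height while standing (m)
#' @param g gravitational acceleration (m/s^2)
#' @return an object of class `subject_params`
#' @export
subject_params <- function(body_mass = 66.1, leg_length = 0.89,
                           foot_length = 0.19, ankle_height = 0.066,
                           g = 9.81) {
  stopifnot(body_mass > 0, leg_length > 0, foot_length > 0, ankle_height > 0)
  structure(
    list(body_mass = body_mass, leg_length = leg_length,
         foot_length = foot_length, ankle_height = ankle_height, g = g),
    class = "subject_params"
  )
}

#' Labelled 3D marker trajectory set
#'
#' @param t sample times (s), uniform
#' @param markers named list of n x 3 matrices with columns `x`, `y`, `z`
#'   (m); roles must include `heel`, `toe`, `ankle` and four hip markers
#'   `hip_lf`, `hip_rf`, `hip_lb`, `hip_rb`
#' @param rate sampling rate (Hz)
#' @param standing_heights named numeric vector of marker heights during
#'   quiet standing (m)
#' @return an object of class `marker_set`
#' @export
marker_set <- function(t, markers, rate, standing_heights) {
  if (anyDuplicated(names(markers))) stop("marker roles must be unique")
  structure(
    list(t = t, markers = markers, rate = rate,
         standing_heights = standing_heights),
    class = "marker_set"
  )
}

com_trajectory <- function(ms) {
  hips <- ms$markers[c("hip_lf", "hip_rf", "hip_lb", "hip_rb")]
  Reduce(`+`, hips) / 4
}

#' Three-axis force-plate trace
#'
#' @param t sample times (s)
#' @param Fx,Fy,Fz force components (N); `y` is along the track, `z` up
#' @param rate sampling rate (Hz)
#' @param baseline_idx index range of a guaranteed-unloaded interval
#' @return an object of class `force_trace`
#' @export
force_trace <- function(t, Fx, Fy, Fz, rate, baseline_idx) {
  structure(
    list(t = t, Fx = Fx, Fy = Fy, Fz = Fz, rate = rate,
         baseline_idx = baseline_idx),
    class = "force_trace"
  )
}

# quintic interpolation on [0, 1]: start at rest (zero velocity and
# acceleration), end with slope m1 and zero acceleration
quintic01 <- function(u, p0, p1, m1) {
  smoothstep <- 6 * u^5 - 15 * u^4 + 10 * u^3
  endslope <- -3 * u^5 + 7 * u^4 - 4 * u^3
  p0 + (p1 - p0) * smoothstep + m1 * endslope
}

# raised-cosine bump centred at c with full width w, on tau in [0, 1]
rc_bump <- function(tau, c, w) {
  out <- numeric(length(tau))
  sel <- abs(tau - c) <= w / 2
  out[sel] <- cos(pi * (tau[sel] - c) / w)^2
  out
}

#' Generate a synthetic running trial with known ground truth
#'
#' Simulates back-and-forth heel-strike running over a terrain field and
#' renders it as the signals the laboratory pipeline consumes: foot and hip
#' marker trajectories at 300 Hz, a 600 Hz force-plate trace for steps
#' landing on the plate region, and a ground-truth table of every stepping
#' event. During stance the heel is planted on the terrain (forward velocity
#' zero, height at the terrain surface); the CoM (mean of the four hip
#' markers) advances at the step's speed with a sinusoidal vertical
#' excursion whose downward velocity at touchdown equals the configured
#' landing speed. The fore-aft force has a braking lobe whose impulse is
#' exactly `braking_fraction` times the step's aerial forward momentum,
#' followed by an equal propulsive lobe; the vertical force is double-peaked
#' (impact plus active peak) and supports body weight on average.
#'
#' @param gait a [gait_spec()]
#' @param field a [terrain_field()]
#' @param duration trial duration (s)
#' @param marker_rate,force_rate sampling rates (Hz)
#' @param marker_noise_sd,force_noise_sd additive Gaussian noise SDs
#'   (m and N); defaults are noise-free markers and a quiet 0.5 N baseline
#' @param plate_region y-range of the force plates (m); defaults to the
#'   central 2 m of the field
#' @param seed integer seed; defaults to the gait spec's seed
#' @return list of class `synthetic_trial` with elements `markers`
#'   (a [marker_set()]), `force` (a [force_trace()]), and `truth` (a
#'   data.frame of per-step ground truth)
#' @export
generate_trial <- function(gait, field, duration = 30,
                           marker_rate = 300, force_rate = 600,
                           marker_noise_sd = 0, force_noise_sd = 0.5,
                           plate_region = NULL, seed = NULL) {
  seed <- seed %||% gait$seed
  ymin <- min(field_y(field)) + 0.3
  ymax <- max(field_y(field)) - 0.3
  if (ymax - ymin < 2 * gait$step_length) {
    stop("track too short for the requested step length")
  }
  x_center <- mean(range(field_x(field)))
  plate_region <- plate_region %||% (mean(c(ymin, ymax)) + c(-1, 1))
  heel_h <- 0.03   # heel marker height above the surface
  with_seed(seed, {
    ## ---- footstep / event schedule -------------------------------------
    steps <- list()
    t <- 1.2          # leave an unloaded force baseline at the start
    y <- ymin + 0.2
    dirn <- 1L
    parity <- 0L
    k <- 0L
    while (t < duration) {
      k <- k + 1L
      sl_k <- gait$step_length + rnorm(1L, 0, gait$step_length_sd)
      sw_k <- gait$step_width + rnorm(1L, 0, gait$step_width_sd)
      y_next <- y + dirn * sl_k
      is_turn <- y_next > ymax || y_next < ymin
      if (is_turn) {
        dirn <- -dirn
        y_next <- y   # plant at the end, then head back on later steps
      }
      x_k <- x_center + (if (parity %% 2L == 0L) 1 else -1) * sw_k / 2
      t_step <- sl_k / gait$speed
      steps[[k]] <- data.frame(
        step = k, t_td = t, x = x_k, y = y_next, dir = dirn,
        step_length = sl_k, step_width = abs(sw_k), t_step = t_step,
        is_turn = is_turn
      )
      t <- t + if (is_turn) gait$turn_dwell else t_step
      y <- y_next
      parity <- parity + 1L
    }
    truth <- do.call(rbind, steps)
    truth <- truth[truth$t_td + 0.6 < duration, , drop = FALSE]
    n_steps <- nrow(truth)
    t_step_nom <- gait$step_length / gait$speed
    t_stance <- 2 * gait$duty_factor * t_step_nom
    truth$t_lo <- truth$t_td +
      ifelse(truth$is_turn, gait$turn_dwell, pmin(t_stance, 0.9 * truth$t_step))
    truth$z_terrain <- terrain_height_at(field, truth$x, truth$y)
    truth$on_plate <- !truth$is_turn &
      truth$y >= plate_region[1L] & truth$y <= plate_region[2L]
    truth$braking_fraction <- ifelse(truth$on_plate, gait$braking_fraction, NA)
    truth$v_aerial <- truth$step_length / truth$t_step

    ## ---- marker trajectories -------------------------------------------
    tm <- seq(0, duration, by = 1 / marker_rate)
    nm <- length(tm)
    sqrtgl <- sqrt(gait$g * gait$leg_length)
    lead <- gait$virtual_leg_frac * gait$leg_length * sin(gait$touchdown_leg_angle)
    com_z0 <- gait$virtual_leg_frac * gait$leg_length * cos(gait$touchdown_leg_angle)
    com <- matrix(NA_real_, nm, 3L)
    td <- truth$t_td; lo <- truth$t_lo
    z_heel_td <- truth$z_terrain + heel_h
    truth$foot <- rep_len(c("l", "r"), n_steps)
    v_land_y <- (gait$fwd_foot_speed_froude +
                   rnorm(n_steps, 0, gait$fwd_foot_speed_sd)) * sqrtgl
    truth$fwd_foot_speed <- v_land_y
    vz_land <- -0.4
    # each foot is planted during its own stances and swings to its next
    # stance (one stride later) with a smooth quintic transport phase and a
    # constant-velocity terminal approach longer than the landing-fit window
    heel_for_foot <- function(foot) {
      heel <- matrix(NA_real_, nm, 3L)
      ks <- which(truth$foot == foot)
      for (kk in ks) {
        sel <- tm >= td[kk] & tm < lo[kk]
        heel[sel, 1L] <- truth$x[kk]
        heel[sel, 2L] <- truth$y[kk]
        heel[sel, 3L] <- z_heel_td[kk]
        nk <- kk + 2L
        if (nk <= n_steps) {
          Tsw <- td[nk] - lo[kk]
          t_lin <- min(0.12, 0.4 * Tsw)
          td1 <- td[nk] - t_lin
          vy_land <- truth$dir[nk] * v_land_y[nk]
          y1 <- truth$y[nk] - vy_land * t_lin
          z1 <- z_heel_td[nk] - vz_land * t_lin
          main <- tm >= lo[kk] & tm < td1
          u <- (tm[main] - lo[kk]) / (td1 - lo[kk])
          T1 <- td1 - lo[kk]
          heel[main, 1L] <- quintic01(u, truth$x[kk], truth$x[nk], 0)
          heel[main, 2L] <- quintic01(u, truth$y[kk], y1, vy_land * T1)
          heel[main, 3L] <- quintic01(u, z_heel_td[kk], z1, vz_land * T1) +
            0.12 * sin(pi * u)^2
          fin <- tm >= td1 & tm < td[nk]
          heel[fin, 1L] <- truth$x[nk]
          heel[fin, 2L] <- truth$y[nk] - vy_land * (td[nk] - tm[fin])
          heel[fin, 3L] <- z_heel_td[nk] - vz_land * (td[nk] - tm[fin])
        }
      }
      # before its first stance the foot descends toward it at the landing
      # velocity (airborne approach); after its last liftoff it floats, so
      # no spurious stance is detected at the trial edges
      k0 <- ks[1L]; k1 <- ks[length(ks)]
      pre <- which(tm < td[k0])
      dt_pre <- td[k0] - tm[pre]
      heel[pre, 1L] <- truth$x[k0]
      heel[pre, 2L] <- truth$y[k0] - truth$dir[k0] * v_land_y[k0] * dt_pre
      heel[pre, 3L] <- z_heel_td[k0] - vz_land * dt_pre
      post <- which(is.na(heel[, 1L]))
      heel[post, 1L] <- truth$x[k1]
      heel[post, 2L] <- truth$y[k1]
      heel[post, 3L] <- heel_h + 0.2
      heel
    }
    heels <- lapply(c(l = "l", r = "r"), heel_for_foot)
    # CoM: linear in y between touchdown anchors, vertical bounce per step
    com_y_td <- truth$y - truth$dir * lead
    com[, 2L] <- approx(td, com_y_td, xout = tm, rule = 2L)$y
    com[, 1L] <- x_center
    A_z <- gait$com_landing_speed * t_step_nom / (2 * pi)
    phase <- rep(0, nm)
    seg <- findInterval(tm, td)
    inside <- seg >= 1L & seg <= n_steps
    dt_step <- c(diff(td), t_step_nom)
    phase[inside] <- (tm[inside] - td[seg[inside]]) / dt_step[seg[inside]]
    com[, 3L] <- com_z0 + heel_h - A_z * sin(2 * pi * pmin(phase, 1))
    dir_t <- truth$dir[pmin(pmax(seg, 1L), n_steps)]
    hip_off <- list(
      hip_lf = c(-0.10, 0.05, 0), hip_rf = c(0.10, 0.05, 0),
      hip_lb = c(-0.10, -0.05, 0), hip_rb = c(0.10, -0.05, 0)
    )
    markers <- c(
      list(
        heel_l = heels$l,
        toe_l = heels$l + cbind(0, dir_t * gait$foot_length, 0.005),
        ankle_l = heels$l + cbind(0, dir_t * 0.02, 0.066),
        heel_r = heels$r,
        toe_r = heels$r + cbind(0, dir_t * gait$foot_length, 0.005),
        ankle_r = heels$r + cbind(0, dir_t * 0.02, 0.066)
      ),
      lapply(hip_off, function(o) sweep(com, 2L, -o))
    )
    if (marker_noise_sd > 0) {
      markers <- lapply(markers, function(m) {
        m + matrix(rnorm(length(m), 0, marker_noise_sd), nrow(m))
      })
    }
    colnames_xyz <- c("x", "y", "z")
    markers <- lapply(markers, `colnames<-`, colnames_xyz)
    standing <- c(heel_l = heel_h, toe_l = heel_h + 0.005,
                  ankle_l = heel_h + 0.066,
                  heel_r = heel_h, toe_r = heel_h + 0.005,
                  ankle_r = heel_h + 0.066)
    ms <- marker_set(tm, markers, marker_rate, standing)

    ## ---- force-plate trace ---------------------------------------------
    tf <- seq(0, duration, by = 1 / force_rate)
    nf <- length(tf)
    Fx <- rnorm(nf, 0, force_noise_sd)
    Fy <- rnorm(nf, 0, force_noise_sd)
    Fz <- rnorm(nf, 0, force_noise_sd)
    m <- gait$body_mass
    for (kk in which(truth$on_plate)) {
      sel <- which(tf >= td[kk] & tf <= lo[kk])
      if (length(sel) < 6L) next
      tau <- (tf[sel] - td[kk]) / (lo[kk] - td[kk])
      dt <- 1 / force_rate
      # vertical: impact + active peak, rising from zero exactly at
      # touchdown and vanishing at liftoff, scaled so the stance impulse
      # supports body weight over one step period
      shape_z <- 0.8 * rc_bump(tau, 0.125, 0.25) + rc_bump(tau, 0.55, 0.90)
      Iz <- sum(shape_z) * dt
      Fz[sel] <- Fz[sel] + shape_z * (m * gait$g * truth$t_step[kk] / Iz)
      # fore-aft: braking lobe then equal propulsion lobe (trapezoid-exact)
      br <- rc_bump(tau, 0.225, 0.45) * (tau <= 0.45)
      pr <- rc_bump(tau, 0.725, 0.55) * (tau > 0.45)
      trapz_w <- rep(dt, length(sel)); trapz_w[c(1L, length(sel))] <- dt / 2
      J_target <- gait$braking_fraction * m * truth$v_aerial[kk]
      Fy[sel] <- Fy[sel] +
        truth$dir[kk] * (-br * J_target / sum(br * trapz_w) +
                           pr * J_target / sum(pr * trapz_w))
    }
    baseline_idx <- which(tf < td[1L] - 0.2)
    ft <- force_trace(tf, Fx, Fy, Fz, force_rate, baseline_idx)

    structure(
      list(markers = ms, force = ft, truth = truth,
           gait = gait, seed = seed, plate_region = plate_region),
      class = "synthetic_trial"
    )
  })
}
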