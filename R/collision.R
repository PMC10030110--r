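# Planar four-link collision model of heel strike.
#
# Sagittal-plane coordinates: y forward (direction of travel), z up,
# rotations about the lateral +x axis. The scalar cross product of two
# in-plane vectors is cross2(a, b) = a_y b_z - a_z b_y, and an angular
# velocity w about +x maps a position vector r to the velocity w * perp(r)
# with perp(r) = (-r_z, r_y).

cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]
perp <- function(r) c(-r[2L], r[1L])

#' Default anthropometric segment table
#'
#' Segment masses as fractions of body mass follow standard gait-analysis
#' tables (foot 0.0145, shank 0.0465, thigh 0.100); the torso link carries
#' the remainder, which lumps head, arms, trunk, and the swing leg. Segment
#' lengths are fractions of leg length (greater trochanter to lateral
#' malleolus); the ankle sits 0.074 leg lengths above the heel along the
#' chain so that heel-to-hip distance equals one leg length. Each link is
#' treated as a uniform slender rod: centre of mass at midlength and radius
#' of gyration \eqn{1/\sqrt{12}} of segment length about its own centre.
#'
#' @return a list of per-segment parameters, editable and reusable by
#'   [build_chain()]
#' @export
default_anthropometry <- function() {
  list(
    mass_frac = c(foot = 0.0145, shank = 0.0465, thigh = 0.100,
                  torso = 1 - 0.0145 - 0.0465 - 0.100),
    ankle_height_frac = 0.074,     # heel to ankle, fraction of leg length
    shank_length_frac = 0.464,
    thigh_length_frac = 0.462,
    torso_length_frac = 0.50,
    com_frac = c(foot = 0.5, shank = 0.5, thigh = 0.5, torso = 0.5),
    rog_frac = c(foot = 1, shank = 1, thigh = 1, torso = 1) / sqrt(12),
    foot_inclination = 20 * pi / 180  # sole angle above horizontal at heel strike
  )
}

# compose whole-body centre of mass and inertia from segments
compose_body <- function(masses, coms, inertias) {
  Mb <- sum(masses)
  G <- c(sum(masses * vapply(coms, `[`, 0, 1L)),
         sum(masses * vapply(coms, `[`, 0, 2L))) / Mb
  IG <- sum(inertias) +
    sum(masses * vapply(coms, function(p) sum((p - G)^2), 0))
  list(Mb = Mb, G = G, I_G = IG)
}

# build segment geometry for a given chain inclination phi (rad from
# vertical, positive tilts the hip behind the heel) and leg stretch factor
chain_geometry <- function(mass, leg_length, foot_length, s, anthro,
                           phi, stretch) {
  u <- c(-sin(phi), cos(phi))            # heel -> hip direction
  sole <- c(cos(anthro$foot_inclination), sin(anthro$foot_inclination))
  A <- c(0, 0)                                        # heel
  B <- A + stretch * anthro$ankle_height_frac * leg_length * u   # ankle
  C <- B + stretch * anthro$shank_length_frac * leg_length * u   # knee
  D <- C + stretch * anthro$thigh_length_frac * leg_length * u   # hip
  Lt <- anthro$torso_length_frac * leg_length
  N <- D + c(0, Lt)                                   # torso top (vertical)
  O <- c(s * foot_length * sole[1L], 0)               # ground contact point
  seg_len <- c(
    foot = foot_length,
    shank = stretch * anthro$shank_length_frac * leg_length,
    thigh = stretch * anthro$thigh_length_frac * leg_length,
    torso = Lt
  )
  coms <- list(
    foot = A + anthro$com_frac[["foot"]] * foot_length * sole,
    shank = B + anthro$com_frac[["shank"]] * (C - B),
    thigh = C + anthro$com_frac[["thigh"]] * (D - C),
    torso = D + anthro$com_frac[["torso"]] * (N - D)
  )
  masses <- anthro$mass_frac * mass
  inertias <- masses * (anthro$rog_frac * seg_len)^2
  body <- compose_body(masses, coms, inertias)
  list(A = A, B = B, C = C, D = D, N = N, O = O,
       masses = masses, coms = coms, inertias = inertias,
       G = body$G, I_G = body$I_G, Mb = body$Mb, seg_len = seg_len)
}

#' Build the four-link body chain at touchdown
#'
#' Constructs the planar foot-shank-thigh-torso chain in its touchdown
#' posture: shank and thigh collinear along the leg line, torso vertical
#' above the hip, foot inclined for heel strike with the ground contact
#' point O a fraction `s` of the foot length ahead of the heel. When
#' `solve_posture` is TRUE (the default), the chain inclination and a
#' uniform leg extension factor are solved so that the composed centre of
#' mass G sits exactly on the virtual leg: at distance
#' `virtual_leg_frac * leg_length` from the heel and at angle `theta` from
#' vertical, matching how touchdown geometry is measured from motion
#' capture.
#'
#' @param mass body mass Mb (kg)
#' @param leg_length leg length (m)
#' @param theta touchdown leg angle (rad), positive when the heel is ahead
#'   of the centre of mass
#' @param s foot-strike index in `[0, 1]`; 0 is a pure heel strike
#' @param virtual_leg_frac heel-to-CoM distance at touchdown, as a fraction
#'   of leg length
#' @param foot_length foot length (m)
#' @param anthro anthropometric table, see [default_anthropometry()]
#' @param solve_posture solve for chain inclination and leg extension so the
#'   composed CoM matches the prescribed virtual leg? If FALSE, `theta` is
#'   used directly as the chain inclination with no extension.
#' @return an object of class `segment_chain`
#' @export
build_chain <- function(mass = 66.1, leg_length = 0.89, theta = 0.20,
                        s = 0.15, virtual_leg_frac = 1.20,
                        foot_length = 0.19,
                        anthro = default_anthropometry(),
                        solve_posture = TRUE) {
  if (s < 0 || s > 1) stop("foot-strike index s must lie in [0, 1]")
  if (abs(sum(anthro$mass_frac) - 1) > 1e-8) {
    stop("anthropometric mass fractions must sum to 1")
  }
  target <- virtual_leg_frac * leg_length * c(-sin(theta), cos(theta))
  geom_for <- function(p) {
    chain_geometry(mass, leg_length, foot_length, s, anthro,
                   phi = p[1L], stretch = p[2L])
  }
  if (solve_posture) {
    p <- c(theta, 1)
    for (iter in 1:50) {
      g <- geom_for(p)
      resid <- g$G - target
      if (sqrt(sum(resid^2)) < 1e-10) break
      # numerical Jacobian of G(phi, stretch)
      eps <- 1e-7
      J <- cbind(
        (geom_for(p + c(eps, 0))$G - g$G) / eps,
        (geom_for(p + c(0, eps))$G - g$G) / eps
      )
      p <- p - solve(J, resid)
    }
    g <- geom_for(p)
    if (sqrt(sum((g$G - target)^2)) > 1e-8) {
      stop("posture solve did not converge for the requested touchdown geometry")
    }
    phi <- p[1L]; stretch <- p[2L]
  } else {
    phi <- theta; stretch <- 1
    g <- geom_for(c(phi, stretch))
  }
  structure(
    c(g, list(theta = theta, phi = phi, stretch = stretch, s = s,
              leg_length = leg_length, foot_length = foot_length,
              virtual_leg_frac = virtual_leg_frac, anthro = anthro)),
    class = "segment_chain"
  )
}

#' @export
print.segment_chain <- function(x, ...) {
  cat(sprintf(
    "<segment_chain> Mb %.1f kg, leg %.2f m, theta %.3f rad, s %.2f\n",
    x$Mb, x$leg_length, x$theta, x$s
  ))
  cat(sprintf("  G = (%.3f, %.3f) m, I/G = %.2f kg m^2\n",
              x$G[1L], x$G[2L], x$I_G))
  invisible(x)
}

#' Pre-collision body state
#'
#' The whole body approaches touchdown translating with the centre-of-mass
#' velocity and rotating with a single shared angular velocity. The angular
#' velocity may be given directly or derived from the forward foot (heel)
#' speed at landing: with the heel at A, `v_heel_y = v_com_y + omega * G_z`,
#' which is how leg retraction shows up in marker data.
#'
#' @param chain a [build_chain()] result
#' @param v_com pre-collision CoM velocity `c(vy, vz)` (m/s); vz negative
#'   downward
#' @param omega pre-collision angular velocity (rad/s, about +x); if `NULL`,
#'   derived from `fwd_foot_speed`
#' @param fwd_foot_speed forward heel speed at landing (m/s), used when
#'   `omega` is `NULL`
#' @return an object of class `collision_state`
#' @export
collision_state <- function(chain, v_com = c(3.2, -0.7), omega = NULL,
                            fwd_foot_speed = NULL) {
  if (is.null(omega)) {
    if (is.null(fwd_foot_speed)) {
      stop("provide either omega or fwd_foot_speed")
    }
    omega <- (fwd_foot_speed - v_com[1L]) / chain$G[2L]
  }
  structure(
    list(v_com = as.numeric(v_com), omega = as.numeric(omega)),
    class = "collision_state"
  )
}

# per-segment pre-collision CoM velocities for a shared angular velocity
pre_velocities <- function(chain, state) {
  lapply(chain$coms, function(p) {
    state$v_com + state$omega * perp(p - chain$G)
  })
}

kinetic_energy <- function(masses, vels, inertias, omegas) {
  sum(masses * vapply(vels, function(v) sum(v^2), 0)) / 2 +
    sum(inertias * omegas^2) / 2
}

finish_result <- function(chain, state, model, omegas_post, v_post, v_pre) {
  masses <- chain$masses
  J <- Reduce(`+`, Map(function(m, vp, vm) m * (vp - vm),
                       masses, v_post, v_pre))
  v_com_post <- Reduce(`+`, Map(`*`, masses, v_post)) / chain$Mb
  Jb <- chain$Mb * state$v_com[1L]
  # contact-point velocity from the foot segment (zero by construction)
  vO_post <- v_post$foot + omegas_post[["foot"]] * perp(chain$O - chain$coms$foot)
  structure(
    list(
      model = model,
      omega_post = omegas_post,
      v_com_post = v_com_post,
      v_segments_post = v_post,
      J = J,
      Jy_star = abs(J[1L]),
      Jb = Jb,
      normalized_impulse = abs(J[1L]) / Jb,
      vO_post = vO_post,
      KE_pre = kinetic_energy(masses, v_pre, chain$inertias,
                              rep(state$omega, 4L)),
      KE_post = kinetic_energy(masses, v_post, chain$inertias, omegas_post)
    ),
    class = "collision_result"
  )
}

#' @export
print.collision_result <- function(x, ...) {
  cat(sprintf(
    "<collision_result:%s> |Jy*| = %.2f N s, Jb = %.1f N s, |Jy*|/Jb = %.4f\n",
    x$model, x$Jy_star, x$Jb, x$normalized_impulse
  ))
  invisible(x)
}

#' Rigid-joint collision
#'
#' Instantaneous inelastic heel-ground collision with all joints locked: the
#' whole chain shares one post-collision angular velocity. The single
#' unknown follows from angular momentum balance about the contact point O
#' (which is brought to rest), and the collisional impulse is the total
#' change of linear momentum.
#'
#' @param chain a [build_chain()] result
#' @param state a [collision_state()]
#' @return a `collision_result` with the post-collision angular velocity,
#'   CoM velocity, impulse `J`, fore-aft magnitude `Jy_star`, normalizer
#'   `Jb = Mb * v_y^-`, and the normalized impulse `|Jy*|/Jb`
#' @export
rigid_collision <- function(chain, state) {
  rGO <- chain$G - chain$O
  if (sum(rGO^2) < 1e-16) stop("degenerate geometry: CoM coincides with contact point")
  v_pre <- pre_velocities(chain, state)
  H_pre <- sum(mapply(function(m, p, v) m * cross2(p - chain$O, v),
                      chain$masses, chain$coms, v_pre)) +
    sum(chain$inertias) * state$omega
  denom <- sum(mapply(function(m, p) m * sum((p - chain$O)^2),
                      chain$masses, chain$coms)) + sum(chain$inertias)
  w_post <- H_pre / denom
  v_post <- lapply(chain$coms, function(p) w_post * perp(p - chain$O))
  omegas <- c(foot = w_post, shank = w_post, thigh = w_post, torso = w_post)
  finish_result(chain, state, "rigid", omegas, v_post, v_pre)
}

#' Compliant-joint collision
#'
#' Instantaneous inelastic heel-ground collision with infinitely compliant
#' joints: each segment keeps its own post-collision angular velocity, and
#' the segments are coupled only by the reaction impulses at the joints.
#' Four angular momentum balances (whole body about O; shank+thigh+torso
#' about the ankle B; thigh+torso about the knee C; torso about the hip D),
#' with segment velocities expressed through the kinematic chain anchored at
#' the arrested contact point O, give a linear system in the four unknown
#' segment angular velocities.
#'
#' @inheritParams rigid_collision
#' @return a `collision_result`; `omega_post` holds the four segment
#'   angular velocities
#' @export
compliant_collision <- function(chain, state) {
  v_pre <- pre_velocities(chain, state)
  segs <- c("foot", "shank", "thigh", "torso")
  # post-collision CoM velocity of each segment as v = V %*% w with
  # w = (wE, wF, wK, wH); each V is a 2x4 coefficient matrix
  pB <- perp(chain$B - chain$O)
  pC <- perp(chain$C - chain$B)
  pD <- perp(chain$D - chain$C)
  V <- list(
    foot = cbind(perp(chain$coms$foot - chain$O), 0, 0, 0),
    shank = cbind(pB, perp(chain$coms$shank - chain$B), 0, 0),
    thigh = cbind(pB, pC, perp(chain$coms$thigh - chain$C), 0),
    torso = cbind(pB, pC, pD, perp(chain$coms$torso - chain$D))
  )
  balance <- function(about, members) {
    # rows of A and entries of b for one angular momentum balance
    a_row <- numeric(4L)
    b_val <- 0
    for (sn in members) {
      k <- match(sn, segs)
      r <- chain$coms[[sn]] - about
      m <- chain$masses[[sn]]
      # m * cross2(r, V w) + I * w_k
      a_row <- a_row + m * (r[1L] * V[[sn]][2L, ] - r[2L] * V[[sn]][1L, ])
      a_row[k] <- a_row[k] + chain$inertias[[sn]]
      b_val <- b_val + m * cross2(r, v_pre[[sn]]) + chain$inertias[[sn]] * state$omega
    }
    list(a = a_row, b = b_val)
  }
  eqs <- list(
    balance(chain$O, segs),
    balance(chain$B, c("shank", "thigh", "torso")),
    balance(chain$C, c("thigh", "torso")),
    balance(chain$D, "torso")
  )
  A <- do.call(rbind, lapply(eqs, `[[`, "a"))
  b <- vapply(eqs, `[[`, 0, "b")
  qr_A <- qr(A)
  if (qr_A$rank < 4L) {
    stop("compliant collision system is singular (rank ", qr_A$rank,
         "): degenerate masses or geometry")
  }
  w <- solve(qr_A, b)
  names(w) <- segs
  v_post <- lapply(segs, function(sn) as.numeric(V[[sn]] %*% w))
  names(v_post) <- segs
  finish_result(chain, state, "compliant", w, v_post, v_pre)
}

#' Sample synthetic landing states
#'
#' Draws an ensemble of per-step landing conditions emulating the measured
#' distributions: dimensionless forward foot speed ~ Normal(0.4, 0.2), CoM
#' speed ~ Normal(3.2, 0.12) m/s, touchdown leg angle covarying with foot
#' speed at 0.07 rad per Froude unit around 0.20 rad, and a fixed vertical
#' landing speed of 0.7 m/s downward.
#'
#' @param n number of landing states
#' @param seed integer seed
#' @param fs_mean,fs_sd forward foot speed (Froude) mean and SD
#' @param v_mean,v_sd CoM forward speed (m/s) mean and SD
#' @param theta0 leg angle (rad) at `fs_mean`
#' @param theta_slope leg angle change per Froude unit of foot speed (rad)
#' @param vz vertical CoM landing speed, positive down (m/s)
#' @param leg_length leg length (m) for Froude conversion
#' @param g gravitational acceleration (m/s^2)
#' @return data.frame with one row per landing state
#' @export
sample_landing_states <- function(n = 1000L, seed = 1L,
                                  fs_mean = 0.4, fs_sd = 0.2,
                                  v_mean = 3.2, v_sd = 0.12,
                                  theta0 = 0.20, theta_slope = 0.07,
                                  vz = 0.7, leg_length = 0.89, g = 9.81) {
  with_seed(seed, {
    fs <- rnorm(n, fs_mean, fs_sd)
    v <- rnorm(n, v_mean, v_sd)
    data.frame(
      fwd_foot_speed_froude = fs,
      com_speed = v,
      leg_angle = theta0 + theta_slope * (fs - fs_mean),
      vz = vz,
      fwd_foot_speed = fs * sqrt(g * leg_length)
    )
  })
}

#' Model impulse versus foot-speed slope
#'
#' Predicts the normalized fore-aft impulse for every landing state in an
#' ensemble under the rigid or compliant collision model, then regresses the
#' predictions on dimensionless forward foot speed by ordinary least
#' squares.
#'
#' @param model `"rigid"` or `"compliant"`
#' @param ensemble data.frame as returned by [sample_landing_states()]
#' @param mass body mass (kg)
#' @param leg_length leg length (m)
#' @param per_step_geometry rebuild the chain with each state's leg angle
#'   (TRUE) or hold the mean-state geometry fixed (FALSE)?
#' @param g gravitational acceleration (m/s^2)
#' @param ... passed to [build_chain()]
#' @return list with `slope`, `intercept`, `slope_se`, and the per-step
#'   `predicted` normalized impulses
#' @export
impulse_speed_slope <- function(model = c("rigid", "compliant"), ensemble,
                                mass = 66.1, leg_length = 0.89,
                                per_step_geometry = TRUE, g = 9.81, ...) {
  model <- match.arg(model)
  if (nrow(ensemble) < 3L) stop("ensemble must contain at least 3 landing states")
  solver <- if (model == "rigid") rigid_collision else compliant_collision
  mean_chain <- build_chain(mass = mass, leg_length = leg_length,
                            theta = mean(ensemble$leg_angle), ...)
  pred <- vapply(seq_len(nrow(ensemble)), function(i) {
    chain <- if (per_step_geometry) {
      build_chain(mass = mass, leg_length = leg_length,
                  theta = ensemble$leg_angle[i], ...)
    } else {
      mean_chain
    }
    st <- collision_state(
      chain,
      v_com = c(ensemble$com_speed[i], -ensemble$vz[i]),
      fwd_foot_speed = ensemble$fwd_foot_speed_froude[i] * sqrt(g * leg_length)
    )
    solver(chain, st)$normalized_impulse
  }, 0)
  if (var(ensemble$fwd_foot_speed_froude) == 0) {
    stop("degenerate ensemble: forward foot speed has zero variance")
  }
  fit <- lm(pred ~ fwd_foot_speed_froude, data = ensemble)
  list(
    model = model,
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    slope_se = suppressWarnings(summary(fit)$coefficients[2L, 2L]),
    predicted = pred
  )
}
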