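# Four-link heel-strike collision model: geometry composition, rigid and
# compliant solutions, and their invariants.

test_that("chain composition matches independent parallel-axis accounting", {
  ch <- mean_subject_chain()
  expect_equal(sum(unlist(ch$masses)), 66.1)
  # posture solve places the composed CoM on the prescribed virtual leg
  expect_equal(ch$G, 1.2 * 0.89 * c(-sin(0.2), cos(0.2)), tolerance = 1e-8)

  # independent route: inertia about the origin, then transfer to G
  I_O <- sum(vapply(names(ch$coms), function(sn) {
    ch$inertias[[sn]] + ch$masses[[sn]] * sum(ch$coms[[sn]]^2)
  }, 0))
  expect_equal(ch$I_G, I_O - ch$Mb * sum(ch$G^2), tolerance = 1e-10)

  # all mass in the torso: G coincides with the torso CoM
  a <- default_anthropometry()
  a$mass_frac <- c(foot = 0, shank = 0, thigh = 0, torso = 1)
  ch1 <- build_chain(anthro = a, solve_posture = FALSE)
  expect_equal(ch1$G, ch1$coms$torso)

  # s = 0 puts the contact point at the heel
  ch0 <- mean_subject_chain(s = 0)
  expect_equal(ch0$O, c(0, 0))
  expect_error(build_chain(s = 2), "foot-strike")
  a_bad <- default_anthropometry()
  a_bad$mass_frac["torso"] <- 0.5
  expect_error(build_chain(anthro = a_bad), "sum to 1")
})

test_that("rigid collision conserves angular momentum about O and matches the point-mass closed form", {
  ch <- mean_subject_chain()
  st <- mean_subject_state(ch)
  res <- rigid_collision(ch, st)

  # independent angular momentum bookkeeping about the contact point
  pre_v <- lapply(ch$coms, function(p) {
    st$v_com + st$omega * c(-(p - ch$G)[2L], (p - ch$G)[1L])
  })
  H_pre <- chain_momentum_about(ch, ch$O, pre_v,
                                as.list(rep(st$omega, 4)))
  H_post <- chain_momentum_about(ch, ch$O, res$v_segments_post,
                                 as.list(res$omega_post))
  expect_equal(H_post, H_pre, tolerance = 1e-12)

  # contact point at rest afterwards
  expect_lt(sqrt(sum(res$vO_post^2)), 1e-12 * sqrt(sum(st$v_com^2)))

  # zero input, zero output; doubling the state doubles the impulse
  st0 <- collision_state(ch, v_com = c(0, 0), omega = 0)
  expect_equal(rigid_collision(ch, st0)$J, c(0, 0))
  st2 <- collision_state(ch, v_com = 2 * st$v_com, omega = 2 * st$omega)
  expect_equal(rigid_collision(ch, st2)$J, 2 * res$J, tolerance = 1e-12)

  # point mass on a rigid strut: omega+ = (r x v) / |r|^2
  a <- default_anthropometry()
  a$mass_frac <- c(foot = 0, shank = 0, thigh = 0, torso = 1)
  a$rog_frac[] <- 0
  chp <- build_chain(anthro = a, solve_posture = FALSE)
  stp <- collision_state(chp, v_com = c(3.2, -0.7), omega = 0)
  resp <- rigid_collision(chp, stp)
  r <- chp$G - chp$O
  expect_equal(unname(resp$omega_post[["torso"]]),
               xprod(r, stp$v_com) / sum(r^2), tolerance = 1e-12)
})

test_that("compliant solution satisfies all four momentum balances and its limits", {
  ch <- mean_subject_chain()
  st <- mean_subject_state(ch)
  res <- compliant_collision(ch, st)

  pre_v <- lapply(ch$coms, function(p) {
    st$v_com + st$omega * c(-(p - ch$G)[2L], (p - ch$G)[1L])
  })
  pre_w <- as.list(rep(st$omega, 4L))
  names(pre_w) <- names(ch$coms)
  balances <- list(
    list(about = ch$O, members = c("foot", "shank", "thigh", "torso")),
    list(about = ch$B, members = c("shank", "thigh", "torso")),
    list(about = ch$C, members = c("thigh", "torso")),
    list(about = ch$D, members = "torso")
  )
  for (bl in balances) {
    sub <- function(vels, oms) {
      sum(vapply(bl$members, function(sn) {
        ch$masses[[sn]] * xprod(ch$coms[[sn]] - bl$about, vels[[sn]]) +
          ch$inertias[[sn]] * oms[[sn]]
      }, 0))
    }
    lhs <- sub(pre_v, pre_w)
    rhs <- sub(res$v_segments_post, as.list(res$omega_post))
    expect_lt(abs(rhs - lhs) / max(abs(lhs), 1), 1e-10)
  }
  expect_lt(sqrt(sum(res$vO_post^2)), 1e-12 * sqrt(sum(st$v_com^2)))

  # zero pre-collision motion
  res0 <- compliant_collision(ch, collision_state(ch, c(0, 0), omega = 0))
  expect_equal(unname(res0$omega_post), rep(0, 4))
  expect_equal(res0$J, c(0, 0))

  # vanishing shank/thigh/torso mass: the fore-aft impulse approaches the
  # single-foot-segment collision closed form
  a <- default_anthropometry()
  eps <- 1e-8
  a$mass_frac <- c(foot = 1 - 3 * eps, shank = eps, thigh = eps,
                   torso = eps)
  chf <- build_chain(anthro = a, solve_posture = FALSE)
  stf <- collision_state(chf, v_com = c(3.2, -0.7), omega = -2)
  resf <- compliant_collision(chf, stf)
  # closed form for the isolated foot about O
  rEO <- chf$coms$foot - chf$O
  vE_pre <- stf$v_com + stf$omega * c(-(chf$coms$foot - chf$G)[2L],
                                      (chf$coms$foot - chf$G)[1L])
  mf <- chf$masses[["foot"]]; IE <- chf$inertias[["foot"]]
  wE <- (mf * xprod(rEO, vE_pre) + IE * stf$omega) /
    (mf * sum(rEO^2) + IE)
  J_closed <- mf * (wE * c(-rEO[2L], rEO[1L]) - vE_pre)
  expect_equal(res$model, "compliant")
  expect_equal(resf$J[1L], J_closed[1L], tolerance = 1e-5)

  # degenerate chain: singular system reported as such
  a0 <- default_anthropometry()
  a0$mass_frac <- c(foot = 0, shank = 0, thigh = 0, torso = 1)
  a0$rog_frac[] <- 0
  ch0 <- build_chain(anthro = a0, solve_posture = FALSE)
  expect_error(compliant_collision(ch0, collision_state(ch0, c(1, 0), omega = 0)),
               "singular")
})

test_that("both models dissipate energy, are homogeneous, and rigid dominates compliant", {
  ch <- mean_subject_chain()
  set.seed(31)
  for (i in 1:25) {
    st <- collision_state(ch, v_com = c(runif(1, 1, 5), runif(1, -1.5, 0)),
                          omega = runif(1, -4, 1))
    for (solver in list(rigid_collision, compliant_collision)) {
      res <- solver(ch, st)
      expect_lte(res$KE_post, res$KE_pre + 1e-9)
      # impulse homogeneous of degree 1
      st3 <- collision_state(ch, 3 * st$v_com, omega = 3 * st$omega)
      expect_equal(solver(ch, st3)$J, 3 * res$J, tolerance = 1e-9)
      expect_lt(sqrt(sum(res$vO_post^2)), 1e-10)
    }
  }
  # physiological grid: rigid normalized impulse >= compliant
  for (fs in seq(0.1, 0.9, by = 0.2)) {
    for (th in c(0.15, 0.20, 0.25)) {
      chg <- build_chain(theta = th)
      stg <- mean_subject_state(chg, fs_froude = fs)
      expect_gte(rigid_collision(chg, stg)$normalized_impulse,
                 compliant_collision(chg, stg)$normalized_impulse)
    }
  }
})

test_that("impulse-speed slope matches a finite-difference oracle and guards degenerate input", {
  # fixed geometry, vary only foot speed: OLS slope equals the directional
  # derivative of the model impulse with respect to foot speed
  ens <- data.frame(
    fwd_foot_speed_froude = seq(0.2, 0.6, length.out = 9),
    com_speed = 3.2, leg_angle = 0.20, vz = 0.7
  )
  for (model in c("rigid", "compliant")) {
    sl <- impulse_speed_slope(model, ens, per_step_geometry = FALSE)
    ch <- build_chain(theta = 0.20)
    f <- function(fs) {
      st <- collision_state(ch, c(3.2, -0.7),
                            fwd_foot_speed = fs * sqrt(9.81 * 0.89))
      if (model == "rigid") rigid_collision(ch, st)$normalized_impulse
      else compliant_collision(ch, st)$normalized_impulse
    }
    h <- 1e-4
    expect_equal(sl$slope, (f(0.4 + h) - f(0.4 - h)) / (2 * h),
                 tolerance = 1e-5)
  }
  ens0 <- ens; ens0$fwd_foot_speed_froude <- 0.4
  expect_error(impulse_speed_slope("rigid", ens0), "zero variance")
  expect_error(impulse_speed_slope("rigid", ens[1:2, ]), "at least 3")
})
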