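# Shared fixtures, built in code.

# small sinusoidal field: h = A * sin(2*pi*y / wl), constant across x
sinusoid_field <- function(A = 0.01, wl = 0.1, length = 6, width = 0.1,
                           res = 0.005) {
  ys <- seq(0, length, by = res)
  xs <- seq(0, width, by = res)
  terrain_field(outer(A * sin(2 * pi * ys / wl), rep(1, length(xs))), res)
}

flat_field <- function(length = 21.6, width = 0.6, res = 0.005) {
  terrain_field(matrix(0, round(length / res) + 1L, round(width / res) + 1L),
                res)
}

# two-level checkerboard with block size in nodes
checkerboard_field <- function(block = 10L, ny = 401L, nx = 81L,
                               res = 0.005, hi = 0.02) {
  iy <- (seq_len(ny) - 1L) %/% block
  ix <- (seq_len(nx) - 1L) %/% block
  h <- outer(iy, ix, function(a, b) ((a + b) %% 2L) * hi)
  terrain_field(h, res)
}

# a minimal marker set: one heel plus four hips tracing a prescribed CoM
synthetic_marker_set <- function(t, heel, com, rate, heel_standing = 0.03) {
  hip_off <- list(
    hip_lf = c(-0.1, 0.05, 0), hip_rf = c(0.1, 0.05, 0),
    hip_lb = c(-0.1, -0.05, 0), hip_rb = c(0.1, -0.05, 0)
  )
  markers <- c(
    list(heel = heel),
    lapply(hip_off, function(o) sweep(com, 2L, -o))
  )
  markers <- lapply(markers, `colnames<-`, c("x", "y", "z"))
  marker_set(t, markers, rate, c(heel = heel_standing))
}

# noise-free flat-terrain reference trial, cached per test file
flat_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gait <- gait_spec(step_length_sd = 0, step_width_sd = 0,
                        fwd_foot_speed_sd = 0, seed = 3L)
      cache <<- generate_trial(gait, flat_field(), duration = 25,
                               force_noise_sd = 0)
    }
    cache
  }
})

mean_subject_chain <- function(...) {
  build_chain(mass = 66.1, leg_length = 0.89, theta = 0.20, ...)
}

mean_subject_state <- function(chain, fs_froude = 0.37) {
  collision_state(chain, v_com = c(3.2, -0.7),
                  fwd_foot_speed = fs_froude * sqrt(9.81 * 0.89))
}

# independent scalar cross product for oracle checks
xprod <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

# independent angular momentum of the whole chain about a point
chain_momentum_about <- function(chain, point, vels, omegas) {
  segs <- names(chain$coms)
  if (is.null(names(omegas))) names(omegas) <- segs
  if (is.null(names(vels))) names(vels) <- segs
  sum(vapply(segs, function(sn) {
    chain$masses[[sn]] * xprod(chain$coms[[sn]] - point, vels[[sn]]) +
      chain$inertias[[sn]] * omegas[[sn]]
  }, 0))
}
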