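test_that("binding-site counts follow the helix repeat", {
  expect_equal(n_sites(0.0355), 1L)
  expect_equal(n_sites(3.55), 100L)
  expect_equal(n_sites(0.3), 8L) # round(8.45)
  expect_equal(n_sites(0.001), 1L) # floor at one site
})

test_that("elastic equilibrium is the mean anchor position", {
  expect_equal(equilibrate(numeric(), z = 3.2), 3.2)
  expect_equal(equilibrate(5), 5)
  expect_equal(equilibrate(c(0, 10)), 5)
  expect_equal(elastic_energy(c(0, 10), 5, kappa = 2), 2 * (2 / 2) * 25)
  # one motor stroking by d moves the equilibrium by d/n
  a <- c(0, 4, 8)
  a2 <- a; a2[2] <- a2[2] + 6
  expect_equal(equilibrate(a2) - equilibrate(a), 6 / 3)
})

test_that("transition rates reduce to unstrained values when unloaded", {
  p <- motor_params(c_coupling = 0)
  expect_equal(transition_rate(p, "attach"), p$k_attach)
  expect_equal(transition_rate(p, "stroke", anchors = c(0, 5), which_motor = 1),
               p$k_stroke)
  p1 <- motor_params()
  # a single bound motor is unloaded for both mechanical steps
  expect_equal(transition_rate(p1, "stroke", anchors = 0), p1$k_stroke)
  expect_equal(transition_rate(p1, "detach", anchors = 7), p1$k_detach)
})

test_that("closed-form energy change matches brute-force bookkeeping", {
  p <- motor_params()
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    anchors <- rnorm(n, 0, 6)
    j <- sample(n, 1)
    z <- equilibrate(anchors)
    x_j <- z - anchors[j]
    for (d in c(p$d_main, p$d_second)) {
      dE_closed <- 0.5 * p$kappa * d^2 * (1 - 1 / n) - p$kappa * d * x_j
      a2 <- anchors; a2[j] <- a2[j] + d
      dE_brute <- elastic_energy(a2, equilibrate(a2), p$kappa) -
        elastic_energy(anchors, z, p$kappa)
      expect_equal(dE_closed, dE_brute, tolerance = 1e-10)
    }
  }
  # rate decreases monotonically as the motor strain drops (opposing load)
  r <- vapply(c(4, 0, -4), function(b)
    transition_rate(p, "stroke", anchors = c(0, b), which_motor = 1), 0)
  expect_true(all(diff(r) < 0))
})

test_that("frozen filaments stay put", {
  p <- motor_params(k_attach = 1e-9) # effectively no binding
  p$k_attach <- 0
  tr <- simulate_filament(p, L = 1, T_total = 3, noise = FALSE)
  expect_true(all(tr$z_um == 0))
  expect_true(all(tr$n_bound == 0))
})

test_that("single-site uncoupled velocity matches the renewal closed form", {
  p <- motor_params(k_attach = 5, k_stroke = 50, k_detach = 25,
                    c_coupling = 0)
  v_expect <- renewal_velocity(p)
  expect_equal(v_expect, (8 + 4) / 1000 / (1 / 5 + 1 / 50 + 1 / 25))
  set.seed(32)
  tr <- simulate_filament(p, L = 0.0355, T_total = 4000, noise = FALSE)
  v_sim <- (tr$z_um[nrow(tr)] - tr$z_um[1]) / tr$time_s[nrow(tr)]
  expect_equal(v_sim, v_expect, tolerance = 0.02)
})

test_that("one full single-motor cycle displaces by both step lengths", {
  p <- motor_params(k_attach = 5, k_stroke = 50, k_detach = 25,
                    c_coupling = 0.9, bind_sigma = 0)
  set.seed(33)
  tr <- simulate_filament(p, L = 0.0355, T_total = 50, noise = FALSE,
                          log_events = TRUE)
  ev <- attr(tr, "events")
  # every stroke advances by d_main and every detachment by d_second, so
  # the final position decomposes exactly into the event counts (a cycle in
  # progress at the end contributes only its completed steps)
  expect_gt(sum(ev$type == 3), 10)
  expect_equal(tr$z_um[nrow(tr)] * 1000,
               sum(ev$type == 2) * p$d_main + sum(ev$type == 3) * p$d_second,
               tolerance = 1e-6)
})

test_that("Gillespie occupancies match the master equation (N = 2 and 3)", {
  p <- motor_params(k_attach = 5, k_stroke = 60, k_detach = 30,
                    c_coupling = 0)
  for (N in 2:3) {
    occ_me <- master_equation_occupancy(N, p)
    set.seed(40 + N)
    L <- N * p$site_spacing
    tr <- simulate_filament(p, L, T_total = 3000, noise = FALSE)
    occ <- attr(tr, "occupancy")
    # compare every composition with >1% stationary mass within 3 SE,
    # using an effective sample of independent holding intervals
    n_eff <- attr(tr, "n_events")
    for (i in seq_len(N + 1)) {
      for (j in seq_len(N + 1)) {
        pm <- occ_me[i, j]
        if (pm < 0.01) next
        se <- sqrt(pm * (1 - pm) / n_eff) * 3 # crude but conservative scale
        expect_lt(abs(occ[i, j] - pm), max(3 * se, 0.01))
      }
    }
    expect_equal(sum(occ), 1, tolerance = 1e-6)
    expect_equal(sum(occ_me), 1, tolerance = 1e-9)
  }
})

test_that("condition multipliers follow the regulated-condition table", {
  expect_equal(as.numeric(condition_params("baseline")), rep(1, 4))
  a <- condition_params("alphaA-TmAlpha")
  expect_equal(unname(a[c("k_attach", "k_stroke", "k_detach")]), rep(1.15, 3))
  expect_equal(unname(a["c_coupling"]), 1)
  g <- condition_params("gammaA-TmAlpha")
  expect_equal(unname(g["c_coupling"]), 1.2)
  b <- condition_params("gammaA-TmBeta")
  expect_equal(unname(b[c("k_detach", "c_coupling")]), c(0.75, 0.8))
  expect_error(condition_params("nope"))
  p <- apply_multipliers(motor_params(), a)
  expect_equal(p$k_stroke, motor_params()$k_stroke * 1.15)
})

test_that("simulated conditions produce plausible motility records", {
  set.seed(35)
  recs <- simulate_condition(motor_params(), n_filaments = 25, T_total = 10)
  expect_s3_class(recs, "motility_records")
  expect_equal(nrow(recs), 25)
  expect_true(all(recs$L_um >= 0.3 & recs$L_um <= 3.25))
  expect_true(all(recs$f_mot >= 0 & recs$f_mot <= 1))
  expect_gt(attr(recs, "cut"), 0)
})

test_that("motile fraction rises with length and run time grows with it", {
  set.seed(36)
  recs <- simulate_condition(motor_params(), n_filaments = 120,
                             T_total = 20)
  cs <- windowed_curves(recs)
  cv <- cs$curves[!is.na(cs$curves$f_mot), ]
  third <- nrow(cv) %/% 3
  expect_gt(mean(cv$f_mot[(2 * third):nrow(cv)]),
            mean(cv$f_mot[1:third]))
  expect_gt(mean(cv$run_time_s[(2 * third):nrow(cv)], na.rm = TRUE),
            mean(cv$run_time_s[1:third], na.rm = TRUE))
  # long filaments approach full motility
  expect_gt(max(cv$f_mot), 0.9)
})

test_that("parameter sweeps span the requested multipliers", {
  mults <- seq(0.25, 1.75, length.out = 15)
  expect_equal(mults[2], 0.25 + 1.5 / 14)
  set.seed(37)
  sw <- parameter_sweep(motor_params(), "k_stroke", 0.8, 1.2, n_steps = 2,
                        n_filaments = 6, T_total = 5, cut = 0.1)
  expect_setequal(unique(sw$multiplier), c(0.8, 1.2))
  expect_setequal(unique(sw$feature),
                  c("v_um_s", "f_mot", "stop_time_s", "run_time_s"))
})

test_that("single-site velocity responds to k_stroke as the cycle formula", {
  base <- motor_params(k_attach = 5, k_stroke = 50, k_detach = 25,
                       c_coupling = 0)
  set.seed(38)
  v <- vapply(c(0.5, 1, 2), function(m) {
    p <- base; p$k_stroke <- p$k_stroke * m
    tr <- simulate_filament(p, 0.0355, T_total = 1500, noise = FALSE)
    (tr$z_um[nrow(tr)] - tr$z_um[1]) / tr$time_s[nrow(tr)]
  }, 0)
  v_pred <- vapply(c(0.5, 1, 2), function(m) {
    p <- base; p$k_stroke <- p$k_stroke * m
    renewal_velocity(p)
  }, 0)
  expect_equal(v, v_pred, tolerance = 0.05)
  expect_true(all(diff(v) > 0)) # velocity non-decreasing in k_stroke
})
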