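#' Kinetic and mechanical parameters of the coupled-myosin model
#'
#' Bundles the parameters of the stochastic model of actin propulsion by
#' surface-bound myosin motors. Motors on a filament of length `L` occupy up to
#' [n_sites()] binding sites (one per actin helix repeat, 0.0355 um). Each
#' motor cycles detached -> pre-stroke -> post-stroke -> detached. Binding is
#' strain-independent; the two mechanical transitions (main power stroke over
#' `d_main` nm, and the secondary step over `d_second` nm that immediately
#' precedes detachment) carry a Boltzmann factor `exp(-c_coupling * dE / kT)`,
#' where `dE` is the elastic-energy change of the whole motor-filament system
#' if the step executes and the rigid filament re-equilibrates.
#'
#' The default numeric values are a calibrated reconstruction (shipped also in
#' `inst/extdata/motor_baseline.yaml`): they are chosen once so that the
#' baseline condition shows a sub-um/s plateau sliding velocity, a motile
#' fraction approaching 1 for long filaments, and run/stop structure resolvable
#' at the 1/3 s analysis time step.
#'
#' @param k_attach Myosin attachment rate per free binding site, 1/s.
#' @param k_stroke Unstrained main power-stroke rate, 1/s.
#' @param k_detach Unstrained rate of the secondary pre-detachment step, 1/s.
#' @param c_coupling Dimensionless impact of mechanical coupling on the
#'   mechanical transition rates (0 = independent motors).
#' @param d_main Main power-stroke distance, nm.
#' @param d_second Secondary step distance, nm.
#' @param kappa Crossbridge stiffness, pN/nm.
#' @param site_spacing Binding-site spacing along actin, um (helix repeat).
#' @param kT Thermal energy, pN nm (default: 30 degrees C).
#' @param noise_sigma Gaussian measurement noise added to sampled positions,
#'   um; sets the width of the stopped-population velocity peak.
#' @param bind_sigma Standard deviation of the binding offset, nm: motors
#'   attach with an anchor offset drawn from a zero-mean Gaussian. The default
#'   exceeds the bare thermal spring value `sqrt(kT / kappa)` because it also
#'   absorbs binding-site registration disorder along the actin helix.
#' @return An object of class `motor_params` (a named list).
#' @export
#' @examples
#' p <- motor_params()
#' p$k_stroke
motor_params <- function(k_attach = 25, k_stroke = 900, k_detach = 120,
                         c_coupling = 1.3, d_main = 8, d_second = 4,
                         kappa = 1.4, site_spacing = 0.0355, kT = 4.19,
                         noise_sigma = 0.02, bind_sigma = 3.5) {
  stopifnot(k_attach >= 0, k_stroke > 0, k_detach > 0, c_coupling >= 0,
            d_main > 0, d_second >= 0, kappa > 0, site_spacing > 0, kT > 0,
            noise_sigma >= 0, bind_sigma >= 0)
  structure(list(k_attach = k_attach, k_stroke = k_stroke,
                 k_detach = k_detach, c_coupling = c_coupling,
                 d_main = d_main, d_second = d_second, kappa = kappa,
                 site_spacing = site_spacing, kT = kT,
                 noise_sigma = noise_sigma, bind_sigma = bind_sigma),
            class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  cat("<motor_params>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Condition-specific parameter multipliers
#'
#' Named multiplier sets that turn the baseline parameter set into the
#' regulated experimental conditions: `"alphaA-TmAlpha"` multiplies all three
#' kinetic rates by 1.15; `"gammaA-TmAlpha"` multiplies the coupling impact by
#' 1.2; `"gammaA-TmBeta"` multiplies the detachment-step rate by 0.75 and the
#' coupling impact by 0.8. `"baseline"` is the identity.
#'
#' @param name Condition name.
#' @return A named numeric vector of multipliers (class `condition_params`).
#' @export
#' @examples
#' condition_params("gammaA-TmBeta")
condition_params <- function(name = c("baseline", "alphaA-TmAlpha",
                                      "gammaA-TmAlpha", "gammaA-TmBeta")) {
  name <- match.arg(name)
  m <- c(k_attach = 1, k_stroke = 1, k_detach = 1, c_coupling = 1)
  m <- switch(name,
    "baseline" = m,
    "alphaA-TmAlpha" = replace(m, c("k_attach", "k_stroke", "k_detach"), 1.15),
    "gammaA-TmAlpha" = replace(m, "c_coupling", 1.2),
    "gammaA-TmBeta" = replace(m, c("k_detach", "c_coupling"), c(0.75, 0.8)))
  structure(m, condition = name, class = c("condition_params", "numeric"))
}

#' Apply condition multipliers to a parameter set
#'
#' @param params A [motor_params()] object.
#' @param multipliers A named numeric vector (e.g. from [condition_params()]);
#'   names must be parameter names.
#' @return A modified `motor_params` object.
#' @export
apply_multipliers <- function(params, multipliers) {
  stopifnot(inherits(params, "motor_params"))
  for (nm in names(multipliers)) {
    if (!nm %in% names(params)) stop("unknown parameter: ", nm)
    params[[nm]] <- params[[nm]] * multipliers[[nm]]
  }
  params
}

#' Number of myosin binding sites on a filament
#'
#' Accessible binding sites are assumed proportional to filament length, one
#' site per actin helix repeat (0.0355 um), with at least one site.
#'
#' @param L Filament length, um.
#' @param site_spacing Site spacing, um.
#' @return Integer site count, `max(1, round(L / site_spacing))`.
#' @export
#' @examples
#' n_sites(3.55) # 100
n_sites <- function(L, site_spacing = 0.0355) {
  stopifnot(all(L > 0), site_spacing > 0)
  pmax(1L, as.integer(round(L / site_spacing)))
}

#' Elastic equilibrium of the motor-filament system
#'
#' With equal-stiffness linear crossbridges the elastic energy
#' `sum (kappa/2) (z - a_i)^2` is minimal at the mean of the bound-motor
#' anchor positions. With no bound motors the filament position is unchanged.
#'
#' @param anchors Numeric vector of bound-motor anchor positions, nm.
#' @param z Current filament position (returned unchanged when no motor is
#'   bound), nm.
#' @return Equilibrium filament position, nm.
#' @export
equilibrate <- function(anchors, z = 0) {
  if (length(anchors) == 0) return(z)
  mean(anchors)
}

#' Elastic energy of a motor-filament configuration
#'
#' @param anchors Bound-motor anchor positions, nm.
#' @param z Filament position, nm.
#' @param kappa Crossbridge stiffness, pN/nm.
#' @return Total elastic energy, pN nm.
#' @export
elastic_energy <- function(anchors, z, kappa) {
  sum(0.5 * kappa * (z - anchors)^2)
}

#' Strain-dependent transition rate
#'
#' Rate of one motor's transition given the full mechanical configuration.
#' Attachment is strain-independent. For mechanical events the energy change
#' `dE` is computed by brute-force bookkeeping: shift the stepping motor's
#' anchor by its step distance, re-equilibrate the filament, and take the
#' difference in total elastic energy. The rate is
#' `k0 * exp(-c_coupling * dE / kT)`. A single unloaded motor therefore
#' recovers its unstrained rate exactly.
#'
#' @param params A [motor_params()] object.
#' @param event One of `"attach"`, `"stroke"`, `"detach"`.
#' @param anchors Anchor positions of all bound motors, nm.
#' @param which_motor Index into `anchors` of the transitioning motor
#'   (ignored for `"attach"`).
#' @param z Filament position, nm; defaults to the elastic equilibrium.
#' @return Rate in 1/s.
#' @export
transition_rate <- function(params, event = c("attach", "stroke", "detach"),
                            anchors = numeric(), which_motor = 1L,
                            z = equilibrate(anchors)) {
  stopifnot(inherits(params, "motor_params"))
  event <- match.arg(event)
  if (event == "attach") return(params$k_attach)
  stopifnot(length(anchors) >= 1, which_motor >= 1,
            which_motor <= length(anchors))
  d <- if (event == "stroke") params$d_main else params$d_second
  k0 <- if (event == "stroke") params$k_stroke else params$k_detach
  e0 <- elastic_energy(anchors, z, params$kappa)
  a1 <- anchors
  a1[which_motor] <- a1[which_motor] + d
  e1 <- elastic_energy(a1, equilibrate(a1), params$kappa)
  k0 * exp(-params$c_coupling * (e1 - e0) / params$kT)
}

#' Simulate one filament trajectory (exact Gillespie)
#'
#' Runs the exact stochastic simulation (next-event time sampled from the
#' total rate, event chosen proportional to its rate; anchors updated and the
#' filament re-equilibrated after every event) and samples the filament
#' position on a regular time grid. Gaussian measurement noise
#' (`params$noise_sigma`) is added at sampling, not in the dynamics, so the
#' frame-to-frame velocity distribution has the stopped/running two-population
#' structure seen in assay recordings.
#'
#' @param params A [motor_params()] object.
#' @param L Filament length, um.
#' @param T_total Simulated duration, s.
#' @param dt Sampling interval, s (the analysis time resolution).
#' @param noise If `FALSE`, suppress measurement noise.
#' @param log_events If `TRUE`, attach the event log.
#' @return A tibble (class `sim_trajectory`) with columns `time_s`, `z_um`,
#'   `n_bound`, plus attributes `occupancy` (time-fraction matrix over
#'   (pre-stroke, post-stroke) motor counts), `n_events`, `L_um`, `dt`.
#' @export
#' @examples
#' set.seed(1)
#' tr <- simulate_filament(motor_params(), L = 1, T_total = 5)
#' head(tr)
simulate_filament <- function(params, L, T_total = 25, dt = 1 / 3,
                              noise = TRUE, log_events = FALSE) {
  stopifnot(inherits(params, "motor_params"), L > 0, T_total > 0, dt > 0)
  N <- n_sites(L, params$site_spacing)
  res <- gillespie_core(N, params$k_attach, params$k_stroke, params$k_detach,
                        params$c_coupling, params$d_main, params$d_second,
                        params$kappa, params$kT, T_total, dt,
                        params$bind_sigma, log_events)
  z_um <- res$z / 1000
  if (noise && params$noise_sigma > 0)
    z_um <- z_um + rnorm(length(z_um), 0, params$noise_sigma)
  out <- tibble::tibble(time_s = res$time, z_um = z_um,
                        n_bound = res$n_bound)
  attr(out, "occupancy") <- res$occupancy
  attr(out, "n_events") <- res$n_events
  attr(out, "L_um") <- L
  attr(out, "dt") <- dt
  if (log_events) attr(out, "events") <- tibble::as_tibble(res$events)
  class(out) <- c("sim_trajectory", class(out))
  out
}

#' Frame-to-frame speeds of a simulated trajectory
#'
#' @param trajectory A [simulate_filament()] result.
#' @return Numeric vector of `|dz| / dt`, um/s.
#' @export
trajectory_v_f2f <- function(trajectory) {
  abs(diff(trajectory$z_um)) / attr(trajectory, "dt")
}

#' Simulate a full experimental condition
#'
#' Simulates `n_filaments` trajectories with lengths drawn uniformly from
#' `L_range`, converts them to frame-to-frame velocity series, determines the
#' run/stop cut velocity from the pooled two-Gaussian fit (or uses a supplied
#' cut), and segments each series into runs and stops — the same feature
#' pipeline applied to experimental traces.
#'
#' @param params A [motor_params()] object (after any condition multipliers).
#' @param n_filaments Number of filaments.
#' @param L_range Length range to sample uniformly, um.
#' @param T_total,dt Trace duration and sampling interval, s.
#' @param condition Condition tag stored in the records.
#' @param cut Optional fixed stop/run cut velocity, um/s; default fits the
#'   pooled two-Gaussian mixture of this condition's velocities.
#' @return A [motility_records()] tibble, one row per filament, with attribute
#'   `cut` (the cut velocity used).
#' @export
simulate_condition <- function(params, n_filaments = 150,
                               L_range = c(0.3, 3.25), T_total = 25,
                               dt = 1 / 3, condition = "sim", cut = NULL) {
  stopifnot(n_filaments >= 1)
  L <- runif(n_filaments, L_range[1], L_range[2])
  traces <- lapply(L, function(l)
    simulate_filament(params, l, T_total = T_total, dt = dt))
  v_series <- lapply(traces, trajectory_v_f2f)
  if (is.null(cut)) {
    fit <- fit_two_gaussians(unlist(v_series))
    cut <- fit$cut
  }
  recs <- purrr::map2_dfr(v_series, seq_along(v_series), function(v, i) {
    seg <- segment_runs_stops(v, cut, dt = dt)
    z <- traces[[i]]$z_um
    tibble::tibble(
      filament_id = i,
      condition = condition,
      chamber_id = NA_character_,
      video_id = NA_character_,
      L_um = L[i],
      v_trace_um_s = abs(z[length(z)] - z[1]) / (attr(traces[[i]], "dt") *
                                                   (length(z) - 1)),
      v_f2f_um_s = mean(v),
      f_mot = seg$f_mot,
      run_times_s = list(seg$run_times_s),
      stop_times_s = list(seg$stop_times_s))
  })
  out <- as_motility_records(recs)
  attr(out, "cut") <- cut
  out
}

#' Sweep one model parameter and collect length-resolved feature curves
#'
#' For each multiplier, the parameter is scaled, a condition is simulated, and
#' the four length-windowed feature curves are computed. Used to locate
#' multipliers that mimic target fold changes.
#'
#' @param params Baseline [motor_params()].
#' @param param Name of the parameter to sweep.
#' @param lo_mult,hi_mult Multiplier range.
#' @param n_steps Number of equally spaced multipliers.
#' @param n_filaments,T_total,dt,L_range Simulation settings per step.
#' @param cut Fixed stop/run cut shared across the sweep (default: fitted on
#'   the baseline multiplier closest to 1).
#' @param ... Passed to [windowed_curves()].
#' @return A tibble of curves with columns `multiplier`, `window_center_um`,
#'   `feature`, `value`.
#' @export
parameter_sweep <- function(params, param, lo_mult = 0.25, hi_mult = 1.75,
                            n_steps = 15, n_filaments = 60, T_total = 20,
                            dt = 1 / 3, L_range = c(0.3, 3.25), cut = NULL,
                            ...) {
  stopifnot(param %in% names(params), lo_mult < hi_mult, n_steps >= 2)
  mults <- seq(lo_mult, hi_mult, length.out = n_steps)
  purrr::map_dfr(mults, function(m) {
    p <- params
    p[[param]] <- p[[param]] * m
    recs <- simulate_condition(p, n_filaments = n_filaments,
                               L_range = L_range, T_total = T_total, dt = dt,
                               condition = sprintf("%s_x%.3f", param, m),
                               cut = cut)
    cs <- windowed_curves(recs, ...)
    tidyr::pivot_longer(
      dplyr::select(cs$curves, "window_center_um", "v_um_s", "f_mot",
                    "stop_time_s", "run_time_s"),
      -"window_center_um", names_to = "feature", values_to = "value") |>
      dplyr::mutate(multiplier = m, parameter = param, .before = 1)
  })
}

#' Stationary composition distribution from the master equation
#'
#' Brute-force oracle for small site counts with decoupled motors
#' (`c_coupling = 0`): enumerates all per-site states, builds the generator of
#' the continuous-time Markov chain, solves for the stationary distribution,
#' and returns the time-fraction in each (pre-stroke, post-stroke) motor-count
#' composition — directly comparable to the `occupancy` attribute of
#' [simulate_filament()].
#'
#' @param n_sites Number of binding sites (kept small; 3^n states).
#' @param params A [motor_params()] object; `c_coupling` must be 0.
#' @return Matrix of stationary probabilities indexed by
#'   `[n_pre + 1, n_post + 1]`.
#' @export
master_equation_occupancy <- function(n_sites, params) {
  stopifnot(n_sites >= 1, n_sites <= 6, inherits(params, "motor_params"))
  if (params$c_coupling != 0)
    stop("master-equation oracle requires c_coupling = 0 (decoupled motors)")
  states <- as.matrix(expand.grid(rep(list(0:2), n_sites)))
  ns <- nrow(states)
  Q <- matrix(0, ns, ns)
  key <- function(s) sum(s * 3^(seq_along(s) - 1)) + 1
  idx <- integer(3^n_sites)
  for (i in seq_len(ns)) idx[key(states[i, ])] <- i
  rate_of <- c(params$k_attach, params$k_stroke, params$k_detach)
  for (i in seq_len(ns)) {
    s <- states[i, ]
    for (j in seq_len(n_sites)) {
      s2 <- s
      s2[j] <- (s[j] + 1) %% 3
      k <- idx[key(s2)]
      Q[i, k] <- Q[i, k] + rate_of[s[j] + 1]
    }
  }
  diag(Q) <- -rowSums(Q)
  # stationary distribution: pi Q = 0, sum pi = 1
  A <- rbind(t(Q), rep(1, ns))
  pi_hat <- qr.solve(A, c(rep(0, ns), 1))
  occ <- matrix(0, n_sites + 1, n_sites + 1)
  for (i in seq_len(ns)) {
    np <- sum(states[i, ] == 1)
    nq <- sum(states[i, ] == 2)
    occ[np + 1, nq + 1] <- occ[np + 1, nq + 1] + pi_hat[i]
  }
  occ
}

#' Closed-form mean sliding velocity of an uncoupled single-site filament
#'
#' With one binding site and no coupling the motor cycle is a renewal process
#' with mean cycle time `1/k_attach + 1/k_stroke + 1/k_detach` and
#' displacement `d_main + d_second` per cycle.
#'
#' @param params A [motor_params()] object.
#' @return Mean velocity, um/s.
#' @export
renewal_velocity <- function(params) {
  if (params$k_attach == 0) return(0)
  cycle <- 1 / params$k_attach + 1 / params$k_stroke + 1 / params$k_detach
  (params$d_main + params$d_second) / 1000 / cycle
}
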