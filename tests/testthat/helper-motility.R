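# Shared fixtures: all synthetic, generated in code.

# Synthetic per-filament records with prescribed velocity and run/stop
# structure; avoids running the simulator where the statistics themselves
# are under test.
make_records <- function(n, v_fun = function(L) rep(0.5, length(L)),
                         f_mot = 0.8, mean_run = 1, mean_stop = 0.6,
                         dt = 1 / 3, L_range = c(0.3, 3.25),
                         condition = "synth", noise_v = 0.05) {
  L <- runif(n, L_range[1], L_range[2])
  v <- pmax(v_fun(L) + rnorm(n, 0, noise_v), 0.01)
  recs <- purrr::map_dfr(seq_len(n), function(i) {
    n_run <- 1 + rpois(1, 2)
    runs <- pmax(rexp(n_run, 1 / mean_run), dt)
    stops <- if (runif(1) < f_mot) pmax(rexp(max(n_run - 1, 1),
                                             1 / mean_stop), dt)
      else pmax(rexp(n_run, 1 / mean_stop), dt)
    tibble::tibble(filament_id = i, condition = condition,
                   chamber_id = sprintf("ch%d", (i %% 4) + 1),
                   video_id = NA_character_, L_um = L[i],
                   v_trace_um_s = v[i], v_f2f_um_s = v[i],
                   f_mot = sum(runs) / (sum(runs) + sum(stops)),
                   run_times_s = list(runs), stop_times_s = list(stops))
  })
  as_motility_records(recs)
}

# Small noise-free mock video of one straight filament.
render_one <- function(L, v, heading = 0.4, duration = 4, frame_rate = 6,
                       pixel_size = 0.08, psf_sigma = 1.5, fov = c(40, 40),
                       x0 = 10, y0 = 20, ...) {
  sp <- filament_specs(length = L, velocity = v, x0 = x0, y0 = y0,
                       heading = heading)
  tt <- build_paths(sp, duration = duration, frame_rate = frame_rate,
                    fov = fov)
  op <- optics_spec(psf_sigma = psf_sigma, pixel_size = pixel_size,
                    frame_rate = frame_rate, background_sd = 0, ...)
  render_video(tt, op)
}

# Feature table + labels with strong class separation, for QC tests that
# target the learner rather than the image pipeline.
make_qc_fixture <- function(n_per_class, seed, shift = 3) {
  set.seed(seed)
  clean <- tibble::tibble(
    trace_id = seq_len(n_per_class),
    n_corners = rpois(n_per_class, 0.3),
    v_cv = abs(rnorm(n_per_class, 0.3, 0.1)),
    area_cv = abs(rnorm(n_per_class, 0.1, 0.05)),
    length_cv = abs(rnorm(n_per_class, 0.1, 0.05)),
    complex_frac = runif(n_per_class, 0, 0.2),
    min_dist_um = runif(n_per_class, 5, 40),
    overlap_events = 0L)
  bad <- tibble::tibble(
    trace_id = n_per_class + seq_len(n_per_class),
    n_corners = rpois(n_per_class, shift),
    v_cv = abs(rnorm(n_per_class, 0.3 + 0.2 * shift / 3, 0.15)),
    area_cv = abs(rnorm(n_per_class, 0.1 + 0.15 * shift / 3, 0.08)),
    length_cv = abs(rnorm(n_per_class, 0.1 + 0.15 * shift / 3, 0.08)),
    complex_frac = runif(n_per_class, 0, 0.5),
    min_dist_um = runif(n_per_class, 0, 3),
    overlap_events = rpois(n_per_class, shift / 2))
  list(features = dplyr::bind_rows(clean, bad),
       labels = rep(c("keep", "reject"), each = n_per_class))
}
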