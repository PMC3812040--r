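#' Per-filament motility records
#'
#' A `motility_records` tibble holds one row per accepted filament with the
#' scalar features used throughout the statistics: filament length `L_um`,
#' trace velocity `v_trace_um_s` (tip path length / lifetime), mean
#' frame-to-frame velocity `v_f2f_um_s`, motile fraction `f_mot` (fraction of
#' frame-to-frame intervals classified as running), and the lists of run and
#' stop segment durations.
#'
#' @param df A data frame with at least `filament_id`, `condition`, `L_um`,
#'   `v_f2f_um_s`, `f_mot`, `run_times_s`, `stop_times_s`.
#' @return The validated tibble with class `motility_records`.
#' @export
as_motility_records <- function(df) {
  need <- c("filament_id", "condition", "L_um", "v_f2f_um_s", "f_mot",
            "run_times_s", "stop_times_s")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("missing columns: ", paste(missing, collapse = ", "))
  stopifnot(all(df$L_um > 0), all(df$f_mot >= 0 & df$f_mot <= 1))
  out <- tibble::as_tibble(df)
  class(out) <- unique(c("motility_records", class(out)))
  out
}

#' Fit a two-Gaussian mixture to a pooled velocity sample
#'
#' In motility recordings the frame-to-frame velocity distribution is a
#' mixture of a stopped population (measurement noise around zero) and a
#' running population. A two-component Gaussian mixture (unequal variances,
#' expectation-maximization) is fitted and the stop/run cut velocity is the
#' equal-posterior-probability point between the component means. If the two
#' components are not separable — the low-time-resolution regime where both
#' populations merge — the fit is flagged as collapsed.
#'
#' @param v Pooled frame-to-frame velocities, um/s (length >= 100).
#' @param sep_tol Collapse tolerance: flag when the mean separation is below
#'   `sep_tol * (sd1 + sd2)`.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `two_gaussian_fit`: fields `mu_stop`, `sd_stop`,
#'   `mu_run`, `sd_run`, `weight_run`, `cut`, `collapsed`.
#' @details The EM is initialized deterministically from quantiles (stopped
#'   component at the lower tail, running component at the upper bulk), which
#'   keeps the stopped component anchored to the low-velocity mode even when
#'   stops are a small fraction of all intervals. The fit is therefore
#'   reproducible without a random start and invariant to component labeling.
#' @export
#' @examples
#' set.seed(1)
#' v <- c(abs(rnorm(500, 0.05, 0.02)), rnorm(500, 1, 0.2))
#' fit_two_gaussians(v)$cut
fit_two_gaussians <- function(v, sep_tol = 1, max_iter = 500, tol = 1e-8) {
  stopifnot(length(v) >= 100)
  lo <- v[v <= quantile(v, 0.10)]
  hi <- v[v >= median(v)]
  mu <- c(mean(lo), mean(hi))
  sdv <- pmax(c(sd(lo), sd(hi)), 1e-4)
  pro <- c(0.1, 0.9)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pro[1] * dnorm(v, mu[1], sdv[1])
    d2 <- pro[2] * dnorm(v, mu[2], sdv[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
    w1 <- sum(g); w2 <- length(v) - w1
    if (w1 < 2 || w2 < 2) break # one component vanished
    mu <- c(sum(g * v) / w1, sum((1 - g) * v) / w2)
    sdv <- c(sqrt(sum(g * (v - mu[1])^2) / w1),
             sqrt(sum((1 - g) * (v - mu[2])^2) / w2))
    sdv <- pmax(sdv, 1e-5)
    pro <- c(w1, w2) / length(v)
  }
  o <- order(mu) # stopped component first; label-invariant
  mu <- mu[o]; sdv <- sdv[o]; pro <- pro[o]
  collapsed <- (mu[2] - mu[1]) < sep_tol * (sdv[1] + sdv[2])
  structure(list(mu_stop = mu[1], sd_stop = sdv[1], mu_run = mu[2],
                 sd_run = sdv[2], weight_run = pro[2],
                 cut = .equal_posterior_cut(mu, sdv, pro),
                 collapsed = collapsed, n = length(v)),
            class = "two_gaussian_fit")
}

# velocity between the means where both components have equal posterior
.equal_posterior_cut <- function(mu, sdv, pro) {
  f <- function(x) pro[1] * dnorm(x, mu[1], sdv[1]) -
    pro[2] * dnorm(x, mu[2], sdv[2])
  lo <- mu[1]; hi <- mu[2]
  if (f(lo) <= 0 || f(hi) >= 0) return(mean(mu)) # degenerate: midpoint
  uniroot(f, c(lo, hi))$root
}

#' @export
print.two_gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "<two_gaussian_fit> stopped N(%.3f, %.3f), running N(%.3f, %.3f), ",
    x$mu_stop, x$sd_stop, x$mu_run, x$sd_run))
  cat(sprintf("weight_run %.2f, cut %.3f um/s%s\n", x$weight_run, x$cut,
              if (x$collapsed) " [collapsed]" else ""))
  invisible(x)
}

#' @export
tidy.two_gaussian_fit <- function(x, ...) {
  tibble::tibble(component = c("stopped", "running"),
                 mean = c(x$mu_stop, x$mu_run),
                 sd = c(x$sd_stop, x$sd_run),
                 weight = c(1 - x$weight_run, x$weight_run))
}

#' @export
glance.two_gaussian_fit <- function(x, ...) {
  tibble::tibble(cut = x$cut, collapsed = x$collapsed, n = x$n)
}

#' Segment a velocity time course into runs and stops
#'
#' Maximal consecutive intervals with velocity at or above the cut are runs,
#' below are stops. The motile fraction is the number of running intervals
#' over the total interval count; run and stop times are the segment
#' durations.
#'
#' @param v_f2f Frame-to-frame velocity series, um/s.
#' @param cut Stop/run cut velocity, um/s.
#' @param dt Interval duration, s.
#' @return List with `f_mot`, `run_times_s`, `stop_times_s`, and the logical
#'   `running` vector.
#' @export
#' @examples
#' segment_runs_stops(c(1, 1, 0.1, 0.1, 0.1, 1), cut = 0.5, dt = 1 / 3)
segment_runs_stops <- function(v_f2f, cut, dt = 1 / 3) {
  stopifnot(length(v_f2f) >= 1, is.finite(cut), dt > 0)
  running <- v_f2f >= cut
  r <- rle(running)
  list(f_mot = mean(running),
       run_times_s = r$lengths[r$values] * dt,
       stop_times_s = r$lengths[!r$values] * dt,
       running = running)
}

# Per-record scalar summaries used by the windowing machinery.
.record_summaries <- function(records) {
  tibble::tibble(
    L = records$L_um,
    v = records$v_f2f_um_s,
    run_sum = vapply(records$run_times_s, sum, 0),
    run_cnt = vapply(records$run_times_s, length, 0L),
    stop_sum = vapply(records$stop_times_s, sum, 0),
    stop_cnt = vapply(records$stop_times_s, length, 0L))
}

#' Length-window grid
#'
#' Equally spaced sliding (overlapping) windows whose extent stays inside the
#' length range: centers run from `range[1] + width/2` to `range[2] - width/2`.
#'
#' @param range Length range, um.
#' @param width Window width, um.
#' @param n_windows Number of windows.
#' @return Tibble with `window_center_um`, `lo`, `hi`.
#' @export
length_windows <- function(range = c(0.3, 3.25), width = 0.59,
                           n_windows = 50) {
  stopifnot(width > 0, n_windows >= 1, diff(range) >= width)
  centers <- seq(range[1] + width / 2, range[2] - width / 2,
                 length.out = n_windows)
  tibble::tibble(window_center_um = centers, lo = centers - width / 2,
                 hi = centers + width / 2)
}

# membership matrix: records x windows
.window_membership <- function(L, windows) {
  outer(L, windows$lo, `>=`) & outer(L, windows$hi, `<=`)
}

# Window statistics for one weight matrix W (records x replicates).
# Returns list of feature matrices (replicates x windows).
.window_stats <- function(s, M, W) {
  den <- t(W) %*% M                       # filament count per window
  num_v <- t(W) %*% (M * s$v)
  # motile fraction from pooled interval time: run time / (run + stop) time
  run_t <- t(W) %*% (M * s$run_sum)
  stop_t <- t(W) %*% (M * s$stop_sum)
  run_n <- t(W) %*% (M * s$run_cnt)
  stop_n <- t(W) %*% (M * s$stop_cnt)
  safe <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  list(v_um_s = safe(num_v, den),
       f_mot = safe(run_t, run_t + stop_t),
       stop_time_s = safe(stop_t, stop_n),
       run_time_s = safe(run_t, run_n),
       n = den)
}

#' Length-resolved motility feature curves
#'
#' Computes the four motility features resolved by filament length with a
#' sliding-window average: per window the mean of per-filament mean
#' frame-to-frame velocity, the motile fraction from pooled run/stop time,
#' and the means of pooled stop and run durations. Empty windows yield `NA`.
#'
#' @param records A [as_motility_records()] tibble (one condition).
#' @param range,width,n_windows Window grid, um (defaults: 0.3-3.25 um range,
#'   0.59 um width, 50 windows).
#' @return A `length_curve_set`: list with `windows` (grid), `curves`
#'   (point-estimate tibble with per-window filament counts), `condition`.
#' @export
windowed_curves <- function(records, range = c(0.3, 3.25), width = 0.59,
                            n_windows = 50) {
  stopifnot(nrow(records) >= 1)
  windows <- length_windows(range, width, n_windows)
  s <- .record_summaries(records)
  M <- .window_membership(s$L, windows)
  if (!any(M)) stop("no record falls in any length window")
  W <- matrix(1, nrow(records), 1)
  st <- .window_stats(s, M, W)
  curves <- tibble::tibble(
    window_center_um = windows$window_center_um,
    v_um_s = st$v_um_s[1, ], f_mot = st$f_mot[1, ],
    stop_time_s = st$stop_time_s[1, ], run_time_s = st$run_time_s[1, ],
    n_filaments = as.integer(st$n[1, ]))
  structure(list(windows = windows, curves = curves,
                 condition = records$condition[1], B = 0L,
                 replicates = NULL, ci = NULL),
            class = "length_curve_set")
}

#' Bootstrap replicates and confidence bands for length-resolved curves
#'
#' Resamples records with replacement (`resample_unit` `"filament"` resamples
#' rows; `"chamber"` resamples chamber labels) `B` times, recomputes the
#' windowed curves for every replicate, and attaches percentile 95% bands.
#'
#' @param records A [as_motility_records()] tibble (one condition).
#' @param B Number of bootstrap data sets.
#' @param range,width,n_windows Window grid as in [windowed_curves()].
#' @param resample_unit `"filament"` or `"chamber"`.
#' @param conf Confidence level for the percentile bands.
#' @return A `length_curve_set` whose `replicates` field holds one
#'   `B x n_windows` matrix per feature and whose `ci` field holds the bands.
#' @export
bootstrap_curves <- function(records, B = 500, range = c(0.3, 3.25),
                             width = 0.59, n_windows = 50,
                             resample_unit = c("filament", "chamber"),
                             conf = 0.95) {
  stopifnot(B >= 2)
  resample_unit <- match.arg(resample_unit)
  base <- windowed_curves(records, range, width, n_windows)
  s <- .record_summaries(records)
  M <- .window_membership(s$L, base$windows)
  n <- nrow(records)
  W <- matrix(0, n, B)
  if (resample_unit == "filament") {
    for (b in seq_len(B)) W[, b] <- tabulate(sample.int(n, n, TRUE), n)
  } else {
    ch <- records$chamber_id
    if (all(is.na(ch))) stop("chamber resampling needs chamber_id")
    uc <- unique(ch)
    for (b in seq_len(B)) {
      take <- sample(uc, length(uc), TRUE)
      W[, b] <- vapply(ch, function(x) sum(take == x), 0)
    }
  }
  st <- .window_stats(s, M, W)
  feats <- c("v_um_s", "f_mot", "stop_time_s", "run_time_s")
  alpha <- (1 - conf) / 2
  ci <- purrr::map_dfr(feats, function(f) {
    tibble::tibble(
      feature = f, window_center_um = base$windows$window_center_um,
      estimate = base$curves[[f]],
      lower = apply(st[[f]], 2, quantile, alpha, na.rm = TRUE, names = FALSE),
      upper = apply(st[[f]], 2, quantile, 1 - alpha, na.rm = TRUE,
                    names = FALSE))
  })
  base$replicates <- st[feats]
  base$ci <- ci
  base$B <- B
  base
}

#' @export
print.length_curve_set <- function(x, ...) {
  cat(sprintf("<length_curve_set> condition %s, %d windows, B = %d\n",
              x$condition %||% "?", nrow(x$curves), x$B))
  print(x$curves, n = 5)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build motility records from tracked filament traces
#'
#' Converts accepted per-trace kinematics (from [trace_kinematics()]) into the
#' per-filament feature records, segmenting each velocity series with the
#' supplied cut (fitted on the pooled sample when `cut = NULL`).
#'
#' @param kin A tibble of per-trace kinematics: `trace_id`, `L_um`,
#'   `v_trace_um_s`, and list-column `v_f2f` (um/s).
#' @param dt Interval duration, s.
#' @param cut Stop/run cut velocity, um/s, or `NULL` to fit.
#' @param condition,chamber_id,video_id Tags stored with each record.
#' @return A [as_motility_records()] tibble with attribute `cut`.
#' @export
records_from_traces <- function(kin, dt = 1 / 3, cut = NULL,
                                condition = "exp", chamber_id = NA_character_,
                                video_id = NA_character_) {
  stopifnot(nrow(kin) >= 1, "v_f2f" %in% names(kin))
  if (is.null(cut)) cut <- fit_two_gaussians(unlist(kin$v_f2f))$cut
  recs <- purrr::map_dfr(seq_len(nrow(kin)), function(i) {
    v <- kin$v_f2f[[i]]
    seg <- segment_runs_stops(v, cut, dt = dt)
    tibble::tibble(filament_id = kin$trace_id[i], condition = condition,
                   chamber_id = chamber_id, video_id = video_id,
                   L_um = kin$L_um[i], v_trace_um_s = kin$v_trace_um_s[i],
                   v_f2f_um_s = mean(v), f_mot = seg$f_mot,
                   run_times_s = list(seg$run_times_s),
                   stop_times_s = list(seg$stop_times_s))
  })
  out <- as_motility_records(recs)
  attr(out, "cut") <- cut
  out
}
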