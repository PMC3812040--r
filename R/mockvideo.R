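#' Filament specifications for mock motility videos
#'
#' Describes the scripted ground truth of one rod-like fluorescent filament:
#' where it starts, how long it is, how fast and along which path it slides.
#'
#' @param length Filament length, um (> 0).
#' @param velocity Sliding speed, um/s (>= 0).
#' @param curvature Path curvature, 1/um; 0 gives a straight path, positive
#'   values a constant-curvature arc of radius `1/curvature`.
#' @param x0,y0 Start position of the filament centroid, um.
#' @param heading Initial direction of motion, radians.
#' @param intensity Emitted intensity per unit length, arbitrary units/um.
#'   The default is bright enough that the rendered ridge stands well above
#'   the default background at pixel sizes down to 0.08 um/px.
#' @return A tibble with one row per filament (class `filament_specs`).
#' @export
#' @examples
#' filament_specs(length = c(1, 2), velocity = c(0.5, 1), x0 = 10, y0 = c(10, 20))
filament_specs <- function(length, velocity, curvature = 0, x0, y0,
                           heading = 0, intensity = 50) {
  stopifnot(all(length > 0), all(velocity >= 0))
  n <- max(lengths(list(length, velocity, curvature, x0, y0, heading)))
  out <- tibble::tibble(filament_id = seq_len(n),
                        length_um = rep_len(length, n),
                        velocity_um_s = rep_len(velocity, n),
                        curvature = rep_len(curvature, n),
                        x0 = rep_len(x0, n), y0 = rep_len(y0, n),
                        heading = rep_len(heading, n),
                        intensity = rep_len(intensity, n))
  class(out) <- c("filament_specs", class(out))
  out
}

#' Optical and noise model for mock-video rendering
#'
#' @param psf_sigma Gaussian point-spread-function sigma, px.
#' @param background_mean,background_sd Background intensity level and noise.
#' @param fluorophore_spacing Spacing of point emitters along the filament, um.
#' @param brightness_fluctuation_sd Per-emitter per-frame brightness
#'   fluctuation, as a fraction of the emitter intensity.
#' @param brownian_sigma Per-emitter isotropic Brownian jitter per frame, um.
#' @param pixel_size Physical pixel size, um/px.
#' @param frame_rate Frames per second; 3, 6 and 30 fps are the supported
#'   recording/analysis rates.
#' @return A list of class `optics_spec`.
#' @export
optics_spec <- function(psf_sigma = 2, background_mean = 0.1,
                        background_sd = 0.01, fluorophore_spacing = 0.05,
                        brightness_fluctuation_sd = 0, brownian_sigma = 0,
                        pixel_size = 0.16, frame_rate = 6) {
  stopifnot(psf_sigma > 0, pixel_size > 0, fluorophore_spacing > 0,
            frame_rate %in% c(3, 6, 30))
  structure(list(psf_sigma = psf_sigma, background_mean = background_mean,
                 background_sd = background_sd,
                 fluorophore_spacing = fluorophore_spacing,
                 brightness_fluctuation_sd = brightness_fluctuation_sd,
                 brownian_sigma = brownian_sigma, pixel_size = pixel_size,
                 frame_rate = frame_rate),
            class = "optics_spec")
}

#' Ground-truth filament paths
#'
#' Integrates the scripted constant-speed motion of each filament over the
#' video duration: straight motion for zero curvature, otherwise a
#' constant-curvature arc. The filament body is a rigid rod along the local
#' direction of motion, with the tip leading.
#'
#' @param specs A [filament_specs()] tibble.
#' @param duration Video duration, s.
#' @param frame_rate Frames per second.
#' @param fov Field of view `c(width, height)`, um; filaments longer than the
#'   field of view are rejected, positions outside are flagged `in_fov =
#'   FALSE`.
#' @return A truth-table tibble: one row per (filament, frame) with centroid,
#'   tip, length, speed, heading and flags (class `truth_table`).
#' @export
#' @examples
#' sp <- filament_specs(length = 1, velocity = 1, x0 = 5, y0 = 5)
#' tt <- build_paths(sp, duration = 1, frame_rate = 3)
#' diff(tt$x_um) # 1/3 um per frame
build_paths <- function(specs, duration, frame_rate, fov = c(81.92, 81.92)) {
  stopifnot(duration > 0, frame_rate > 0)
  if (any(specs$length_um > min(fov)))
    stop("filament longer than the field of view")
  times <- seq(0, duration, by = 1 / frame_rate)
  out <- purrr::pmap_dfr(specs, function(filament_id, length_um,
                                         velocity_um_s, curvature, x0, y0,
                                         heading, intensity, ...) {
    if (curvature == 0) {
      x <- x0 + velocity_um_s * times * cos(heading)
      y <- y0 + velocity_um_s * times * sin(heading)
      th <- rep(heading, length(times))
    } else {
      r <- 1 / curvature
      # centre of the circular path sits left of the heading
      cx <- x0 - r * sin(heading)
      cy <- y0 + r * cos(heading)
      phi <- velocity_um_s * curvature * times
      x <- cx + r * sin(heading + phi)
      y <- cy - r * cos(heading + phi)
      th <- heading + phi
    }
    tibble::tibble(
      filament_id = filament_id, frame = seq_along(times) - 1L,
      time_s = times, x_um = x, y_um = y,
      tip_x_um = x + length_um / 2 * cos(th),
      tip_y_um = y + length_um / 2 * sin(th),
      length_um = length_um, velocity_um_s = velocity_um_s, heading = th,
      intensity = intensity,
      in_fov = x - length_um / 2 >= 0 & x + length_um / 2 <= fov[1] &
        y - length_um / 2 >= 0 & y + length_um / 2 <= fov[2],
      label = "clean")
  })
  out <- .flag_overlaps(out)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "fov") <- fov
  class(out) <- c("truth_table", class(out))
  out
}

# mark frames in which two filament body segments come closer than `radius`
.flag_overlaps <- function(truth, radius = 0.3) {
  truth$overlap <- FALSE
  for (f in unique(truth$frame)) {
    i <- which(truth$frame == f)
    if (length(i) < 2) next
    seg <- truth[i, ]
    for (a in seq_len(nrow(seg) - 1)) {
      for (b in seq(a + 1, nrow(seg))) {
        d <- .segment_distance(
          seg$x_um[a], seg$y_um[a], seg$heading[a], seg$length_um[a],
          seg$x_um[b], seg$y_um[b], seg$heading[b], seg$length_um[b])
        if (d < radius) truth$overlap[i[c(a, b)]] <- TRUE
      }
    }
  }
  truth
}

# minimum distance between two rod segments, sampled along their backbones
.segment_distance <- function(x1, y1, th1, l1, x2, y2, th2, l2) {
  s1 <- seq(-l1 / 2, l1 / 2, length.out = max(2, ceiling(l1 / 0.1)))
  s2 <- seq(-l2 / 2, l2 / 2, length.out = max(2, ceiling(l2 / 0.1)))
  p1x <- x1 + s1 * cos(th1); p1y <- y1 + s1 * sin(th1)
  p2x <- x2 + s2 * cos(th2); p2y <- y2 + s2 * sin(th2)
  min(sqrt(outer(p1x, p2x, `-`)^2 + outer(p1y, p2y, `-`)^2))
}

#' Render a truth table into a fluorescence image stack
#'
#' Each filament is a chain of point emitters at `fluorophore_spacing`,
#' convolved with a Gaussian point-spread function, over a Gaussian-noise
#' background. Optional per-emitter brightness fluctuations and Brownian
#' jitter reproduce the appearance of real recordings; the returned truth is
#' the scripted (unjittered) path.
#'
#' @param truth A [build_paths()] truth table.
#' @param optics An [optics_spec()].
#' @param fov_px Field of view in pixels `c(nx, ny)`; defaults to the truth
#'   table's field of view divided by the pixel size.
#' @return A list with `stack` (array `ny x nx x frames`, values >= 0) and
#'   `truth` (the input table).
#' @export
render_video <- function(truth, optics, fov_px = NULL) {
  fov <- attr(truth, "fov") %||% c(81.92, 81.92)
  if (is.null(fov_px)) fov_px <- round(fov / optics$pixel_size)
  if (optics$pixel_size >= 0.5)
    warning("pixel size >= 0.5 um/px: filaments undersampled")
  frames <- sort(unique(truth$frame))
  ny <- fov_px[2]; nx <- fov_px[1]
  stack <- array(0, dim = c(ny, nx, length(frames)))
  half <- ceiling(3 * optics$psf_sigma)
  kx <- seq(-half, half)
  for (fi in seq_along(frames)) {
    img <- matrix(0, ny, nx)
    rows <- truth[truth$frame == frames[fi], ]
    for (r in seq_len(nrow(rows))) {
      s <- seq(-rows$length_um[r] / 2, rows$length_um[r] / 2,
               by = optics$fluorophore_spacing)
      ex <- rows$x_um[r] + s * cos(rows$heading[r])
      ey <- rows$y_um[r] + s * sin(rows$heading[r])
      if (optics$brownian_sigma > 0) {
        ex <- ex + rnorm(length(ex), 0, optics$brownian_sigma)
        ey <- ey + rnorm(length(ey), 0, optics$brownian_sigma)
      }
      amp <- rep(rows$intensity[r] * optics$fluorophore_spacing, length(ex))
      if (optics$brightness_fluctuation_sd > 0)
        amp <- amp * pmax(0, 1 + rnorm(length(amp), 0,
                                       optics$brightness_fluctuation_sd))
      px <- ex / optics$pixel_size
      py <- ey / optics$pixel_size
      for (e in seq_along(px)) {
        cx <- round(px[e]); cy <- round(py[e])
        ix <- cx + kx; iy <- cy + kx
        ok_x <- ix >= 0 & ix < nx; ok_y <- iy >= 0 & iy < ny
        if (!any(ok_x) || !any(ok_y)) next
        gx <- exp(-((ix - px[e])^2) / (2 * optics$psf_sigma^2))
        gy <- exp(-((iy - py[e])^2) / (2 * optics$psf_sigma^2))
        patch <- amp[e] / (2 * pi * optics$psf_sigma^2) *
          outer(gy[ok_y], gx[ok_x])
        img[iy[ok_y] + 1, ix[ok_x] + 1] <- img[iy[ok_y] + 1, ix[ok_x] + 1] +
          patch
      }
    }
    img <- img + optics$background_mean
    if (optics$background_sd > 0)
      img <- img + matrix(rnorm(ny * nx, 0, optics$background_sd), ny, nx)
    stack[, , fi] <- pmax(img, 0)
  }
  list(stack = stack, truth = truth)
}

#' Scripted scenarios with labeled clean, crossing and irregular traces
#'
#' Builds a truth table containing, per scenario, one clean constant-velocity
#' filament, one pair of filaments scripted to cross (each crossing event has
#' at least one overlapping frame), and one filament with irregular motion
#' (random heading and speed changes). The labels are carried in the truth
#' table and serve as ground truth for training and testing the trace quality
#' control.
#'
#' @param n Number of scenarios (>= 0).
#' @param seed Random seed; fixed seeds give identical tables.
#' @param duration,frame_rate Video timing.
#' @param fov Field of view, um.
#' @return A `truth_table` tibble with a `label` column
#'   (`clean` / `crossing` / `irregular`).
#' @export
crossing_scenario <- function(n, seed = 1, duration = 10, frame_rate = 3,
                              fov = c(81.92, 81.92)) {
  stopifnot(n >= 0)
  if (n == 0) {
    out <- tibble::tibble(filament_id = integer(), frame = integer(),
                          time_s = numeric(), x_um = numeric(),
                          y_um = numeric(), tip_x_um = numeric(),
                          tip_y_um = numeric(), length_um = numeric(),
                          velocity_um_s = numeric(), heading = numeric(),
                          intensity = numeric(), in_fov = logical(),
                          label = character(), overlap = logical())
    class(out) <- c("truth_table", class(out))
    return(out)
  }
  set.seed(seed)
  times <- seq(0, duration, by = 1 / frame_rate)
  nf <- length(times)
  out <- vector("list", n)
  id <- 0L
  for (k in seq_len(n)) {
    margin <- 12
    base_xy <- runif(2, margin, fov - margin)
    mk <- function(id, x, y, th, L, v, label) {
      tibble::tibble(filament_id = id, frame = seq_len(nf) - 1L,
                     time_s = times, x_um = x, y_um = y,
                     tip_x_um = x + L / 2 * cos(th),
                     tip_y_um = y + L / 2 * sin(th), length_um = L,
                     velocity_um_s = v, heading = th, intensity = 1,
                     in_fov = TRUE, label = label)
    }
    # clean straight filament
    L1 <- runif(1, 0.8, 2.5); v1 <- runif(1, 0.4, 1.2); th1 <- runif(1, 0, 2 * pi)
    x1 <- base_xy[1] + v1 * times * cos(th1)
    y1 <- base_xy[2] + v1 * times * sin(th1)
    out[[k]] <- list(mk(id <- id + 1L, x1, y1, rep(th1, nf), L1, v1, "clean"))
    # crossing pair: paths meet at mid-time in a fresh spot
    cxy <- runif(2, margin, fov - margin)
    tm <- duration / 2
    thA <- runif(1, 0, 2 * pi); thB <- thA + runif(1, pi / 3, 2 * pi / 3)
    for (th in c(thA, thB)) {
      L <- runif(1, 0.8, 2.5); v <- runif(1, 0.4, 1.2)
      x <- cxy[1] + v * (times - tm) * cos(th)
      y <- cxy[2] + v * (times - tm) * sin(th)
      out[[k]] <- c(out[[k]],
                    list(mk(id <- id + 1L, x, y, rep(th, nf), L, v,
                            "crossing")))
    }
    # irregular motion: heading and speed jump every few frames
    L4 <- runif(1, 0.8, 2.5)
    ixy <- runif(2, margin, fov - margin)
    th <- runif(1, 0, 2 * pi)
    v <- runif(1, 0.2, 1.2)
    x <- numeric(nf); y <- numeric(nf); ths <- numeric(nf)
    x[1] <- ixy[1]; y[1] <- ixy[2]; ths[1] <- th
    for (f in 2:nf) {
      if (runif(1) < 0.35) {
        th <- th + rnorm(1, 0, 1.2)
        v <- pmin(pmax(v * exp(rnorm(1, 0, 0.6)), 0), 2)
      }
      x[f] <- x[f - 1] + v / frame_rate * cos(th)
      y[f] <- y[f - 1] + v / frame_rate * sin(th)
      ths[f] <- th
    }
    out[[k]] <- c(out[[k]], list(mk(id <- id + 1L, x, y, ths, L4,
                                    mean(abs(v)), "irregular")))
  }
  out <- dplyr::bind_rows(unlist(out, recursive = FALSE))
  out <- .flag_overlaps(out)
  attr(out, "frame_rate") <- frame_rate
  attr(out, "fov") <- fov
  class(out) <- c("truth_table", class(out))
  out
}

#' Write an image stack as multi-page TIFF
#'
#' Intensities are divided by the stack maximum before writing (32-bit
#' float storage holds values in `[0, 1]`); the analysis pipeline is
#' invariant to this global scale because frames are contrast-stretched.
#'
#' @param stack Array `ny x nx x frames`.
#' @param path Output file.
#' @return The scale factor that was divided out, invisibly.
#' @export
write_video_tiff <- function(stack, path) {
  scale <- max(stack, 1e-12)
  frames <- lapply(seq_len(dim(stack)[3]), function(i)
    pmax(stack[, , i], 0) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(scale)
}

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file.
#' @return Array `ny x nx x frames`.
#' @export
read_video_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) if (length(dim(f)) == 3) f[, , 1] else f)
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Write a truth table as CSV
#'
#' @param truth A `truth_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}
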