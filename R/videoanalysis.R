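#' Merge and enhance raw video frames
#'
#' Averages frames in non-overlapping blocks to reach the analysis time
#' resolution (default 1/3 s), then enhances each merged frame by subtracting
#' its median background level and stretching the contrast to `[0, 1]`.
#'
#' @param stack Array `ny x nx x frames`.
#' @param native_dt Native frame interval, s (1/30 s for 30 fps recordings).
#' @param target_dt Analysis time resolution, s; must be an integer multiple
#'   of `native_dt`.
#' @param enhance If `FALSE`, skip background subtraction/contrast stretch.
#' @return Array of merged frames with attribute `dt`.
#' @export
#' @examples
#' st <- array(runif(16 * 16 * 30), dim = c(16, 16, 30))
#' dim(preprocess_stack(st, native_dt = 1 / 30))[3] # 3 merged frames
preprocess_stack <- function(stack, native_dt, target_dt = 1 / 3,
                             enhance = TRUE) {
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] >= 2)
  ratio <- target_dt / native_dt
  if (abs(ratio - round(ratio)) > 1e-6)
    stop("target_dt must be an integer multiple of the native frame interval")
  ratio <- as.integer(round(ratio))
  n_merged <- dim(stack)[3] %/% ratio
  if (n_merged < 1) stop("stack shorter than one merged frame")
  out <- array(0, dim = c(dim(stack)[1], dim(stack)[2], n_merged))
  for (i in seq_len(n_merged)) {
    block <- stack[, , ((i - 1) * ratio + 1):(i * ratio), drop = FALSE]
    frame <- rowMeans(block, dims = 2)
    if (enhance) {
      frame <- frame - median(frame)
      mx <- max(frame)
      frame <- if (mx > 0) pmin(pmax(frame / mx, 0), 1) else frame * 0
    }
    out[, , i] <- frame
  }
  attr(out, "dt") <- target_dt
  out
}

#' Binarize a frame at a fraction of its dynamic range
#'
#' The black-white threshold is deliberately exposed: filament width and
#' length depend on it, while velocity estimates must be robust over a
#' central range of thresholds.
#'
#' @param frame Numeric matrix.
#' @param bw_threshold Threshold as a fraction of the frame's dynamic range,
#'   in (0, 1). The top of the range is the maximum of a 3x3 box-smoothed
#'   copy of the frame, so that single hot pixels (per-fluorophore
#'   brightness fluctuations) do not shift the threshold.
#' @return Logical mask.
#' @export
binarize_frame <- function(frame, bw_threshold = 0.35) {
  stopifnot(bw_threshold > 0, bw_threshold < 1)
  lo <- min(frame)
  frame >= lo + bw_threshold * (max(.box3(frame)) - lo)
}

# 3x3 box mean via shift-and-add (edges handled by replication)
.box3 <- function(m) {
  sh <- function(m, dr, dc) {
    r <- pmin(pmax(seq_len(nrow(m)) + dr, 1), nrow(m))
    c <- pmin(pmax(seq_len(ncol(m)) + dc, 1), ncol(m))
    m[r, c, drop = FALSE]
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) out <- out + sh(m, dr, dc)
  out / 9
}

# Perimeter of one object mask: Moore-neighbour boundary chain with axial
# steps counting 1 px and diagonal steps sqrt(2) px, plus 4 px for closing
# the crack boundary around the pixel squares. An axis-aligned l x w pixel
# rectangle then measures exactly 2 (l + w), so rectangle-equivalent lengths
# are consistent with pixel areas.
.crack_perimeter <- function(mask) {
  npx <- sum(mask)
  if (npx == 1) return(4)
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  idx <- which(pad, arr.ind = TRUE)
  start <- idx[order(idx[, 1], idx[, 2])[1], ] # topmost, then leftmost
  # neighbour order: N, NE, E, SE, S, SW, W, NW (0-based indices 0..7)
  nbr <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  step_len <- rep(c(1, sqrt(2)), 4)
  cur <- start
  dir_prev <- 2L # pretend we arrived moving east (from the west neighbour,
                 # which is background for the topmost-leftmost pixel)
  per <- 0
  steps <- 0L
  max_steps <- 4L * npx + 8L
  repeat {
    moved <- FALSE
    for (k in 0:7) {
      d <- (dir_prev + 5L + k) %% 8L # backtrack + 1, then clockwise sweep
      rr <- cur[1] + nbr[d + 1, 1]
      cc <- cur[2] + nbr[d + 1, 2]
      if (pad[rr, cc]) {
        per <- per + step_len[d + 1]
        cur <- c(rr, cc)
        dir_prev <- d
        moved <- TRUE
        break
      }
    }
    if (!moved) return(4) # isolated pixel (cannot happen for npx > 1)
    steps <- steps + 1L
    if ((cur[1] == start[1] && cur[2] == start[2]) || steps >= max_steps)
      break
  }
  per + 4
}

#' Extract filament objects from a binary mask
#'
#' 8-connected components of at least `min_area_px` pixels, with
#' intensity-weighted sub-pixel centroids, pixel areas and crack-boundary
#' perimeters converted to physical units, and rectangle-equivalent lengths
#' and widths.
#'
#' @param mask Logical matrix from [binarize_frame()].
#' @param frame Intensity frame used for centroid weighting (defaults to the
#'   mask itself).
#' @param min_area_px Minimum component size, px.
#' @param pixel_size Pixel size, um/px.
#' @param frame_index Frame number stored with the objects.
#' @return Tibble of objects: centroid (`x_um`, `y_um`, 0-based pixel-centre
#'   convention), `area_um2`, `perimeter_um`, `length_um`, `width_um`,
#'   `complex_flag`, `theta` (major-axis orientation), `area_px`.
#' @export
extract_objects <- function(mask, frame = NULL, min_area_px = 5,
                            pixel_size = 0.16, frame_index = 0L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  if (!any(mask)) return(.empty_objects())
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  if (is.null(frame)) frame <- mask * 1
  fg <- which(labm > 0)
  by_id <- split(fg, labm[fg])
  by_id <- by_id[lengths(by_id) >= min_area_px]
  out <- list()
  for (id in names(by_id)) {
    lin <- by_id[[id]]
    npx <- length(lin)
    idx <- cbind((lin - 1) %% nrow(mask) + 1, (lin - 1) %/% nrow(mask) + 1)
    w <- frame[lin]
    if (all(w <= 0)) w <- rep(1, npx)
    # rows index y, columns x; 0-based pixel centres
    cy <- sum((idx[, 1] - 1) * w) / sum(w)
    cx <- sum((idx[, 2] - 1) * w) / sum(w)
    # principal axis from second central moments of the pixel mask
    my <- idx[, 1] - 1 - mean(idx[, 1] - 1)
    mx <- idx[, 2] - 1 - mean(idx[, 2] - 1)
    theta <- 0.5 * atan2(2 * sum(mx * my), sum(mx^2) - sum(my^2))
    # bounding-box crop keeps the boundary trace cheap
    rr <- range(idx[, 1]); cc <- range(idx[, 2])
    sub <- matrix(FALSE, rr[2] - rr[1] + 1, cc[2] - cc[1] + 1)
    sub[cbind(idx[, 1] - rr[1] + 1, idx[, 2] - cc[1] + 1)] <- TRUE
    per_px <- .crack_perimeter(sub)
    A <- npx * pixel_size^2
    P <- per_px * pixel_size
    re <- rect_equivalent(A, P)
    out[[length(out) + 1]] <- tibble::tibble(
      frame = frame_index, object_id = as.integer(id), x_um = cx * pixel_size,
      y_um = cy * pixel_size, area_um2 = A, perimeter_um = P,
      length_um = re$length, width_um = re$width,
      complex_flag = re$complex_flag, theta = theta, area_px = npx)
  }
  if (length(out) == 0) return(.empty_objects())
  dplyr::bind_rows(out)
}

.empty_objects <- function() {
  tibble::tibble(frame = integer(), object_id = integer(), x_um = numeric(),
                 y_um = numeric(), area_um2 = numeric(),
                 perimeter_um = numeric(), length_um = numeric(),
                 width_um = numeric(), complex_flag = logical(),
                 theta = numeric(), area_px = integer())
}

#' Rectangle-equivalent length and width
#'
#' Transforms an image object into the rectangle with the same area `A` and
#' perimeter `P`; the longer edge is the filament length. Lengths and widths
#' are the roots of `x^2 - (P/2) x + A = 0`. When the discriminant is
#' negative (very small objects), the roots are complex: the object is
#' flagged and both edges are reported as the real part `P/4`, which keeps
#' such objects correctly ordered by size.
#'
#' @param A Area, um^2 (> 0). Vectorized.
#' @param P Perimeter, um (> 0).
#' @return A tibble with `length`, `width`, `complex_flag`.
#' @export
#' @examples
#' rect_equivalent(2, 6) # length 2, width 1
rect_equivalent <- function(A, P) {
  stopifnot(all(A > 0), all(P > 0))
  disc <- (P / 2)^2 - 4 * A
  cf <- disc < 0
  s <- sqrt(pmax(disc, 0))
  tibble::tibble(length = ifelse(cf, P / 4, (P / 2 + s) / 2),
                 width = ifelse(cf, P / 4, (P / 2 - s) / 2),
                 complex_flag = cf)
}

#' Track objects across frames
#'
#' Greedy frame-to-frame assignment: candidate pairs within `max_jump` are
#' matched in order of increasing centroid distance, ties broken by the
#' smaller relative area change. Unmatched objects start new traces; traces
#' end when no match is found.
#'
#' @param objects Tibble of per-frame objects (from [extract_objects()],
#'   concatenated over frames).
#' @param max_jump Maximum centroid displacement between consecutive frames,
#'   um.
#' @param area_tolerance Maximum relative area change for a valid match.
#' @return The objects tibble with a `trace_id` column.
#' @export
track_objects <- function(objects, max_jump = 1.2, area_tolerance = 0.5) {
  if (nrow(objects) == 0) return(dplyr::mutate(objects, trace_id = integer()))
  frames <- sort(unique(objects$frame))
  objects$trace_id <- NA_integer_
  next_id <- 1L
  prev <- objects$frame == frames[1]
  objects$trace_id[prev] <- seq_len(sum(prev))
  next_id <- sum(prev) + 1L
  for (fi in seq_along(frames)[-1]) {
    cur <- which(objects$frame == frames[fi])
    pre <- which(objects$frame == frames[fi - 1] & !is.na(objects$trace_id))
    if (length(cur) == 0) next
    if (length(pre) > 0) {
      d <- sqrt(outer(objects$x_um[pre], objects$x_um[cur], `-`)^2 +
                outer(objects$y_um[pre], objects$y_um[cur], `-`)^2)
      rel_a <- abs(outer(objects$area_um2[pre], objects$area_um2[cur], `-`)) /
        outer(objects$area_um2[pre], rep(1, length(cur)))
      cand <- which(d <= max_jump & rel_a <= area_tolerance, arr.ind = TRUE)
      if (length(cand) > 0) {
        ord <- order(d[cand], rel_a[cand])
        used_p <- logical(length(pre)); used_c <- logical(length(cur))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_p[i] || used_c[j]) next
          objects$trace_id[cur[j]] <- objects$trace_id[pre[i]]
          used_p[i] <- TRUE; used_c[j] <- TRUE
        }
      }
    }
    new <- cur[is.na(objects$trace_id[cur])]
    if (length(new) > 0) {
      objects$trace_id[new] <- seq(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
  }
  objects
}

#' Per-trace kinematics
#'
#' Computes frame-to-frame velocities from centroid displacements and the
#' trace velocity from the travelled tip path: the tip is the endpoint of the
#' object's major axis that leads in the direction of motion, and the trace
#' velocity is the total tip path length divided by the trace lifetime.
#' Traces shorter than two frames are dropped (with a message).
#'
#' @param tracked Tibble from [track_objects()].
#' @param dt Frame interval of the (merged) video, s.
#' @return Tibble with one row per trace: `trace_id`, `n_frames`,
#'   `L_um` (median object length), `width_um`, `v_trace_um_s`,
#'   `complex_frac`, plus list-columns `v_f2f` (um/s), `frames`, `x_um`,
#'   `y_um`, `areas`, `lengths`.
#' @export
trace_kinematics <- function(tracked, dt = 1 / 3) {
  stopifnot(nrow(tracked) > 0)
  dropped <- 0L
  out <- lapply(split(tracked, tracked$trace_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) {
      dropped <<- dropped + 1L
      return(NULL)
    }
    dx <- diff(tr$x_um); dy <- diff(tr$y_um)
    v <- sqrt(dx^2 + dy^2) / dt
    # leading major-axis endpoint per frame
    ux <- cos(tr$theta); uy <- sin(tr$theta)
    step_x <- c(dx, dx[length(dx)]); step_y <- c(dy, dy[length(dy)])
    lead <- sign(ux * step_x + uy * step_y)
    lead[lead == 0] <- 1
    tip_x <- tr$x_um + lead * tr$length_um / 2 * ux
    tip_y <- tr$y_um + lead * tr$length_um / 2 * uy
    tip_path <- sum(sqrt(diff(tip_x)^2 + diff(tip_y)^2))
    lifetime <- (nrow(tr) - 1) * dt
    tibble::tibble(
      trace_id = tr$trace_id[1], n_frames = nrow(tr),
      L_um = median(tr$length_um), width_um = median(tr$width_um),
      v_trace_um_s = tip_path / lifetime,
      complex_frac = mean(tr$complex_flag),
      v_f2f = list(v), frames = list(tr$frame),
      x_um = list(tr$x_um), y_um = list(tr$y_um),
      areas = list(tr$area_um2), lengths = list(tr$length_um))
  })
  if (dropped > 0)
    message(dropped, " trace(s) shorter than 2 frames dropped")
  dplyr::bind_rows(out)
}

#' Full video-analysis pipeline
#'
#' Preprocess, binarize, extract, track, and compute kinematics in one call.
#'
#' @param stack Raw image stack (array `ny x nx x frames`).
#' @param native_dt Native frame interval, s.
#' @param target_dt Analysis time resolution, s.
#' @param bw_threshold Binarization threshold (fraction of dynamic range).
#' @param min_area_px Minimum object size, px.
#' @param pixel_size Pixel size, um/px.
#' @param max_jump Tracking jump limit, um per merged frame.
#' @return A list with `objects` (tracked per-frame objects) and `traces`
#'   (per-trace kinematics from [trace_kinematics()]), plus `dt`.
#' @export
analyze_video <- function(stack, native_dt, target_dt = 1 / 3,
                          bw_threshold = 0.35, min_area_px = 5,
                          pixel_size = 0.16, max_jump = 1.2) {
  merged <- preprocess_stack(stack, native_dt, target_dt)
  objs <- purrr::map_dfr(seq_len(dim(merged)[3]), function(i) {
    frame <- merged[, , i]
    extract_objects(binarize_frame(frame, bw_threshold), frame,
                    min_area_px = min_area_px, pixel_size = pixel_size,
                    frame_index = i - 1L)
  })
  tracked <- track_objects(objs, max_jump = max_jump)
  traces <- if (nrow(tracked) > 0) trace_kinematics(tracked, dt = target_dt)
    else tibble::tibble()
  list(objects = tracked, traces = traces, dt = target_dt)
}
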