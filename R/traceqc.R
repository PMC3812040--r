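#' Quality-control features of a filament trace
#'
#' Summarizes one tracked trace into the feature vector used by the
#' decision-tree-ensemble quality control: the number of corners detected
#' along the rasterized trajectory (Harris detector on the
#' Gaussian-smoothed trajectory image; kernel length 21, sigma 2.5,
#' sensitivity factor 0.2, quality level 0.15, at most 200 corners),
#' coefficients of variation of velocity, object area and length, the
#' fraction of frames with complex rectangle-equivalent solutions, the
#' minimum distance to any other trace, and the number of proximity
#' (potential crossing) events.
#'
#' @param trace One row of a [trace_kinematics()] tibble (>= 3 frames).
#' @param all_traces The full kinematics tibble (for distances to others).
#' @param pixel_size Raster pixel size for the trajectory image, um/px.
#' @param proximity_um Distance below which another trace counts as a
#'   potential crossing partner.
#' @return A one-row tibble of features.
#' @export
qc_features <- function(trace, all_traces = NULL, pixel_size = 0.16,
                        proximity_um = 1.0) {
  stopifnot(trace$n_frames >= 3)
  v <- trace$v_f2f[[1]]
  cv <- function(x) if (length(x) < 2 || mean(x) == 0) 0 else sd(x) / mean(x)
  min_dist <- Inf
  overlap_events <- 0L
  if (!is.null(all_traces) && nrow(all_traces) > 1) {
    others <- all_traces[all_traces$trace_id != trace$trace_id, ]
    for (i in seq_len(nrow(others))) {
      common <- intersect(trace$frames[[1]], others$frames[[i]])
      if (length(common) == 0) next
      ia <- match(common, trace$frames[[1]])
      ib <- match(common, others$frames[[i]])
      d <- sqrt((trace$x_um[[1]][ia] - others$x_um[[i]][ib])^2 +
                (trace$y_um[[1]][ia] - others$y_um[[i]][ib])^2)
      min_dist <- min(min_dist, min(d))
      overlap_events <- overlap_events + sum(d < proximity_um)
    }
  }
  tibble::tibble(
    trace_id = trace$trace_id,
    n_corners = trajectory_corners(trace$x_um[[1]], trace$y_um[[1]],
                                   pixel_size = pixel_size),
    v_cv = cv(v),
    area_cv = cv(trace$areas[[1]]),
    length_cv = cv(trace$lengths[[1]]),
    complex_frac = trace$complex_frac,
    min_dist_um = if (is.finite(min_dist)) min_dist else 99,
    overlap_events = overlap_events)
}

#' Featurize all traces of a video
#'
#' @param traces A [trace_kinematics()] tibble.
#' @param ... Passed to [qc_features()].
#' @return Feature tibble, one row per trace with >= 3 frames.
#' @export
qc_featurize <- function(traces, ...) {
  keep <- traces$n_frames >= 3
  purrr::map_dfr(which(keep), function(i)
    qc_features(traces[i, ], all_traces = traces, ...))
}

#' Corner count along a rasterized trajectory
#'
#' The trajectory is drawn into a binary image (line segments between
#' consecutive centroids), smoothed with a Gaussian filter (kernel length
#' 21, sigma 2.5), and corners are detected with a Harris detector:
#' sensitivity factor `k`, response threshold `quality_level` times the
#' maximal response, and at most `max_corners` local maxima are counted. A
#' straight constant-velocity trajectory yields 0 corners; direction changes
#' produce corners.
#'
#' @param x,y Trajectory coordinates, um.
#' @param pixel_size Raster resolution, um/px.
#' @param kernel_length,sigma Gaussian smoothing parameters (px).
#' @param k Harris sensitivity factor.
#' @param quality_level Response threshold as a fraction of the maximum.
#' @param max_corners Cap on the number of reported corners.
#' @return Integer corner count.
#' @export
trajectory_corners <- function(x, y, pixel_size = 0.16, kernel_length = 21,
                               sigma = 2.5, k = 0.2, quality_level = 0.15,
                               max_corners = 200) {
  px <- round((x - min(x)) / pixel_size)
  py <- round((y - min(y)) / pixel_size)
  pad <- 12L
  nx <- max(px) + 2L * pad + 1L
  ny <- max(py) + 2L * pad + 1L
  img <- matrix(0, ny, nx)
  for (i in seq_along(px)[-1]) {
    nstep <- max(abs(px[i] - px[i - 1]), abs(py[i] - py[i - 1]), 1) + 1
    xs <- round(seq(px[i - 1], px[i], length.out = nstep)) + pad
    ys <- round(seq(py[i - 1], py[i], length.out = nstep)) + pad
    img[cbind(ys + 1, xs + 1)] <- 1
  }
  if (sum(img) <= 1) return(0L) # degenerate single-pixel trajectory
  g <- dnorm(seq(-(kernel_length - 1) / 2, (kernel_length - 1) / 2), 0, sigma)
  g <- g / sum(g)
  smooth <- .sep_filter(img, g)
  # gradients and Harris structure tensor (window = same Gaussian)
  gx <- (cbind(smooth[, -1], 0) - cbind(0, smooth[, -ncol(smooth)])) / 2
  gy <- (rbind(smooth[-1, ], 0) - rbind(0, smooth[-nrow(smooth), ])) / 2
  sxx <- .sep_filter(gx * gx, g)
  syy <- .sep_filter(gy * gy, g)
  sxy <- .sep_filter(gx * gy, g)
  R <- (sxx * syy - sxy^2) - k * (sxx + syy)^2
  mx <- max(R)
  if (mx <= 0) return(0L)
  thr <- quality_level * mx
  # trajectory endpoints always excite the detector; mask them out so only
  # genuine direction changes count
  ends <- rbind(c(py[1], px[1]), c(py[length(py)], px[length(px)])) + pad + 1
  # local maxima in a 3x3 neighbourhood above threshold
  n <- 0L
  for (i in 2:(nrow(R) - 1)) {
    for (j in 2:(ncol(R) - 1)) {
      v <- R[i, j]
      if (v >= thr && v == max(R[(i - 1):(i + 1), (j - 1):(j + 1)])) {
        d_end <- min(sqrt((i - ends[, 1])^2 + (j - ends[, 2])^2))
        if (d_end <= 2 * sigma + 2) next
        n <- n + 1L
        if (n >= max_corners) return(max_corners)
      }
    }
  }
  n
}

# separable 1-D convolution along both axes, zero padding
.sep_filter <- function(img, g) {
  half <- (length(g) - 1) / 2
  conv1 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (s in seq_along(g)) {
      sh <- s - 1 - half
      src <- seq_len(ncol(m)) - sh
      ok <- src >= 1 & src <= ncol(m)
      out[, ok] <- out[, ok] + g[s] * m[, src[ok]]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Train the trace-rejection ensemble
#'
#' Fits a bagged ensemble of decision trees (a random forest with all
#' features available at every split, i.e. pure bagging) that scores traces
#' as keep vs reject. The out-of-bag error as a function of tree count is
#' attached, which plateaus well below the default 150 trees.
#'
#' @param features Feature tibble from [qc_featurize()].
#' @param labels Factor or character vector, `"keep"` / `"reject"`.
#' @param n_trees Number of trees.
#' @param seed Random seed.
#' @return An object of class `qc_model`: the forest, the OOB error curve,
#'   and the feature names.
#' @export
qc_train <- function(features, labels, n_trees = 150, seed = 1) {
  labels <- factor(labels, levels = c("keep", "reject"))
  if (nlevels(droplevels(labels)) < 2)
    stop("training labels must contain both classes")
  x <- as.data.frame(features[, setdiff(names(features), "trace_id")])
  set.seed(seed)
  rf <- randomForest::randomForest(x, labels, ntree = n_trees,
                                   mtry = ncol(x), keep.forest = TRUE)
  structure(list(forest = rf,
                 oob_error = rf$err.rate[, "OOB"],
                 features = names(x), n_trees = n_trees, seed = seed),
            class = "qc_model")
}

#' @export
print.qc_model <- function(x, ...) {
  cat(sprintf("<qc_model> %d trees, OOB error %.3f\n", x$n_trees,
              utils::tail(x$oob_error, 1)))
  invisible(x)
}

#' Ensemble keep-score for traces
#'
#' @param model A [qc_train()] model.
#' @param features Feature tibble.
#' @return Numeric vector in `[0, 1]`: fraction of trees voting "keep".
#' @export
qc_score <- function(model, features) {
  x <- as.data.frame(features[, model$features])
  predict(model$forest, x, type = "prob")[, "keep"]
}

#' Cost-optimal acceptance threshold
#'
#' Sweeps the ensemble score and picks the acceptance threshold minimizing
#' `cost_fp * FPR + cost_fn * FNR`, where a false positive is a bad trace
#' kept (contaminating the data set, hence the higher default cost) and a
#' false negative a good trace rejected. The ROC curve of the validation
#' scores is attached for cross-day style validation.
#'
#' @param model A [qc_train()] model.
#' @param features,labels Validation set (both classes present).
#' @param cost_fp,cost_fn Misclassification costs.
#' @return List: `threshold`, `cost`, `roc` (a [pROC::roc] object), `auc`,
#'   and the sweep table.
#' @export
qc_threshold <- function(model, features, labels, cost_fp = 5, cost_fn = 1) {
  labels <- factor(labels, levels = c("keep", "reject"))
  stopifnot(nlevels(droplevels(labels)) == 2)
  score <- qc_score(model, features)
  grid <- sort(unique(c(0, score, 1)))
  sweep <- purrr::map_dfr(grid, function(th) {
    kept <- score >= th
    fp <- sum(kept & labels == "reject") / sum(labels == "reject")
    fn <- sum(!kept & labels == "keep") / sum(labels == "keep")
    tibble::tibble(threshold = th, fpr = fp, fnr = fn,
                   cost = cost_fp * fp + cost_fn * fn)
  })
  best <- sweep[which.min(sweep$cost), ]
  roc <- pROC::roc(response = labels, predictor = score, levels =
                     c("reject", "keep"), direction = "<", quiet = TRUE)
  list(threshold = best$threshold, cost = best$cost, roc = roc,
       auc = as.numeric(pROC::auc(roc)), sweep = sweep)
}

#' Apply the quality control to traces
#'
#' @param model A [qc_train()] model.
#' @param features Feature tibble (with `trace_id`).
#' @param threshold Acceptance threshold on the keep-score.
#' @return List: `accepted` trace ids, `log` tibble with score, decision and
#'   features per trace.
#' @export
qc_filter <- function(model, features, threshold) {
  score <- qc_score(model, features)
  log <- dplyr::mutate(features, score = score,
                       decision = ifelse(score >= threshold, "keep",
                                         "reject"))
  list(accepted = features$trace_id[score >= threshold], log = log)
}

#' Label traces of a scripted scenario by matching to the truth table
#'
#' Associates each tracked trace with the nearest scripted filament (mean
#' centroid distance over common frames) and returns that filament's label,
#' for building labeled QC training sets from [crossing_scenario()] videos.
#'
#' @param traces A [trace_kinematics()] tibble.
#' @param truth A `truth_table` with a `label` column.
#' @return Character vector of labels, one per trace.
#' @export
label_traces_from_truth <- function(traces, truth) {
  vapply(seq_len(nrow(traces)), function(i) {
    fr <- traces$frames[[i]]
    best <- Inf; lab <- "clean"
    for (fid in unique(truth$filament_id)) {
      tt <- truth[truth$filament_id == fid, ]
      common <- intersect(fr, tt$frame)
      if (length(common) < 2) next
      ia <- match(common, fr); ib <- match(common, tt$frame)
      d <- mean(sqrt((traces$x_um[[i]][ia] - tt$x_um[ib])^2 +
                     (traces$y_um[[i]][ia] - tt$y_um[ib])^2))
      if (d < best) { best <- d; lab <- tt$label[1] }
    }
    lab
  }, character(1))
}
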