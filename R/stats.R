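#' Assemble the condition matrix for bootstrapped PCA
#'
#' Stacks, for every condition, the main length-resolved curves and all
#' bootstrap replicate curves into one matrix: one row per data set, columns
#' the four features concatenated over length windows. Windows missing in
#' any row are dropped globally; constant columns are dropped with a log
#' message; remaining columns are standardized to zero mean and unit
#' variance.
#'
#' @param curve_sets Named list of [bootstrap_curves()] results (one per
#'   condition, same window grid).
#' @return A list of class `condition_matrix`: `x` (standardized matrix),
#'   `condition` (row labels), `is_main` (logical), `feature`, `window`
#'   (column annotations).
#' @export
assemble_condition_matrix <- function(curve_sets) {
  stopifnot(length(curve_sets) >= 1, !is.null(names(curve_sets)))
  feats <- c("v_um_s", "f_mot", "stop_time_s", "run_time_s")
  grids <- lapply(curve_sets, function(cs) cs$windows$window_center_um)
  if (length(unique(lapply(grids, round, 6))) != 1)
    stop("curve sets use different window grids")
  rows <- list(); cond <- character(); main <- logical()
  for (nm in names(curve_sets)) {
    cs <- curve_sets[[nm]]
    if (is.null(cs$replicates)) stop("curve set '", nm, "' has no replicates")
    main_row <- unlist(lapply(feats, function(f) cs$curves[[f]]))
    boot <- do.call(cbind, lapply(feats, function(f) cs$replicates[[f]]))
    rows[[nm]] <- rbind(main_row, boot)
    cond <- c(cond, rep(nm, 1 + nrow(boot)))
    main <- c(main, TRUE, rep(FALSE, nrow(boot)))
  }
  x <- do.call(rbind, rows)
  n_win <- length(grids[[1]])
  feature <- rep(feats, each = n_win)
  window <- rep(grids[[1]], length(feats))
  ok <- colSums(is.na(x)) == 0
  x <- x[, ok, drop = FALSE]
  feature <- feature[ok]; window <- window[ok]
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant column(s) dropped")
    x <- x[, sds > 0, drop = FALSE]
    feature <- feature[sds > 0]; window <- window[sds > 0]
    sds <- sds[sds > 0]
  }
  x <- scale(x, center = TRUE, scale = sds)
  rownames(x) <- NULL
  structure(list(x = x, condition = cond, is_main = main,
                 feature = feature, window = window),
            class = "condition_matrix")
}

#' First three principal components of the condition matrix
#'
#' Thin singular-value PCA with a deterministic sign convention: within each
#' component, the largest-magnitude loading is positive.
#'
#' @param cm An [assemble_condition_matrix()] result.
#' @return An object of class `pc_embedding`: `scores` (rows x 3),
#'   `loadings`, `explained` (variance fractions for all components),
#'   `condition`, `is_main`.
#' @export
pca3 <- function(cm) {
  stopifnot(inherits(cm, "condition_matrix"))
  p <- prcomp(cm$x, center = FALSE, scale. = FALSE)
  if (length(p$sdev) < 3 || p$sdev[3] < 1e-12)
    stop("condition matrix has rank < 3")
  flip <- vapply(1:3, function(k) {
    l <- p$rotation[, k]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  scores <- sweep(p$x[, 1:3, drop = FALSE], 2, flip, `*`)
  loadings <- sweep(p$rotation[, 1:3, drop = FALSE], 2, flip, `*`)
  colnames(scores) <- colnames(loadings) <- paste0("PC", 1:3)
  structure(list(scores = scores, loadings = loadings,
                 explained = p$sdev^2 / sum(p$sdev^2),
                 condition = cm$condition, is_main = cm$is_main,
                 feature = cm$feature, window = cm$window),
            class = "pc_embedding")
}

#' @export
print.pc_embedding <- function(x, ...) {
  cat(sprintf("<pc_embedding> %d rows, PC1-3 explain %.1f%%\n",
              nrow(x$scores), 100 * sum(x$explained[1:3])))
  invisible(x)
}

#' @export
tidy.pc_embedding <- function(x, ...) {
  tibble::tibble(condition = x$condition, is_main = x$is_main,
                 PC1 = x$scores[, 1], PC2 = x$scores[, 2],
                 PC3 = x$scores[, 3])
}

#' @export
glance.pc_embedding <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores),
                 explained_pc1 = x$explained[1],
                 explained_pc2 = x$explained[2],
                 explained_pc3 = x$explained[3],
                 explained_pc123 = sum(x$explained[1:3]))
}

# 95% Mahalanobis confidence ellipsoid of a point cloud: centre, covariance,
# and the radius containing `conf` of the points
.cloud_ellipsoid <- function(pts, conf = 0.95) {
  mu <- colMeans(pts)
  S <- cov(pts)
  S <- S + diag(1e-12, ncol(pts))
  r2 <- quantile(mahalanobis(pts, mu, S), conf, names = FALSE)
  list(mu = mu, S = S, r2 = r2)
}

# do two ellipsoids (x-mu)' S^-1 (x-mu) <= r2 overlap?
.ellipsoids_overlap <- function(e1, e2) {
  A <- solve(e1$S) / e1$r2 # ellipsoid 1: (x-mu1)' A (x-mu1) <= 1
  B <- solve(e2$S) / e2$r2
  # inside each other's centre?
  if (mahalanobis(e2$mu, e1$mu, e1$S) <= e1$r2) return(TRUE)
  if (mahalanobis(e1$mu, e2$mu, e2$S) <= e2$r2) return(TRUE)
  # minimise Mahalanobis distance to mu2 over the boundary of ellipsoid 1:
  # x(t) = (A/t + B)^-1 (A mu1 / t + B mu2), t in (0, inf) traces the
  # Pareto path between the two centres; find t where x lies on ellipsoid 1
  g <- function(t) {
    x <- solve(A / t + B, A %*% e1$mu / t + B %*% e2$mu)
    drop(t(x - e1$mu) %*% A %*% (x - e1$mu)) - 1
  }
  lo <- 1e-8; hi <- 1e8
  if (g(lo) > 0 || g(hi) < 0) return(FALSE) # numeric fallback: disjoint
  t_star <- uniroot(g, c(lo, hi), tol = 1e-10)$root
  x <- solve(A / t_star + B, A %*% e1$mu / t_star + B %*% e2$mu)
  drop(t(x - e2$mu) %*% B %*% (x - e2$mu)) <= 1
}

#' Separation test between two conditions in PC space
#'
#' Two conditions are significantly separated when their 95% confidence
#' regions in the first three principal components do not overlap. The
#' confidence region of a condition is the Mahalanobis ellipsoid containing
#' 95% of its bootstrap scores.
#'
#' @param embedding A [pca3()] result.
#' @param cond_a,cond_b Condition names.
#' @param conf Confidence level.
#' @return `TRUE` (significant separation) or `FALSE`.
#' @export
separation_test <- function(embedding, cond_a, cond_b, conf = 0.95) {
  stopifnot(inherits(embedding, "pc_embedding"))
  if (identical(cond_a, cond_b)) return(FALSE)
  pa <- embedding$scores[embedding$condition == cond_a & !embedding$is_main, ,
                         drop = FALSE]
  pb <- embedding$scores[embedding$condition == cond_b & !embedding$is_main, ,
                         drop = FALSE]
  stopifnot(nrow(pa) >= 10, nrow(pb) >= 10)
  !.ellipsoids_overlap(.cloud_ellipsoid(pa, conf), .cloud_ellipsoid(pb, conf))
}

#' Pairwise separation matrix
#'
#' @param embedding A [pca3()] result.
#' @param conf Confidence level.
#' @return Logical matrix: `TRUE` where conditions separate significantly.
#' @export
pairwise_separation <- function(embedding, conf = 0.95) {
  conds <- unique(embedding$condition)
  m <- matrix(FALSE, length(conds), length(conds),
              dimnames = list(conds, conds))
  for (i in seq_along(conds)) {
    for (j in seq_along(conds)) {
      if (j > i) m[i, j] <- m[j, i] <-
          separation_test(embedding, conds[i], conds[j], conf)
    }
  }
  m
}

#' Agglomerative clustering of PC scores
#'
#' Ward-linkage hierarchical clustering of all bootstrap scores in PC1-3.
#' The number of clusters is chosen at the largest relative drop of the
#' merge linkage: `k` such that the height of the merge reducing `k` to
#' `k - 1` clusters is large compared with the merge reducing `k + 1` to
#' `k`.
#'
#' @param embedding A [pca3()] result.
#' @param max_k Largest cluster count considered.
#' @return List of class `cluster_profile`: `k` (selected), `heights` (last
#'   `max_k` merge heights), `assignment` (cluster per row), `composition`
#'   (condition x cluster table), `hclust` (the tree), `degenerate` flag.
#' @export
hcluster_embedding <- function(embedding, max_k = 8) {
  stopifnot(inherits(embedding, "pc_embedding"))
  pts <- embedding$scores
  stopifnot(nrow(pts) >= max_k)
  if (all(apply(pts, 2, function(c) diff(range(c))) < 1e-12)) {
    return(structure(list(k = 1L, heights = numeric(), degenerate = TRUE,
                          assignment = rep(1L, nrow(pts)),
                          composition = table(embedding$condition,
                                              rep(1L, nrow(pts)))),
                     class = "cluster_profile"))
  }
  hc <- hclust(dist(pts), method = "ward.D2")
  h <- rev(hc$height) # h[k] = height of the merge reducing k+1 to k clusters
  # linkage cost of going below k clusters is h[k-1]; pick the k where that
  # cost is largest relative to the cost of the merge just above (the
  # "large reduction of linkage" elbow)
  drops <- h[seq_len(max_k - 1)] / h[seq_len(max_k - 1) + 1]
  k <- which.max(drops) + 1L
  assignment <- cutree(hc, k)
  structure(list(k = k, heights = h[seq_len(max_k)], degenerate = FALSE,
                 assignment = assignment,
                 composition = table(embedding$condition, assignment),
                 hclust = hc),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("<cluster_profile> selected k = %d\n", x$k))
  if (!x$degenerate) print(x$composition)
  invisible(x)
}

# mean over windows of one feature curve (vector) or of replicate rows
.window_mean <- function(v) mean(v, na.rm = TRUE)

#' Fold change of a motility feature between two conditions
#'
#' The feature is averaged over the length-window grid; the fold change is
#' the target average divided by the baseline average. Each condition gets
#' its own percentile confidence interval of the window-averaged feature
#' from its bootstrap replicates; the fold-change interval is the ratio of
#' interval limits, so the fold interval excludes 1 exactly when the two
#' conditions' confidence intervals do not overlap — the non-overlap
#' significance rule. `margin` is the normalized non-overlap margin
#' (positive = significant).
#'
#' @param target,baseline [bootstrap_curves()] results on the same grid.
#' @param feature One of `"v_um_s"`, `"f_mot"`, `"stop_time_s"`,
#'   `"run_time_s"`.
#' @param conf Confidence level.
#' @return A one-row tibble of class `fold_change`: `feature`, `fold`,
#'   `lower`, `upper`, `significant`, `margin`. The per-replicate fold
#'   ratios are attached as attribute `replicate_folds`.
#' @export
fold_changes <- function(target, baseline,
                         feature = c("v_um_s", "f_mot", "stop_time_s",
                                     "run_time_s"),
                         conf = 0.95) {
  feature <- match.arg(feature)
  base_mean <- .window_mean(baseline$curves[[feature]])
  if (!is.finite(base_mean) || base_mean == 0)
    stop("baseline mean is zero or undefined")
  point <- .window_mean(target$curves[[feature]]) / base_mean
  if (is.null(target$replicates) || is.null(baseline$replicates))
    stop("fold_changes needs bootstrap replicates on both sides")
  tb <- apply(target$replicates[[feature]], 1, .window_mean)
  bb <- apply(baseline$replicates[[feature]], 1, .window_mean)
  alpha <- (1 - conf) / 2
  ci_t <- quantile(tb, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  ci_b <- quantile(bb, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  ci <- c(ci_t[1] / ci_b[2], ci_t[2] / ci_b[1])
  margin <- max(ci[1] - 1, 1 - ci[2])
  B <- min(length(tb), length(bb))
  out <- tibble::tibble(feature = feature, fold = point, lower = ci[1],
                        upper = ci[2], significant = margin > 0,
                        margin = margin)
  attr(out, "replicate_folds") <- tb[seq_len(B)] / bb[seq_len(B)]
  class(out) <- c("fold_change", class(out))
  out
}

#' Joint two-feature significance test
#'
#' Some regulation shifts two features together without either marginal fold
#' change reaching significance. Both conditions' bootstrap replicates are
#' placed in the plane of the two features' length-averaged fold changes
#' (relative to the baseline main estimate), projected onto the unit vector
#' connecting the two condition means, and the shift is significant when the
#' 95% percentile intervals of the projections do not overlap.
#'
#' @param target,baseline [bootstrap_curves()] results on the same grid.
#' @param features Two feature names.
#' @param conf Confidence level.
#' @return List: `significant`, `gap` (positive when the projection
#'   intervals are disjoint), and the projected samples.
#' @export
joint_fold_test <- function(target, baseline,
                            features = c("v_um_s", "f_mot"), conf = 0.95) {
  stopifnot(length(features) == 2)
  ref <- vapply(features, function(f) .window_mean(baseline$curves[[f]]), 0)
  if (any(ref == 0)) stop("baseline mean is zero")
  pts <- function(cs) cbind(
    apply(cs$replicates[[features[1]]], 1, .window_mean) / ref[1],
    apply(cs$replicates[[features[2]]], 1, .window_mean) / ref[2])
  pa <- pts(target); pb <- pts(baseline)
  # whiten per axis so both features contribute on comparable scales
  sds <- sqrt((apply(pa, 2, var) + apply(pb, 2, var)) / 2)
  sds[sds == 0] <- 1
  pa <- sweep(pa, 2, sds, `/`); pb <- sweep(pb, 2, sds, `/`)
  dir <- colMeans(pa) - colMeans(pb)
  nrm <- sqrt(sum(dir^2))
  if (nrm < 1e-12)
    return(list(significant = FALSE, gap = -Inf,
                proj_target = numeric(), proj_baseline = numeric()))
  u <- dir / nrm
  qa <- pa %*% u; qb <- pb %*% u
  alpha <- (1 - conf) / 2
  ia <- quantile(qa, c(alpha, 1 - alpha), names = FALSE)
  ib <- quantile(qb, c(alpha, 1 - alpha), names = FALSE)
  gap <- max(ia[1] - ib[2], ib[1] - ia[2])
  list(significant = gap > 0, gap = gap, proj_target = drop(qa),
       proj_baseline = drop(qb))
}

#' Type-I error self-check by comparing resamples of the baseline
#'
#' Repeatedly draws two random resamples (with replacement) of the baseline
#' records as pseudo-conditions, runs the fold-change analysis on each of
#' the four features, and records the non-overlap margin (positive margin =
#' a spurious significant detection). With a well-powered baseline the
#' margins sit several distribution widths below zero for all features.
#'
#' @param records Baseline [as_motility_records()].
#' @param n_comparisons Number of comparison rounds.
#' @param B Bootstrap replicates per side and round.
#' @param range,width,n_windows Window grid.
#' @param conf Confidence level.
#' @return Tibble: `round`, `feature`, `margin`, `significant`.
#' @export
type_i_assessment <- function(records, n_comparisons = 300, B = 200,
                              range = c(0.3, 3.25), width = 0.59,
                              n_windows = 50, conf = 0.95) {
  stopifnot(nrow(records) >= 4)
  feats <- c("v_um_s", "f_mot", "stop_time_s", "run_time_s")
  n <- nrow(records)
  purrr::map_dfr(seq_len(n_comparisons), function(r) {
    a <- bootstrap_curves(records[sample.int(n, n, replace = TRUE), ],
                          B = B, range = range, width = width,
                          n_windows = n_windows)
    b <- bootstrap_curves(records[sample.int(n, n, replace = TRUE), ],
                          B = B, range = range, width = width,
                          n_windows = n_windows)
    purrr::map_dfr(feats, function(f) {
      fc <- fold_changes(a, b, feature = f, conf = conf)
      tibble::tibble(round = r, feature = f, margin = fc$margin,
                     significant = fc$significant)
    })
  })
}
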