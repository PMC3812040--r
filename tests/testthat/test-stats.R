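make_curve_sets <- function(conds, n = 120, B = 60, v_shift = 0) {
  out <- list()
  for (i in seq_along(conds)) {
    shift <- if (i == length(conds)) v_shift else 0
    recs <- make_records(n, v_fun = function(L) rep(0.6 + shift, length(L)))
    out[[conds[i]]] <- bootstrap_curves(recs, B = B)
  }
  out
}

test_that("condition matrix stacks, standardizes and annotates rows", {
  set.seed(81)
  cs <- make_curve_sets(c("a", "b"), n = 100, B = 40)
  cm <- assemble_condition_matrix(cs)
  expect_equal(nrow(cm$x), 2 * 41)
  expect_equal(sum(cm$is_main), 2)
  expect_true(all(abs(colMeans(cm$x)) < 1e-9))
  expect_true(all(abs(apply(cm$x, 2, sd) - 1) < 1e-9))
  expect_false(any(is.na(cm$x)))
})

test_that("PCA embeds with deterministic signs and honest variance", {
  set.seed(82)
  cs <- make_curve_sets(c("a", "b", "c"), n = 100, B = 50)
  emb <- pca3(assemble_condition_matrix(cs))
  expect_true(all(diff(emb$explained) < 1e-9))
  expect_equal(sum(emb$explained), 1, tolerance = 1e-9)
  # largest-magnitude loading positive in every component
  for (k in 1:3)
    expect_gt(emb$loadings[which.max(abs(emb$loadings[, k])), k], 0)
  # near-1-D data: PC1 dominates
  x <- matrix(rnorm(300), 300, 1) %*% t(c(1, 2, 3, 4)) +
    matrix(rnorm(1200, 0, 0.01), 300, 4)
  cm <- structure(list(x = scale(x, scale = FALSE), condition = rep("a", 300),
                       is_main = rep(FALSE, 300),
                       feature = rep("v_um_s", 4), window = 1:4),
                  class = "condition_matrix")
  expect_gt(pca3(cm)$explained[1], 0.99)
  # explained variances invariant under an orthogonal rotation
  q <- qr.Q(qr(matrix(rnorm(16), 4)))
  cm_rot <- cm; cm_rot$x <- scale(x %*% q, scale = FALSE)
  expect_equal(pca3(cm)$explained, pca3(cm_rot)$explained, tolerance = 1e-6)
})

test_that("separation test distinguishes real shifts from noise", {
  # embed three identical baseline conditions together with clearly
  # regulated ones, as in the full condition panel: the baselines must
  # overlap while strong effects separate
  set.seed(83)
  mkcs <- function(v = 0.6, fm = 0.8, mr = 1)
    bootstrap_curves(make_records(120, v_fun = function(L) rep(v, length(L)),
                                  f_mot = fm, mean_run = mr), B = 60)
  null_hits <- 0; effect_hits <- 0
  rounds <- 4
  for (r in seq_len(rounds)) {
    cs <- list(a = mkcs(), b = mkcs(), c = mkcs(),
               d = mkcs(v = 0.75), f = mkcs(mr = 2.5))
    emb <- pca3(assemble_condition_matrix(cs))
    m <- pairwise_separation(emb)
    null_hits <- null_hits + m["a", "b"] + m["a", "c"] + m["b", "c"]
    effect_hits <- effect_hits + m["a", "d"] + m["a", "f"]
    if (r == 1) expect_false(separation_test(emb, "a", "a"))
  }
  expect_lte(null_hits, 2)             # ~95% of null pairs overlap
  expect_equal(effect_hits, 2 * rounds) # strong shifts always separate
})

test_that("main-dataset scores sit inside their bootstrap cloud", {
  set.seed(84)
  cs <- make_curve_sets(c("a", "b"), n = 120, B = 80)
  emb <- pca3(assemble_condition_matrix(cs))
  for (cond in c("a", "b")) {
    boot <- emb$scores[emb$condition == cond & !emb$is_main, ]
    main <- emb$scores[emb$condition == cond & emb$is_main, ]
    e <- motilitykit:::.cloud_ellipsoid(boot)
    expect_lte(stats::mahalanobis(main, e$mu, e$S), e$r2)
  }
})

test_that("cluster count lands on the linkage elbow", {
  set.seed(85)
  centers <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0), c(0, 0, 8))
  pts <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(150, 0, 0.4), 50, 3), 2, centers[i, ], `+`)))
  emb <- structure(list(scores = pts,
                        condition = rep(paste0("c", 1:4), each = 50),
                        is_main = rep(FALSE, 200)),
                   class = "pc_embedding")
  prof <- hcluster_embedding(emb)
  expect_equal(prof$k, 4L)
  # composition pure: every condition maps to a single cluster
  expect_true(all(apply(prof$composition, 1, function(r) sum(r > 0)) == 1))
  # invariant to row order
  ord <- sample(200)
  emb2 <- emb; emb2$scores <- pts[ord, ]; emb2$condition <- emb$condition[ord]
  prof2 <- hcluster_embedding(emb2)
  expect_equal(prof2$k, 4L)
  # degenerate identical points
  emb3 <- emb; emb3$scores <- matrix(1, 40, 3)
  emb3$condition <- rep("a", 40); emb3$is_main <- rep(FALSE, 40)
  prof3 <- hcluster_embedding(emb3, max_k = 5)
  expect_equal(prof3$k, 1L)
  expect_true(prof3$degenerate)
})

test_that("fold changes are calibrated, scale-equivariant and honest", {
  set.seed(86)
  recs <- make_records(150, v_fun = function(L) rep(0.6, length(L)))
  a <- bootstrap_curves(recs, B = 80)
  fc <- fold_changes(a, a, "v_um_s")
  expect_equal(fc$fold, 1)
  expect_false(fc$significant) # a condition cannot differ from itself
  # multiplying all velocities by a constant leaves the fold unchanged
  recs_b <- make_records(150, v_fun = function(L) rep(0.5, length(L)))
  scale_v <- function(r, s) as_motility_records(
    dplyr::mutate(r, v_f2f_um_s = s * v_f2f_um_s))
  pair_fold <- function(rt, rb) {
    set.seed(101); ct <- bootstrap_curves(rt, B = 60)
    set.seed(102); cb <- bootstrap_curves(rb, B = 60)
    fold_changes(ct, cb, "v_um_s")
  }
  f1 <- pair_fold(recs, recs_b)
  f2 <- pair_fold(scale_v(recs, 2), scale_v(recs_b, 2))
  expect_equal(f2$fold, f1$fold)
  expect_equal(f2$lower, f1$lower)

  # a known 12% velocity inflation is recovered with a covering interval
  set.seed(87)
  base <- make_records(400, v_fun = function(L) 0.5 + 0.05 * L)
  up <- as_motility_records(
    dplyr::mutate(base, filament_id = filament_id + 1000,
                  v_f2f_um_s = 1.12 * v_f2f_um_s))
  fc2 <- fold_changes(bootstrap_curves(up, B = 150),
                      bootstrap_curves(base, B = 150), "v_um_s")
  expect_gte(1.12, fc2$lower)
  expect_lte(1.12, fc2$upper)
  expect_equal(fc2$fold, 1.12, tolerance = 0.02)
})

test_that("the joint two-feature test sees aligned sub-threshold shifts", {
  # build replicate clouds directly: each feature shifted by 3.2 bootstrap
  # standard deviations (below the ~3.9 sd needed for marginal interval
  # non-overlap), but aligned, so the projected shift is ~4.5 sd
  set.seed(88)
  B <- 400; W <- 5
  mk_cs <- function(mu_v, mu_r) {
    reps <- list(
      v_um_s = matrix(rnorm(B, mu_v, 0.01), B, W),
      f_mot = matrix(0.8, B, W),
      stop_time_s = matrix(0.5, B, W),
      run_time_s = matrix(rnorm(B, mu_r, 0.05), B, W))
    curves <- tibble::tibble(window_center_um = seq_len(W),
                             v_um_s = mu_v, f_mot = 0.8, stop_time_s = 0.5,
                             run_time_s = mu_r,
                             n_filaments = 100L)
    structure(list(windows = tibble::tibble(window_center_um = seq_len(W)),
                   curves = curves, replicates = reps, B = B, ci = NULL,
                   condition = "x"),
              class = "length_curve_set")
  }
  base <- mk_cs(0.6, 1.0)
  shift <- mk_cs(0.6 + 3.2 * 0.01, 1.0 + 3.2 * 0.05)
  marg_v <- fold_changes(shift, base, "v_um_s")
  marg_r <- fold_changes(shift, base, "run_time_s")
  jt <- joint_fold_test(shift, base, c("v_um_s", "run_time_s"))
  expect_false(marg_v$significant)
  expect_false(marg_r$significant)
  expect_true(jt$significant)
  # identical conditions: never significant
  expect_false(joint_fold_test(base, base,
                               c("v_um_s", "run_time_s"))$significant)
  # orthogonal noise inflation without a mean shift: not significant
  noisy <- mk_cs(0.6, 1.0)
  noisy$replicates$v_um_s <- matrix(rnorm(B, 0.6, 0.04), B, W)
  expect_false(joint_fold_test(noisy, base,
                               c("v_um_s", "run_time_s"))$significant)
})

test_that("comparing baseline resamples rarely reaches significance", {
  set.seed(89)
  recs <- make_records(250)
  t1 <- type_i_assessment(recs, n_comparisons = 12, B = 60)
  expect_equal(nrow(t1), 12 * 4)
  # the interval-non-overlap rule is conservative: at most an occasional
  # marginal detection, and margins centred well below zero
  expect_lte(sum(t1$significant), 2)
  by_feat <- split(t1$margin, t1$feature)
  for (m in by_feat) expect_lt(median(m), 0)
  # reproducible single round
  set.seed(7); r1 <- type_i_assessment(recs, n_comparisons = 1, B = 30)
  set.seed(7); r2 <- type_i_assessment(recs, n_comparisons = 1, B = 30)
  expect_identical(r1, r2)
})
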