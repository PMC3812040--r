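test_that("frame merging reduces count and preserves constant stacks", {
  st <- array(rep(0.5, 8 * 8 * 30), dim = c(8, 8, 30))
  m <- preprocess_stack(st, native_dt = 1 / 30, target_dt = 1 / 3,
                        enhance = FALSE)
  expect_equal(dim(m)[3], 3)
  expect_equal(m[, , 1], st[, , 1])
  expect_error(preprocess_stack(st, native_dt = 1 / 30, target_dt = 0.15),
               "integer multiple")
})

test_that("binarization respects trivial thresholds", {
  set.seed(14)
  fr <- matrix(abs(rnorm(10000, 0, 0.01)), 100, 100)
  fr[40:48, 40:48] <- 1 # bright object on a dim background
  # a threshold at the top of the range keeps only the object core
  hi <- binarize_frame(fr, 0.999)
  expect_true(all(which(hi) %in% which(fr == 1)))
  # a threshold at the bottom keeps essentially everything
  expect_gt(mean(binarize_frame(fr, 1e-9)), 0.99)
  # raising the threshold never grows the mask
  masks <- lapply(c(0.2, 0.4, 0.6, 0.8), function(t) binarize_frame(fr, t))
  areas <- vapply(masks, sum, 0)
  expect_true(all(diff(areas) <= 0))
  # a single hot pixel does not shift the threshold reference
  fr2 <- fr; fr2[10, 10] <- 3
  expect_equal(sum(binarize_frame(fr2, 0.5) & fr == 1),
               sum(binarize_frame(fr, 0.5) & fr == 1))
})

test_that("rectangle-equivalent transformation solves the quadratic", {
  expect_equal(rect_equivalent(2, 6)$length, 2)
  expect_equal(rect_equivalent(2, 6)$width, 1)
  sq <- rect_equivalent(4, 8)
  expect_equal(sq$length, 2)
  expect_equal(sq$width, 2)
  expect_false(sq$complex_flag)
  cx <- rect_equivalent(2, 5)
  expect_true(cx$complex_flag)
  expect_equal(cx$length, 1.25)
  expect_equal(cx$width, 1.25)
  # real solutions reproduce area and perimeter exactly
  A <- c(1.3, 2.6, 5); P <- c(5, 8, 11)
  re <- rect_equivalent(A, P)
  expect_equal(re$length * re$width, A)
  expect_equal(2 * (re$length + re$width), P)
  expect_true(all(re$length >= re$width))
  expect_error(rect_equivalent(-1, 3))
})

test_that("crack-boundary perimeter matches rectangles and diagonals", {
  cp <- motilitykit:::.crack_perimeter
  expect_equal(cp(matrix(TRUE, 1, 1)), 4)
  expect_equal(cp(matrix(TRUE, 1, 3)), 8)
  expect_equal(cp(matrix(TRUE, 3, 19)), 44)
  # diagonal pair: two sqrt(2) steps plus closure
  m <- diag(2) == 1
  expect_equal(cp(m), 2 * sqrt(2) + 4)
})

test_that("objects are extracted with physical units and centroids", {
  mask <- matrix(FALSE, 20, 20)
  mask[5:6, 3:12] <- TRUE # 10 x 2 px rectangle
  o <- extract_objects(mask, pixel_size = 0.16)
  expect_equal(nrow(o), 1)
  expect_equal(o$area_um2, 20 * 0.16^2)
  expect_equal(o$perimeter_um, 24 * 0.16)
  expect_equal(o$length_um, 10 * 0.16)
  expect_equal(o$width_um, 2 * 0.16)
  expect_equal(o$x_um, mean(2:11) * 0.16) # 0-based pixel centres
  expect_equal(nrow(extract_objects(matrix(FALSE, 5, 5))), 0)
  # min_area filter
  mask2 <- mask; mask2[15, 15] <- TRUE
  expect_equal(nrow(extract_objects(mask2, min_area_px = 5)), 1)
  expect_equal(nrow(extract_objects(mask2, min_area_px = 1)), 2)
})

test_that("tracking follows filaments and starts/ends traces correctly", {
  mk <- function(frame, x, y, id = 1, a = 0.5) tibble::tibble(
    frame = frame, object_id = id, x_um = x, y_um = y, area_um2 = a,
    perimeter_um = 3, length_um = 1, width_um = 0.3, complex_flag = FALSE,
    theta = 0, area_px = 20L)
  # one moving object: a single trace
  objs <- dplyr::bind_rows(lapply(0:5, function(f) mk(f, 1 + 0.3 * f, 2)))
  tr <- track_objects(objs)
  expect_equal(length(unique(tr$trace_id)), 1)
  # two well-separated objects: two traces, no identity swap
  objs2 <- dplyr::bind_rows(lapply(0:5, function(f) dplyr::bind_rows(
    mk(f, 1 + 0.3 * f, 2, id = 1), mk(f, 20 - 0.3 * f, 30, id = 2))))
  tr2 <- track_objects(objs2)
  expect_equal(length(unique(tr2$trace_id)), 2)
  by_trace <- split(tr2, tr2$trace_id)
  expect_true(all(vapply(by_trace, function(d)
    max(abs(diff(d$y_um))) < 1e-9, TRUE)))
  # an object that disappears ends its trace
  objs3 <- dplyr::bind_rows(lapply(0:2, function(f) mk(f, 1 + 0.3 * f, 2)))
  objs4 <- dplyr::bind_rows(objs3, mk(5, 10, 10))
  tr3 <- track_objects(objs4)
  expect_equal(length(unique(tr3$trace_id)), 2)
})

test_that("kinematics recover scripted velocities from mock videos", {
  rv <- render_one(L = 1.5, v = 1, heading = 0.3, duration = 4,
                   x0 = 6, y0 = 20)
  res <- analyze_video(rv$stack, native_dt = 1 / 6, bw_threshold = 0.5,
                       pixel_size = 0.08)
  expect_equal(nrow(res$traces), 1)
  v <- res$traces$v_f2f[[1]]
  expect_equal(mean(v), 1, tolerance = 0.05)
  expect_equal(res$traces$v_trace_um_s, 1, tolerance = 0.06)
  expect_equal(res$traces$L_um, 1.5, tolerance = 0.1)

  # zero-noise stationary filament: all frame-to-frame velocities 0
  rv0 <- render_one(L = 1.5, v = 0, duration = 2, x0 = 10, y0 = 10)
  res0 <- analyze_video(rv0$stack, native_dt = 1 / 6, bw_threshold = 0.5,
                        pixel_size = 0.08)
  expect_true(all(res0$traces$v_f2f[[1]] < 1e-9))
})

test_that("merged crossing frames yield a single object", {
  tt <- crossing_scenario(1, seed = 2, duration = 4, frame_rate = 6)
  cross <- tt[tt$label == "crossing", ]
  attr(cross, "fov") <- attr(tt, "fov")
  frame_overlap <- unique(cross$frame[cross$overlap])
  expect_gt(length(frame_overlap), 0)
  op <- optics_spec(pixel_size = 0.16, frame_rate = 6, background_sd = 0)
  rv <- render_video(cross, op)
  fr <- rv$stack[, , frame_overlap[1] + 1]
  fr <- fr - median(fr); fr <- fr / max(fr)
  o <- extract_objects(binarize_frame(fr, 0.3), fr, pixel_size = 0.16)
  expect_equal(nrow(o), 1) # the two filaments merge into one component
})
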