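#' Plot length-resolved motility feature curves
#'
#' Four panels (sliding velocity, motile fraction, stop time, run time)
#' against filament length, with percentile confidence bands when bootstrap
#' replicates are present.
#'
#' @param object A `length_curve_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.length_curve_set <- function(object, ...) {
  labs <- c(v_um_s = "velocity (um/s)", f_mot = "motile fraction",
            stop_time_s = "stop time (s)", run_time_s = "run time (s)")
  if (!is.null(object$ci)) {
    df <- object$ci
  } else {
    df <- tidyr::pivot_longer(object$curves,
                              cols = dplyr::all_of(names(labs)),
                              names_to = "feature", values_to = "estimate")
    df$lower <- df$upper <- NA_real_
  }
  df$feature <- factor(labs[df$feature], levels = labs)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$window_center_um,
                                        y = .data$estimate)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "filament length (um)", y = NULL)
  if (!all(is.na(df$lower)))
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                               ymax = .data$upper),
                                  alpha = 0.3)
  p
}

#' Plot a PC embedding with per-condition bootstrap clouds
#'
#' @param object A `pc_embedding`.
#' @param dims Which two components to draw.
#' @param ... Unused.
#' @return A ggplot object with hollow bootstrap points, solid main-dataset
#'   points, and convex hulls per condition.
#' @export
autoplot.pc_embedding <- function(object, dims = c(1, 2), ...) {
  df <- tidy(object)
  dn <- paste0("PC", dims)
  hulls <- dplyr::group_modify(
    dplyr::group_by(df[!df$is_main, ], .data$condition),
    function(d, ...) d[grDevices::chull(d[[dn[1]]], d[[dn[2]]]), ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[dn[1]]], y = .data[[dn[2]]],
                                   colour = .data$condition)) +
    ggplot2::geom_point(data = df[!df$is_main, ], shape = 1, alpha = 0.5) +
    ggplot2::geom_polygon(data = hulls, fill = NA) +
    ggplot2::geom_point(data = df[df$is_main, ], colour = "black", size = 3) +
    ggplot2::labs(x = sprintf("%s (%.0f%%)", dn[1],
                              100 * object$explained[dims[1]]),
                  y = sprintf("%s (%.0f%%)", dn[2],
                              100 * object$explained[dims[2]]))
}

#' Plot the linkage profile of a cluster analysis
#'
#' Merge linkage against cluster count; the selected cluster number sits
#' just before the large linkage drop.
#'
#' @param profile A [hcluster_embedding()] result.
#' @return A ggplot object.
#' @export
plot_linkage <- function(profile) {
  df <- tibble::tibble(k = seq_along(profile$heights),
                       height = profile$heights)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$height)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = profile$k, linetype = 2) +
    ggplot2::labs(x = "cluster count", y = "linkage height")
}

#' Plot fold changes with confidence intervals
#'
#' @param folds A tibble of [fold_changes()] rows (optionally with a
#'   `condition` column).
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(folds) {
  if (!"condition" %in% names(folds)) folds$condition <- "condition"
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$feature, y = .data$fold,
                                      fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "fold change vs baseline")
}

#' Plot the out-of-bag error curve of a QC model
#'
#' @param model A [qc_train()] model.
#' @return A ggplot object.
#' @export
plot_oob_curve <- function(model) {
  df <- tibble::tibble(trees = seq_along(model$oob_error),
                       oob = model$oob_error)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trees, y = .data$oob)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of trees", y = "out-of-bag error")
}

#' @export
tidy.qc_model <- function(x, ...) {
  tibble::tibble(trees = seq_along(x$oob_error), oob_error = x$oob_error)
}

#' @export
glance.qc_model <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees,
                 oob_error = utils::tail(x$oob_error, 1), seed = x$seed)
}

#' @export
tidy.fold_change <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
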