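#' Plot training history
#'
#' Train and validation loss per epoch on a log-scaled y axis, with the
#' learning-rate schedule as a secondary panel caption.
#'
#' @param object a trained `oar_unet`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.oar_unet <- function(object, ...) {
  h <- object$history
  if (is.null(h)) stop("model has no training history")
  df <- rbind(
    data.frame(epoch = h$epoch, loss = h$train_loss, partition = "train"),
    data.frame(epoch = h$epoch, loss = h$val_loss, partition = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = paste("U-Net training", object$organ %||% ""),
                  x = "epoch", y = "combined Dice + BCE loss") +
    ggplot2::theme_minimal()
}

#' Box plots of cohort evaluation metrics
#'
#' One panel per metric (DSC, MSD, HD95), methods side by side per organ,
#' mirroring the standard presentation of contour-comparison studies.
#'
#' @param evaluation result of [evaluate_cohort()].
#' @return a ggplot.
#' @export
plot_eval_metrics <- function(evaluation) {
  rec <- evaluation$records
  long <- rbind(
    data.frame(organ = rec$organ, method = rec$method, metric = "DSC",
               value = rec$dsc),
    data.frame(organ = rec$organ, method = rec$method, metric = "MSD (mm)",
               value = rec$msd),
    data.frame(organ = rec$organ, method = rec$method, metric = "HD95 (mm)",
               value = rec$hd95))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$organ, y = .data$value,
                                     fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mid-slice overlay of a mask on a CT volume
#'
#' Quick visual QA: the windowed CT slice with the mask contour region
#' highlighted.
#'
#' @param volume a [ct_volume].
#' @param mask binary array on the volume grid.
#' @param slice slice index (default: densest mask slice).
#' @param window a [window_preset()].
#' @return a ggplot.
#' @export
plot_slice_overlay <- function(volume, mask, slice = NULL,
                               window = window_preset("tissue")) {
  if (is.null(slice)) {
    counts <- apply(mask, 3, sum)
    slice <- if (any(counts > 0)) which.max(counts) else dim(mask)[3] %/% 2L
  }
  img <- window_normalize(volume$voxels[, , slice], window)
  d <- dim(img)
  df <- data.frame(row = rep(seq_len(d[1]), d[2]),
                   col = rep(seq_len(d[2]), each = d[1]),
                   hu = as.vector(img),
                   mask = as.vector(mask[, , slice]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$hu)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_point(data = df[df$mask, ], color = "red", size = 0.1,
                        alpha = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
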