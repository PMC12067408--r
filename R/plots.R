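#' Bullseye plot of a 28-segment table
#'
#' Polar display with basal rings outermost: LV rings hold 6/6/4 sectors
#' plus the apex disc; the RV (if present in the table) is drawn as a
#' separate facet with 4/4/2 sectors plus apex.
#'
#' @param tab Output of [bullseye_table()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_bullseye <- function(tab, title = NULL) {
  ring_of <- c(basal = 3, mid = 2, apical = 1, apex = 0)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    lev <- tab$level[i]
    vent <- tab$ventricle[i]
    n_sect <- if (lev == "apex") 1
              else if (lev == "apical") { if (vent == "LV") 4 else 2 }
              else { if (vent == "LV") 6 else 4 }
    lay <- segment_layout(vent)
    within_lev <- lay$segment[lay$level == lev]
    pos <- match(tab$segment[i], within_lev) - 1
    width <- 360 / n_sect
    r <- ring_of[[lev]]
    tibble::tibble(ventricle = vent, segment = tab$segment[i],
                   value = tab$value[i],
                   start = pos * width, end = (pos + 1) * width,
                   r0 = r, r1 = r + 1)
  })
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = .data$r0, ymax = .data$r1,
                                    fill = .data$value),
                       colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = (.data$r0 + .data$r1) / 2,
                                    label = .data$segment), size = 3) +
    ggplot2::coord_polar(theta = "x", start = 0) +
    ggplot2::facet_wrap(~ventricle) +
    ggplot2::scale_fill_viridis_c(name = attr(tab, "component")) +
    ggplot2::theme_void() +
    ggplot2::labs(title = title)
}

#' Bland-Altman plot
#'
#' Mean-difference plot with the bias as a continuous line and the 1.96 SD
#' limits of agreement as dashed lines.
#'
#' @param auto,manual Paired measurements.
#' @param label Quantity name for the axes.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(auto, manual, label = "value") {
  ag <- agreement(auto, manual)
  df <- tibble::tibble(mean = (auto + manual) / 2, diff = auto - manual)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ag$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(ag$loa_lower, ag$loa_upper),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = sprintf("mean of methods (%s)", label),
                  y = sprintf("auto - manual (%s)", label)) +
    ggplot2::theme_minimal()
}

#' Training loss curves
#'
#' @param model A trained `segnet` (with `loss_history`).
#' @return A ggplot object.
#' @export
plot_loss_history <- function(model) {
  h <- model$loss_history
  stopifnot(!is.null(h))
  df <- tibble::tibble(epoch = rep(h$epoch, 2),
                       loss = c(h$train, h$val),
                       set = rep(c("train", "validation"), each = nrow(h)))
  df <- df[is.finite(df$loss), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = "cross-entropy loss")
}

#' Mid-ventricular slice view of an image and/or label map
#'
#' Quick QC visualization: grey image with label contours.
#'
#' @param img An [image_volume()] (or `NULL`).
#' @param lab A [label_volume()] (or `NULL`).
#' @param slice Slice index; defaults to the middle slice.
#' @return A ggplot object.
#' @export
plot_slice <- function(img = NULL, lab = NULL, slice = NULL) {
  ref <- if (!is.null(img)) img else lab
  stopifnot(!is.null(ref))
  if (is.null(slice)) slice <- ceiling(dim(ref$values)[3] / 2)
  p <- ggplot2::ggplot()
  if (!is.null(img)) {
    d <- dim(img$values)
    di <- tibble::tibble(
      x = rep(seq_len(d[1]), times = d[2]),
      y = rep(seq_len(d[2]), each = d[1]),
      value = as.vector(img$values[, , slice]))
    p <- p + ggplot2::geom_raster(data = di,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none")
  }
  if (!is.null(lab)) {
    d <- dim(lab$values)
    dl <- tibble::tibble(
      x = rep(seq_len(d[1]), times = d[2]),
      y = rep(seq_len(d[2]), each = d[1]),
      label = factor(as.vector(lab$values[, , slice])))
    dl <- dl[dl$label != "0", ]
    p <- p + ggplot2::geom_point(data = dl,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$label),
      size = 0.1, alpha = 0.6)
  }
  p + ggplot2::coord_fixed() + ggplot2::theme_void()
}
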