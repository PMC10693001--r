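# ggplot2 views of the main result types.

#' Plot a folded allele-frequency spectrum
#'
#' @param afs Tibble from [folded_afs()].
#' @return A ggplot object (per-category proportion by minor-allele count).
#' @export
plot_afs <- function(afs) {
  afs |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(prop = .data$count / sum(.data$count)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$bin, y = .data$prop,
                                 fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "minor allele copies", y = "proportion of loci",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot SV density along the genome
#'
#' @param density Tibble from [window_density()].
#' @return A ggplot object.
#' @export
plot_window_density <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(x = .data$start / 1e6,
                                        y = .data$sv_count)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "SVs per window") +
    ggplot2::theme_minimal()
}

#' Plot LD decay by stratum
#'
#' @param ld Tibble from [ld_profile()].
#' @return A ggplot object.
#' @export
plot_ld_profile <- function(ld) {
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$bin_mid, y = .data$mean_r2,
                                   colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pairwise distance (bp)", y = expression(mean ~ r^2),
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of the population branch statistic
#'
#' @param pbs_tbl Tibble from [pbs()].
#' @param group Focal group to plot (default: first `pbs_` column).
#' @param quantile Dotted outlier threshold.
#' @return A ggplot object.
#' @export
plot_pbs <- function(pbs_tbl, group = NULL, quantile = 0.95) {
  cols <- grep("^pbs_", names(pbs_tbl), value = TRUE)
  col <- if (is.null(group)) cols[1] else paste0("pbs_", group)
  thr <- stats::quantile(pbs_tbl[[col]], quantile, names = FALSE)
  ggplot2::ggplot(pbs_tbl, ggplot2::aes(x = .data$start / 1e6,
                                        y = .data[[col]])) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dotted") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = sub("pbs_", "PBS ", col)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bslmm_fit <- function(object, ...) {
  v <- object$variants
  v$index <- seq_len(nrow(v))
  ggplot2::ggplot(v, ggplot2::aes(x = .data$index, y = .data$pip)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "variant", y = "posterior inclusion probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sv_pca <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  if (!is.null(groups)) df$group <- groups[df$individual]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)",
                  100 * object$eigenvalues[1] / sum(object$eigenvalues)),
      y = sprintf("PC2 (%.1f%%)",
                  100 * object$eigenvalues[2] / sum(object$eigenvalues)))
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' @export
autoplot.pgs_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(
      x = "predicted (polygenic score)", y = "observed",
      subtitle = sprintf("r = %.2f, p = %.3g", object$r, object$p_value)) +
    ggplot2::theme_minimal()
}
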