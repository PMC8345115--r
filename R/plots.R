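#' Plotting helpers (violin/box representations)
#'
#' Optional ggplot2-based renderings of the two SMLM summaries: the
#' occupied-bin count distributions (violin + box, log-scaled count axis)
#' and the per-ring density box plots from nuclear centre to periphery.
#' ggplot2 is a suggested dependency; these helpers error informatively
#' when it is absent.
#'
#' @name plots
NULL

.need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' Violin + box plot of occupied-bin count distributions
#'
#' @param dists named list of `bin_count_dist` objects (one per group).
#' @return A ggplot object with the per-bin count on a log axis.
#' @export
plot_bin_distribution <- function(dists) {
  .need_ggplot2()
  if (inherits(dists, "bin_count_dist")) dists <- list(all = dists)
  df <- do.call(rbind, lapply(names(dists), function(nm)
    data.frame(group = nm, count = dists[[nm]]$counts)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$count)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "localisations per bin (log scale)") +
    ggplot2::theme_classic()
}

#' Box plots of radial ring densities
#'
#' @param profiles list of `ring_profile` objects (e.g. one per nucleus).
#' @return A ggplot object, ring 1 (centre) to ring n (periphery).
#' @export
plot_ring_profile <- function(profiles) {
  .need_ggplot2()
  if (inherits(profiles, "ring_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(seq_along(profiles), function(k) {
    p <- profiles[[k]]
    data.frame(nucleus = k, ring = seq_along(p$counts),
               density = p$densities_per_um2)
  }))
  df$ring <- factor(paste("Nucleus ring area", df$ring),
                    levels = paste("Nucleus ring area", sort(unique(df$ring))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ring, y = .data$density)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::labs(x = NULL, y = "localisation density (per um^2)") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
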