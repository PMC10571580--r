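#' Manhattan plot of a maternal GWAS fit
#'
#' Bayes factors per SNP along the chromosomes, with the calling
#' threshold drawn as a dashed line.
#'
#' @param object An `"mgwa_fit"` with map information.
#' @param bf_threshold Threshold line (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mgwa_fit <- function(object, bf_threshold = 10, ...) {
  snp <- object$snp
  if (!"chrom" %in% names(snp)) {
    abort("fit has no map information; refit with map = ...")
  }
  snp <- arrange(snp, as.numeric(.data$chrom), .data$pos)
  offsets <- snp |>
    group_by(.data$chrom) |>
    summarise(len = max(.data$pos), .groups = "drop") |>
    mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  snp <- left_join(snp, offsets, by = "chrom") |>
    mutate(x = .data$pos + .data$offset,
           parity = factor(as.integer(factor(.data$chrom,
             levels = unique(.data$chrom))) %% 2))
  ggplot2::ggplot(snp, ggplot2::aes(x = .data$x, y = pmin(.data$bf, 1e6),
                                    colour = .data$parity)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = bf_threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "genome position", y = "Bayes factor",
                  title = object$trait) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mgwa_fit
#' @export
plot_manhattan <- function(object, bf_threshold = 10, ...) {
  autoplot.mgwa_fit(object, bf_threshold = bf_threshold, ...)
}

#' Trace and density plots for an animal-model chain
#'
#' @param object An `"animal_model_fit"`.
#' @param pars Parameter (draw column) names; defaults to the derived
#'   genetic parameters.
#' @param ... Unused.
#' @return A ggplot object (facetted traces with marginal densities).
#' @export
autoplot.animal_model_fit <- function(object, pars = NULL, ...) {
  d <- object$draws
  if (is.null(pars)) {
    pars <- grep("^(h2d|h2m|c2|me2|rho_dm)", names(d), value = TRUE)
  }
  long <- d[, pars, drop = FALSE] |>
    mutate(.iter = dplyr::row_number()) |>
    tidyr::pivot_longer(-".iter", names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.iter, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "grey40") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained draw", y = NULL) +
    ggplot2::theme_minimal()
}
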