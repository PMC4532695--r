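#' Map of largest Lyapunov exponents over the input plane
#'
#' Scatter plot of sweep points in the (p_ee, p_ei) plane colored by the
#' largest Lyapunov exponent, hard-clipped to [-20, 20] 1/s on a
#' blue-green-red diverging scale (blue: strong contraction / point
#' attractors; green: near-zero exponents / limit cycles; red: strong
#' chaos).  With `fdcOverlay`, points classified as four-dimensional
#' chaos are overdrawn in black.  The caption embeds the package version
#' and the sweep's config hash.
#'
#' @param sweep a `lileySweep` from [runSweep()]
#' @param fdcOverlay overlay four-dimensional chaotic points in black
#' @param clip clipping magnitude for the color scale (1/s)
#' @return a `ggplot` object
#' @export
plotLLEMap <- function(sweep, fdcOverlay = TRUE, clip = 20) {
  stopifnot(inherits(sweep, "lileySweep"))
  df <- sweep$points[!sweep$points$diverged, , drop = FALSE]
  if (nrow(df) == 0) stop("no points to plot")
  df$lle <- pmin(pmax(df$lambda1, -clip), clip)
  sz <- max(0.3, min(3, 60 / sqrt(nrow(df))))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = p_ee, y = p_ei)) +
    ggplot2::geom_point(ggplot2::aes(colour = lle), size = sz) +
    ggplot2::scale_colour_gradientn(
      colours = c("blue", "green", "red"),
      limits = c(-clip, clip),
      name = "LLE (1/s)") +
    ggplot2::labs(
      x = expression(p[ee] ~ (ms^-1)), y = expression(p[ei] ~ (ms^-1)),
      caption = sprintf("lileyChaos %s | config %s | seed %d",
                        as.character(utils::packageVersion("lileyChaos")),
                        sweep$configHash, sweep$spec$seed)) +
    ggplot2::theme_minimal()
  if (fdcOverlay) {
    fdc <- df[df$label == "chaotic_4d", , drop = FALSE]
    if (nrow(fdc) > 0)
      gg <- gg + ggplot2::geom_point(data = fdc, colour = "black",
                                     size = sz)
  }
  gg
}

utils::globalVariables(c("p_ee", "p_ei", "lle"))
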