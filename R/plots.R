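# Small base-graphics helpers for quick visual checks and CLI output.

#' Plot a transverse dose slice
#'
#' @param dose an `rm3d_dose`.
#' @param depth slice depth in mm.
#' @param ... passed to [graphics::image()].
#' @export
plot_dose_slice <- function(dose, depth, ...) {
  sl <- dose_slice(dose, depth)
  graphics::image(sl$x, sl$y, sl$values, xlab = "x [mm]", ylab = "y [mm]",
                  main = sprintf("dose @ %.0f mm depth", sl$depth),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(NULL)
}

#' Plot one or more depth-dose profiles
#'
#' @param profiles a single profile data.frame (`z`, `dose`) or a named
#'   list of them; each is normalized to its plateau-free maximum.
#' @param normalize divide each curve by its own maximum.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_sobp <- function(profiles, normalize = TRUE, ...) {
  if (is.data.frame(profiles)) profiles <- list(profile = profiles)
  ys <- sapply(profiles, function(p)
    if (normalize) p$dose / max(p$dose) else p$dose)
  graphics::matplot(profiles[[1]]$z, ys, type = "l", lty = 1,
                    xlab = "depth [mm]", ylab = "relative dose", ...)
  if (length(profiles) > 1)
    graphics::legend("bottomleft", legend = names(profiles),
                     col = seq_along(profiles), lty = 1, bty = "n")
  invisible(NULL)
}
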