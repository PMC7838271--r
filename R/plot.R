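#' Plot predicted signal and bleed-through per detector
#'
#' Side-by-side bars of the signal (for the intended fluorophore) and the
#' total bleed-through in each detector of a panel, with the eta threshold
#' line drawn at `eta * signal`.
#'
#' @param pan A [panel()].
#' @param S A `signal_matrix`.
#' @param eta Bleed-through threshold to annotate.
#' @param ... Passed to [graphics::barplot()].
#' @return The [bleedthrough_report()] data.frame, invisibly.
#' @export
plot_panel_prediction <- function(pan, S, eta = 0.1, ...) {
  rep <- bleedthrough_report(pan, S, eta = eta)
  h <- rbind(signal = rep$signal, bleedthrough = rep$bleedthrough)
  mid <- graphics::barplot(h, beside = TRUE,
                           names.arg = paste(rep$detector, rep$fluorophore,
                                             sep = "\n"),
                           col = c("forestgreen", "firebrick"),
                           ylab = "predicted intensity",
                           legend.text = c("signal", "bleed-through"),
                           las = 2, cex.names = 0.7, ...)
  graphics::segments(mid[1, ] - 0.5, eta * rep$signal,
                     mid[2, ] + 0.5, eta * rep$signal, lty = 2)
  invisible(rep)
}
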