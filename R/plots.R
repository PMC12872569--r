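# ggplot2 presentation helpers.  Each analysis function returns plot-ready
# coordinates; these wrappers only render them.

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_col
#'   geom_hline geom_vline geom_text labs theme_minimal coord_flip
NULL

#' @export
ggplot2::autoplot

#' Kaplan-Meier curve plot
#'
#' @param object a `faers_km` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot faers_km
#' @export
autoplot.faers_km <- function(object, ...) {
  dat <- bind_rows(tibble(time = 0, survival = 1),
                   object$curve[c("time", "survival")])
  ggplot(dat, aes(x = .data$time, y = .data$survival)) +
    geom_step() +
    labs(x = "Days since therapy start", y = "Event-free probability",
         title = sprintf("Kaplan-Meier time-to-onset curve (n = %d)",
                         object$n)) +
    theme_minimal()
}

#' Volcano plot of sex-differential signals
#'
#' x = log2 ROR (female vs male), y = -log10 adjusted p; points past the
#' significance threshold are labelled with their PT.
#'
#' @param object a `gender_signals` result.
#' @param alpha significance threshold drawn as a horizontal line.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gender_signals
#' @export
autoplot.gender_signals <- function(object, alpha = 0.05, ...) {
  ggplot(object, aes(x = .data$log2_ror, y = .data$neglog10_padj)) +
    geom_point(aes(colour = .data$direction)) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    geom_vline(xintercept = 0, linetype = "dotted") +
    geom_text(data = function(d) d[d$labeled, ],
              aes(label = .data$pt), vjust = -0.6, size = 3) +
    labs(x = "log2(ROR), female vs male", y = "-log10(adjusted p)",
         colour = "direction") +
    theme_minimal()
}

#' @rdname autoplot.gender_signals
#' @export
plot_volcano <- function(object, alpha = 0.05, ...) {
  autoplot.gender_signals(object, alpha = alpha, ...)
}

#' Bar chart of the top reported preferred terms
#'
#' @param signals a `faers_signals` result.
#' @param k number of PTs shown (by report count).
#' @return a ggplot.
#' @export
plot_top_pts <- function(signals, k = 20) {
  top <- rank_top_pts(signals, k = k, by = "n_reports")
  top$pt <- factor(top$pt, levels = rev(top$pt))
  ggplot(top, aes(x = .data$pt, y = .data$n_reports,
                  fill = .data$is_signal)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "Reports (cases)", fill = "signal") +
    theme_minimal()
}
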