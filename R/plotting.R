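# Figures: volcano plot of per-RE enrichment and top/bottom family bar
# diagrams. Every figure is accompanied by a TSV of exactly the plotted
# values, which is the machine-checkable surface; the image is a rendering
# of that table.

.volcano_classes <- c("grey", "enriched", "depleted", "not_significant")

#' Classify enrichment rows for the volcano plot
#'
#' `x = log2(mean enrichment)` and `y = -log10(p)` (raw p positions the
#' point; the FDR-adjusted p decides colour). Points with `|x| <= grey_threshold`
#' are greyed as not meaningful regardless of significance; the rest are
#' `enriched`/`depleted` when `p_fdr <= alpha` and `not_significant`
#' otherwise.
#'
#' @param rows Data frame from [enrichment_table()] (columns `name`,
#'   `mean`, `p`, `p_fdr`).
#' @param alpha FDR significance level (default 0.05).
#' @param grey_threshold Absolute log2 fold-change below which points are
#'   greyed (default 0.5).
#' @return Data frame `name`, `x`, `y`, `p_fdr`, `class`.
#' @export
volcano_data <- function(rows, alpha = 0.05, grey_threshold = 0.5) {
  x <- log2(rows$mean)
  y <- -log10(pmax(rows$p, 1e-300))
  sig <- rows$p_fdr <= alpha
  cls <- ifelse(abs(x) <= grey_threshold, "grey",
                ifelse(!sig, "not_significant",
                       ifelse(x > 0, "enriched", "depleted")))
  data.frame(name = rows$name, x = x, y = y, p_fdr = rows$p_fdr,
             class = factor(cls, levels = .volcano_classes),
             stringsAsFactors = FALSE)
}

#' Volcano plot of RE enrichment
#'
#' Renders significance versus fold-change with three coloured classes
#' (enriched, depleted, grey for `|log2| <= grey_threshold`) and writes the
#' plotted values alongside as TSV.
#'
#' @param rows Data frame from [enrichment_table()].
#' @param prefix Output prefix; writes `<prefix>.volcano.png` (and `.svg`
#'   when the device is available) plus `<prefix>.volcano.tsv`.
#' @param alpha,grey_threshold See [volcano_data()].
#' @param palette Named colours for the four classes.
#' @return The data frame of plotted values, invisibly.
#' @export
volcano <- function(rows, prefix, alpha = 0.05, grey_threshold = 0.5,
                    palette = c(grey = "grey70", enriched = "#c0392b",
                                depleted = "#2f6db3",
                                not_significant = "grey35")) {
  vd <- volcano_data(rows, alpha, grey_threshold)
  utils::write.table(vd, paste0(prefix, ".volcano.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(vd) == 0L) warning("volcano: empty enrichment table")
  p <- ggplot2::ggplot(vd, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$class)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = palette, drop = FALSE) +
    ggplot2::geom_vline(xintercept = c(-grey_threshold, grey_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "log2 fold-change (ChIP/input)",
                  y = "significance -log10(p)",
                  colour = sprintf("FDR-adj. p <= %g", alpha)) +
    ggplot2::theme_classic()
  .save_figure(p, prefix, "volcano")
  invisible(vd)
}

#' Family bar diagrams of the most enriched and depleted families
#'
#' Bars show the mean enrichment over the two replicates with SD whiskers
#' and the individual replicate values as points. Families in the
#' exclusion set are omitted (short and low-coverage categories prone to
#' unreliable enrichment reports), as are families whose reproducibility
#' p-value exceeds `p_max`. The `k` most enriched and `k` most depleted of
#' the remaining families are drawn.
#'
#' @param summaries Data frame from [summarize_families()].
#' @param prefix Output prefix; writes `<prefix>.family_bars.png` (and
#'   `.svg` when available) plus `<prefix>.family_bars.tsv`.
#' @param k Families per panel (default 10).
#' @param p_max Maximum reproducibility p-value (default 0.05).
#' @param exclude Families dropped from the figure (default
#'   `Simple_repeat`, `Low_complexity`, `Unknown`, `tRNA`).
#' @return The data frame of plotted values, invisibly.
#' @export
family_bars <- function(summaries, prefix, k = 10L, p_max = 0.05,
                        exclude = c("Simple_repeat", "Low_complexity",
                                    "Unknown", "tRNA")) {
  keep <- summaries[!(summaries$family %in% exclude) &
                      summaries$p <= p_max, , drop = FALSE]
  keep <- keep[order(-keep$mean), , drop = FALSE]
  if (nrow(keep) < 2L * k)
    warning("family_bars: only ", nrow(keep), " qualifying families (",
            2L * k, " requested); plotting all")
  if (nrow(keep) == 0L) {
    empty <- data.frame(family = character(), panel = character(),
                        mean = numeric(), sd = numeric(),
                        enr1 = numeric(), enr2 = numeric(),
                        p = numeric(), p_fdr = numeric())
    utils::write.table(empty, paste0(prefix, ".family_bars.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(empty))
  }
  top <- utils::head(keep, k)
  bottom <- utils::tail(keep, min(k, max(0L, nrow(keep) - nrow(top))))
  sel <- rbind(cbind(top, panel = "most enriched"),
               if (nrow(bottom)) cbind(bottom, panel = "most depleted"))
  out <- sel[, c("family", "panel", "mean", "sd", "enr1", "enr2", "p",
                 "p_fdr")]
  utils::write.table(out, paste0(prefix, ".family_bars.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sel$family <- factor(sel$family, levels = rev(sel$family))
  long <- rbind(
    data.frame(family = sel$family, panel = sel$panel, value = sel$enr1),
    data.frame(family = sel$family, panel = sel$panel, value = sel$enr2))
  p <- ggplot2::ggplot(sel, ggplot2::aes(x = .data$family,
                                         y = .data$mean)) +
    ggplot2::geom_col(fill = "#5b8db8") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3, linewidth = 0.3) +
    ggplot2::geom_point(data = long, ggplot2::aes(y = .data$value),
                        shape = 1, size = 1.3) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "enrichment (ChIP/input)") +
    ggplot2::theme_classic()
  .save_figure(p, prefix, "family_bars")
  invisible(out)
}

# PNG always; SVG when the device is available on this build of R.
.save_figure <- function(p, prefix, tag, width = 6, height = 4.5) {
  png_path <- paste0(prefix, ".", tag, ".png")
  grDevices::png(png_path, width = width * 120, height = height * 120,
                 res = 120)
  print(p)
  grDevices::dev.off()
  svg_path <- paste0(prefix, ".", tag, ".svg")
  ok <- tryCatch({
    grDevices::svg(svg_path, width = width, height = height)
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    unlink(svg_path)
    FALSE
  })
  invisible(ok)
}
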