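open_device <- function(file, width, height) {
  if (grepl("\\.svg$", file, ignore.case = TRUE)) {
    grDevices::svg(file, width = width / 100, height = height / 100)
  } else {
    grDevices::png(file, width = width, height = height)
  }
}

#' Stacked bar chart of per-sample cell type proportions
#'
#' One bar per sample, stacked to height 1 by cell type; colors are
#' assigned deterministically by panel (column) order. When group
#' metadata is supplied, samples are arranged by group in the metadata's
#' group order.
#'
#' @param props a `proportion_matrix`.
#' @param groups optional sample-to-group mapping for ordering and axis
#'   annotation.
#' @param file optional output path (`.png` or `.svg`); when `NULL`,
#'   draws on the current device.
#' @param width,height device size in pixels.
#' @return Invisibly, the sample order plotted.
#' @export
plot_composition <- function(props, groups = NULL, file = NULL,
                             width = 960, height = 480) {
  stopifnot(inherits(props, "proportion_matrix"))
  if (nrow(props) == 0L) stop("no samples to plot")
  ord <- rownames(props)
  grp_lab <- NULL
  if (!is.null(groups)) {
    groups <- as_sample_groups(groups)
    g <- group_factor(data.frame(sample_id = ord), groups)
    ord <- ord[order(as.integer(g))]
    grp_lab <- sort(as.integer(g))
  }
  m <- t(unclass(props)[ord, , drop = FALSE])
  cols <- grDevices::hcl.colors(nrow(m), "Spectral")
  if (!is.null(file)) {
    open_device(file, width, height)
    on.exit(grDevices::dev.off())
  }
  graphics::par(mar = c(7, 4, 2, 10), xpd = TRUE)
  mids <- graphics::barplot(m, col = cols, border = NA, las = 2,
                            ylab = "proportion of cells",
                            cex.names = 0.7,
                            main = "Cell type composition per sample")
  if (!is.null(grp_lab)) {
    lv <- levels(group_factor(data.frame(sample_id = rownames(props)), groups))
    for (gi in unique(grp_lab)) {
      at <- mids[grp_lab == gi]
      graphics::mtext(lv[gi], side = 1, line = 5, at = mean(at), cex = 0.9)
    }
  }
  graphics::legend("topright", inset = c(-0.18, 0), legend = rownames(m),
                   fill = cols, border = NA, bty = "n", cex = 0.7)
  invisible(ord)
}

#' Boxplots of the diversity statistic by sample group
#'
#' One box per group, groups ordered as they first appear in the
#' metadata; individual samples are overlaid as jittered points.
#'
#' @param div a `diversity_table`.
#' @param groups sample-to-group mapping.
#' @param file optional output path (`.png` or `.svg`).
#' @param width,height device size in pixels.
#' @return Invisibly, `NULL`.
#' @export
plot_diversity_boxplot <- function(div, groups, file = NULL,
                                   width = 640, height = 480) {
  g <- group_factor(div, groups)
  if (!is.null(file)) {
    open_device(file, width, height)
    on.exit(grDevices::dev.off())
  }
  res <- unique(as.character(div$resolution))
  graphics::boxplot(div$diversity ~ g, xlab = "group",
                    ylab = "cell type diversity (Es)",
                    main = paste0("Diversity by group",
                                  if (length(res) == 1L)
                                    paste0(" (", res, ")")),
                    col = "grey90")
  graphics::points(jitter(as.integer(g), amount = 0.08), div$diversity,
                   pch = 19, cex = 0.6,
                   col = grDevices::adjustcolor("steelblue", 0.7))
  invisible(NULL)
}
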