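#' Sample-to-group assignment
#'
#' @param x a data.frame whose first two columns are sample id and group
#'   label, or a named character vector (names = sample ids). Group order
#'   of first appearance is preserved and used for plotting and pairwise
#'   comparisons.
#' @return A `sample_groups` data.frame with columns `sample_id`, `group`.
#' @export
as_sample_groups <- function(x) {
  if (inherits(x, "sample_groups")) return(x)
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("sample groups need two columns (sample_id, group)")
    out <- data.frame(sample_id = as.character(x[[1L]]),
                      group = as.character(x[[2L]]),
                      stringsAsFactors = FALSE)
  } else if (is.character(x) && !is.null(names(x))) {
    out <- data.frame(sample_id = names(x), group = unname(x),
                      stringsAsFactors = FALSE)
  } else {
    stop("sample groups must be a two-column data.frame or named character vector")
  }
  if (anyNA(out) || any(out$group == "")) stop("missing group labels")
  if (anyDuplicated(out$sample_id))
    stop("duplicated sample_id in group table: ",
         out$sample_id[duplicated(out$sample_id)][1L])
  class(out) <- c("sample_groups", "data.frame")
  out
}

# Match diversity rows to group labels; factor levels keep the order in
# which groups appear in the metadata (the plotting / contrast order).
group_factor <- function(div, groups) {
  groups <- as_sample_groups(groups)
  idx <- match(div$sample_id, groups$sample_id)
  if (anyNA(idx))
    stop("no group for sample: ",
         paste(div$sample_id[is.na(idx)], collapse = ", "))
  factor(groups$group[idx], levels = unique(groups$group))
}

check_group_sizes <- function(g, min_n = 2L) {
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("at least two groups required")
  tab <- table(g)
  small <- names(tab)[tab < min_n]
  if (length(small))
    stop("group with fewer than ", min_n, " samples: ",
         paste(small, collapse = ", "))
  g
}

#' One-way ANOVA of the diversity statistic across sample groups
#'
#' Classic fixed-effects one-way ANOVA (equal-variance F test) of the
#' per-sample statistic `diversity` against the group labels.
#'
#' @param div a `diversity_table` (or data.frame with `sample_id` and
#'   `diversity` columns).
#' @param groups sample-to-group mapping, see [as_sample_groups()].
#' @return List with elements `F`, `p_anova`, `df_between`, `df_within`
#'   and the per-group sample sizes `n`.
#' @export
anova_across_groups <- function(div, groups) {
  g <- check_group_sizes(group_factor(div, groups))
  y <- div$diversity
  within_var <- tapply(y, g, stats::var)
  if (all(within_var == 0))
    stop("degenerate ANOVA: zero within-group variance in every group")
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic),
       p_anova = unname(ft$p.value),
       df_between = unname(ft$parameter[1L]),
       df_within = unname(ft$parameter[2L]),
       n = as.integer(table(g)))
}

#' Pairwise two-sample t-tests of the diversity statistic between groups
#'
#' Two-sided two-sample t-tests for every unordered pair of groups, or for
#' one reference group against each of the others. Raw p-values are always
#' reported; multiplicity-adjusted p-values are appended on request.
#'
#' @inheritParams anova_across_groups
#' @param reference optional group label; when given, only the contrasts
#'   reference vs. each other group are tested.
#' @param variance_mode `"pooled"` for the classic equal-variance t-test
#'   (the default), `"welch"` for the unequal-variance form.
#' @param adjust multiple-testing correction for the set of reported
#'   pairs: `"none"` (default), `"holm"` or `"bh"` (Benjamini-Hochberg).
#' @return data.frame with one row per pair: `group_a`, `group_b`, `n_a`,
#'   `n_b`, `t`, `df`, `p_value`, and `p_adjusted` when `adjust != "none"`.
#'   `t > 0` means group_a has the larger mean.
#' @export
pairwise_ttests <- function(div, groups, reference = NULL,
                            variance_mode = c("pooled", "welch"),
                            adjust = c("none", "holm", "bh")) {
  variance_mode <- match.arg(variance_mode)
  adjust <- match.arg(adjust)
  g <- check_group_sizes(group_factor(div, groups))
  y <- div$diversity
  lev <- levels(droplevels(g))
  if (!is.null(reference)) {
    if (!reference %in% lev) stop("reference group not present: ", reference)
    pairs <- cbind(reference, setdiff(lev, reference))
  } else {
    pairs <- t(utils::combn(lev, 2L))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    xa <- y[g == a]; xb <- y[g == b]
    tt <- stats::t.test(xa, xb, var.equal = variance_mode == "pooled")
    data.frame(group_a = a, group_b = b,
               n_a = length(xa), n_b = length(xb),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = unname(tt$p.value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust != "none") {
    method <- c(holm = "holm", bh = "BH")[[adjust]]
    out$p_adjusted <- stats::p.adjust(out$p_value, method = method)
  }
  rownames(out) <- NULL
  out
}

#' Full group comparison: ANOVA plus pairwise t-tests
#'
#' Convenience wrapper bundling [anova_across_groups()] and
#' [pairwise_ttests()] into a single result object, the analysis applied
#' per cell type resolution in the standard workflow.
#'
#' @inheritParams pairwise_ttests
#' @param alpha significance level recorded with the result (default
#'   0.05); used only for reporting, never to censor p-values.
#' @return A `group_comparison` list with elements `anova`, `pairwise`,
#'   `alpha`, `variance_mode`, `adjust` and `resolution` (taken from `div`
#'   when present).
#' @export
compare_groups <- function(div, groups, reference = NULL,
                           variance_mode = c("pooled", "welch"),
                           adjust = c("none", "holm", "bh"),
                           alpha = 0.05) {
  variance_mode <- match.arg(variance_mode)
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  res <- list(
    anova = anova_across_groups(div, groups),
    pairwise = pairwise_ttests(div, groups, reference = reference,
                               variance_mode = variance_mode,
                               adjust = adjust),
    alpha = alpha,
    variance_mode = variance_mode,
    adjust = adjust,
    resolution = if ("resolution" %in% names(div))
      unique(as.character(div$resolution))[1L] else NA_character_
  )
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison of cell type diversity",
      if (!is.na(x$resolution)) paste0(" (resolution: ", x$resolution, ")"),
      "\n", sep = "")
  cat(sprintf("  one-way ANOVA: F = %.4g on %d and %d df, p = %.4g\n",
              x$anova$F, x$anova$df_between, x$anova$df_within,
              x$anova$p_anova))
  cat("  pairwise t-tests (", x$variance_mode, " variance, adjust = ",
      x$adjust, ", alpha = ", x$alpha, "):\n", sep = "")
  print(x$pairwise, digits = 4, row.names = FALSE)
  invisible(x)
}
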