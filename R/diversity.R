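#' Adjusted-entropy cell type diversity statistic
#'
#' Summarizes how evenly a sample's cells are spread over the `k` cell
#' types of the analysis panel. The Shannon entropy of the proportion
#' vector is normalized by its maximum `log(k)` and shifted by -1:
#'
#' \deqn{E_s = \frac{-\sum_{i=1}^{k} p_{is} \log p_{is}}{\log k} - 1}
#'
#' so the statistic lives in `[-1, 0]`: `0` for a perfectly even
#' composition (all proportions `1/k`) and `-1` when every cell belongs to
#' a single type. Normalizing by `log(k)` makes values comparable across
#' panels of different resolution, which is the point of the statistic.
#'
#' Zero proportions contribute nothing (`0 * log(0)` is taken as its limit
#' 0), so panels may include cell types absent from a sample. The natural
#' logarithm is used internally; the result is invariant to the log base
#' since numerator and denominator rescale together.
#'
#' @param p numeric vector of `k >= 2` proportions, non-negative and
#'   summing to 1 within `1e-9`.
#' @return A single number in `[-1, 0]`. Values within `1e-12` of a
#'   boundary are clamped to exactly `-1` or `0` so that floating-point
#'   overshoot never violates the range.
#' @examples
#' diversity_statistic(rep(1 / 4, 4))   # 0: perfectly even
#' diversity_statistic(c(1, 0, 0))      # -1: single type
#' diversity_statistic(c(0.7, 0.3))     # about -0.119
#' @export
diversity_statistic <- function(p) {
  p <- as.numeric(p)
  k <- length(p)
  if (k < 2L) stop("statistic undefined for k<2 (log k = 0)")
  if (anyNA(p) || any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  nz <- p > 0
  es <- -sum(p[nz] * log(p[nz])) / log(k) - 1
  if (es > -1e-12) es <- 0
  if (es < -1 + 1e-12) es <- -1
  es
}

#' Diversity statistic for every sample of a proportion matrix
#'
#' @param props a `proportion_matrix` (see [to_proportions()]); its number
#'   of columns is the panel size `k`, which must be at least 2.
#' @param resolution tag recorded with each row, naming the cell type
#'   resolution the panel represents (e.g. `"lineage"`, `"subtype"`).
#' @return A `diversity_table`: data.frame with columns `sample_id`,
#'   `resolution`, `k`, `n_cells` and `diversity` (the statistic), one row
#'   per sample.
#' @export
diversity_per_sample <- function(props, resolution = "subtype") {
  stopifnot(inherits(props, "proportion_matrix"))
  k <- ncol(props)
  if (k < 2L) stop("statistic undefined for k<2 (log k = 0)")
  n_cells <- attr(props, "n_cells")
  if (is.null(n_cells)) n_cells <- rep(NA_integer_, nrow(props))
  es <- vapply(seq_len(nrow(props)), function(i) {
    tryCatch(diversity_statistic(props[i, ]),
             error = function(e) stop("sample ", rownames(props)[i], ": ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  out <- data.frame(
    sample_id = rownames(props),
    resolution = as.character(resolution),
    k = k,
    n_cells = as.integer(n_cells),
    diversity = es,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("diversity_table", "data.frame")
  out
}
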