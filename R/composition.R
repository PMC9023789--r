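#' Per-cell annotation table
#'
#' Validates and classes a long-format table with one row per cell. This is
#' the rawest input granularity the package accepts: a cell barcode, the
#' sample it came from, and its (already assigned) cell type label.
#'
#' @param x data.frame with at least the three annotation columns.
#' @param cell_id,sample_id,cell_type names of the columns holding the cell
#'   identifier, sample identifier and cell type label.
#' @return A `cell_table`: a data.frame with standardized column names
#'   `cell_id`, `sample_id`, `cell_type`.
#' @details Cell ids must be unique within the table and no field may be
#'   missing or empty; both are hard errors because silent duplication or
#'   dropped annotations would bias downstream proportions.
#' @export
as_cell_table <- function(x, cell_id = "cell_id", sample_id = "sample_id",
                          cell_type = "cell_type") {
  if (!is.data.frame(x)) stop("cell table must be a data.frame")
  if (nrow(x) == 0L) stop("no cells")
  need <- c(cell_id, sample_id, cell_type)
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    cell_id = as.character(x[[cell_id]]),
    sample_id = as.character(x[[sample_id]]),
    cell_type = as.character(x[[cell_type]]),
    stringsAsFactors = FALSE
  )
  bad <- !stats::complete.cases(out) | out$sample_id == "" | out$cell_type == ""
  if (any(bad))
    stop("cell table has missing sample_id or cell_type in ",
         sum(bad), " row(s)")
  if (anyDuplicated(out$cell_id)) {
    d <- out$cell_id[duplicated(out$cell_id)][1L]
    stop("duplicated cell_id: ", d)
  }
  class(out) <- c("cell_table", "data.frame")
  out
}

new_composition_matrix <- function(counts) {
  class(counts) <- c("composition_matrix", "matrix", "array")
  counts
}

#' Sample-by-cell-type count matrix
#'
#' @param counts numeric matrix of non-negative integer counts, samples in
#'   rows (rownames = sample ids), cell types in columns (colnames = the
#'   analysis panel).
#' @return A `composition_matrix`.
#' @export
composition_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("composition matrix needs sample ids as rownames and type labels as colnames")
  if (anyDuplicated(colnames(counts)))
    stop("type labels must be unique")
  if (anyDuplicated(rownames(counts)))
    stop("sample ids must be unique")
  if (ncol(counts) < 1L) stop("at least one cell type label required")
  storage <- suppressWarnings(as.numeric(counts))
  if (anyNA(storage) || any(storage < 0) || any(storage != round(storage)))
    stop("counts must be non-negative integers")
  mode(counts) <- "integer"
  new_composition_matrix(counts)
}

#' Count cells into a sample-by-cell-type composition matrix
#'
#' Tallies a per-cell annotation table into a `composition_matrix` whose
#' columns form the analysis panel. The panel is what fixes `k`, the number
#' of cell types the diversity statistic is normalized by: panel types never
#' observed in a sample (or in the whole table) keep an explicit zero count
#' so that the statistic stays comparable across samples.
#'
#' @param cells a `cell_table` (or coercible data.frame).
#' @param panel optional character vector giving the full ordered panel of
#'   cell type labels. When omitted the panel is the lexicographically
#'   sorted set of observed labels.
#' @return `composition_matrix` with rows ordered lexicographically by
#'   sample id and columns in panel order.
#' @examples
#' cells <- data.frame(cell_id = paste0("c", 1:6), sample_id = "S1",
#'                     cell_type = c("T", "T", "T", "B", "B", "NK"))
#' count_composition(cells)
#' count_composition(cells, panel = c("T", "B", "NK", "Mono"))
#' @export
count_composition <- function(cells, panel = NULL) {
  cells <- as_cell_table(cells)
  if (is.null(panel)) {
    panel <- sort(unique(cells$cell_type))
  } else {
    panel <- as.character(panel)
    if (anyDuplicated(panel)) stop("panel labels must be unique")
    extra <- setdiff(unique(cells$cell_type), panel)
    if (length(extra))
      stop("cell_type not in panel: ", paste(extra, collapse = ", "))
  }
  samples <- sort(unique(cells$sample_id))
  tab <- table(factor(cells$sample_id, levels = samples),
               factor(cells$cell_type, levels = panel))
  counts <- matrix(as.integer(tab), nrow = length(samples),
                   dimnames = list(samples, panel))
  new_composition_matrix(counts)
}

#' Per-sample cell totals
#' @param comp a `composition_matrix`.
#' @return Named integer vector of n_s, the total cells per sample.
#' @export
cell_totals <- function(comp) {
  stopifnot(inherits(comp, "composition_matrix"))
  v <- rowSums(unclass(comp))
  storage.mode(v) <- "integer"
  v
}

#' @export
`[.composition_matrix` <- function(x, ...) {
  out <- unclass(x)[...]
  if (is.matrix(out) && !is.null(rownames(out)) && !is.null(colnames(out)))
    out <- new_composition_matrix(out)
  out
}

# Subsets keep the class only while rows still sit on the simplex
# (dropping columns breaks the constraint and yields a plain matrix).
#' @export
`[.proportion_matrix` <- function(x, ...) {
  n <- attr(x, "n_cells")
  out <- unclass(x)[...]
  if (is.matrix(out) && !is.null(rownames(out)) && !is.null(colnames(out)) &&
      all(abs(rowSums(out) - 1) <= 1e-9)) {
    if (!is.null(n)) n <- n[rownames(out)]
    out <- structure(out, n_cells = n,
                     class = c("proportion_matrix", "matrix", "array"))
  }
  out
}

#' Cell type hierarchy (fine label -> coarse label)
#'
#' @param x either a named character vector (names = fine labels, values =
#'   coarse labels) or a data.frame whose first two columns are fine and
#'   coarse labels.
#' @return Named character vector of class `cell_hierarchy`.
#' @export
as_hierarchy <- function(x) {
  if (inherits(x, "cell_hierarchy")) return(x)
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("hierarchy needs two columns (fine, coarse)")
    h <- stats::setNames(as.character(x[[2L]]), as.character(x[[1L]]))
  } else if (is.character(x) && !is.null(names(x))) {
    h <- x
  } else {
    stop("hierarchy must be a named character vector or two-column data.frame")
  }
  if (anyDuplicated(names(h))) {
    d <- names(h)[duplicated(names(h))][1L]
    stop("fine label mapped more than once: ", d)
  }
  if (anyNA(h) || anyNA(names(h)) || any(h == "") || any(names(h) == ""))
    stop("hierarchy contains missing labels")
  class(h) <- "cell_hierarchy"
  h
}

#' Re-aggregate a composition matrix to a coarser cell type resolution
#'
#' Sums the counts of fine cell types that share a coarse label (e.g.
#' collapsing 12 PBMC subpopulations into the lymphoid and myeloid
#' lineages). Per-sample totals are conserved exactly; only `k` changes.
#'
#' @param comp `composition_matrix` at the fine resolution.
#' @param hierarchy fine-to-coarse mapping, see [as_hierarchy()].
#' @param other_bucket if `TRUE`, fine labels absent from the hierarchy are
#'   collected into a literal `"Other"` coarse type instead of raising an
#'   error. Off by default: an unmapped label is usually a typo.
#' @return `composition_matrix` with one column per coarse label, ordered as
#'   the coarse labels first appear in the hierarchy (`"Other"` last).
#' @export
aggregate_composition <- function(comp, hierarchy, other_bucket = FALSE) {
  stopifnot(inherits(comp, "composition_matrix"))
  h <- as_hierarchy(hierarchy)
  fine <- colnames(comp)
  unmapped <- setdiff(fine, names(h))
  if (length(unmapped)) {
    if (!other_bucket)
      stop("unmapped label: ", paste(unmapped, collapse = ", "))
    h <- c(unclass(h), stats::setNames(rep("Other", length(unmapped)), unmapped))
  }
  coarse_of <- unname(unclass(h)[fine])
  coarse_levels <- unique(unname(unclass(h)))
  coarse_levels <- c(setdiff(coarse_levels[coarse_levels %in% coarse_of], "Other"),
                     if ("Other" %in% coarse_of) "Other")
  m <- unclass(comp)
  out <- vapply(coarse_levels, function(cl) {
    cols <- which(coarse_of == cl)
    if (length(cols) == 1L) m[, cols] else rowSums(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1L,
                                   dimnames = list(rownames(m), coarse_levels))
  mode(out) <- "integer"
  rownames(out) <- rownames(m)
  new_composition_matrix(out)
}

#' Convert counts to per-sample proportions on the simplex
#'
#' Divides each sample's counts by its total so that every row sums to 1.
#' Samples with zero cells have no defined composition; they are dropped
#' with a warning rather than erroring so that batch runs survive empty
#' samples.
#'
#' @param comp `composition_matrix`.
#' @return A `proportion_matrix`; per-sample totals of the retained samples
#'   are kept in the `n_cells` attribute for downstream reporting.
#' @export
to_proportions <- function(comp) {
  stopifnot(inherits(comp, "composition_matrix"))
  totals <- cell_totals(comp)
  zero <- totals == 0
  if (all(zero)) stop("all samples have zero cells")
  if (any(zero))
    warning("dropping ", sum(zero), " sample(s) with zero cells: ",
            paste(names(totals)[zero], collapse = ", "))
  m <- unclass(comp)[!zero, , drop = FALSE]
  totals <- totals[!zero]
  props <- m / totals
  proportion_matrix(props, n_cells = totals)
}

#' Sample-by-cell-type proportion matrix
#'
#' @param props numeric matrix of proportions in `[0, 1]`, each row summing
#'   to 1 within `1e-9`; dimnames as for [composition_matrix()].
#' @param n_cells optional named vector of per-sample cell totals, carried
#'   along for reporting.
#' @return A `proportion_matrix`.
#' @export
proportion_matrix <- function(props, n_cells = NULL) {
  props <- as.matrix(props)
  if (is.null(rownames(props)) || is.null(colnames(props)))
    stop("proportion matrix needs sample ids as rownames and type labels as colnames")
  if (any(props < 0) || any(props > 1) || anyNA(props))
    stop("proportions must lie in [0, 1]")
  dev <- abs(rowSums(props) - 1)
  if (any(dev > 1e-9)) {
    bad <- rownames(props)[which.max(dev)]
    stop("proportion rows must sum to 1 (off by ", max(dev), " for ", bad, ")")
  }
  structure(props, n_cells = n_cells,
            class = c("proportion_matrix", "matrix", "array"))
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat("composition_matrix: ", nrow(x), " sample(s) x ", ncol(x),
      " cell type(s)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.proportion_matrix <- function(x, ...) {
  cat("proportion_matrix: ", nrow(x), " sample(s) x ", ncol(x),
      " cell type(s) (rows sum to 1)\n", sep = "")
  y <- unclass(x)
  attr(y, "n_cells") <- NULL
  print(y, ...)
  invisible(x)
}
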