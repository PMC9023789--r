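# Delimiter by extension: .tsv/.tab/.txt are tab, everything else comma.
delim_for <- function(path) {
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_file <- function(path, ...) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "", ...)
}

write_delim_file <- function(df, path) {
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-cell annotation table from CSV/TSV
#'
#' Expects a header with (by default) `cell_id`, `sample_id` and
#' `cell_type` columns; other columns are ignored. Tab-separated files are
#' recognized by the `.tsv`/`.tab`/`.txt` extension.
#'
#' @param path file path.
#' @param cell_id,sample_id,cell_type column names to use.
#' @return A `cell_table` (see [as_cell_table()]).
#' @export
read_cell_table <- function(path, cell_id = "cell_id",
                            sample_id = "sample_id",
                            cell_type = "cell_type") {
  as_cell_table(read_delim_file(path), cell_id = cell_id,
                sample_id = sample_id, cell_type = cell_type)
}

#' Read / write a sample-by-cell-type count matrix as CSV/TSV
#'
#' The on-disk layout has one header row, a first column `sample_id` and
#' one integer column per cell type label.
#'
#' @param path file path.
#' @return `read_composition()` returns a [composition_matrix()];
#'   `write_composition()` returns `path` invisibly.
#' @export
read_composition <- function(path) {
  df <- read_delim_file(path)
  if (ncol(df) < 2L) stop("count matrix needs sample_id plus >=1 type column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  composition_matrix(m)
}

#' @rdname read_composition
#' @param comp a `composition_matrix`.
#' @export
write_composition <- function(comp, path) {
  stopifnot(inherits(comp, "composition_matrix"))
  df <- data.frame(sample_id = rownames(comp), unclass(comp),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_delim_file(df, path)
}

#' Read a fine-to-coarse cell type hierarchy from CSV/TSV
#'
#' Two columns with a header: first the fine label, second the coarse
#' label it collapses into.
#'
#' @param path file path.
#' @return A `cell_hierarchy` (see [as_hierarchy()]).
#' @export
read_hierarchy <- function(path) {
  df <- read_delim_file(path)
  as_hierarchy(df)
}

#' Read / write per-sample diversity tables as CSV/TSV
#'
#' Columns: `sample_id`, `resolution`, `k`, `n_cells`, `diversity`.
#'
#' @param path file path.
#' @return `read_diversity()` returns a `diversity_table`;
#'   `write_diversity()` returns `path` invisibly.
#' @export
read_diversity <- function(path) {
  df <- read_delim_file(path)
  need <- c("sample_id", "resolution", "k", "n_cells", "diversity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("diversity table is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  class(df) <- c("diversity_table", "data.frame")
  df
}

#' @rdname read_diversity
#' @param div a `diversity_table`.
#' @export
write_diversity <- function(div, path) {
  write_delim_file(as.data.frame(div), path)
}

#' Read sample group metadata from CSV/TSV
#'
#' Two columns with a header: `sample_id`, `group`. The order in which
#' group labels first appear defines the group ordering used in plots and
#' pairwise contrasts.
#'
#' @param path file path.
#' @return A `sample_groups` table (see [as_sample_groups()]).
#' @export
read_sample_groups <- function(path) {
  as_sample_groups(read_delim_file(path))
}

#' @rdname read_sample_groups
#' @param groups a `sample_groups` table.
#' @export
write_sample_groups <- function(groups, path) {
  write_delim_file(as.data.frame(as_sample_groups(groups)), path)
}

#' Write a group comparison result to ANOVA and pairwise tables
#'
#' @param cmp a `group_comparison` from [compare_groups()].
#' @param anova_path,pairwise_path output file paths (CSV/TSV by
#'   extension).
#' @return Invisibly, the two paths.
#' @export
write_comparison <- function(cmp, anova_path, pairwise_path) {
  stopifnot(inherits(cmp, "group_comparison"))
  an <- data.frame(
    resolution = cmp$resolution,
    F = cmp$anova$F,
    df_between = cmp$anova$df_between,
    df_within = cmp$anova$df_within,
    p_anova = cmp$anova$p_anova,
    alpha = cmp$alpha,
    variance_mode = cmp$variance_mode,
    adjust = cmp$adjust,
    stringsAsFactors = FALSE
  )
  write_delim_file(an, anova_path)
  write_delim_file(cmp$pairwise, pairwise_path)
  invisible(c(anova_path, pairwise_path))
}
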