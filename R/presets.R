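#' Bundled PBMC cell type panel and lineage hierarchy
#'
#' A 12-type peripheral blood mononuclear cell panel (7 lymphoid, 5
#' myeloid subpopulations) with its two-lineage collapse, used by the
#' aging demo preset and shipped as `inst/extdata/pbmc_lineage_hierarchy.csv`.
#'
#' @return For `pbmc_panel()`, a character vector of 12 labels; for
#'   `pbmc_lineages()`, a `cell_hierarchy` mapping each label to
#'   `"lymphoid"` or `"myeloid"`.
#' @export
pbmc_panel <- function() {
  c("CD4_T", "CD8_T", "NK", "B_naive", "B_memory", "Plasma", "MAIT",
    "CD14_Mono", "CD16_Mono", "cDC", "pDC", "Megakaryocyte")
}

#' @rdname pbmc_panel
#' @export
pbmc_lineages <- function() {
  as_hierarchy(stats::setNames(
    c(rep("lymphoid", 7L), rep("myeloid", 5L)),
    pbmc_panel()
  ))
}

#' Aging-study-shaped simulation preset
#'
#' A ready-made [simulation_config()] emulating the structure of a
#' cross-sectional PBMC aging cohort: four age groups of 12, 26, 14 and
#' 14 samples over the 12-type [pbmc_panel()], each sample holding a few
#' hundred to about a thousand cells. The three younger groups'
#' concentrations are skewed toward the dominant lymphoid types (CD4/CD8
#' T cells), while the extreme-old-age group's concentration is
#' distinctly more even, with a larger myeloid share — so its expected
#' diversity statistic is the highest of the four groups.
#'
#' The concentration values are artifact choices of this package chosen
#' to look like plausible PBMC compositions; they are not estimated from
#' any real cohort.
#'
#' @param cells_per_sample per-sample cell count or `c(min, max)` range
#'   (default 300-1200, drawn uniformly).
#' @param seed root seed.
#' @return A `simulation_config` with groups `younger`, `middle`,
#'   `older`, `extreme_old`.
#' @export
aging_preset <- function(cells_per_sample = c(300L, 1200L), seed = 1L) {
  simulation_config(
    groups = list(
      group_spec("younger", 12L,
                 c(9.0, 6.0, 3.0, 2.5, 1.5, 0.3, 0.7, 4.0, 1.0, 0.8, 0.5, 0.7)),
      group_spec("middle", 26L,
                 c(8.5, 6.5, 3.2, 2.3, 1.4, 0.3, 0.8, 4.2, 1.1, 0.8, 0.4, 0.5)),
      group_spec("older", 14L,
                 c(8.0, 6.0, 3.5, 2.0, 1.3, 0.4, 0.8, 4.8, 1.4, 0.9, 0.4, 0.5)),
      group_spec("extreme_old", 14L,
                 c(4.5, 4.0, 3.0, 2.0, 1.5, 0.8, 1.2, 6.0, 2.8, 1.8, 1.0, 1.4))
    ),
    panel = pbmc_panel(),
    cells_per_sample = cells_per_sample,
    seed = seed
  )
}

#' Null (no group effect) counterpart of the aging preset
#'
#' Same four group sizes and 12-type panel as [aging_preset()], but every
#' group draws from the same concentration vector (the preset's
#' `younger` values), so any detected group difference is a false
#' positive. Used for type-I-error calibration of the comparison
#' pipeline.
#'
#' @param cells_per_sample per-sample cell count (default a fixed 500).
#' @param seed root seed.
#' @return A `simulation_config`.
#' @export
aging_null_preset <- function(cells_per_sample = 500L, seed = 1L) {
  al <- c(9.0, 6.0, 3.0, 2.5, 1.5, 0.3, 0.7, 4.0, 1.0, 0.8, 0.5, 0.7)
  simulation_config(
    groups = list(
      group_spec("younger", 12L, al),
      group_spec("middle", 26L, al),
      group_spec("older", 14L, al),
      group_spec("extreme_old", 14L, al)
    ),
    panel = pbmc_panel(),
    cells_per_sample = cells_per_sample,
    seed = seed
  )
}

#' Read / write a simulation config as a plain-text key-value file
#'
#' The format is a flat, human-editable `key: value` file. Global keys
#' `panel`, `cells_per_sample` and `seed` come first; each `group:` line
#' then opens a group block whose `n_samples:` and `alpha:` lines belong
#' to it. List values are comma-separated. Lines starting with `#` and
#' blank lines are ignored.
#'
#' @param path file path.
#' @return `read_simulation_config()` returns a `simulation_config`;
#'   `write_simulation_config()` returns `path` invisibly.
#' @export
read_simulation_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  panel <- NULL; cells <- NULL; seed <- 1L
  groups <- list(); cur <- NULL
  split_list <- function(v) trimws(strsplit(v, ",", fixed = TRUE)[[1L]])
  flush_group <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$n_samples) || is.null(cur$alpha))
      stop("group '", cur$label, "' needs both n_samples and alpha")
    groups[[length(groups) + 1L]] <<-
      group_spec(cur$label, cur$n_samples, cur$alpha)
  }
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("unparseable config line: ", ln)
    key <- m[2L]; val <- m[3L]
    switch(key,
      panel = panel <- split_list(val),
      cells_per_sample = cells <- as.integer(split_list(val)),
      seed = seed <- as.integer(val),
      group = { flush_group(); cur <- list(label = val) },
      n_samples = {
        if (is.null(cur)) stop("n_samples outside a group block")
        cur$n_samples <- as.integer(val)
      },
      alpha = {
        if (is.null(cur)) stop("alpha outside a group block")
        cur$alpha <- as.numeric(split_list(val))
      },
      stop("unknown config key: ", key)
    )
  }
  flush_group()
  if (is.null(panel)) stop("config is missing 'panel'")
  if (is.null(cells)) stop("config is missing 'cells_per_sample'")
  simulation_config(groups, panel, cells, seed)
}

#' @rdname read_simulation_config
#' @param cfg a `simulation_config`.
#' @export
write_simulation_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "simulation_config"))
  lines <- c(
    "# celldiv simulation config",
    paste0("panel: ", paste(cfg$panel, collapse = ", ")),
    paste0("cells_per_sample: ", paste(cfg$cells_per_sample, collapse = ", ")),
    paste0("seed: ", cfg$seed)
  )
  for (g in cfg$groups) {
    lines <- c(lines,
               paste0("group: ", g$label),
               paste0("n_samples: ", g$n_samples),
               paste0("alpha: ", paste(format(g$alpha, trim = TRUE,
                                              scientific = FALSE),
                                       collapse = ", ")))
  }
  writeLines(lines, path)
  invisible(path)
}
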