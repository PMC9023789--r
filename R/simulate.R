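#' Specification of one simulated sample group
#'
#' @param label group label (e.g. `"younger"`).
#' @param n_samples number of samples to draw for the group.
#' @param alpha Dirichlet concentration vector over the panel types, all
#'   entries strictly positive. Its normalization `alpha / sum(alpha)` is
#'   the expected composition; its total controls sample-to-sample
#'   overdispersion (smaller total = noisier samples).
#' @return A `group_spec` list.
#' @export
group_spec <- function(label, n_samples, alpha) {
  if (!is.character(label) || length(label) != 1L || label == "")
    stop("group label must be a non-empty string")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) stop("n_samples must be >= 1")
  alpha <- as.numeric(alpha)
  if (length(alpha) < 1L || anyNA(alpha) || any(alpha <= 0))
    stop("alpha entries must be > 0")
  structure(list(label = label, n_samples = n_samples, alpha = alpha),
            class = "group_spec")
}

#' Configuration of a Dirichlet-multinomial composition simulation
#'
#' The generative model: for each sample of a group, a composition is
#' drawn from `Dirichlet(alpha_group)` and cell counts from
#' `Multinomial(n_s, p)`. This induces the negative dependence among type
#' counts that real fixed-depth single-cell samples exhibit, plus
#' between-sample overdispersion.
#'
#' @param groups list of [group_spec()] objects (at least one).
#' @param panel ordered character vector of cell type labels; every
#'   group's `alpha` must have one entry per panel type.
#' @param cells_per_sample either a single integer (fixed `n_s`) or a
#'   length-2 integer vector `c(min, max)` from which each sample's cell
#'   count is drawn uniformly.
#' @param seed root seed; per-sample substreams are derived from it so
#'   that adding groups or samples never perturbs earlier samples' draws.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(groups, panel, cells_per_sample, seed = 1L) {
  if (!is.list(groups) || length(groups) == 0L)
    stop("at least one group required")
  groups <- lapply(groups, function(g) {
    if (!inherits(g, "group_spec")) g <- do.call(group_spec, g)
    g
  })
  panel <- as.character(panel)
  if (length(panel) < 2L || anyDuplicated(panel))
    stop("panel must hold at least two unique type labels")
  for (g in groups)
    if (length(g$alpha) != length(panel))
      stop("alpha for group '", g$label, "' has ", length(g$alpha),
           " entries; panel has ", length(panel))
  labs <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicated group labels")
  cells_per_sample <- as.integer(cells_per_sample)
  if (!length(cells_per_sample) %in% 1:2 || anyNA(cells_per_sample) ||
      any(cells_per_sample < 1L))
    stop("cells_per_sample must be a positive integer or (min, max) range")
  if (length(cells_per_sample) == 2L &&
      cells_per_sample[2L] < cells_per_sample[1L])
    stop("cells_per_sample range must have min <= max")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(groups = groups, panel = panel,
                 cells_per_sample = cells_per_sample, seed = seed),
            class = "simulation_config")
}

# Deterministic substream seed: a distinct, reproducible 31-bit seed per
# (root seed, stream index). Linear mixing in double precision stays exact
# well below 2^53.
derive_seed <- function(root, index) {
  as.integer((abs(as.numeric(root)) * 48271 + as.numeric(index) * 104729) %%
               2147483563) + 1L
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

#' Simulate a grouped sample-by-cell-type count matrix
#'
#' Draws, for every sample, a composition from the group's Dirichlet and
#' counts from a multinomial at that composition (see
#' [simulation_config()]). Fully reproducible: the same config (including
#' seed) always yields the same matrix, and each sample has its own
#' derived random substream, so extending the config with further samples
#' or groups leaves existing samples' draws untouched.
#'
#' @param cfg a `simulation_config`.
#' @return List with `counts` (a [composition_matrix()]; sample ids
#'   `S001`, `S002`, ... in group order, which is also lexicographic
#'   order) and `groups` (a [as_sample_groups()] table).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  k <- length(cfg$panel)
  n_tot <- sum(vapply(cfg$groups, `[[`, integer(1), "n_samples"))
  width <- max(3L, nchar(as.character(n_tot)))
  ids <- sprintf(paste0("S%0", width, "d"), seq_len(n_tot))
  counts <- matrix(0L, nrow = n_tot, ncol = k,
                   dimnames = list(ids, cfg$panel))
  grp <- character(n_tot)
  j <- 0L
  with_preserved_rng(
    for (g in cfg$groups) {
      for (s in seq_len(g$n_samples)) {
        j <- j + 1L
        set.seed(derive_seed(cfg$seed, j))
        n_s <- if (length(cfg$cells_per_sample) == 2L)
          sample(cfg$cells_per_sample[1L]:cfg$cells_per_sample[2L], 1L)
        else cfg$cells_per_sample
        gam <- stats::rgamma(k, shape = g$alpha)
        p <- gam / sum(gam)
        counts[j, ] <- as.integer(stats::rmultinom(1L, n_s, p))
        grp[j] <- g$label
      }
    }
  )
  list(counts = new_composition_matrix(counts),
       groups = as_sample_groups(data.frame(sample_id = ids, group = grp,
                                            stringsAsFactors = FALSE)))
}

#' Simulate a per-cell annotation table
#'
#' Expands [simulate_counts()] to one row per cell, with cell ids
#' `<sample>_c0001`, ... Counting the result with [count_composition()]
#' reproduces the simulated count matrix exactly under the same config.
#'
#' @inheritParams simulate_counts
#' @return List with `cells` (a `cell_table`) and `groups`.
#' @export
simulate_cells <- function(cfg) {
  sim <- simulate_counts(cfg)
  m <- unclass(sim$counts)
  per_sample <- lapply(seq_len(nrow(m)), function(i) {
    n <- sum(m[i, ])
    if (n == 0L)
      return(data.frame(cell_id = character(0), sample_id = character(0),
                        cell_type = character(0), stringsAsFactors = FALSE))
    data.frame(
      cell_id = sprintf("%s_c%04d", rownames(m)[i], seq_len(n)),
      sample_id = rownames(m)[i],
      cell_type = rep(colnames(m), m[i, ]),
      stringsAsFactors = FALSE
    )
  })
  cells <- do.call(rbind, per_sample)
  rownames(cells) <- NULL
  list(cells = as_cell_table(cells), groups = sim$groups)
}

#' Monte-Carlo calibration of the group-comparison ANOVA
#'
#' Repeatedly simulates grouped composition data, runs the full pipeline
#' (proportions, diversity statistic, one-way ANOVA across groups) and
#' records the fraction of replicates rejecting at level `alpha`. Under a
#' null configuration (identical `alpha` concentration in every group)
#' this estimates the type-I error rate; under alternative configurations
#' it estimates power.
#'
#' @param null_cfg a `simulation_config` in which all groups share the
#'   same concentration vector.
#' @param alt_cfgs optional named list of alternative configs.
#' @param replicates Monte-Carlo replicates per configuration.
#' @param alpha significance level of the ANOVA rejection.
#' @param seed root seed for the experiment; each (config, replicate)
#'   pair gets its own derived substream.
#' @return data.frame with one row per configuration: `config`,
#'   `replicates`, `alpha`, `rejections`, `rejection_rate`.
#' @export
calibration_experiment <- function(null_cfg, alt_cfgs = list(),
                                   replicates = 1000L, alpha = 0.05,
                                   seed = 1L) {
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop("replicates must be >= 1")
  cfgs <- c(list(null = null_cfg), alt_cfgs)
  if (is.null(names(cfgs)) || any(names(cfgs)[-1L] == ""))
    names(cfgs) <- c("null", paste0("alt", seq_along(alt_cfgs)))
  rows <- lapply(seq_along(cfgs), function(ci) {
    cfg <- cfgs[[ci]]
    stopifnot(inherits(cfg, "simulation_config"))
    rej <- 0L
    for (r in seq_len(replicates)) {
      cfg$seed <- derive_seed(seed, (ci - 1L) * replicates + r)
      sim <- simulate_counts(cfg)
      div <- diversity_per_sample(to_proportions(sim$counts),
                                  resolution = "panel")
      p <- anova_across_groups(div, sim$groups)$p_anova
      if (p < alpha) rej <- rej + 1L
    }
    data.frame(config = names(cfgs)[ci], replicates = replicates,
               alpha = alpha, rejections = rej,
               rejection_rate = rej / replicates,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
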