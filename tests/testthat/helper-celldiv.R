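# Independent direct-summation oracle for the diversity statistic.
# Deliberately written differently from the package: explicit loop,
# base-2 logarithm (the statistic is log-base invariant).
oracle_diversity <- function(p) {
  k <- length(p)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h / log2(k) - 1
}

# Uniform draw from the k-simplex (Dirichlet(1, ..., 1)).
rand_simplex <- function(k) {
  g <- rgamma(k, shape = 1)
  g / sum(g)
}

toy_cells <- function() {
  data.frame(
    cell_id = paste0("c", 1:10),
    sample_id = rep(c("S1", "S2"), c(6, 4)),
    cell_type = c("T", "T", "T", "B", "B", "NK", "T", "B", "T", "T"),
    stringsAsFactors = FALSE
  )
}

toy_hierarchy <- function() {
  c(T = "Lymph", B = "Lymph", NK = "Lymph", Mono = "Myel")
}

small_sim_config <- function(seed = 1L, cells = 200L) {
  simulation_config(
    groups = list(
      group_spec("A", 4L, c(6, 3, 2, 1)),
      group_spec("B", 4L, c(1, 2, 3, 6))
    ),
    panel = c("T", "B", "NK", "Mono"),
    cells_per_sample = cells,
    seed = seed
  )
}
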