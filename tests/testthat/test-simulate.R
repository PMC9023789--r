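test_that("config validation rejects malformed inputs", {
  expect_error(simulation_config(list(), c("a", "b"), 100), "at least one group")
  expect_error(group_spec("g", 0, c(1, 1)), "n_samples")
  expect_error(group_spec("g", 2, c(1, -1)), "alpha")
  expect_error(
    simulation_config(list(group_spec("g", 2, c(1, 1, 1))), c("a", "b"), 100),
    "panel has"
  )
  expect_error(
    simulation_config(list(group_spec("g", 2, c(1, 1))), c("a", "b"),
                      c(200, 100)),
    "min <= max"
  )
})

test_that("simulation is deterministic and draws live on the right scales", {
  cfg <- small_sim_config(seed = 5)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(unclass(s1$counts), unclass(s2$counts))
  expect_identical(s1$groups, s2$groups)
  expect_true(all(cell_totals(s1$counts) == 200L))
  s3 <- simulate_counts(small_sim_config(seed = 6))
  expect_false(identical(unclass(s1$counts), unclass(s3$counts)))
})

test_that("cells_per_sample ranges are respected", {
  cfg <- simulation_config(list(group_spec("g", 6, c(2, 2, 2))),
                           panel = c("a", "b", "c"),
                           cells_per_sample = c(50, 80), seed = 3)
  tot <- cell_totals(simulate_counts(cfg)$counts)
  expect_true(all(tot >= 50 & tot <= 80))
  one <- simulation_config(list(group_spec("g", 3, c(1, 1))),
                           panel = c("a", "b"), cells_per_sample = 1, seed = 3)
  expect_true(all(cell_totals(simulate_counts(one)$counts) == 1L))
})

test_that("appending groups leaves earlier samples' draws untouched", {
  base <- small_sim_config(seed = 9)
  extended <- simulation_config(
    groups = c(base$groups, list(group_spec("C", 3, c(1, 1, 1, 1)))),
    panel = base$panel, cells_per_sample = base$cells_per_sample,
    seed = base$seed
  )
  m1 <- unclass(simulate_counts(base)$counts)
  m2 <- unclass(simulate_counts(extended)$counts)
  expect_identical(m2[seq_len(nrow(m1)), ], m1)
})

test_that("simulate_cells round-trips through count_composition", {
  cfg <- small_sim_config(seed = 21, cells = 80)
  sim_cells <- simulate_cells(cfg)
  sim_counts <- simulate_counts(cfg)
  recounted <- count_composition(sim_cells$cells, panel = cfg$panel)
  expect_identical(unclass(recounted), unclass(sim_counts$counts))
  expect_identical(sim_cells$groups, sim_counts$groups)
  expect_false(anyDuplicated(sim_cells$cells$cell_id) > 0)
})

test_that("concentration limits drive the diversity statistic to its bounds", {
  even <- simulation_config(list(group_spec("g", 20, rep(1e4, 5))),
                            panel = paste0("t", 1:5),
                            cells_per_sample = 2000, seed = 31)
  div <- diversity_per_sample(to_proportions(simulate_counts(even)$counts))
  expect_gt(mean(div$diversity), -0.01)

  skewed <- simulation_config(list(group_spec("g", 20, c(5e3, rep(1e-2, 4)))),
                              panel = paste0("t", 1:5),
                              cells_per_sample = 2000, seed = 32)
  div2 <- diversity_per_sample(to_proportions(simulate_counts(skewed)$counts))
  expect_lt(mean(div2$diversity), -0.9)
})

test_that("empirical mean proportions converge to alpha / sum(alpha)", {
  al <- c(6, 3, 2, 1)
  cfg <- simulation_config(list(group_spec("g", 10000, al)),
                           panel = paste0("t", 1:4),
                           cells_per_sample = 50, seed = 41)
  props <- to_proportions(simulate_counts(cfg)$counts)
  expect_equal(unname(colMeans(props)), al / sum(al), tolerance = 0.02)
})

test_that("calibration_experiment returns reproducible rejection rates", {
  cfg <- small_sim_config()
  r1 <- calibration_experiment(cfg, replicates = 5, seed = 2)
  r2 <- calibration_experiment(cfg, replicates = 5, seed = 2)
  expect_identical(r1, r2)
  expect_true(r1$rejection_rate >= 0 && r1$rejection_rate <= 1)
  single <- calibration_experiment(cfg, replicates = 1, seed = 2)
  expect_true(single$rejection_rate %in% c(0, 1))
  expect_error(calibration_experiment(cfg, replicates = 0), "replicates")
})

test_that("power is monotone in the size of the group shift", {
  al <- c(4, 3, 2, 1)
  make_cfg <- function(shift) {
    # second group mixes toward uniform by `shift`
    al2 <- (1 - shift) * al + shift * rep(mean(al), 4)
    simulation_config(list(group_spec("g1", 8, al), group_spec("g2", 8, al2)),
                      panel = paste0("t", 1:4), cells_per_sample = 400,
                      seed = 1)
  }
  res <- calibration_experiment(make_cfg(0),
                                alt_cfgs = list(weak = make_cfg(0.4),
                                                strong = make_cfg(0.9)),
                                replicates = 40, alpha = 0.05, seed = 3)
  expect_lte(res$rejection_rate[res$config == "null"],
             res$rejection_rate[res$config == "strong"])
  expect_lte(res$rejection_rate[res$config == "weak"],
             res$rejection_rate[res$config == "strong"])
})

test_that("presets are well-formed and the null preset has no group effect", {
  cfg <- aging_preset()
  expect_s3_class(cfg, "simulation_config")
  expect_identical(vapply(cfg$groups, `[[`, integer(1), "n_samples"),
                   c(12L, 26L, 14L, 14L))
  expect_length(cfg$panel, 12L)
  h <- pbmc_lineages()
  expect_setequal(unname(unclass(h)), c("lymphoid", "myeloid"))
  expect_identical(sort(names(h)), sort(cfg$panel))
  null_cfg <- aging_null_preset()
  als <- unique(lapply(null_cfg$groups, `[[`, "alpha"))
  expect_length(als, 1L)
})

test_that("simulation config round-trips through the key-value file format", {
  cfg <- aging_preset(seed = 17)
  f <- withr::local_tempfile(fileext = ".cfg")
  write_simulation_config(cfg, f)
  back <- read_simulation_config(f)
  expect_identical(back$panel, cfg$panel)
  expect_identical(back$cells_per_sample, cfg$cells_per_sample)
  expect_identical(back$seed, cfg$seed)
  expect_equal(lapply(back$groups, unclass), lapply(cfg$groups, unclass))
  # identical draws from the reread config
  expect_identical(unclass(simulate_counts(back)$counts),
                   unclass(simulate_counts(cfg)$counts))
})

test_that("bundled extdata fixtures agree with the in-code presets", {
  hf <- system.file("extdata", "pbmc_lineage_hierarchy.csv",
                    package = "celldiv")
  expect_true(nzchar(hf))
  expect_identical(unclass(read_hierarchy(hf)), unclass(pbmc_lineages()))
  cf <- system.file("extdata", "preset_aging.cfg", package = "celldiv")
  cfg <- read_simulation_config(cf)
  expect_equal(lapply(cfg$groups, unclass),
               lapply(aging_preset()$groups, unclass))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(1)
  set.seed(123)
  invisible(simulate_counts(small_sim_config()))
  x2 <- runif(1)
  expect_identical(x1, x2)
})
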