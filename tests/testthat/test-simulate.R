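test_that("invalid configurations are rejected with informative errors", {
  expect_error(
    simulation_config(n_planted = 100, genes_per_platform = 50),
    "n_planted"
  )
  expect_error(
    simulation_config(n_planted = 80, genes_per_platform = 100,
                      shared_gene_fraction = 0.5),
    "shared"
  )
  expect_error(
    simulation_config(samples_per_study = 10, metastasis_fraction = 0.1),
    "nonempty"
  )
  expect_error(simulation_config(platform_scale_sd = -1), "nonnegative")
  expect_error(simulation_config(noise_sd = 0), "positive")
  expect_error(
    simulation_config(n_studies = 3, samples_per_study = c(40, 40)),
    "samples_per_study"
  )
  expect_error(
    apply_platform_effect(signal_study(), scale_sd = -0.1, shift_sd = 0, seed = 1),
    "nonnegative"
  )
})

test_that("simulation is deterministic and class counts follow the rounding rule", {
  cfg <- simulation_config(
    n_studies = 3, genes_per_platform = 50, n_planted = 5,
    samples_per_study = 40, metastasis_fraction = 0.25, seed = 7
  )
  sim1 <- simulate_multistudy(cfg)
  sim2 <- simulate_multistudy(cfg)
  expect_identical(sim1$studies, sim2$studies)
  for (s in sim1$studies) {
    expect_equal(sum(s$outcome == 1L), 10L)
    expect_equal(sum(s$outcome == 0L), 30L)
    expect_false(anyDuplicated(s$gene_ids) > 0)
    expect_equal(nrow(s$matrix), length(s$gene_ids))
  }
  sim3 <- simulate_multistudy(simulation_config(
    n_studies = 3, genes_per_platform = 50, n_planted = 5,
    samples_per_study = 40, metastasis_fraction = 0.25, seed = 8
  ))
  expect_false(identical(sim1$studies[[1]]$matrix, sim3$studies[[1]]$matrix))
})

test_that("per-study sample sizes and platform gene sets are honoured", {
  cfg <- simulation_config(
    n_studies = 4, genes_per_platform = 100, shared_gene_fraction = 0.6,
    n_planted = 10, samples_per_study = c(40, 60, 40, 80),
    platform_assignment = c("P1", "P2", "P1", "P2"), seed = 3
  )
  sim <- simulate_multistudy(cfg)
  expect_equal(vapply(sim$studies, function(s) ncol(s$matrix), integer(1)),
               c(40L, 60L, 40L, 80L))
  g1 <- sim$studies[[1]]$gene_ids
  g2 <- sim$studies[[2]]$gene_ids
  expect_length(g1, 100)
  expect_length(intersect(g1, g2), 60)
  expect_identical(g1, sim$studies[[3]]$gene_ids)
  expect_true(all(sim$planted_genes %in% intersect(g1, g2)))
})

test_that("with no planted genes per-gene t statistics are null-calibrated", {
  cfg <- simulation_config(
    n_studies = 1, genes_per_platform = 2500, n_planted = 0,
    samples_per_study = 40, metastasis_fraction = 0.3, seed = 42
  )
  s <- simulate_multistudy(cfg)$studies[[1]]
  pos <- s$outcome == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  m1 <- rowMeans(s$matrix[, pos]); m0 <- rowMeans(s$matrix[, !pos])
  v1 <- apply(s$matrix[, pos], 1, var); v0 <- apply(s$matrix[, !pos], 1, var)
  tstat <- (m1 - m0) / sqrt(v1 / n1 + v0 / n0)
  df <- (v1 / n1 + v0 / n0)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("planted genes carry the configured standardized mean difference", {
  cfg <- simulation_config(
    n_studies = 2, genes_per_platform = 100, shared_gene_fraction = 1,
    n_planted = 20, effect_size = 2, noise_sd = 1,
    samples_per_study = 5000, metastasis_fraction = 0.3, seed = 5
  )
  sim <- simulate_multistudy(cfg)
  m <- cbind(sim$studies[[1]]$matrix, sim$studies[[2]]$matrix)
  outcome <- c(sim$studies[[1]]$outcome, sim$studies[[2]]$outcome)
  pos <- outcome == 1L
  smd <- (rowMeans(m[, pos]) - rowMeans(m[, !pos])) /
    sqrt((apply(m[, pos], 1, var) + apply(m[, !pos], 1, var)) / 2)
  planted <- rownames(m) %in% sim$planted_genes
  expect_true(all(abs(smd[planted] - 2) < 0.1))
  expect_true(all(abs(smd[!planted]) < 0.1))
})

test_that("signal penetrance scales the mean class difference", {
  cfg <- simulation_config(
    n_studies = 1, genes_per_platform = 60, n_planted = 30,
    effect_size = 2, signal_penetrance = 0.5,
    samples_per_study = 4000, metastasis_fraction = 0.5, seed = 9
  )
  sim <- simulate_multistudy(cfg)
  s <- sim$studies[[1]]
  pos <- s$outcome == 1L
  diff <- rowMeans(s$matrix[sim$planted_genes, pos]) -
    rowMeans(s$matrix[sim$planted_genes, !pos])
  # expected shift = penetrance * effect = 1
  expect_true(all(abs(diff - 1) < 0.15))
})

test_that("platform effect is per-gene affine, identity at zero, sign-preserving", {
  s <- signal_study(n = 40, n_genes = 30, informative = 1:5, seed = 2)
  expect_identical(apply_platform_effect(s, 0, 0, seed = 1)$matrix, s$matrix)

  d <- apply_platform_effect(s, scale_sd = 0.8, shift_sd = 0, seed = 11)
  pos <- s$outcome == 1L
  diff0 <- rowMeans(s$matrix[, pos]) - rowMeans(s$matrix[, !pos])
  diff1 <- rowMeans(d$matrix[, pos]) - rowMeans(d$matrix[, !pos])
  expect_true(all(sign(diff0) == sign(diff1)))
  expect_identical(d$outcome, s$outcome)

  # per-gene standardization removes a pure shift exactly
  sh <- apply_platform_effect(s, scale_sd = 0, shift_sd = 3, seed = 12)
  expect_equal(standardize_study(sh)$matrix, standardize_study(s)$matrix,
               tolerance = 1e-12)
})

test_that("TSV serialization round-trips and is byte-stable", {
  cfg <- simulation_config(
    n_studies = 2, genes_per_platform = 30, n_planted = 4,
    samples_per_study = 20, metastasis_fraction = 0.3, seed = 13
  )
  sim <- simulate_multistudy(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_studies(sim, d1)
  write_studies(sim, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  back <- read_studies(d1)
  expect_identical(back$planted_genes, sim$planted_genes)
  expect_equal(length(back$studies), 2)
  expect_equal(back$studies[[1]]$matrix, sim$studies[[1]]$matrix,
               tolerance = 1e-12)
  expect_identical(back$studies[[1]]$outcome, sim$studies[[1]]$outcome)
  expect_identical(back$studies[[2]]$role, sim$studies[[2]]$role)
})
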