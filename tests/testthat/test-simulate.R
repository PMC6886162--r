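# the synthetic electropherogram generator

test_that("a degenerate no-artifact config emits exactly the genotype", {
  panel <- tiny_panel()
  bundle <- default_model_bundle()
  bundle$allele_dropout$`*`$theta <- c(1e-12, 0)   # no allele drop-out
  g <- list(L1 = c("10", "12"), L2 = c("9", "11"))
  cfg <- sim_config(panel, list(g), amplitude = 3000, lambda = 0,
                    bundle = bundle, stutter = FALSE, noise = FALSE)
  set.seed(2)
  sim <- simulate_profile(cfg)
  expect_equal(nrow(sim$profile$peaks), 4L)
  expect_setequal(sim$profile$peaks$allele[sim$profile$peaks$marker ==
                                             "L1"], c("10", "12"))
  expect_true(all(sim$truth$component == "allele"))
  expect_true(all(sim$truth$h > 0))
})

test_that("simulation is reproducible under a fixed seed", {
  panel <- tiny_panel()
  g <- list(L1 = c("10", "12"), L2 = c("9", "11"))
  cfg <- sim_config(panel, list(g), amplitude = 500, lambda = 0.005)
  s1 <- local({ set.seed(7); simulate_profile(cfg) })
  s2 <- local({ set.seed(7); simulate_profile(cfg) })
  expect_identical(s1, s2)
  d1 <- simulate_calibration_dataset(tiny_panel(), 5, seed = 11)
  d2 <- simulate_calibration_dataset(tiny_panel(), 5, seed = 11)
  expect_identical(d1, d2)
})

test_that("zero degradation gives size-independent expected heights", {
  panel <- default_panel()
  g <- random_genotype(panel)
  cfg <- sim_config(panel, list(g), amplitude = 2000, lambda = 0,
                    stutter = FALSE, noise = FALSE)
  set.seed(3)
  sims <- do.call(rbind, lapply(1:50, function(i) simulate_profile(cfg)$truth))
  sims <- sims[sims$h > 0 & sims$copies == 1, ]
  lo <- sims$h[sims$s < 200]; hi <- sims$h[sims$s >= 200]
  # same u(x) everywhere: means agree within Monte Carlo error
  se <- sqrt(var(lo) / length(lo) + var(hi) / length(hi))
  expect_lt(abs(mean(lo) - mean(hi)), 4 * se)
})

test_that("mixtures sum independent contributions at shared alleles", {
  panel <- tiny_panel()
  bundle <- default_model_bundle()
  bundle$allele_dropout$`*`$theta <- c(1e-12, 0)
  g1 <- list(L1 = c("10", "10"))
  g2 <- list(L1 = c("10", "12"))
  cfg <- sim_config(panel, list(g1, g2), phi = c(0.5, 0.5),
                    amplitude = 4000, lambda = 0, bundle = bundle,
                    stutter = FALSE, noise = FALSE)
  set.seed(4)
  reps <- vapply(1:200, function(i) {
    tr <- simulate_profile(cfg)$truth
    tr$h[tr$s == allele_size(panel, "L1", "10")]
  }, numeric(1))
  # shared position carries 3 copies at phi * A = 2000 each:
  # E[h] = 3 * (0.5 * 2000 + 10) = 3030
  expect_lt(abs(mean(reps) - 3 * (0.5 * 2000 + 10)),
            4 * sd(reps) / sqrt(length(reps)))
})

test_that("calibration datasets keep truthful component bookkeeping", {
  panel <- tiny_panel()
  obs <- simulate_calibration_dataset(panel, n_profiles = 40,
                                      amplitudes = 2000, lambdas = 0,
                                      seed = 8)
  # every profile contributes every candidate position exactly once
  per_prof <- table(obs$sample_id)
  expect_true(all(per_prof == per_prof[1]))
  al <- obs[obs$component == "allele", ]
  # allele positions per profile = distinct genotype alleles (1 or 2/locus)
  counts <- tapply(al$marker, al$sample_id, length)
  expect_true(all(counts >= 2 & counts <= 4))
  # drop-out-free configuration yields no zero-height allele rows
  bundle <- default_model_bundle()
  bundle$allele_dropout$`*`$theta <- c(1e-12, 0)
  obs2 <- simulate_calibration_dataset(panel, n_profiles = 10,
                                       amplitudes = 2000, lambdas = 0,
                                       bundle = bundle, seed = 9,
                                       noise = FALSE, stutter = FALSE)
  expect_equal(sum(obs2$h == 0), 0L)
})

test_that("every emitted peak clears the analytical threshold", {
  panel <- tiny_panel()
  g <- list(L1 = c("10", "12"), L2 = c("9", "11"))
  cfg <- sim_config(panel, list(g), amplitude = 30, lambda = 0.01, at = 1)
  set.seed(5)
  for (i in 1:20) {
    sim <- simulate_profile(cfg)
    if (nrow(sim$profile$peaks))
      expect_true(all(sim$profile$peaks$height >= 1))
  }
})

test_that("classification recovers simulated truth labels exactly", {
  panel <- default_panel()
  set.seed(6)
  g <- random_genotype(panel)
  cfg <- sim_config(panel, list(g), amplitude = 3000, lambda = 0.002)
  sim <- simulate_profile(cfg, "S1")
  cl <- classify_peaks(sim$profile, g, panel)
  tr <- sim$truth[sim$truth$h > 0, ]
  m <- merge(cl[, c("marker", "s", "component")],
             tr[, c("marker", "s", "component")], by = c("marker", "s"))
  expect_equal(nrow(m), nrow(cl))
  expect_equal(m$component.x, m$component.y)
  # drop-outs agree too
  dr <- enumerate_dropouts(sim$profile, g, panel)
  trd <- sim$truth[sim$truth$h == 0, ]
  md <- merge(dr[, c("marker", "s", "component")],
              trd[, c("marker", "s", "component")], by = c("marker", "s"))
  expect_equal(nrow(md), nrow(dr))
  expect_equal(nrow(md), nrow(trd))
  expect_equal(md$component.x, md$component.y)
})
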