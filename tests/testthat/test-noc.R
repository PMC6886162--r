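# posterior on the number of contributors

noc_panel <- function() {
  lad <- data.frame(allele = c("10", "11", "12"),
                    size = c(146, 150, 154))
  str_panel(list(list(name = "L1", dye = "blue", repeat_len = 4,
                      ladder = lad)))
}

test_that("the nuisance grid enumerates sorted simplex compositions", {
  g1 <- theta_grid(1, 0.5, 0)
  expect_length(g1$points, 1)
  expect_equal(g1$points[[1]]$phi, 1)
  g2 <- theta_grid(2, 0.5, 0)
  phis <- lapply(g2$points, `[[`, "phi")
  expect_equal(phis, list(c(1, 0), c(0.5, 0.5)))
  g3 <- theta_grid(2, 0.25, 0)
  expect_length(g3$points, 3)  # (1,0), (.75,.25), (.5,.5)
  # decay grid crosses per contributor
  g4 <- theta_grid(2, 0.5, c(-0.004, 0))
  expect_length(g4$points, 2 * 4)
  expect_equal(sum(g4$weights), 1)
  expect_error(theta_grid(2, 0.3), "divide")
})

test_that("the posterior always normalizes to one", {
  panel <- noc_panel()
  freqs <- list(L1 = c("10" = 0.5, "11" = 0.3, "12" = 0.2))
  p <- str_profile("S", data.frame(marker = "L1", allele = c("10", "11"),
                                   size = c(146, 150),
                                   height = c(800, 750)))
  res <- app(p, panel, freqs, N_max = 3, delta = 0.5, decay_grid = 0,
             mc_iters = 100, seed = 4, amplitude = 2000)
  expect_equal(sum(res$probabilities), 1, tolerance = 1e-9)
  expect_true(all(res$probabilities >= 0))
  oracle <- brute_force_app(p, panel, freqs, N_max = 3, delta = 0.5,
                            decay_grid = 0, amplitude = 2000)
  expect_equal(sum(oracle$probabilities), 1, tolerance = 1e-9)
})

test_that("a degenerate allele frequency makes MC exact", {
  panel <- noc_panel()
  freqs <- list(L1 = c("10" = 1))  # forces genotype (10, 10)
  p <- str_profile("S", data.frame(marker = "L1", allele = "10",
                                   size = 146, height = 2010))
  res <- app(p, panel, freqs, N_max = 2, delta = 0.5, decay_grid = 0,
             mc_iters = 25, seed = 1, amplitude = 2000)
  oracle <- brute_force_app(p, panel, freqs, N_max = 2, delta = 0.5,
                            decay_grid = 0, amplitude = 2000)
  expect_equal(res$log_pE, oracle$log_pE, tolerance = 1e-9)
  expect_equal(res$probabilities, oracle$probabilities, tolerance = 1e-9)
})

test_that("Monte Carlo agrees with enumeration within its own error", {
  panel <- noc_panel()
  freqs <- list(L1 = c("10" = 0.6, "11" = 0.4))
  p <- str_profile("S", data.frame(marker = "L1", allele = c("10", "11"),
                                   size = c(146, 150),
                                   height = c(1050, 980)))
  oracle <- brute_force_app(p, panel, freqs, N_max = 2, delta = 0.5,
                            decay_grid = 0, amplitude = 2000)
  reps <- vapply(1:12, function(s)
    app(p, panel, freqs, N_max = 2, delta = 0.5, decay_grid = 0,
        mc_iters = 2000, seed = s, amplitude = 2000)$probabilities[1],
    numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - oracle$probabilities[1]), 3 * se + 1e-6)
  # convergence: error shrinks as iterations grow
  errs <- vapply(c(100, 1000, 10000), function(it)
    abs(app(p, panel, freqs, N_max = 2, delta = 0.5, decay_grid = 0,
            mc_iters = it, seed = 99,
            amplitude = 2000)$probabilities[1] -
          oracle$probabilities[1]), numeric(1))
  expect_lt(errs[3], errs[1] + 1e-9)
})

test_that("the posterior is invariant to locus order and contributor
           relabeling", {
  lad <- data.frame(allele = c("10", "11"), size = c(146, 150))
  lad2 <- data.frame(allele = c("8", "9"), size = c(250, 254))
  panel <- str_panel(list(
    list(name = "L1", dye = "blue", repeat_len = 4, ladder = lad),
    list(name = "L2", dye = "green", repeat_len = 4, ladder = lad2)))
  freqs <- list(L1 = c("10" = 0.6, "11" = 0.4),
                L2 = c("8" = 0.5, "9" = 0.5))
  pk <- data.frame(marker = c("L1", "L1", "L2"),
                   allele = c("10", "11", "8"),
                   size = c(146, 150, 250), height = c(900, 850, 1700))
  p1 <- str_profile("S", pk)
  p2 <- str_profile("S", pk[c(3, 1, 2), ])
  r1 <- brute_force_app(p1, panel, freqs, N_max = 2, delta = 0.5,
                        decay_grid = 0, amplitude = 2000)
  r2 <- brute_force_app(p2, panel, freqs, N_max = 2, delta = 0.5,
                        decay_grid = 0, amplitude = 2000)
  expect_equal(r1$probabilities, r2$probabilities, tolerance = 1e-12)
})

test_that("a pristine single-source profile points to one contributor", {
  panel <- default_panel()
  set.seed(17)
  freqs <- lapply(panel$loci[1:6], function(l)
    setNames(rep(1 / nrow(l$ladder), nrow(l$ladder)), l$ladder$allele))
  names(freqs) <- names(panel$loci)[1:6]
  g <- random_genotype(panel, loci = names(freqs))
  cfg <- sim_config(panel, list(g), amplitude = 3000, lambda = 0.001)
  sim <- simulate_profile(cfg, "S1")
  res <- app(sim$profile, panel, freqs, N_max = 3, delta = 0.25,
             decay_grid = c(-0.002, 0), mc_iters = 300, seed = 21)
  expect_equal(which.max(res$probabilities), 1L, ignore_attr = TRUE)
  expect_gt(res$probabilities[1], 0.99)
})
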