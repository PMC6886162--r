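# the model-family registry, its likelihoods, and maximum-likelihood fits

test_that("registry family dimensions and kinds are as designed", {
  dims <- c(TP1 = 4, TP2 = 4, TP3 = 4, TP4 = 4, TP5 = 5, SP1 = 4, SP2 = 4,
            SR1 = 5, SPE1 = 5, SPE2 = 7, SPE3 = 8, NP1 = 4, NP2 = 4,
            NP3 = 5, TDO1 = 2, TDO2 = 2, SDO1 = 2, SDO2 = 2, NDO1 = 2,
            NDO2 = 1)
  expect_setequal(family_ids(), names(dims))
  for (id in names(dims))
    expect_equal(model_family(id)$dim, unname(dims[id]), info = id)
  expect_equal(model_family("SR1")$kind, "stutter_ratio")
  expect_equal(model_family("TDO2")$kind, "dropout")
  expect_error(model_family("TP9"), "unknown")
})

test_that("the selected model set maps components to their families", {
  sel <- selected_model_set()
  expect_equal(unname(sel["allele"]), "TP4")
  expect_equal(unname(sel["reverse_stutter"]), "SP1")
  expect_equal(unname(sel["noise"]), "NP2")
  expect_equal(unname(sel["allele_dropout"]), "TDO1")
  expect_equal(unname(sel["reverse_stutter_dropout"]), "SDO1")
  expect_equal(unname(sel["noise_dropout"]), "NDO2")
  expect_equal(model_family(sel[["allele"]])$input, "decayed_amplitude")
  expect_equal(model_family(sel[["reverse_stutter"]])$input, "pph")
})

test_that("peak-height likelihood matches the direct-summation oracle", {
  # single-observation cases with hand-computable values
  obs1 <- data.frame(x = 0)
  expect_equal(loglik_peak_heights(10, obs1, "TP4", c(0, 10, 0, 2)),
               -log(2))
  expect_equal(loglik_peak_heights(12, obs1, "TP4", c(0, 10, 0, 2)),
               -(log(2) + 0.5))
  set.seed(11)
  for (rep in 1:5) {
    n <- 37
    obs <- data.frame(x = runif(n, 0, 500))
    theta <- c(runif(1, 0.1, 1), runif(1, 0, 20), runif(1, 0.01, 0.2),
               runif(1, 1, 10))
    h <- rnorm(n, affine_u(theta, obs$x), affine_v(theta, obs$x))
    expect_equal(loglik_peak_heights(h, obs, "TP4", theta),
                 oracle_Lh(h, affine_u(theta, obs$x),
                           affine_v(theta, obs$x)),
                 tolerance = 1e-12)
  }
  # a family whose raw sd goes nonpositive invalidates the likelihood
  raw_fam <- model_family("TP4")
  raw_fam$sd <- function(theta, obs) theta[3] * obs$x + theta[4]
  expect_identical(loglik_peak_heights(10, data.frame(x = 100), raw_fam,
                                       c(1, 0, -1, 5)), -Inf)
  # the registry family floors its sd instead, keeping the fit defined
  expect_true(is.finite(loglik_peak_heights(10, data.frame(x = 100),
                                            "TP4", c(1, 0, -1, 5))))
})

test_that("likelihood is order invariant and additive over subsets", {
  set.seed(12)
  obs <- data.frame(x = runif(40, 10, 400))
  theta <- c(0.5, 10, 0.05, 5)
  h <- rnorm(40, affine_u(theta, obs$x), affine_v(theta, obs$x))
  full <- loglik_peak_heights(h, obs, "TP4", theta)
  perm <- sample(40)
  expect_equal(loglik_peak_heights(h[perm], obs[perm, , drop = FALSE],
                                   "TP4", theta), full, tolerance = 1e-12)
  split1 <- loglik_peak_heights(h[1:15], obs[1:15, , drop = FALSE], "TP4",
                                theta)
  split2 <- loglik_peak_heights(h[16:40], obs[16:40, , drop = FALSE],
                                "TP4", theta)
  expect_equal(split1 + split2, full, tolerance = 1e-12)
})

test_that("stutter-ratio likelihood matches its oracle and excludes
           dropped parents", {
  theta <- c(0.05, 0.001, 0.05, 0.02, 0.01)
  obs <- data.frame(x = 200)
  # zero-residual single observation: -log v_r
  ur <- theta[1] * exp(-theta[2] * 200) + theta[3]
  vr <- theta[4] * exp(-theta[2] * 200) + theta[5]
  expect_equal(loglik_stutter_ratio(ur * 200, 200, obs, "SR1", theta),
               -log(vr), tolerance = 1e-10)
  expect_warning(
    loglik_stutter_ratio(c(10, 10), c(100, 0), data.frame(x = c(100, 0)),
                         "SR1", theta), "excluded")
  expect_error(suppressWarnings(
    loglik_stutter_ratio(10, 0, data.frame(x = 0), "SR1", theta)),
    "no stutter")
})

test_that("height- and ratio-scale stutter likelihoods obey the
           log-PPh identity", {
  # u = PPh * u_r and v = PPh * v_r  =>  L_h = L_r - sum(log PPh)
  set.seed(13)
  for (rep in 1:5) {
    n <- 25
    pph <- runif(n, 50, 2000)
    theta <- c(runif(1, 0.01, 0.2), runif(1, 0, 0.002), runif(1, 0, 0.1),
               runif(1, 0.005, 0.05), runif(1, 0.001, 0.02))
    obs <- data.frame(x = pph)
    fam <- model_family("SR1")
    ur <- fam$mean(theta, obs); vr <- fam$sd(theta, obs)
    h <- rnorm(n, pph * ur, pph * vr)
    Lr <- loglik_stutter_ratio(h, pph, obs, "SR1", theta)
    Lh <- oracle_Lh(h, pph * ur, pph * vr)
    expect_equal(Lh, Lr - sum(log(pph)), tolerance = 1e-10)
  }
})

test_that("drop-out likelihood matches the Bernoulli oracle", {
  obs <- data.frame(x = 0)
  expect_equal(as.numeric(loglik_dropout(1, obs, "NDO2", 0.5)), log(0.5))
  expect_equal(as.numeric(loglik_dropout(0, obs, "NDO2", 0)), 0)
  # printed-convention value is the negation
  ll <- loglik_dropout(1, obs, "NDO2", 0.5)
  expect_equal(attr(ll, "L_DO"), -as.numeric(ll))
  # exponential family evaluated at x = 0 gives p = a
  fam <- model_family("TDO1")
  expect_equal(fam$p(c(0.684, 0.0139), data.frame(x = 0)), 0.684)
  set.seed(14)
  x <- runif(60, 0, 400)
  p <- 0.7 * exp(-0.008 * x)
  y <- rbinom(60, 1, p)
  expect_equal(as.numeric(loglik_dropout(y, data.frame(x = x), "TDO1",
                                         c(0.7, 0.008))),
               oracle_Ldo(y, p), tolerance = 1e-12)
})

test_that("logistic drop-out probability decreases in the signal", {
  fam <- model_family("TDO2")
  x <- seq(0, 1000, by = 50)
  p <- fam$p(c(150, 0.02), data.frame(x = x))
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("constant drop-out fits to the empirical frequency", {
  set.seed(15)
  y <- rbinom(400, 1, 0.3)
  obs <- data.frame(h = ifelse(y == 1, 0, 50), x = NA_real_)
  f <- fit_component(obs, "NDO2")
  expect_equal(f$theta, mean(y), tolerance = 1e-12)
})

test_that("fitting demands enough observations and flags failure", {
  obs <- data.frame(h = c(10, 20), x = c(1, 2), pph = NA)
  expect_error(fit_component(obs, "TP4"), "too few")
})

test_that("affine and exponential fits recover generating parameters", {
  set.seed(16)
  n <- 3000
  x <- runif(n, 0, 500)
  theta <- c(0.6, 8, 0.04, 6)
  h <- pmax(rnorm(n, affine_u(theta, x), affine_v(theta, x)), 1)
  f <- fit_component(data.frame(h = h, x = x, pph = NA), "TP4", seed = 3)
  expect_true(all(abs(f$theta - theta) / theta < 0.10))
  y <- rbinom(n, 1, 0.6 * exp(-0.01 * x))
  fd <- fit_component(data.frame(h = ifelse(y == 1, 0, 100), x = x,
                                 pph = NA), "TDO1", seed = 3)
  expect_true(all(abs(fd$theta - c(0.6, 0.01)) / c(0.6, 0.01) < 0.10))
})
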