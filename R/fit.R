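## Maximum-likelihood calibration of one model family on one
## component x locus x dataset slice of classified observations.

rng_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

## Deterministic moment-based starts for each family kind.
fit_starts <- function(fam, h, y, obs) {
  x <- obs$x
  if (fam$kind == "dropout") {
    if (fam$id == "NDO2") return(list(mean(y)))
    b0 <- 0
    if (stats::var(x) > 0 && length(unique(y)) > 1) {
      g <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
      b0 <- max(-unname(stats::coef(g)[2]), 0)
      if (!is.finite(b0)) b0 <- 0
    }
    if (fam$id == "TDO2") {
      a0 <- if (b0 > 0 && stats::var(x) > 0) {
        g <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
        unname(stats::coef(g)[1]) / b0
      } else stats::median(x)
      if (!is.finite(a0)) a0 <- stats::median(x)
      return(list(c(a0, max(b0, 1e-4)), c(stats::median(x), 0.01),
                  c(mean(x), 1 / max(mean(x), 1)),
                  c(stats::quantile(x, 0.25), 0.1), c(0, 1e-3)))
    }
    ybar <- min(max(mean(y), 1e-3), 1.4)
    xm <- max(mean(x), 1e-6)
    return(list(c(ybar, 1e-6), c(ybar, b0), c(min(1, 1.4), b0),
                c(0.5, 1 / xm), c(ybar, 2 / xm)))
  }
  if (fam$kind == "stutter_ratio") {
    r <- h / obs$x  # x = pph for SR1
    m <- mean(r); s <- max(stats::sd(r), 1e-4)
    xm <- max(mean(obs$x), 1e-6)
    return(list(c(0, 1e-6, m, 0, s), c(m, 1 / xm, 0, s, s / 2),
                c(m / 2, 0.5 / xm, m / 2, 0, s),
                c(2 * m, 2 / xm, 0, s, 1e-3), c(0, 0.1 / xm, m, 0, s)))
  }
  # peak-height kinds
  if (fam$input %in% c("pph") && fam$dim >= 5) {
    # SPE exponential-on-parent families
    ratio <- pmax(h / pmax(x, 1e-6), 1e-6)
    c0 <- log(mean(ratio)); s0 <- log(max(stats::sd(ratio), 1e-3))
    xm <- max(mean(x), 1e-6)
    base <- switch(as.character(fam$dim),
                   "5" = c(1, 1e-6, c0, 1, s0),
                   "7" = c(1, 1e-6, c0, 1, s0, 0, 1),
                   "8" = c(1, 1e-6, c0, 1, s0, 1e-6, 0, 1))
    alt <- base; alt[2] <- 0.5 / xm
    if (fam$dim == 8) alt[6] <- 0.5 / xm
    alt2 <- base; alt2[3] <- c0 - 1; alt3 <- base; alt3[3] <- c0 + 1
    alt4 <- base; alt4[5] <- s0 + 1
    return(list(base, alt, alt2, alt3, alt4))
  }
  # affine families (TP1-TP4, SP1, SP2, NP1, NP2) and locus-decay (TP5, NP3)
  x0 <- if (fam$input == "locus_decay") obs$A * exp(obs$B * obs$s) else x
  co <- if (stats::var(x0) > 0)
    unname(stats::coef(stats::lm(h ~ x0))) else c(mean(h), 0)
  a0 <- if (length(co) == 2) co[2] else 0
  b0 <- co[1]
  res <- h - (a0 * x0 + b0)
  sco <- if (stats::var(x0) > 0)
    unname(stats::coef(stats::lm(abs(res) ~ x0))) else c(stats::sd(res), 0)
  c0 <- if (length(sco) == 2) sco[2] else 0
  d0 <- sco[1]
  # ensure the start's v(x) is positive over the data
  vmin <- min(c0 * x0 + d0)
  if (!is.finite(vmin) || vmin <= 0) d0 <- d0 - vmin + max(stats::sd(res),
                                                           1)
  base <- c(a0, b0, c0, d0)
  starts <- list(base, c(a0, b0, 0, max(stats::sd(res), 1)),
                 c(a0 * 0.5, b0, c0, d0 * 2 + 1),
                 c(a0 * 2, b0 * 0.5, c0 * 0.5, d0 + 1),
                 c(a0, 0, c0, d0))
  if (fam$input == "locus_decay")
    starts <- c(lapply(starts[1:3], function(s) c(s, 1)),
                list(c(base, 0.5), c(base, 2)))
  starts
}

#' Fit one model family by maximum likelihood
#'
#' Fits the family's parameters on classified observations of one component
#' at one locus in one dataset, maximizing the component's log-likelihood
#' (peak-height, stutter-ratio, or Bernoulli drop-out) with a deterministic
#' moment-based multi-start and bounded quasi-Newton optimization
#' (`L-BFGS-B`). The standard-deviation function of peak models is floored
#' at 0.001 RFU so the likelihood stays defined throughout the search.
#'
#' Peak-height fits use observed peaks only (`h > 0`); parent-peak-height
#' families additionally exclude observations whose parent dropped out.
#' Drop-out fits use all positions, observed and dropped. The constant
#' noise drop-out family is fitted in closed form (the empirical drop-out
#' frequency).
#'
#' @param obs data.frame of classified observations with columns `h`
#'   (height, 0 = drop-out), `pph` where relevant, and the explanatory
#'   columns the family needs (`x` is computed via [model_input()] when
#'   absent).
#' @param family family definition or id.
#' @param seed integer seed controlling the (deterministic) start jitter.
#' @param locus,dataset labels stored in the result.
#' @return a `fitted_component_model`: list with `family`, `theta`,
#'   `component`, `locus`, `dataset`, `loglik`, `n_obs`.
#' @export
fit_component <- function(obs, family, seed = 1L, locus = NA_character_,
                          dataset = NA_character_) {
  fam <- if (is.character(family)) model_family(family) else family
  obs <- as.data.frame(obs)
  if (!"x" %in% names(obs) || all(is.na(obs$x)))
    obs$x <- model_input(fam$id, obs)
  if (fam$kind == "dropout") {
    y <- as.integer(obs$h == 0)
    if (fam$input == "pph" && "pph" %in% names(obs))
      obs$x <- ifelse(is.na(obs$pph), 0, obs$pph)
    keep <- rep(TRUE, nrow(obs))
  } else {
    keep <- obs$h > 0
    if (fam$input == "pph")
      keep <- keep & !is.na(obs$pph) & obs$pph > 0
    y <- NULL
  }
  obs <- obs[keep, , drop = FALSE]
  if (!is.null(y)) y <- y[keep]
  h <- obs$h
  n <- nrow(obs)
  if (n < fam$dim + 1)
    stop("too few observations (", n, ") to fit ", fam$id, " (dim ",
         fam$dim, ")")
  if (fam$id == "NDO2") {
    a <- mean(y)
    ll <- as.numeric(loglik_dropout(y, obs, fam, a))
    return(structure(list(family = fam, theta = a, component = fam$component,
                          locus = locus, dataset = dataset, loglik = ll,
                          n_obs = n), class = "fitted_component_model"))
  }
  # plain-list view of the columns the family functions touch ($ access on
  # a list is much cheaper than on a data.frame inside the optimizer loop)
  od <- list(x = obs$x, A = obs$A, B = obs$B, s = obs$s)
  objective <- function(theta) {
    ll <- switch(fam$kind,
                 peak_height = loglik_peak_heights(h, od, fam, theta),
                 stutter_ratio = suppressWarnings(
                   loglik_stutter_ratio(h, od$x, od, fam, theta)),
                 dropout = as.numeric(loglik_dropout(y, od, fam, theta)))
    if (!is.finite(ll)) 1e12 else -ll
  }
  starts <- rng_local(seed, {
    s0 <- fit_starts(fam, h, y, obs)
    lapply(s0, function(s) s * (1 + stats::rnorm(length(s), 0, 1e-3)))
  })
  lower <- fam$lower; upper <- fam$upper
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-9), upper - 1e-9)
    st[!is.finite(st)] <- 0
    fit <- tryCatch(stats::optim(st, objective, method = "L-BFGS-B",
                                 lower = lower, upper = upper,
                                 control = list(maxit = 200, factr = 1e9,
                                                parscale = pmax(abs(st),
                                                                0.01))),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e12) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("maximum-likelihood fit of ", fam$id, " failed to converge from ",
         length(starts), " starts (n = ", n, ")")
  structure(list(family = fam, theta = unname(best$par),
                 component = fam$component, locus = locus,
                 dataset = dataset, loglik = -best$value, n_obs = n),
            class = "fitted_component_model")
}

#' @export
print.fitted_component_model <- function(x, ...) {
  cat(sprintf("%s fit (%s): theta = (%s), loglik = %.4g, n = %d\n",
              x$family$id, x$family$label,
              paste(signif(x$theta, 5), collapse = ", "), x$loglik, x$n_obs))
  invisible(x)
}
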