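## Posterior distribution on the number of contributors (NOC).
##
## The evidence likelihood P(E | N = n) is averaged over a discretized grid
## of nuisance parameters (mixture fractions on a simplex grid, one decay
## factor per contributor from a finite grid) and, at each locus, over
## contributor genotypes drawn from Hardy-Weinberg priors by Monte Carlo
## (or enumerated exhaustively on small instances).

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Discretized nuisance-parameter grid for n contributors
#'
#' Enumerates all mixture-fraction vectors of length `n` on a simplex grid
#' of resolution `delta` (fractions sorted in descending order, so
#' contributor relabelings are not double-counted), crossed with every
#' assignment of a per-contributor decay factor from `decay_grid`. The
#' prior over grid points is uniform.
#'
#' @param n number of contributors (>= 1).
#' @param delta simplex resolution; `1 / delta` must be (near) integer.
#' @param decay_grid finite grid of per-contributor decay factors `B`
#'   (per bp, <= 0 for degradation).
#' @return a `theta_grid`: list with `n`, `points` (list of
#'   `list(phi, B)`), and uniform `weights`.
#' @export
theta_grid <- function(n, delta = 0.1, decay_grid = c(-0.004, 0)) {
  stopifnot(n >= 1, delta > 0, length(decay_grid) >= 1)
  M <- round(1 / delta)
  if (abs(M - 1 / delta) > 1e-9) stop("delta must divide 1")
  # non-increasing compositions of M into n parts (unordered contributors)
  comps <- function(total, parts, cap) {
    if (parts == 1) {
      if (total <= cap) return(list(total)) else return(list())
    }
    out <- list()
    for (first in min(total, cap):ceiling(total / parts))
      for (rest in comps(total - first, parts - 1, first))
        out[[length(out) + 1L]] <- c(first, rest)
    out
  }
  phis <- lapply(comps(M, n, M), function(v) v / M)
  decays <- expand.grid(rep(list(decay_grid), n), KEEP.OUT.ATTRS = FALSE)
  points <- list()
  for (p in phis) for (i in seq_len(nrow(decays)))
    points[[length(points) + 1L]] <- list(phi = p,
                                          B = as.numeric(decays[i, ]))
  if (!length(points)) stop("empty nuisance-parameter grid")
  structure(list(n = n, points = points,
                 weights = rep(1 / length(points), length(points))),
            class = "theta_grid")
}

## Candidate-position context for one locus: every ladder position plus the
## one-repeat flanks, plus any observed peak outside those windows; each
## position carries the summed observed height (0 = no peak).
locus_context <- function(profile, panel, marker, window = 0.5) {
  locus <- panel$loci[[marker]]
  if (is.null(locus)) stop("unknown locus '", marker, "'")
  lad <- locus$ladder
  cand <- sort(unique(round(c(lad$size, lad$size - locus$repeat_len,
                              lad$size + locus$repeat_len), 6)))
  pk <- profile$peaks[profile$peaks$marker == marker, , drop = FALSE]
  extra <- pk$size[!vapply(pk$size, function(s)
    any(abs(cand - s) <= window), logical(1))]
  pos <- sort(unique(c(cand, extra)))
  h <- vapply(pos, function(s)
    sum(pk$height[abs(pk$size - s) <= window]), numeric(1))
  near_idx <- function(target) vapply(pos, function(s) {
    j <- which(abs(pos - (s + target)) <= window)
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
  lad_pos <- vapply(lad$size, function(s) {
    j <- which(abs(pos - s) <= window); j[1]
  }, integer(1))
  rev_parent <- near_idx(locus$repeat_len)
  fwd_parent <- near_idx(-locus$repeat_len)
  np <- length(pos)
  list(marker = marker, dye = locus$dye, pos = pos, h = h, lad = lad,
       lad_pos = stats::setNames(lad_pos, lad$allele),
       rev_parent = rev_parent, fwd_parent = fwd_parent,
       rev_children = lapply(seq_len(np), function(p)
         which(!is.na(rev_parent) & rev_parent == p)),
       fwd_children = lapply(seq_len(np), function(p)
         which(!is.na(fwd_parent) & fwd_parent == p)))
}

## Resolve the 8 component-model entries of a bundle for one locus.
locus_models <- function(bundle, marker) {
  comps <- c("allele", "reverse_stutter", "forward_stutter", "noise",
             "allele_dropout", "reverse_stutter_dropout",
             "forward_stutter_dropout", "noise_dropout")
  mods <- lapply(comps, function(cp) {
    e <- bundle_entry(bundle, cp, marker)
    list(fam = model_family(e$family), theta = e$theta)
  })
  stats::setNames(mods, comps)
}

mod_uv <- function(m, x) {
  obs <- list(x = x)
  list(u = m$fam$mean(m$theta, obs), v = m$fam$sd(m$theta, obs))
}
mod_p <- function(m, x) m$fam$p(m$theta, list(x = x))

## Per-(locus, theta) precomputation shared by all genotype draws: the
## per-contributor decayed-amplitude matrix, the allele-model sd at every
## possible single-copy input, and the "all positions are noise" baseline
## log-likelihood (per-draw evaluation then only replaces the terms of
## allele and stutter positions).
theta_ctx <- function(ctx, mods, phi, B, A) {
  np <- length(ctx$pos)
  X <- exp(outer(ctx$pos, B)) * rep(phi * A, each = np)  # np x n
  va2 <- matrix(mod_uv(mods$allele, as.vector(X))$v^2, np, length(phi))
  xn <- rowSums(X)
  pn <- mod_p(mods$noise_dropout, xn)
  uvn <- mod_uv(mods$noise, xn)
  obs <- ctx$h > 0
  noise_log <- ifelse(obs,
                      log1p(-pn) + stats::dnorm(ctx$h, uvn$u, uvn$v,
                                                log = TRUE),
                      log(pn))
  list(X = X, va2 = va2, noise_log = noise_log,
       base_ll = sum(noise_log))
}

## log P(E_l | genotypes, theta): copy_pos gives the position index of each
## of the 2n allele copies, copy_contrib the contributor of each copy.
## Positions not claimed by an allele or a stutter of an allele are noise;
## reverse stutter takes precedence over forward at collisions.
locus_loglik_g <- function(ctx, mods, tc, copy_pos, copy_contrib) {
  h <- ctx$h
  apos <- unique(copy_pos)
  na <- length(apos)
  x_sum <- numeric(na); v2 <- numeric(na)
  for (k in seq_along(copy_pos)) {
    j <- match(copy_pos[k], apos)
    x_sum[j] <- x_sum[j] + tc$X[copy_pos[k], copy_contrib[k]]
    v2[j] <- v2[j] + tc$va2[copy_pos[k], copy_contrib[k]]
  }
  ua <- mod_uv(mods$allele, x_sum)$u
  pdo <- mod_p(mods$allele_dropout, x_sum)
  obs <- h[apos] > 0
  allele_log <- ifelse(obs,
                       log1p(-pdo) + stats::dnorm(h[apos], ua, sqrt(v2),
                                                  log = TRUE),
                       log(pdo))
  ll <- tc$base_ll + sum(allele_log - tc$noise_log[apos])
  rpos <- setdiff(unique(unlist(ctx$rev_children[apos])), apos)
  fpos <- setdiff(unique(unlist(ctx$fwd_children[apos])), c(apos, rpos))
  stutter_ll <- function(idx, parent_idx, comp) {
    if (!length(idx)) return(0)
    pp <- parent_idx[idx]
    pph <- ifelse(h[pp] > 0, h[pp], ua[match(pp, apos)])
    pdo <- mod_p(mods[[paste0(comp, "_dropout")]], pph)
    uv <- mod_uv(mods[[comp]], pph)
    sobs <- h[idx] > 0
    term <- ifelse(sobs,
                   log1p(-pdo) + stats::dnorm(h[idx], uv$u, uv$v,
                                              log = TRUE),
                   log(pdo))
    sum(term - tc$noise_log[idx])
  }
  ll <- ll + stutter_ll(rpos, ctx$rev_parent, "reverse_stutter")
  ll <- ll + stutter_ll(fpos, ctx$fwd_parent, "forward_stutter")
  if (!is.finite(ll)) -Inf else ll
}

#' Monte Carlo locus likelihood given n and nuisance parameters
#'
#' Estimates `P(E_l | N = n, Theta = theta)` by averaging the conditional
#' evidence likelihood over `mc_iters` draws of `n` contributor genotypes
#' from Hardy-Weinberg priors on the locus allele frequencies.
#'
#' @param ctx locus context (internal; built from the profile and panel).
#' @param mods resolved component models for the locus.
#' @param freq named allele-frequency vector for the locus.
#' @param phi,B mixture fractions and per-contributor decay factors.
#' @param A profile amplitude scale (RFU).
#' @param mc_iters Monte Carlo iterations (>= 1).
#' @return log of the estimated locus likelihood.
#' @keywords internal
locus_likelihood_mc <- function(ctx, mods, freq, phi, B, A, mc_iters) {
  if (mc_iters < 1) stop("mc_iters must be >= 1")
  n <- length(phi)
  allele_pos <- ctx$lad_pos[names(freq)]
  if (anyNA(allele_pos))
    stop("frequency allele(s) ", paste(names(freq)[is.na(allele_pos)],
                                       collapse = ","),
         " not on the ladder of locus ", ctx$marker)
  tc <- theta_ctx(ctx, mods, phi, B, A)
  copy_contrib <- rep(seq_len(n), each = 2)
  draws <- matrix(sample.int(length(freq), 2 * n * mc_iters,
                             replace = TRUE, prob = freq),
                  nrow = mc_iters)
  # canonicalize the two copies within each contributor, then deduplicate
  # repeated genotype combinations (the likelihood is computed once each)
  for (j in seq_len(n)) {
    a <- draws[, 2 * j - 1]; b <- draws[, 2 * j]
    draws[, 2 * j - 1] <- pmin(a, b); draws[, 2 * j] <- pmax(a, b)
  }
  keys <- do.call(paste, c(split(draws, col(draws)), sep = "."))
  tab <- table(keys)
  uniq <- match(names(tab), keys)
  lls <- vapply(uniq, function(i)
    locus_loglik_g(ctx, mods, tc, allele_pos[draws[i, ]], copy_contrib),
    numeric(1))
  logsumexp(lls + log(as.numeric(tab))) - log(mc_iters)
}

## Exhaustive version: sums over all ordered genotype combinations.
locus_likelihood_enum <- function(ctx, mods, freq, phi, B, A,
                                  max_combos = 4096) {
  n <- length(phi)
  k <- length(freq)
  allele_pos <- ctx$lad_pos[names(freq)]
  pairs <- list(); lp <- numeric(0)
  for (i in seq_len(k)) for (j in i:k) {
    pairs[[length(pairs) + 1L]] <- c(i, j)
    lp <- c(lp, log(freq[i]) + log(freq[j]) + if (i != j) log(2) else 0)
  }
  combos <- expand.grid(rep(list(seq_along(pairs)), n),
                        KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) > max_combos)
    stop("instance too large to enumerate (", nrow(combos),
         " genotype combinations)")
  tc <- theta_ctx(ctx, mods, phi, B, A)
  copy_contrib <- rep(seq_len(n), each = 2)
  terms <- vapply(seq_len(nrow(combos)), function(ci) {
    pidx <- as.integer(combos[ci, ])
    copies <- unlist(pairs[pidx])
    locus_loglik_g(ctx, mods, tc, allele_pos[copies], copy_contrib) +
      sum(lp[pidx])
  }, numeric(1))
  logsumexp(terms)
}

app_engine <- function(profile, panel, freqs, bundle, N_max, delta,
                       decay_grid, mc_iters, seed, amplitude, window,
                       estimator) {
  loci <- intersect(unique(profile$peaks$marker), names(freqs))
  loci <- intersect(loci, names(panel$loci))
  if (!length(loci)) stop("no locus shared by the profile, the panel and ",
                          "the frequency table")
  if (is.null(amplitude)) {
    fit <- fit_decay(profile, panel, mode = "pooled")
    amplitude <- fit$A[1]
  }
  ctxs <- lapply(loci, function(m) locus_context(profile, panel, m, window))
  modss <- lapply(loci, function(m) locus_models(bundle, m))
  names(ctxs) <- names(modss) <- loci
  log_pE <- rng_local(seed, vapply(seq_len(N_max), function(n) {
    grid <- theta_grid(n, delta, decay_grid)
    log_theta <- vapply(grid$points, function(tp) {
      sum(vapply(loci, function(m) {
        f <- freqs[[m]]
        if (estimator == "mc")
          locus_likelihood_mc(ctxs[[m]], modss[[m]], f, tp$phi, tp$B,
                              amplitude, mc_iters)
        else
          locus_likelihood_enum(ctxs[[m]], modss[[m]], f, tp$phi, tp$B,
                                amplitude)
      }, numeric(1)))
    }, numeric(1))
    logsumexp(log_theta + log(grid$weights))
  }, numeric(1)))
  if (all(!is.finite(log_pE)))
    stop("evidence likelihood is zero for every contributor count; ",
         "per-n log-likelihoods: ", paste(signif(log_pE, 4),
                                          collapse = ", "))
  p <- exp(log_pE - logsumexp(log_pE))
  p[!is.finite(p)] <- 0
  p <- p / sum(p)
  structure(list(probabilities = stats::setNames(p, seq_len(N_max)),
                 log_pE = stats::setNames(log_pE, seq_len(N_max)),
                 N_max = N_max, mc_iters = mc_iters, seed = seed,
                 amplitude = amplitude, estimator = estimator),
            class = "app_result")
}

#' Posterior probability on the number of contributors
#'
#' Computes `P(N = n | E)` for `n = 1..N_max` by averaging Monte Carlo
#' locus-likelihood estimates over a uniform prior on the discretized
#' nuisance grid (mixture fractions, per-contributor decay factors),
#' multiplying across loci, and normalizing over `n`. All accumulation is
#' in log space. The profile's amplitude scale defaults to its own pooled
#' decayed-amplitude fit.
#'
#' @param profile an `str_profile` (pull-up filtered).
#' @param panel an `str_panel`.
#' @param freqs population allele-frequency table (see
#'   [read_frequencies()]).
#' @param bundle component-model parameter bundle.
#' @param N_max largest contributor count considered (default 5).
#' @param delta simplex grid resolution for mixture fractions.
#' @param decay_grid finite grid of per-contributor decay factors.
#' @param mc_iters Monte Carlo genotype draws per locus and grid point.
#' @param seed integer seed (the estimate is reproducible given the seed).
#' @param amplitude override for the profile amplitude scale `A` (RFU);
#'   default: pooled decay fit of the profile.
#' @param window position-matching half-window, bp.
#' @return an `app_result`: normalized posterior `probabilities` (summing
#'   to 1), per-n marginal log-likelihoods `log_pE`, and run metadata.
#' @export
app <- function(profile, panel, freqs, bundle = default_model_bundle(),
                N_max = 5L, delta = 0.1, decay_grid = c(-0.004, 0),
                mc_iters = 1000L, seed = 1L, amplitude = NULL,
                window = 0.5) {
  app_engine(profile, panel, freqs, bundle, N_max, delta, decay_grid,
             mc_iters, seed, amplitude, window, "mc")
}

#' Exhaustive-enumeration posterior on the number of contributors
#'
#' Identical pipeline to [app()] with the Monte Carlo genotype sampling
#' replaced by an exact sum over every genotype combination; only feasible
#' on small instances (few alleles in the frequency table, small `N_max`).
#'
#' @inheritParams app
#' @return an `app_result`.
#' @export
brute_force_app <- function(profile, panel, freqs,
                            bundle = default_model_bundle(), N_max = 2L,
                            delta = 0.5, decay_grid = 0, seed = 1L,
                            amplitude = NULL, window = 0.5) {
  app_engine(profile, panel, freqs, bundle, N_max, delta, decay_grid,
             mc_iters = NA_integer_, seed = seed, amplitude = amplitude,
             window = window, estimator = "enum")
}

#' @export
print.app_result <- function(x, ...) {
  cat("Posterior on the number of contributors (",
      if (x$estimator == "mc") paste0("Monte Carlo, ", x$mc_iters,
                                      " iters")
      else "exhaustive", "):\n", sep = "")
  for (n in seq_len(x$N_max))
    cat(sprintf("  P(N=%d | E) = %.4f\n", n, x$probabilities[n]))
  invisible(x)
}
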