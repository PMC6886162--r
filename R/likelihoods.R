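#' Peak-height log-likelihood
#'
#' The heteroscedastic Gaussian log-likelihood of observed peak heights,
#' up to its additive constant `-n log(sqrt(2 pi))`:
#' `L_h = -sum_i [ log v(x_i) + (h_i - u(x_i))^2 / (2 v(x_i)^2) ]`. The
#' dropped constant cancels whenever models are compared on identical
#' data; the quadratic term keeps the Gaussian 1/2 so that `v(x)` is
#' exactly the standard deviation of the peak-height model `N(u(x), v(x))`
#' that the simulator and the evidence likelihood use.
#'
#' @param h observed peak heights (RFU).
#' @param obs data.frame of explanatory inputs (column `x`, plus `A`, `B`,
#'   `s` for locus-decay families).
#' @param family a family definition or id (kind `peak_height`).
#' @param theta parameter vector of length `family$dim`.
#' @return the log-likelihood; `-Inf` if any `v(x_i) <= 0`.
#' @export
loglik_peak_heights <- function(h, obs, family, theta) {
  if (is.character(family)) family <- model_family(family)
  u <- family$mean(theta, obs)
  v <- family$sd(theta, obs)
  if (any(!is.finite(u)) || any(!is.finite(v)) || any(v <= 0)) return(-Inf)
  -sum(log(v) + (h - u)^2 / (2 * v^2))
}

#' Stutter-ratio log-likelihood
#'
#' Gaussian log-likelihood of stutter ratios `r_i = h_i / PPh_i` under a
#' ratio-scale family, up to the same additive constant as
#' [loglik_peak_heights()]:
#' `L_r = -sum_i [ log v_r(x_i) + (r_i - u_r(x_i))^2 / (2 v_r(x_i)^2) ]`.
#' Observations whose parent peak dropped out (`pph = 0`) have no defined
#' ratio and are excluded with a warning. On the height scale, defining
#' `u = PPh * u_r` and `v = PPh * v_r` gives the identity
#' `L_h = L_r - sum_i log(PPh_i)`, which puts ratio models on the same
#' footing as peak-height models when comparing stutter families.
#'
#' @param h stutter peak heights (RFU).
#' @param pph parent-allele peak heights (RFU).
#' @param obs data.frame of explanatory inputs (column `x`).
#' @param family a family definition or id (kind `stutter_ratio`).
#' @param theta parameter vector.
#' @return the log-likelihood over observations with `pph > 0`.
#' @export
loglik_stutter_ratio <- function(h, pph, obs, family, theta) {
  if (is.character(family)) family <- model_family(family)
  keep <- pph > 0
  if (!all(keep)) {
    warning(sum(!keep), " stutter observation(s) with dropped parent ",
            "excluded (undefined ratio)")
    h <- h[keep]; pph <- pph[keep]
    obs <- obs[keep, , drop = FALSE]
  }
  if (!length(h)) stop("no stutter observations with observed parent peak")
  r <- h / pph
  u <- family$mean(theta, obs)
  v <- family$sd(theta, obs)
  if (any(!is.finite(u)) || any(!is.finite(v)) || any(v <= 0)) return(-Inf)
  -sum(log(v) + (r - u)^2 / (2 * v^2))
}

#' Drop-out (Bernoulli) log-likelihood
#'
#' Drop-out indicators `y_i` (1 = no peak observed at the position) are
#' Bernoulli with probability `p(x_i; theta)`. Returns the log-likelihood
#' `sum_i log( p(x_i) y_i + (1 - p(x_i)) (1 - y_i) )`, the quantity the
#' maximum-likelihood fit maximizes; its negation is attached as attribute
#' `"L_DO"` for reporting on the minimized scale.
#'
#' @param y drop-out indicators (0/1).
#' @param obs data.frame of explanatory inputs (column `x`).
#' @param family a family definition or id (kind `dropout`).
#' @param theta parameter vector.
#' @return log-likelihood (numeric scalar, `-Inf` if any `p` outside
#'   `[0, 1]`), with attribute `L_DO = -loglik`.
#' @export
loglik_dropout <- function(y, obs, family, theta) {
  if (is.character(family)) family <- model_family(family)
  p <- family$p(theta, obs)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) return(-Inf)
  lik <- p * y + (1 - p) * (1 - y)
  if (any(lik <= 0)) return(-Inf)
  ll <- sum(log(lik))
  attr(ll, "L_DO") <- -ll
  ll
}

## Held-out log-likelihood of a fitted component model, on the scale used
## for cross-model comparison (peak-height scale for all stutter families).
heldout_loglik <- function(fit, h, pph, y, obs) {
  fam <- fit$family
  if (fam$kind == "dropout") {
    as.numeric(loglik_dropout(y, obs, fam, fit$theta))
  } else if (fam$kind == "stutter_ratio") {
    keep <- pph > 0
    h <- h[keep]; pph <- pph[keep]; obs <- obs[keep, , drop = FALSE]
    if (!length(h)) return(NA_real_)
    lr <- suppressWarnings(loglik_stutter_ratio(h, pph, obs, fam,
                                                fit$theta))
    lr - sum(log(pph))
  } else {
    loglik_peak_heights(h, obs, fam, fit$theta)
  }
}
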