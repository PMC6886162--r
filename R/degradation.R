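#' Locus signal amplitude
#'
#' The amplitude of the signal at a locus is the sum of all observed peak
#' heights there (0 for an empty locus).
#'
#' @param heights numeric vector of peak heights (RFU) at one locus.
#' @return total amplitude in RFU.
#' @export
locus_amplitude <- function(heights) {
  if (!length(heights)) return(0)
  sum(heights)
}

#' Height-weighted mean allele size at a locus
#'
#' @param heights peak heights (RFU).
#' @param sizes fragment sizes (bp), same length.
#' @return the weighted average size in bp.
#' @export
weighted_mean_size <- function(heights, sizes) {
  if (!length(heights)) stop("weighted mean size is undefined for a locus ",
                             "with no peaks")
  stopifnot(length(heights) == length(sizes))
  sum(heights * sizes) / sum(heights)
}

#' Fit the decayed-amplitude curve of a profile
#'
#' For each dye color (or pooled across dyes), fits the exponential curve
#' `f(s) = A * exp(B * s)` through the per-locus points (weighted mean
#' allele size, locus amplitude). With exactly two loci the fit is the exact
#' two-point interpolation; with more, an ordinary least-squares regression
#' of `log H` on `s` (back-transformed). `A` is the expected undegraded
#' amplitude (RFU); `B` is the decay factor per bp (<= 0 for a degraded
#' sample). `B` is clamped at +0.01/bp; clamped fits are flagged.
#'
#' @param profile an `str_profile` (pull-up filtered).
#' @param panel an `str_panel`.
#' @param mode `"per_dye"` (one fit per dye color, falling back to pooled
#'   for dyes with fewer than two usable loci) or `"pooled"` (one fit across
#'   all dyes).
#' @param b_max upper clamp for the decay factor (default 0.01 per bp).
#' @return a `decay_fit` object: data.frame with one row per fitted group
#'   (`dye` is `"*"` for the pooled fit) and columns `A`, `B`, `n_loci`,
#'   `pooled`, `clamped`.
#' @export
fit_decay <- function(profile, panel, mode = c("per_dye", "pooled"),
                      b_max = 0.01) {
  mode <- match.arg(mode)
  pk <- profile$peaks
  pts <- do.call(rbind, lapply(unique(pk$marker), function(m) {
    l <- panel$loci[[m]]
    if (is.null(l)) stop("unknown locus '", m, "'")
    h <- pk$height[pk$marker == m]
    s <- pk$size[pk$marker == m]
    H <- locus_amplitude(h)
    if (H <= 0) return(NULL)
    data.frame(marker = m, dye = l$dye, sbar = weighted_mean_size(h, s),
               H = H, stringsAsFactors = FALSE)
  }))
  if (is.null(pts) || nrow(pts) < 2)
    stop("decay fit needs at least two loci with nonzero amplitude")
  fit1 <- function(g, dye, pooled) {
    co <- stats::coef(stats::lm(log(H) ~ sbar, data = g))
    B <- unname(co[2]); A <- exp(unname(co[1]))
    clamped <- FALSE
    if (!is.finite(B)) { B <- 0; A <- exp(mean(log(g$H))); clamped <- TRUE }
    if (B > b_max) {
      # noise-dominated profile implying amplitude growth with size:
      # refit amplitude at the clamp
      B <- b_max
      A <- exp(mean(log(g$H) - B * g$sbar))
      clamped <- TRUE
    }
    data.frame(dye = dye, A = A, B = B, n_loci = nrow(g), pooled = pooled,
               clamped = clamped, stringsAsFactors = FALSE)
  }
  if (mode == "pooled") {
    out <- fit1(pts, "*", TRUE)
  } else {
    out <- do.call(rbind, lapply(split(pts, pts$dye), function(g)
      if (nrow(g) >= 2) fit1(g, g$dye[1], FALSE)))
    have <- if (is.null(out)) character(0) else out$dye
    missing_dyes <- setdiff(unique(pts$dye), have)
    if (length(missing_dyes)) {
      pooled <- fit1(pts, "*", TRUE)
      out <- rbind(out, pooled)
    }
    rownames(out) <- NULL
  }
  structure(out, class = c("decay_fit", "data.frame"))
}

#' Evaluate the decayed amplitude at a fragment size
#'
#' The decayed amplitude `x = A * exp(B * s)` is the expected locus-level
#' signal a fragment of size `s` would produce given the profile's own decay
#' fit; it is the explanatory input of the amplitude-based peak-height and
#' drop-out models.
#'
#' @param fit a `decay_fit` (from [fit_decay()]).
#' @param s fragment size(s) in bp.
#' @param dye dye color to use; falls back to the pooled row (`"*"`) if that
#'   dye was not fitted.
#' @return decayed amplitude(s), RFU.
#' @export
decayed_amplitude <- function(fit, s, dye = NULL) {
  row <- NULL
  if (!is.null(dye)) {
    i <- which(fit$dye == dye)
    if (length(i)) row <- fit[i[1], ]
  }
  if (is.null(row)) {
    i <- which(fit$dye == "*")
    if (!length(i)) {
      if (nrow(fit) == 1L) i <- 1L
      else stop("no decay fit for dye '", dye, "' and no pooled fit")
    }
    row <- fit[i[1], ]
  }
  row$A * exp(row$B * s)
}

#' Convert a qPCR Degradation Index to a degradation rate
#'
#' The Degradation Index `q` is the ratio of qPCR quantification results for
#' a small (80 bp) and a large (214 bp) autosomal target. Under the Poisson
#' degradation model, `log(q) = -delta * lambda` with `delta = 134` bp. The
#' printed relation and the instrument convention (DI >= 1 for degraded
#' samples) disagree in sign, so the magnitude `|log q| / delta` is used and
#' the sign convention is recorded in the result.
#'
#' @param q Degradation Index (> 0).
#' @param delta target-size difference in bp (default 214 - 80 = 134).
#' @return list with `lambda` (degradation events per bp, >= 0) and
#'   `sign_convention`.
#' @export
di_to_lambda <- function(q, delta = 134) {
  if (!is.finite(q) || q <= 0) stop("Degradation Index must be > 0")
  list(lambda = abs(log(q)) / delta,
       sign_convention = "lambda = |log(q)| / delta")
}

#' Poisson survival probability of a target of length s
#' @param s target length (bp).
#' @param lambda degradation rate per bp (>= 0).
#' @return `exp(-lambda * s)`.
#' @export
survival_prob <- function(s, lambda) {
  stopifnot(lambda >= 0)
  exp(-lambda * s)
}

#' Explanatory input of a model family for classified observations
#'
#' Computes the scalar explanatory variable `x` that a model family regresses
#' on, per observation: the qPCR template amount (`c_dna`), its
#' size-decayed version, the undegraded amplitude `A`, the decayed amplitude
#' `A * exp(B * s)`, or the parent peak height `pph`. Families with a
#' locus-specific degradation parameter (`TP5`, `NP3`) apply their extra
#' scaling inside the family's mean/sd functions; here they receive the raw
#' `(A, B, s)` columns instead.
#'
#' @param family_id a model family id (see [model_families()]).
#' @param obs data.frame of observations; depending on the family it must
#'   carry columns `s`, `pph`, `A`, `B`, `c_dna`, `lambda`, `s1`.
#' @return numeric vector `x` (NA for families whose input is computed
#'   inside the family functions).
#' @export
model_input <- function(family_id, obs) {
  fam <- model_family(family_id)
  need <- function(cols) {
    miss <- setdiff(cols, names(obs))
    if (length(miss)) stop("family ", family_id,
                           " needs observation column(s): ",
                           paste(miss, collapse = ", "))
    if (any(!is.finite(as.matrix(obs[cols]))))
      stop("family ", family_id, ": missing values in required column(s) ",
           paste(cols, collapse = ", "))
  }
  switch(fam$input,
         c_dna = { need("c_dna"); obs$c_dna },
         template_decay = { need(c("c_dna", "lambda", "s", "s1"))
           obs$c_dna * exp(-obs$lambda * (obs$s - obs$s1)) },
         amplitude = { need("A"); obs$A },
         decayed_amplitude = { need(c("A", "B", "s"))
           obs$A * exp(obs$B * obs$s) },
         pph = { need("pph"); obs$pph },
         locus_decay = { need(c("A", "B", "s")); rep(NA_real_, nrow(obs)) },
         constant = rep(NA_real_, nrow(obs)),
         stop("unknown input rule for family ", family_id))
}

#' Attach decay fits and model inputs to classified observations
#'
#' Convenience wrapper: computes each profile's decay fit and adds `A`, `B`
#' (per observation, by dye) plus the decayed amplitude column `x` to a
#' classified-observation table.
#'
#' @param obs data.frame from [classify_peaks()]/[enumerate_dropouts()].
#' @param profiles named list of `str_profile` (names = sample ids).
#' @param panel an `str_panel`.
#' @param mode decay-fit mode, see [fit_decay()].
#' @return `obs` with columns `A`, `B`, `x` added.
#' @export
attach_decay_inputs <- function(obs, profiles, panel, mode = "pooled") {
  obs$A <- NA_real_; obs$B <- NA_real_
  for (sid in unique(obs$sample_id)) {
    p <- profiles[[sid]]
    if (is.null(p)) stop("no profile for sample '", sid, "'")
    fit <- fit_decay(p, panel, mode = mode)
    i <- which(obs$sample_id == sid)
    for (k in i) {
      row <- fit[match(obs$dye[k], fit$dye), ]
      if (is.na(row$A[1])) row <- fit[match("*", fit$dye), ]
      if (is.na(row$A[1])) row <- fit[1, ]
      obs$A[k] <- row$A; obs$B[k] <- row$B
    }
  }
  obs$x <- obs$A * exp(obs$B * obs$s)
  obs
}
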