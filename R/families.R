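## Model-family registry.
##
## Peak-height families are heteroscedastic Gaussians N(u(x), v(x)); the
## stutter-ratio family models r = h / PPh; drop-out families are Bernoulli
## with probability p(x). Families differ in their explanatory input x:
## qPCR template, size-decayed template, undegraded amplitude, decayed
## amplitude, or parent peak height. `mean`/`sd` take (theta, obs) where obs
## carries the precomputed column `x` and, for the locus-decay families, the
## raw columns `A`, `B`, `s`.

V_FLOOR <- 1e-3  # RFU floor keeping v(x) positive during optimization

affine_mean <- function(theta, obs) theta[1] * obs$x + theta[2]
affine_sd <- function(theta, obs) pmax.int(theta[3] * obs$x + theta[4], V_FLOOR)

locus_decay_x <- function(theta, obs) obs$A * exp(obs$B * obs$s / theta[5])

registry <- local({
  fams <- list()
  add <- function(id, kind, component, dim, input, mean = NULL, sd = NULL,
                  p = NULL, lower = NULL, upper = NULL, label = "") {
    fams[[id]] <<- list(id = id, kind = kind, component = component,
                        dim = dim, input = input, mean = mean, sd = sd,
                        p = p, lower = lower, upper = upper, label = label)
  }

  aff_lo <- c(-Inf, -Inf, -Inf, -Inf); aff_hi <- c(Inf, Inf, Inf, Inf)

  # --- allelic (true) peak height families -------------------------------
  add("TP1", "peak_height", "allele", 4, "c_dna", affine_mean, affine_sd,
      lower = aff_lo, upper = aff_hi, label = "DNA template")
  add("TP2", "peak_height", "allele", 4, "template_decay", affine_mean,
      affine_sd, lower = aff_lo, upper = aff_hi,
      label = "Degradation Index")
  add("TP3", "peak_height", "allele", 4, "amplitude", affine_mean,
      affine_sd, lower = aff_lo, upper = aff_hi,
      label = "undegraded amplitude")
  add("TP4", "peak_height", "allele", 4, "decayed_amplitude", affine_mean,
      affine_sd, lower = aff_lo, upper = aff_hi, label = "decayed amplitude")
  add("TP5", "peak_height", "allele", 5, "locus_decay",
      mean = function(theta, obs) {
        x <- locus_decay_x(theta, obs); theta[1] * x + theta[2]
      },
      sd = function(theta, obs) {
        x <- locus_decay_x(theta, obs)
        pmax.int(theta[3] * x + theta[4], V_FLOOR)
      },
      lower = c(-Inf, -Inf, -Inf, -Inf, 0.1),
      upper = c(Inf, Inf, Inf, Inf, 10),
      label = "decayed amplitude, locus-specific decay")

  # --- stutter peak height families --------------------------------------
  add("SP1", "peak_height", "stutter", 4, "pph", affine_mean, affine_sd,
      lower = aff_lo, upper = aff_hi, label = "affine on parent peak height")
  add("SP2", "peak_height", "stutter", 4, "decayed_amplitude", affine_mean,
      affine_sd, lower = aff_lo, upper = aff_hi,
      label = "affine on decayed amplitude")
  add("SR1", "stutter_ratio", "stutter", 5, "pph",
      mean = function(theta, obs)
        theta[1] * exp(-theta[2] * obs$x) + theta[3],
      sd = function(theta, obs)
        pmax.int(theta[4] * exp(-theta[2] * obs$x) + theta[5], 1e-6),
      lower = c(-Inf, 0, -Inf, -Inf, -Inf),
      upper = c(Inf, 1, Inf, Inf, Inf), label = "Gaussian stutter ratio")
  add("SPE1", "peak_height", "stutter", 5, "pph",
      mean = function(theta, obs)
        obs$x * (theta[1] * exp(-theta[2] * obs$x + theta[3])),
      sd = function(theta, obs)
        pmax.int(obs$x * (theta[4] * exp(-theta[2] * obs$x + theta[5])),
             V_FLOOR),
      lower = c(-Inf, 0, -Inf, -Inf, -Inf),
      upper = c(Inf, 1, Inf, Inf, Inf),
      label = "exponential on parent peak height")
  add("SPE2", "peak_height", "stutter", 7, "pph",
      mean = function(theta, obs)
        obs$x * (theta[1] * exp(-theta[2] * obs$x + theta[3])) + theta[6],
      sd = function(theta, obs)
        pmax.int(obs$x * (theta[4] * exp(-theta[2] * obs$x + theta[5])) +
               theta[7], V_FLOOR),
      lower = c(-Inf, 0, -Inf, -Inf, -Inf, -Inf, -Inf),
      upper = c(Inf, 1, Inf, Inf, Inf, Inf, Inf),
      label = "exponential on parent peak height, offset")
  add("SPE3", "peak_height", "stutter", 8, "pph",
      mean = function(theta, obs)
        obs$x * (theta[1] * exp(-theta[2] * obs$x + theta[3])) + theta[7],
      sd = function(theta, obs)
        pmax.int(obs$x * (theta[4] * exp(-theta[6] * obs$x + theta[5])) +
               theta[8], V_FLOOR),
      lower = c(-Inf, 0, -Inf, -Inf, -Inf, 0, -Inf, -Inf),
      upper = c(Inf, 1, Inf, Inf, Inf, 1, Inf, Inf),
      label = "exponential on parent peak height, separate decay rates")

  # --- noise peak height families ----------------------------------------
  add("NP1", "peak_height", "noise", 4, "amplitude", affine_mean, affine_sd,
      lower = aff_lo, upper = aff_hi, label = "undegraded amplitude")
  add("NP2", "peak_height", "noise", 4, "decayed_amplitude", affine_mean,
      affine_sd, lower = aff_lo, upper = aff_hi, label = "decayed amplitude")
  add("NP3", "peak_height", "noise", 5, "locus_decay",
      mean = function(theta, obs) {
        x <- locus_decay_x(theta, obs); theta[1] * x + theta[2]
      },
      sd = function(theta, obs) {
        x <- locus_decay_x(theta, obs)
        pmax.int(theta[3] * x + theta[4], V_FLOOR)
      },
      lower = c(-Inf, -Inf, -Inf, -Inf, 0.1),
      upper = c(Inf, Inf, Inf, Inf, 10),
      label = "decayed amplitude, locus-specific decay")

  # --- drop-out families -------------------------------------------------
  # exponential p(DO) = a * exp(-b x), clamped to [0, 1] at evaluation
  p_exp <- function(theta, obs)
    pmin(pmax(theta[1] * exp(-theta[2] * obs$x), 0), 1)
  exp_lo <- c(1e-8, 0); exp_hi <- c(1.5, Inf)
  # logistic p(DO) = 1 - 1 / (1 + exp(-b (x - a))) = plogis(-b (x - a))
  p_logis <- function(theta, obs) stats::plogis(-theta[2] * (obs$x - theta[1]))

  add("TDO1", "dropout", "allele_dropout", 2, "decayed_amplitude",
      p = p_exp, lower = exp_lo, upper = exp_hi,
      label = "exponential on decayed amplitude")
  add("TDO2", "dropout", "allele_dropout", 2, "decayed_amplitude",
      p = p_logis, lower = c(-Inf, 0), upper = c(Inf, Inf),
      label = "logistic on decayed amplitude")
  add("SDO1", "dropout", "stutter_dropout", 2, "pph",
      p = p_exp, lower = exp_lo, upper = exp_hi,
      label = "exponential on parent peak height")
  add("SDO2", "dropout", "stutter_dropout", 2, "decayed_amplitude",
      p = p_exp, lower = exp_lo, upper = exp_hi,
      label = "exponential on decayed amplitude")
  add("NDO1", "dropout", "noise_dropout", 2, "decayed_amplitude",
      p = p_exp, lower = exp_lo, upper = exp_hi,
      label = "exponential on decayed amplitude")
  add("NDO2", "dropout", "noise_dropout", 1, "constant",
      p = function(theta, obs) rep(pmin(pmax(theta[1], 0), 1),
                                   length(obs$x)),
      lower = 1e-8, upper = 1, label = "constant frequency")
  fams
})

#' The model-family registry
#'
#' Eighteen candidate families across the four peak components and their
#' drop-out counterparts: five allelic peak-height families (`TP1`-`TP5`),
#' five stutter families (`SP1`, `SP2`, `SR1`, `SPE1`-`SPE3`), three noise
#' families (`NP1`-`NP3`), and the drop-out families (`TDO1`, `TDO2`,
#' `SDO1`, `SDO2`, `NDO1`, `NDO2`). Peak-height families are heteroscedastic
#' Gaussians with mean `u(x; theta)` and standard deviation `v(x; theta)`;
#' the stutter-ratio family models `h / PPh`; drop-out families give a
#' Bernoulli probability `p(x; theta)`.
#'
#' @return named list of family definitions (id, kind, component, dim,
#'   input rule, mean/sd or p functions, box constraints).
#' @export
model_families <- function() registry

#' @rdname model_families
#' @export
family_ids <- function() names(registry)

#' @rdname model_families
#' @param id family id, e.g. `"TP4"`.
#' @export
model_family <- function(id) {
  f <- registry[[id]]
  if (is.null(f)) stop("unknown model family id: ", id,
                       " (known: ", paste(family_ids(), collapse = ", "), ")")
  f
}

#' Components a family applies to
#'
#' Maps a family's `component` slot to the classified-observation component
#' labels it is fitted on (`stutter` families pool reverse and forward
#' stutter observations).
#' @param fam a family definition from [model_family()].
#' @return character vector of component labels.
#' @export
family_components <- function(fam) {
  switch(fam$component,
         allele = "allele",
         stutter = c("reverse_stutter", "forward_stutter"),
         noise = "noise",
         allele_dropout = "allele",
         stutter_dropout = c("reverse_stutter", "forward_stutter"),
         noise_dropout = "noise")
}

#' The selected model set
#'
#' The family retained for each component after cross-validation model
#' selection: affine decayed-amplitude Gaussians for allelic and noise
#' peaks, affine parent-peak-height Gaussians for both stutters,
#' exponential drop-out on decayed amplitude for alleles, exponential
#' drop-out on parent peak height for stutters, and a constant noise
#' drop-out frequency.
#' @return named character vector component -> family id.
#' @export
selected_model_set <- function() {
  c(allele = "TP4", reverse_stutter = "SP1", forward_stutter = "SP1",
    noise = "NP2", allele_dropout = "TDO1", reverse_stutter_dropout = "SDO1",
    forward_stutter_dropout = "SDO1", noise_dropout = "NDO2")
}
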