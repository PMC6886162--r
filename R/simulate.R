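#' A small built-in STR panel for simulation and testing
#'
#' Nine autosomal tetranucleotide loci over three dye colors (three loci per
#' dye) plus a non-autosomal sex-typing locus, with ladders of ten alleles
#' each and fragment sizes spanning roughly 80-420 bp, mimicking the size
#' layout of a commercial autosomal STR multiplex.
#'
#' @param n_alleles ladder length per locus (default 10).
#' @return an `str_panel`.
#' @export
default_panel <- function(n_alleles = 10L) {
  dyes <- c("blue", "green", "yellow")
  base_sizes <- c(80, 190, 320, 95, 210, 340, 110, 230, 360)
  loci <- list()
  for (i in seq_len(9)) {
    lad <- data.frame(allele = as.character(5:(4 + n_alleles)),
                      size = base_sizes[i] + 4 * (0:(n_alleles - 1)))
    loci[[i]] <- list(name = paste0("L", i), dye = dyes[(i - 1) %/% 3 + 1],
                      repeat_len = 4, ladder = lad)
  }
  loci[[10]] <- list(name = "SEX", dye = "blue", repeat_len = 6,
                     ladder = data.frame(allele = c("X", "Y"),
                                         size = c(106.5, 112.5)),
                     is_autosomal = FALSE)
  str_panel(loci)
}

#' A synthetic fitted-parameter bundle for the selected model set
#'
#' Parameter values are synthetic: chosen to produce realistic-looking
#' profiles (allelic peaks near half the locus amplitude for a heterozygote,
#' reverse stutter near 8% and forward stutter near 2% of the parent peak,
#' rare low noise peaks, drop-out concentrated at low amplitude), not fitted
#' to any laboratory dataset. The locus key `"*"` applies each entry to
#' every locus.
#'
#' @param noise_dropout constant noise drop-out frequency (default 0.98).
#' @return a parameter bundle (`component -> locus -> list(family, theta)`).
#' @export
default_model_bundle <- function(noise_dropout = 0.98) {
  list(
    allele = list("*" = list(family = "TP4",
                             theta = c(0.5, 10, 0.05, 5))),
    reverse_stutter = list("*" = list(family = "SP1",
                                      theta = c(0.08, 2, 0.015, 2))),
    forward_stutter = list("*" = list(family = "SP1",
                                      theta = c(0.02, 1, 0.008, 1.5))),
    noise = list("*" = list(family = "NP2",
                            theta = c(0.005, 3, 0.003, 2))),
    allele_dropout = list("*" = list(family = "TDO1",
                                     theta = c(0.684, 0.0139))),
    reverse_stutter_dropout = list("*" = list(family = "SDO1",
                                              theta = c(0.9, 0.012))),
    forward_stutter_dropout = list("*" = list(family = "SDO1",
                                              theta = c(0.98, 0.008))),
    noise_dropout = list("*" = list(family = "NDO2", theta = noise_dropout))
  )
}

#' Simulation configuration
#'
#' @param panel an `str_panel`.
#' @param genotypes list of per-contributor genotypes (each a named list
#'   locus -> allele pair).
#' @param phi mixture fractions, one per contributor, summing to 1.
#' @param amplitude undegraded total amplitude `A` in RFU (signal scale of
#'   the whole sample before splitting by `phi`).
#' @param lambda per-contributor degradation rates (events per bp, >= 0);
#'   recycled.
#' @param bundle component-model parameter bundle (see
#'   [default_model_bundle()]).
#' @param at analytical threshold in RFU (default 1).
#' @param stutter simulate stutter components (default TRUE).
#' @param noise simulate noise components (default TRUE).
#' @return a `sim_config` list.
#' @export
sim_config <- function(panel, genotypes, phi = 1, amplitude = 2000,
                       lambda = 0, bundle = default_model_bundle(), at = 1,
                       stutter = TRUE, noise = TRUE) {
  if (!is.list(genotypes[[1]])) genotypes <- list(genotypes)
  n <- length(genotypes)
  phi <- rep_len(phi, n)
  if (abs(sum(phi) - 1) > 1e-9) stop("mixture fractions must sum to 1")
  lambda <- rep_len(lambda, n)
  if (any(lambda < 0)) stop("degradation rates must be >= 0")
  stopifnot(at >= 0, amplitude > 0)
  structure(list(panel = panel, genotypes = genotypes, phi = phi,
                 amplitude = amplitude, lambda = lambda, bundle = bundle,
                 at = at, stutter = stutter, noise = noise),
            class = "sim_config")
}

## Draw one truncated-Gaussian peak height: resample up to 100 times above
## the analytical threshold, then emit the threshold itself.
rheight <- function(u, v, at) {
  for (i in 1:100) {
    h <- stats::rnorm(1, u, v)
    if (h >= at) return(h)
  }
  at
}

eval_uv <- function(entry, x) {
  fam <- model_family(entry$family)
  obs <- list(x = x)
  list(u = fam$mean(entry$theta, obs), v = fam$sd(entry$theta, obs))
}

eval_pdo <- function(entry, x) {
  fam <- model_family(entry$family)
  fam$p(entry$theta, list(x = x))
}

#' Simulate one CE-STR profile
#'
#' Generative counterpart of the calibrated signal model. For every
#' contributor allele of size `s`, the contributor-level decayed amplitude
#' is `x = phi * A * exp(-lambda * s)`; the allelic peak survives with
#' probability `1 - p(allele drop-out | x)` and its height is Gaussian
#' `N(u(x), v(x))` truncated at the analytical threshold. Contributions of
#' different contributors at a shared position are drawn independently and
#' summed (amplicon counts add). Stutter positions fire against the
#' realized parent height, and every remaining candidate position of each
#' locus can emit a noise peak. A truth record labels every emitted peak
#' and every dropped position.
#'
#' @param config a `sim_config`.
#' @param sample_id sample identifier for the emitted profile.
#' @param dataset dataset label recorded in the truth table.
#' @return list with `profile` (an `str_profile`) and `truth` (data.frame
#'   of classified observations, drop-outs included, with the generating
#'   explanatory input in column `x_true`).
#' @export
simulate_profile <- function(config, sample_id = "sim1",
                             dataset = NA_character_) {
  panel <- config$panel
  bundle <- config$bundle
  n <- length(config$genotypes)
  tr_marker <- character(0); tr_dye <- character(0)
  tr_comp <- character(0); tr_allele <- character(0)
  tr_h <- numeric(0); tr_s <- numeric(0); tr_pph <- numeric(0)
  tr_x <- numeric(0); tr_copies <- integer(0)
  emit <- function(marker, dye, component, allele, size, h, pph, x_true,
                   copies = NA_integer_) {
    tr_marker[length(tr_marker) + 1L] <<- marker
    tr_dye[length(tr_dye) + 1L] <<- dye
    tr_comp[length(tr_comp) + 1L] <<- component
    tr_allele[length(tr_allele) + 1L] <<- allele
    tr_h[length(tr_h) + 1L] <<- h
    tr_s[length(tr_s) + 1L] <<- size
    tr_pph[length(tr_pph) + 1L] <<- pph
    tr_x[length(tr_x) + 1L] <<- x_true
    tr_copies[length(tr_copies) + 1L] <<- copies
  }
  loci <- intersect(names(panel$loci),
                    unique(unlist(lapply(config$genotypes, names))))
  for (m in loci) {
    locus <- panel$loci[[m]]
    lad <- locus$ladder
    # allele copies: each contributor carries two (possibly equal) alleles;
    # every copy contributes an independent amplicon pool of expected
    # decayed amplitude phi * A * exp(-lambda s)
    copies <- list()
    for (ci in seq_len(n)) {
      g <- config$genotypes[[ci]][[m]]
      if (is.null(g)) next
      for (a in g) copies[[a]] <- c(copies[[a]], ci)
    }
    allele_peaks <- list()
    for (a in names(copies)) {
      sz <- allele_size(panel, m, a)
      hsum <- 0; xsum <- 0
      for (ci in copies[[a]]) {
        x <- config$phi[ci] * config$amplitude *
          exp(-config$lambda[ci] * sz)
        xsum <- xsum + x
        pdo <- eval_pdo(bundle_entry(bundle, "allele_dropout", m), x)
        if (stats::runif(1) < pdo) next
        uv <- eval_uv(bundle_entry(bundle, "allele", m), x)
        hsum <- hsum + rheight(uv$u, uv$v, config$at)
      }
      emit(m, locus$dye, "allele", a, sz, hsum, NA_real_, xsum,
           length(copies[[a]]))
      allele_peaks[[a]] <- list(size = sz, h = hsum)
    }
    taken <- vapply(allele_peaks, function(p) p$size, numeric(1))
    # stutter positions: parent allele -/+ one repeat, against realized
    # PPh; a position claimed by an allele or an earlier stutter (reverse
    # precedes forward) is skipped
    stutter_taken <- numeric(0)
    if (isTRUE(config$stutter)) {
      for (dir in c(reverse_stutter = -1, forward_stutter = +1)) {
        comp <- names(which(c(reverse_stutter = -1,
                              forward_stutter = +1) == dir))
        for (a in names(allele_peaks)) {
          sz <- allele_peaks[[a]]$size + dir * locus$repeat_len
          if (any(abs(taken - sz) < 0.5) ||
              any(abs(stutter_taken - sz) < 0.5)) next
          stutter_taken <- c(stutter_taken, sz)
          pph <- allele_peaks[[a]]$h
          pdo <- eval_pdo(bundle_entry(bundle,
                                       paste0(comp, "_dropout"), m), pph)
          if (stats::runif(1) < pdo) {
            emit(m, locus$dye, comp, NA_character_, sz, 0, pph, pph)
          } else {
            uv <- eval_uv(bundle_entry(bundle, comp, m), pph)
            emit(m, locus$dye, comp, NA_character_, sz,
                 rheight(uv$u, uv$v, config$at), pph, pph)
          }
        }
      }
    }
    # noise candidates: ladder plus one-repeat flanks, minus allele and
    # stutter positions (observed or dropped)
    if (isTRUE(config$noise)) {
      used <- c(taken, stutter_taken)
      cand <- sort(unique(round(c(lad$size, lad$size - locus$repeat_len,
                                  lad$size + locus$repeat_len), 6)))
      cand <- cand[!vapply(cand, function(s) any(abs(used - s) <= 0.5),
                           logical(1))]
      # profile-level decayed amplitude at the candidate size
      for (sz in cand) {
        x <- sum(config$phi * config$amplitude *
                   exp(-config$lambda * sz))
        pdo <- eval_pdo(bundle_entry(bundle, "noise_dropout", m), x)
        if (stats::runif(1) < pdo) {
          emit(m, locus$dye, "noise", NA_character_, sz, 0, NA_real_, x)
        } else {
          uv <- eval_uv(bundle_entry(bundle, "noise", m), x)
          li <- which(abs(lad$size - sz) <= 0.5)
          emit(m, locus$dye, "noise",
               if (length(li)) lad$allele[li[1]] else "OL", sz,
               rheight(uv$u, uv$v, config$at), NA_real_, x)
        }
      }
    }
  }
  tr <- data.frame(sample_id = rep(sample_id, length(tr_h)),
                   dataset = rep(dataset, length(tr_h)),
                   marker = tr_marker, dye = tr_dye, component = tr_comp,
                   h = tr_h, s = tr_s, pph = tr_pph, x_true = tr_x,
                   copies = tr_copies, stringsAsFactors = FALSE)
  obs <- tr$h > 0
  pk <- data.frame(marker = tr_marker[obs], allele = tr_allele[obs],
                   size = tr_s[obs], height = tr_h[obs],
                   stringsAsFactors = FALSE)
  list(profile = str_profile(sample_id, pk), truth = tr)
}

#' Draw a random genotype from allele frequencies
#'
#' Two alleles per autosomal locus, drawn independently under
#' Hardy-Weinberg equilibrium (uniform over the ladder when no frequency
#' table is given).
#'
#' @param panel an `str_panel`.
#' @param freqs optional frequency table (see [read_frequencies()]).
#' @param loci loci to draw; default all autosomal panel loci.
#' @return named list locus -> character allele pair.
#' @export
random_genotype <- function(panel, freqs = NULL, loci = NULL) {
  if (is.null(loci))
    loci <- names(panel$loci)[vapply(panel$loci, function(l)
      isTRUE(l$is_autosomal), logical(1))]
  g <- lapply(loci, function(m) {
    if (!is.null(freqs) && !is.null(freqs[[m]]))
      sample(names(freqs[[m]]), 2, replace = TRUE, prob = freqs[[m]])
    else sample(panel$loci[[m]]$ladder$allele, 2, replace = TRUE)
  })
  stats::setNames(g, loci)
}

#' Simulate a calibration dataset of labeled observations
#'
#' Emulates a single-source calibration study: `n_profiles` profiles with
#' genotypes drawn under Hardy-Weinberg, template amplitudes and
#' degradation rates cycled over a condition grid, each simulated with
#' [simulate_profile()]. Observations carry their true component labels and
#' generating explanatory inputs (column `x`), bypassing classification, so
#' they can be fed directly to [fit_component()] and [cv_errors()].
#'
#' @param panel an `str_panel`.
#' @param n_profiles number of profiles.
#' @param amplitudes vector of undegraded amplitudes (RFU) cycled over
#'   profiles.
#' @param lambdas vector of degradation rates cycled over profiles.
#' @param bundle parameter bundle used for generation.
#' @param seed integer seed.
#' @param dataset dataset label.
#' @param freqs optional allele-frequency table for genotype draws.
#' @param loci loci to simulate (default: all autosomal).
#' @param noise,stutter passed to [sim_config()].
#' @return data.frame of classified observations (drop-outs as `h = 0`)
#'   with columns as in [classify_peaks()] plus `x` (true generating input)
#'   and `A`, `B` (true generating amplitude parameters).
#' @export
simulate_calibration_dataset <- function(panel, n_profiles = 100L,
                                         amplitudes = 2000,
                                         lambdas = c(0, 0.002, 0.005),
                                         bundle = default_model_bundle(),
                                         seed = 1L, dataset = "sim",
                                         freqs = NULL, loci = NULL,
                                         noise = TRUE, stutter = TRUE) {
  rng_local(seed, {
    out <- vector("list", n_profiles)
    for (i in seq_len(n_profiles)) {
      amp <- amplitudes[(i - 1) %% length(amplitudes) + 1]
      lam <- lambdas[(i - 1) %% length(lambdas) + 1]
      g <- random_genotype(panel, freqs, loci)
      cfg <- sim_config(panel, list(g), phi = 1, amplitude = amp,
                        lambda = lam, bundle = bundle, noise = noise,
                        stutter = stutter)
      sim <- simulate_profile(cfg, sample_id = sprintf("sim%04d", i),
                              dataset = dataset)
      tr <- sim$truth
      tr$x <- tr$x_true
      tr$A <- amp
      tr$B <- -lam
      out[[i]] <- tr
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
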