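#' Partition observations into k cross-validation folds
#'
#' Folds are formed over source samples, not individual observations: all
#' observations from one profile stay in the same fold, so a profile's peaks
#' never leak between training and test sets. Shuffled deterministically by
#' `seed`; fold sizes (in samples) differ by at most one.
#'
#' @param obs data.frame with a `sample_id` column.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold assignments (1..k), one per row of `obs`.
#' @export
kfold_partition <- function(obs, k, seed = 1L) {
  ids <- unique(obs$sample_id)
  if (length(ids) < k)
    stop("cannot make ", k, " folds from ", length(ids), " samples")
  perm <- rng_local(seed, sample(ids))
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(perm)),
                             perm)
  unname(fold_of[obs$sample_id])
}

#' Out-of-sample prediction errors of a family by k-fold cross-validation
#'
#' For each dataset and fold: the family is fitted on the other k-1 folds
#' and the appropriate log-likelihood `L` is evaluated on the held-out fold;
#' the prediction error is `L* = -L / N` with `N` the held-out observation
#' count. Stutter-ratio families are evaluated on the peak-height scale
#' (`L_h = L_r - sum log PPh`) so all stutter families are comparable.
#' Reverse- and forward-stutter observation sets enter as separate datasets,
#' which is why stutter families accumulate twice as many estimates.
#'
#' @param datasets named list of observation data.frames (one per dataset
#'   label), each carrying the columns the family needs plus `sample_id`,
#'   `h` and, for drop-out kinds, drop-out rows with `h = 0`.
#' @param family family definition or id.
#' @param k number of folds (default 10).
#' @param seed integer seed (fold assignment and fit starts).
#' @return a `cv_report`: list with `family`, `dim`, `errors` (data.frame
#'   dataset/fold/Lstar/N), `mu`, `sigma` (unbiased SD), `n_estimates`,
#'   `failed` (count of skipped folds).
#' @export
cv_errors <- function(datasets, family, k = 10L, seed = 1L) {
  fam <- if (is.character(family)) model_family(family) else family
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  rows <- list(); failed <- 0L
  for (ds in names(datasets)) {
    obs <- as.data.frame(datasets[[ds]])
    if (!"x" %in% names(obs) || all(is.na(obs$x)))
      obs$x <- model_input(fam$id, obs)
    folds <- kfold_partition(obs, k, seed = seed)
    for (f in seq_len(k)) {
      train <- obs[folds != f, , drop = FALSE]
      test <- obs[folds == f, , drop = FALSE]
      fit <- tryCatch(fit_component(train, fam, seed = seed,
                                    dataset = ds),
                      error = function(e) NULL)
      if (is.null(fit)) { failed <- failed + 1L; next }
      if (fam$kind == "dropout") {
        y <- as.integer(test$h == 0)
        if (fam$input == "pph")
          test$x <- ifelse(is.na(test$pph), 0, test$pph)
        N <- nrow(test)
        L <- heldout_loglik(fit, test$h, test$pph, y, test)
      } else {
        test <- test[test$h > 0, , drop = FALSE]
        if (fam$input == "pph")
          test <- test[!is.na(test$pph) & test$pph > 0, , drop = FALSE]
        N <- nrow(test)
        if (N == 0L) { failed <- failed + 1L; next }
        L <- heldout_loglik(fit, test$h, test$pph, NULL, test)
      }
      if (!is.finite(L)) { failed <- failed + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(dataset = ds, fold = f,
                                              Lstar = -L / N, N = N)
    }
  }
  errors <- do.call(rbind, rows)
  if (is.null(errors)) stop("cross-validation produced no usable folds for ",
                            fam$id)
  structure(list(family = fam$id, dim = fam$dim, errors = errors,
                 mu = mean(errors$Lstar), sigma = stats::sd(errors$Lstar),
                 n_estimates = nrow(errors), failed = failed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("CV %s (dim %d): L* = %.5g +/- %.3g over %d estimates%s\n",
              x$family, x$dim, x$mu, x$sigma, x$n_estimates,
              if (x$failed) paste0(" (", x$failed, " folds failed)") else ""))
  invisible(x)
}

#' One-standard-error model selection
#'
#' Given cross-validation reports for competing families, finds the family
#' with the lowest mean prediction error `mu(f_min)` and selects the most
#' parsimonious family (fewest free parameters) whose mean error is below
#' `mu(f_min) + sigma(f_min)`. Ties at equal dimension are broken by lower
#' mean error, then by report order (a fixed precedence standing in for
#' scientific preference between statistically indistinguishable models).
#'
#' @param reports list of `cv_report` objects.
#' @return the selected family id, with the candidate summary attached as
#'   attribute `"summary"`.
#' @export
select_model <- function(reports) {
  stopifnot(length(reports) >= 1)
  mu <- vapply(reports, function(r) r$mu, numeric(1))
  dim <- vapply(reports, function(r) r$dim, numeric(1))
  fam <- vapply(reports, function(r) r$family, character(1))
  i_min <- which.min(mu)
  thr <- mu[i_min] + reports[[i_min]]$sigma
  ok <- which(mu < thr)
  sel <- ok[order(dim[ok], mu[ok], ok)][1]
  structure(fam[sel],
            summary = data.frame(family = fam, dim = dim, mu = mu,
                                 threshold = thr, admissible =
                                   seq_along(fam) %in% ok,
                                 selected = seq_along(fam) == sel))
}
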