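#' Pull-up filtering parameters
#'
#' Pull-up is spectral bleed-through: a tall peak in one dye induces a small
#' spurious peak at the same size in another dye. A peak is flagged as
#' pull-up when a much taller peak sits in a different dye within a small
#' size window. Complex pull-up additionally requires tall peaks in at least
#' two other dyes plus a same-dye "sister" peak of comparable height within
#' the window.
#'
#' @param pullup_ratio max height ratio (pulled / tall) for simple pull-up.
#' @param pullup_window size window in bp for simple pull-up.
#' @param complex_ratio max height ratio for complex pull-up.
#' @param sister_ratio min sister/peak height ratio for complex pull-up.
#' @param complex_window size window in bp for complex pull-up.
#' @return a `pullup_params` list.
#' @export
pullup_params <- function(pullup_ratio = 0.06, pullup_window = 0.6,
                          complex_ratio = 0.06, sister_ratio = 0.50,
                          complex_window = 0.3) {
  stopifnot(pullup_ratio > 0, pullup_ratio < 1, pullup_window > 0,
            complex_ratio > 0, complex_ratio < 1, sister_ratio > 0,
            sister_ratio < 1, complex_window > 0)
  structure(list(pullup_ratio = pullup_ratio, pullup_window = pullup_window,
                 complex_ratio = complex_ratio, sister_ratio = sister_ratio,
                 complex_window = complex_window), class = "pullup_params")
}

#' Remove pull-up and complex pull-up artifacts from a profile
#'
#' Both rules are evaluated against the original (pre-filter) peak set, so
#' removal of one peak never rescues another.
#'
#' @param profile an `str_profile`.
#' @param panel an `str_panel` supplying the dye of each locus.
#' @param params a `pullup_params` object.
#' @return list with `profile` (filtered) and `removed` (data.frame of
#'   removed peaks with the triggering `rule`).
#' @export
filter_pullup <- function(profile, panel, params = pullup_params()) {
  pk <- profile$peaks
  if (!nrow(pk)) return(list(profile = profile,
                             removed = cbind(pk, rule = character(0))))
  dye <- vapply(pk$marker, function(m) {
    l <- panel$loci[[m]]
    if (is.null(l)) stop("unknown locus '", m, "'; panel loci: ",
                         paste(names(panel$loci), collapse = ", "))
    l$dye
  }, character(1))
  n <- nrow(pk)
  rule <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ds <- abs(pk$size - pk$size[i])
    # complex pull-up first (the more specific diagnosis): >= 2 other dyes
    # with tall peaks in the tight window, plus a same-dye sister of
    # comparable height
    inwin <- ds <= params$complex_window & seq_len(n) != i
    other <- inwin & dye != dye[i]
    if (length(unique(dye[other])) >= 2) {
      tallest <- max(pk$height[other])
      sister <- inwin & dye == dye[i] &
        pk$height >= params$sister_ratio * pk$height[i]
      if (pk$height[i] / tallest <= params$complex_ratio && any(sister)) {
        rule[i] <- "complex_pullup"; next
      }
    }
    # simple pull-up: a taller peak in another dye within the window
    cand <- dye != dye[i] & ds <= params$pullup_window &
      pk$height[i] / pk$height <= params$pullup_ratio
    if (any(cand)) rule[i] <- "pullup"
  }
  keep <- is.na(rule)
  removed <- cbind(pk[!keep, , drop = FALSE], rule = rule[!keep])
  rownames(removed) <- NULL
  out <- profile
  out$peaks <- pk[keep, , drop = FALSE]
  rownames(out$peaks) <- NULL
  list(profile = out, removed = removed)
}

## Candidate position universe of a locus for a given genotype:
## every ladder position plus the +/- one-repeat flanks of ladder positions,
## labeled by precedence allele > reverse stutter > forward stutter > noise.
locus_positions <- function(locus, geno_alleles, window = 0.5) {
  lad <- locus$ladder
  rep_len <- locus$repeat_len
  sizes <- sort(unique(round(c(lad$size, lad$size - rep_len,
                               lad$size + rep_len), 6)))
  g <- unique(as.character(geno_alleles))
  gi <- match(g, lad$allele)
  if (anyNA(gi)) stop("locus ", locus$name, ": genotype allele(s) ",
                      paste(g[is.na(gi)], collapse = ","), " not in ladder")
  asz <- lad$size[gi]
  pos <- data.frame(size = sizes, component = "noise",
                    parent_size = NA_real_, allele = NA_character_,
                    stringsAsFactors = FALSE)
  near <- function(x, y) abs(x - y) <= window
  for (k in seq_along(asz)) {
    i <- which(near(pos$size, asz[k] + rep_len) & pos$component == "noise")
    pos$component[i] <- "forward_stutter"; pos$parent_size[i] <- asz[k]
  }
  for (k in seq_along(asz)) {
    i <- which(near(pos$size, asz[k] - rep_len) &
                 pos$component %in% c("noise", "forward_stutter"))
    pos$component[i] <- "reverse_stutter"; pos$parent_size[i] <- asz[k]
  }
  for (k in seq_along(asz)) {
    i <- which(near(pos$size, asz[k]))
    pos$component[i] <- "allele"; pos$parent_size[i] <- NA
    pos$allele[i] <- g[k]
  }
  li <- vapply(pos$size, function(s) {
    j <- which(near(lad$size, s)); if (length(j)) lad$allele[j[1]]
    else NA_character_ }, character(1))
  pos$allele <- ifelse(is.na(pos$allele), li, pos$allele)
  pos
}

#' Classify observed peaks against a known genotype
#'
#' Every retained peak is assigned exactly one component by size-window
#' matching with precedence allele > reverse stutter > forward stutter >
#' noise: within `window` bp of a genotype-allele ladder size it is an
#' allele peak; within `window` of (allele size - repeat length) a reverse
#' stutter; within `window` of (allele size + repeat length) a forward
#' stutter; anything else is noise. Stutter observations carry the observed
#' parent-allele peak height `pph` (0 if the parent dropped out).
#'
#' @param profile an `str_profile` (already pull-up filtered).
#' @param genotype per-locus genotype: named list of allele pairs.
#' @param panel an `str_panel`.
#' @param window matching half-window in bp (default 0.5).
#' @param dataset dataset label attached to the observations.
#' @return data.frame of classified observations with columns `sample_id`,
#'   `dataset`, `marker`, `dye`, `component`, `h`, `s`, `pph`.
#' @export
classify_peaks <- function(profile, genotype, panel, window = 0.5,
                           dataset = NA_character_) {
  pk <- profile$peaks
  loci <- unique(pk$marker)
  miss <- setdiff(loci, names(genotype))
  if (length(miss)) stop("genotype missing locus: ",
                         paste(miss, collapse = ", "))
  out <- lapply(loci, function(m) {
    locus <- panel$loci[[m]]
    if (is.null(locus)) stop("unknown locus '", m, "'")
    pos <- locus_positions(locus, genotype[[m]], window)
    p <- pk[pk$marker == m, , drop = FALSE]
    comp <- rep("noise", nrow(p))
    parent <- rep(NA_real_, nrow(p))
    for (i in seq_len(nrow(p))) {
      d <- abs(pos$size - p$size[i])
      j <- which(d <= window)
      if (length(j)) {
        j <- j[order(match(pos$component[j],
                           c("allele", "reverse_stutter", "forward_stutter",
                             "noise")), d[j])][1]
        comp[i] <- pos$component[j]
        parent[i] <- pos$parent_size[j]
      }
    }
    pph <- rep(NA_real_, nrow(p))
    st <- comp %in% c("reverse_stutter", "forward_stutter")
    for (i in which(st)) {
      pj <- which(comp == "allele" & abs(p$size - parent[i]) <= window)
      pph[i] <- if (length(pj)) sum(p$height[pj]) else 0
    }
    data.frame(sample_id = profile$sample_id, dataset = dataset, marker = m,
               dye = locus$dye, component = comp, h = p$height, s = p$size,
               pph = pph, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample_id = character(0), dataset = character(0),
                      marker = character(0), dye = character(0),
                      component = character(0), h = numeric(0),
                      s = numeric(0), pph = numeric(0))
  rownames(res) <- NULL
  res
}

#' Enumerate drop-out positions of a profile
#'
#' For every candidate position of each locus with no observed peak within
#' the matching window, emits one observation with height 0: allele drop-out
#' for unmatched genotype alleles (one position per distinct allele), stutter
#' drop-out for unmatched parent-allele +/- one-repeat positions (with `pph`
#' = observed parent height, 0 if the parent itself dropped), and noise
#' drop-out for every remaining candidate position (the locus ladder plus
#' its one-repeat flanks, minus allele and stutter positions).
#'
#' @inheritParams classify_peaks
#' @param loci loci to enumerate; defaults to every locus in the genotype
#'   that the panel knows.
#' @return data.frame in the same layout as [classify_peaks()] with `h = 0`
#'   and component one of `allele`, `reverse_stutter`, `forward_stutter`,
#'   `noise`.
#' @export
enumerate_dropouts <- function(profile, genotype, panel, window = 0.5,
                               dataset = NA_character_, loci = NULL) {
  if (is.null(loci))
    loci <- intersect(names(genotype), names(panel$loci))
  pk <- profile$peaks
  out <- lapply(loci, function(m) {
    locus <- panel$loci[[m]]
    pos <- locus_positions(locus, genotype[[m]], window)
    p <- pk[pk$marker == m, , drop = FALSE]
    matched <- vapply(pos$size, function(s)
      any(abs(p$size - s) <= window), logical(1))
    pos <- pos[!matched, , drop = FALSE]
    if (!nrow(pos)) return(NULL)
    pph <- rep(NA_real_, nrow(pos))
    st <- pos$component %in% c("reverse_stutter", "forward_stutter")
    for (i in which(st)) {
      pj <- which(abs(p$size - pos$parent_size[i]) <= window)
      pph[i] <- if (length(pj)) sum(p$height[pj]) else 0
    }
    data.frame(sample_id = profile$sample_id, dataset = dataset, marker = m,
               dye = locus$dye, component = pos$component, h = 0,
               s = pos$size, pph = pph, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample_id = character(0), dataset = character(0),
                      marker = character(0), dye = character(0),
                      component = character(0), h = numeric(0),
                      s = numeric(0), pph = numeric(0))
  rownames(res) <- NULL
  res
}
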