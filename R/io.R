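#' Profiles, genotype tables, frequencies and parameter bundles
#'
#' A profile is one sample's observed electropherogram: a peak table with one
#' row per peak (locus, allele designation, fragment size in bp, height in
#' RFU) plus sample-level metadata. Peak heights are strictly positive for
#' observed peaks; drop-out is represented downstream as height 0, never in
#' the peak table itself.
#'
#' @param sample_id sample identifier.
#' @param peaks data.frame with columns `marker`, `allele`, `size`, `height`.
#' @param kit amplification kit label (e.g. `"GF"`).
#' @param injection_s CE injection time in seconds.
#' @param c_dna template DNA amount in ng (qPCR), optional.
#' @param di qPCR Degradation Index, optional (must be > 0 when given).
#' @return an object of class `str_profile`.
#' @export
str_profile <- function(sample_id, peaks, kit = NA_character_,
                        injection_s = NA_real_, c_dna = NA_real_,
                        di = NA_real_) {
  peaks <- as.data.frame(peaks)
  need <- c("marker", "allele", "size", "height")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peak table missing column(s): ",
                         paste(miss, collapse = ", "))
  peaks$marker <- as.character(peaks$marker)
  peaks$allele <- as.character(peaks$allele)
  peaks$size <- as.numeric(peaks$size)
  peaks$height <- as.numeric(peaks$height)
  if (nrow(peaks) && (any(peaks$height <= 0) || any(peaks$size <= 0)))
    stop("observed peaks must have positive size and height")
  if (!is.na(di) && di <= 0) stop("Degradation Index must be > 0")
  structure(list(sample_id = as.character(sample_id), kit = kit,
                 injection_s = injection_s, c_dna = c_dna, di = di,
                 peaks = peaks[need]),
            class = "str_profile")
}

#' @export
print.str_profile <- function(x, ...) {
  cat(sprintf("STR profile '%s': %d peaks over %d loci\n", x$sample_id,
              nrow(x$peaks), length(unique(x$peaks$marker))))
  invisible(x)
}

#' Read genotype tables exported as CSV
#'
#' Reads the per-peak tables exported by CE analysis software. Two dialects
#' are supported: `long` (one row per peak, columns
#' `Sample,Marker,Allele,Size,Height`) and `wide` (one row per sample-marker,
#' repeated `Allele i / Size i / Height i` column triplets, empty cells
#' skipped).
#'
#' @param path CSV path.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param panel optional `str_panel`; when given, loci are validated against
#'   it.
#' @return a list of `str_profile`, one per distinct sample identifier, peaks
#'   kept in file order within each locus.
#' @export
read_genotype_table <- function(path, dialect = c("long", "wide"),
                                panel = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype table not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (dialect == "long") {
    need <- c("Sample", "Marker", "Allele", "Size", "Height")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("missing required column(s): ",
                           paste(miss, collapse = ", "))
    long <- data.frame(sample = d$Sample, marker = d$Marker,
                       allele = d$Allele, size = d$Size, height = d$Height,
                       line = seq_len(nrow(d)) + 1L,
                       stringsAsFactors = FALSE)
  } else {
    if (!all(c("Sample", "Marker") %in% names(d)))
      stop("missing required column(s): ",
           paste(setdiff(c("Sample", "Marker"), names(d)), collapse = ", "))
    idx <- grep("^Allele ?[0-9]+$", names(d))
    if (!length(idx)) stop("missing required column(s): Allele 1")
    rows <- list()
    for (i in seq_len(nrow(d))) {
      for (j in idx) {
        n <- sub("^Allele ?", "", names(d)[j])
        a <- d[i, j]
        if (is.na(a) || !nzchar(a)) next
        scol <- grep(paste0("^Size ?", n, "$"), names(d))
        hcol <- grep(paste0("^Height ?", n, "$"), names(d))
        if (!length(scol) || !length(hcol))
          stop("missing required column(s): Size ", n, " / Height ", n)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = d$Sample[i], marker = d$Marker[i], allele = a,
          size = d[i, scol], height = d[i, hcol], line = i + 1L,
          stringsAsFactors = FALSE)
      }
    }
    long <- do.call(rbind, rows)
    if (is.null(long)) long <- data.frame(sample = character(0),
                                          marker = character(0),
                                          allele = character(0),
                                          size = character(0),
                                          height = character(0),
                                          line = integer(0))
  }
  size <- suppressWarnings(as.numeric(long$size))
  height <- suppressWarnings(as.numeric(long$height))
  bad <- which(is.na(size) | is.na(height))
  if (length(bad))
    stop("non-numeric Size/Height at line ", long$line[bad[1]], " of ", path)
  long$size <- size
  long$height <- height
  if (!is.null(panel)) {
    unk <- setdiff(unique(long$marker), names(panel$loci))
    if (length(unk))
      stop("unknown locus '", unk[1], "'; panel loci: ",
           paste(names(panel$loci), collapse = ", "))
  }
  lapply(split(long, factor(long$sample, levels = unique(long$sample))),
         function(g) str_profile(g$sample[1],
                                 g[c("marker", "allele", "size", "height")]))
}

#' Write profiles to a long-dialect CSV
#' @param profiles a list of `str_profile` (or a single profile).
#' @param path output CSV path.
#' @export
write_genotype_table <- function(profiles, path) {
  if (inherits(profiles, "str_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p)
    if (nrow(p$peaks)) cbind(Sample = p$sample_id,
                             stats::setNames(p$peaks, c("Marker", "Allele",
                                                        "Size", "Height")))))
  if (is.null(rows))
    rows <- data.frame(Sample = character(0), Marker = character(0),
                       Allele = character(0), Size = numeric(0),
                       Height = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read known genotypes
#'
#' CSV with columns `Sample,Marker,Allele1,Allele2` (a homozygote repeats the
#' allele). Returned as a nested list: `genotypes[[sample]][[marker]]` is an
#' unordered character pair.
#'
#' @param path CSV path.
#' @return named list of per-sample genotypes.
#' @export
read_genotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("Sample", "Marker", "Allele1", "Allele2")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(d)))
    out[[d$Sample[i]]][[d$Marker[i]]] <- c(d$Allele1[i], d$Allele2[i])
  out
}

#' Read a population allele-frequency table
#'
#' CSV with columns `Marker,Allele,Frequency`. Frequencies must be positive;
#' per-locus sums may be renormalized to 1.
#'
#' @param path CSV path.
#' @param renormalize divide each locus by its frequency sum (default `TRUE`).
#' @return named list: per locus, a named numeric vector of allele
#'   frequencies.
#' @export
read_frequencies <- function(path, renormalize = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Marker", "Allele", "Frequency")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  d$Frequency <- as.numeric(d$Frequency)
  if (any(!is.finite(d$Frequency)) || any(d$Frequency <= 0))
    stop("allele frequencies must be positive")
  freqs <- lapply(split(d, d$Marker), function(g)
    stats::setNames(g$Frequency, as.character(g$Allele)))
  frequency_table(freqs, renormalize = renormalize)
}

#' Build/validate a frequency table from a named list
#' @param freqs named list of named numeric vectors (per-locus allele
#'   frequencies).
#' @param renormalize rescale each locus to sum to 1.
#' @return validated frequency table (named list).
#' @export
frequency_table <- function(freqs, renormalize = TRUE) {
  out <- lapply(freqs, function(f) {
    if (any(f <= 0)) stop("allele frequencies must be positive")
    if (renormalize) f <- f / sum(f)
    if (abs(sum(f) - 1) > 1e-6)
      stop("per-locus frequencies must sum to 1 (within 1e-6); use ",
           "renormalize = TRUE")
    f
  })
  out
}

#' Read/write fitted model-parameter bundles
#'
#' A bundle stores, per dataset label, per model component, per locus, the
#' selected model family id and its maximum-likelihood parameter vector. The
#' locus key `"*"` acts as a wildcard applying to every locus. Written as
#' JSON; `read_model_params(write_model_params(b, p))` returns an equal
#' bundle.
#'
#' @param bundle nested list `dataset -> component -> locus ->
#'   list(family, theta)`.
#' @param path JSON path.
#' @return `read_model_params`: the bundle; `write_model_params`: `path`,
#'   invisibly.
#' @export
write_model_params <- function(bundle, path) {
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  b <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(b, function(ds) lapply(ds, function(comp) lapply(comp, function(m) {
    if (is.null(m$family) || !(m$family %in% family_ids()))
      stop("unknown model family id: ", if (is.null(m$family)) "<missing>"
           else m$family)
    list(family = m$family, theta = as.numeric(unlist(m$theta)))
  })))
}

#' Look up the model entry for one component and locus in a bundle
#' @param bundle a parameter bundle (one dataset level already selected, i.e.
#'   `component -> locus -> entry`).
#' @param component component name.
#' @param marker locus name.
#' @return `list(family, theta)`.
#' @export
bundle_entry <- function(bundle, component, marker) {
  comp <- bundle[[component]]
  if (is.null(comp)) stop("parameter bundle missing component '", component,
                          "'")
  e <- comp[[marker]]
  if (is.null(e)) e <- comp[["*"]]
  if (is.null(e)) stop("parameter bundle missing locus '", marker,
                       "' for component '", component, "'")
  e
}
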