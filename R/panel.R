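#' STR panel (multiplex) definitions
#'
#' A panel describes the STR multiplex used to generate a profile: the loci,
#' the dye color each locus is labeled with, the repeat-unit length, and the
#' allelic ladder (allele designation and fragment size in bp) for each locus.
#' The smallest autosomal ladder size across the panel, `s1`, is the reference
#' length used by template-decay explanatory variables.
#'
#' @param loci a list of locus definitions; each element is a list with fields
#'   `name`, `dye`, `repeat_len`, `ladder` (data.frame with columns `allele`,
#'   `size`), optional `size_range` (length-2 numeric) and `is_autosomal`
#'   (default `TRUE`).
#' @return an object of class `str_panel`: a list with `loci` (named list) and
#'   `s1` (smallest autosomal ladder size, bp).
#' @export
str_panel <- function(loci) {
  if (length(loci) == 0L) stop("panel must contain at least one locus")
  names(loci) <- vapply(loci, function(l) as.character(l$name), character(1))
  if (anyDuplicated(names(loci)))
    stop("duplicate locus in panel: ",
         paste(unique(names(loci)[duplicated(names(loci))]), collapse = ", "))
  loci <- lapply(loci, validate_panel_locus)
  auto_sizes <- unlist(lapply(loci, function(l)
    if (isTRUE(l$is_autosomal)) l$ladder$size else numeric(0)))
  if (length(auto_sizes) == 0L)
    stop("panel has no autosomal locus; cannot define smallest target size")
  structure(list(loci = loci, s1 = min(auto_sizes)), class = "str_panel")
}

validate_panel_locus <- function(l) {
  stopifnot(is.list(l), !is.null(l$name), !is.null(l$dye))
  l$name <- as.character(l$name)
  l$dye <- as.character(l$dye)
  l$repeat_len <- as.numeric(l$repeat_len)
  if (is.na(l$repeat_len) || l$repeat_len < 1 || l$repeat_len > 7)
    stop("locus ", l$name, ": repeat unit length must be in [1, 7] bp, got ",
         l$repeat_len)
  lad <- as.data.frame(l$ladder)
  if (!all(c("allele", "size") %in% names(lad)))
    stop("locus ", l$name, ": ladder needs columns 'allele' and 'size'")
  lad$allele <- as.character(lad$allele)
  lad$size <- as.numeric(lad$size)
  if (any(!is.finite(lad$size)) || any(lad$size <= 0))
    stop("locus ", l$name, ": ladder sizes must be positive")
  if (is.unsorted(lad$size, strictly = TRUE))
    stop("locus ", l$name, ": ladder sizes must be strictly increasing")
  l$ladder <- lad
  if (is.null(l$is_autosomal)) l$is_autosomal <- TRUE
  if (is.null(l$size_range))
    l$size_range <- c(min(lad$size) - 2 * l$repeat_len,
                      max(lad$size) + 2 * l$repeat_len)
  l$size_range <- as.numeric(l$size_range)
  if (any(lad$size < l$size_range[1] | lad$size > l$size_range[2]))
    stop("locus ", l$name, ": ladder sizes outside declared size range")
  l
}

#' @export
print.str_panel <- function(x, ...) {
  cat("STR panel:", length(x$loci), "loci, s1 =", x$s1, "bp\n")
  for (l in x$loci)
    cat(sprintf("  %-12s dye=%-8s repeat=%g bp  alleles=%d%s\n", l$name,
                l$dye, l$repeat_len, nrow(l$ladder),
                if (isTRUE(l$is_autosomal)) "" else "  [non-autosomal]"))
  invisible(x)
}

#' Read a panel definition from JSON
#'
#' The JSON carries a `loci` array; each entry has `name`, `dye`,
#' `repeat_len`, a `ladder` array of `{allele, size}` objects, and optional
#' `size_range` and `is_autosomal` fields.
#'
#' @param path path to the JSON panel file.
#' @return an `str_panel` object.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$loci)) stop("panel JSON must contain a 'loci' array")
  loci <- lapply(raw$loci, function(e) {
    lad <- do.call(rbind, lapply(e$ladder, function(r)
      data.frame(allele = as.character(r$allele), size = as.numeric(r$size),
                 stringsAsFactors = FALSE)))
    list(name = e$name, dye = e$dye, repeat_len = e$repeat_len, ladder = lad,
         size_range = if (!is.null(e$size_range)) unlist(e$size_range),
         is_autosomal = if (!is.null(e$is_autosomal)) e$is_autosomal else TRUE)
  })
  str_panel(loci)
}

#' Write a panel definition to JSON
#' @param panel an `str_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  loci <- lapply(unname(panel$loci), function(l)
    list(name = l$name, dye = l$dye, repeat_len = l$repeat_len,
         ladder = lapply(seq_len(nrow(l$ladder)), function(i)
           list(allele = l$ladder$allele[i], size = l$ladder$size[i])),
         size_range = l$size_range, is_autosomal = l$is_autosomal))
  jsonlite::write_json(list(loci = loci), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Ladder size of an allele designation at a locus
#' @param panel an `str_panel`.
#' @param marker locus name.
#' @param allele allele designation (character).
#' @return fragment size in bp.
#' @export
allele_size <- function(panel, marker, allele) {
  l <- panel$loci[[marker]]
  if (is.null(l)) stop("unknown locus '", marker, "'; panel loci: ",
                       paste(names(panel$loci), collapse = ", "))
  i <- match(as.character(allele), l$ladder$allele)
  if (anyNA(i)) stop("allele ", paste(allele[is.na(i)], collapse = ","),
                     " not in ladder of locus ", marker)
  l$ladder$size[i]
}
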