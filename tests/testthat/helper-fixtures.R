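# Shared fixtures: a tiny two-locus panel (alleles 8..14, tetranucleotide,
# allele 10 of L1 at 146 bp) and independent brute-force likelihood oracles.

tiny_panel <- function() {
  lad1 <- data.frame(allele = as.character(8:14), size = 138 + 4 * (0:6))
  lad2 <- data.frame(allele = as.character(8:14), size = 250 + 4 * (0:6))
  str_panel(list(
    list(name = "L1", dye = "blue", repeat_len = 4, ladder = lad1),
    list(name = "L2", dye = "green", repeat_len = 4, ladder = lad2)))
}

# direct-summation oracles, deliberately written as plain loops
oracle_Lh <- function(h, u, v) {
  s <- 0
  for (i in seq_along(h)) s <- s - log(v[i]) - (h[i] - u[i])^2 / (2 * v[i]^2)
  s
}

oracle_Ldo <- function(y, p) {
  s <- 0
  for (i in seq_along(y)) s <- s + log(p[i] * y[i] + (1 - p[i]) * (1 - y[i]))
  s
}

affine_u <- function(theta, x) theta[1] * x + theta[2]
affine_v <- function(theta, x) theta[3] * x + theta[4]

write_tmp_csv <- function(df, name = "f.csv") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}
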