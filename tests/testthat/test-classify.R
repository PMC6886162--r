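# classification of peaks against a known genotype, pull-up filtering, and
# drop-out enumeration

test_that("pull-up filter removes low cross-dye peaks at matching sizes", {
  panel <- tiny_panel()
  p <- str_profile("S1", data.frame(
    marker = c("L1", "L2"), allele = c("11", "OL"),
    size = c(150.0, 150.3), height = c(1000, 50)))
  res <- filter_pullup(p, panel)
  expect_equal(nrow(res$removed), 1L)
  expect_equal(res$removed$height, 50)
  expect_equal(res$removed$rule, "pullup")
  expect_equal(res$profile$peaks$height, 1000)

  # 9% ratio survives the 6% threshold
  p2 <- str_profile("S2", data.frame(
    marker = c("L1", "L2"), allele = c("11", "OL"),
    size = c(150.0, 150.3), height = c(1000, 90)))
  res2 <- filter_pullup(p2, panel)
  expect_equal(nrow(res2$removed), 0L)

  # a single-dye profile passes through unchanged
  p3 <- str_profile("S3", data.frame(
    marker = c("L1", "L1"), allele = c("10", "11"),
    size = c(146, 150), height = c(40, 900)))
  expect_equal(filter_pullup(p3, panel)$profile$peaks, p3$peaks)
})

test_that("complex pull-up needs two other dyes plus a sister peak", {
  lad <- data.frame(allele = as.character(8:14), size = 138 + 4 * (0:6))
  panel <- str_panel(list(
    list(name = "B1", dye = "blue", repeat_len = 4, ladder = lad),
    list(name = "G1", dye = "green", repeat_len = 4, ladder = lad),
    list(name = "Y1", dye = "yellow", repeat_len = 4, ladder = lad)))
  mk <- function(...) str_profile("S", data.frame(...))
  # tall blue + tall green within 0.3 bp, small yellow with a sister
  p <- mk(marker = c("B1", "G1", "Y1", "Y1"),
          allele = c("11", "11", "OL", "OL"),
          size = c(150.0, 150.1, 150.2, 150.15),
          height = c(2000, 1500, 40, 30))
  res <- filter_pullup(p, panel)
  expect_true("complex_pullup" %in% res$removed$rule)
  # without the sister only the simple single-dye rule applies
  p2 <- mk(marker = c("B1", "G1", "Y1"), allele = c("11", "11", "OL"),
           size = c(150.0, 150.1, 150.2), height = c(2000, 1500, 40))
  expect_equal(filter_pullup(p2, panel)$removed$rule, "pullup")
})

test_that("peaks classify by size window with allele > stutter precedence", {
  panel <- tiny_panel()
  # genotype {10, 12}; allele 10 at 146 bp, allele 12 at 154 bp
  g <- list(L1 = c("10", "12"))
  p <- str_profile("S1", data.frame(
    marker = "L1", allele = c("10", "9", "12", "OL"),
    size = c(146.2, 142.1, 154.0, 148.0),
    height = c(800, 60, 700, 9)))
  obs <- classify_peaks(p, g, panel)
  expect_equal(obs$component[obs$s == 146.2], "allele")
  expect_equal(obs$component[obs$s == 142.1], "reverse_stutter")
  expect_equal(obs$pph[obs$s == 142.1], 800)
  # the N+2 position between the two alleles is noise
  expect_equal(obs$component[obs$s == 148.0], "noise")
  # allele 12's reverse-stutter position (150) collides with nothing here;
  # allele 10's forward (150) vs 12's reverse (150): reverse wins
  p2 <- str_profile("S2", data.frame(marker = "L1", allele = "11",
                                     size = 150.1, height = 50))
  obs2 <- classify_peaks(p2, g, panel)
  expect_equal(obs2$component, "reverse_stutter")
  expect_equal(obs2$pph, 0)  # parent allele 12 dropped out
})

test_that("classification partitions peaks and is order independent", {
  panel <- tiny_panel()
  g <- list(L1 = c("10", "12"), L2 = c("9", "9"))
  set.seed(7)
  pk <- data.frame(
    marker = rep(c("L1", "L2"), each = 4),
    allele = "x",
    size = c(146, 154, 142, 160, 254, 250, 258, 270),
    height = runif(8, 10, 1000))
  p <- str_profile("S", pk)
  obs <- classify_peaks(p, g, panel)
  expect_equal(nrow(obs), nrow(pk))
  expect_true(all(table(obs$component) >= 0))
  expect_equal(sum(table(obs$component)), nrow(pk))
  # permuted input gives identical classification
  perm <- sample(nrow(pk))
  obs2 <- classify_peaks(str_profile("S", pk[perm, ]), g, panel)
  key <- function(d) d[order(d$marker, d$s),
                       c("marker", "component", "h", "s", "pph")]
  expect_equal(key(obs2), key(obs), ignore_attr = TRUE)
})

test_that("drop-out enumeration matches a brute-force position census", {
  panel <- tiny_panel()
  g <- list(L1 = c("10", "12"))
  # only the allele-10 peak observed
  p <- str_profile("S", data.frame(marker = "L1", allele = "10",
                                   size = 146, height = 500))
  drops <- enumerate_dropouts(p, g, panel)
  expect_equal(sum(drops$component == "allele"), 1L)   # allele 12 dropped
  expect_true(all(drops$h == 0))
  # reverse stutter of 10 dropped, with the observed parent height
  rs <- drops[drops$component == "reverse_stutter" & drops$s == 142, ]
  expect_equal(rs$pph, 500)
  # brute-force census of the position universe:
  # ladder 138..162 (7) plus flanks 134 and 166 -> 9 positions
  lad <- panel$loci$L1$ladder$size
  universe <- sort(unique(c(lad, lad - 4, lad + 4)))
  expect_equal(length(universe), 9L)
  # allele positions {146, 154}; stutter positions {142, 150, 158}
  expected_noise <- length(universe) - 2 - 3
  expect_equal(sum(drops$component == "noise"), expected_noise)
  # completeness: observed alleles + allele drop-outs = distinct alleles
  cl <- classify_peaks(p, g, panel)
  expect_equal(sum(cl$component == "allele") +
                 sum(drops$component == "allele"), 2L)
})

test_that("homozygotes yield a single allele position", {
  panel <- tiny_panel()
  g <- list(L1 = c("11", "11"))
  p <- str_profile("S", data.frame(marker = "L1", allele = "8",
                                   size = 138, height = 10))
  drops <- enumerate_dropouts(p, g, panel)
  expect_equal(sum(drops$component == "allele"), 1L)
})
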