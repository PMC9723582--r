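test_that("error estimation uses HSP length plus unaligned reference bases", {
  set.seed(111)
  ref <- rcaits:::.randDna(1000)
  # identical query -> 100%
  outSame <- estimateError(c(q = ref), c(r1 = ref))
  expect_equal(outSame$perSequence$percent_identity, 100)
  expect_equal(outSame$meanErrorPct, 0)

  # query covering 990 reference bases with 10 internal substitutions:
  # identities 980, alignment length 990 + 10 unaligned -> 98.0%
  q <- substr(ref, 1, 990)
  at <- seq(100, 900, length.out = 10)
  for (p in at) substr(q, p, p) <- setdiff(c("A", "C", "G", "T"),
                                           substr(q, p, p))[1]
  out <- estimateError(c(q = q), c(r1 = ref))
  expect_equal(out$perSequence$alignment_length, 1000L)
  expect_equal(out$perSequence$identities, 980L)
  expect_equal(out$perSequence$percent_identity, 98.0)

  # best reference wins
  ref2 <- rcaits:::.randDna(1000)
  out2 <- estimateError(c(q = q), c(far = ref2, near = ref))
  expect_equal(out2$perSequence$best_ref, "near")
  expect_error(estimateError(c(q = q), character(0)), "empty")

  # duplicating inputs leaves the mean unchanged (and sd nearly so)
  out3 <- estimateError(c(a = q, b = q), c(r1 = ref))
  expect_equal(out3$meanIdentity, out$meanIdentity)
})

test_that("uniform chi-square matches closed forms and the base implementation", {
  z <- chisqUniform(c(50, 50))
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)

  z2 <- chisqUniform(c(10, 20))
  expect_equal(z2$statistic, 10 / 3, tolerance = 1e-12)
  expect_equal(z2$df, 1L)
  # df = 1 closed form via the normal tail
  expect_equal(z2$p.value, 2 * (1 - pnorm(sqrt(10 / 3))), tolerance = 1e-12)
  expect_equal(round(z2$p.value, 4), 0.0679)

  z3 <- chisqUniform(rep(100, 7))
  expect_equal(z3$statistic, 0)
  expect_equal(z3$p.value, 1)

  expect_error(chisqUniform(c(0, 0)), "zero total")
  expect_error(chisqUniform(5), "2 categories")

  set.seed(112)
  for (i in 1:10) {
    x <- rpois(sample(3:8, 1), lambda = 40) + 1
    ours <- chisqUniform(x)
    ref <- suppressWarnings(chisq.test(x))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("correlation statistics match brute-force definitions", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(pearsonR(x, x), 1)
  expect_equal(spearmanRho(x, x), 1)
  expect_equal(suppressWarnings(rSquared(x, x)), 1)

  # anti-sorted, no ties: rho = -1 by the sum-of-d-squared formula
  y <- sort(x + seq_along(x) * 1e-3, decreasing = TRUE)
  xs <- sort(x + seq_along(x) * 1e-3)
  n <- length(xs)
  d2 <- sum((rank(xs) - rank(y))^2)
  expect_equal(1 - 6 * d2 / (n * (n^2 - 1)), -1)
  expect_equal(spearmanRho(xs, y), -1)

  set.seed(113)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12) + 0.5 * a
    # Pearson by the product-moment sums
    rBrute <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearsonR(a, b), rBrute, tolerance = 1e-12)
    # Spearman = Pearson on mid-ranks
    expect_equal(spearmanRho(a, b),
                 pearsonR(rank(a), rank(b)), tolerance = 1e-12)
    # R^2 of the least-squares fit equals r^2 for simple regression
    expect_equal(rSquared(a, b), rBrute^2, tolerance = 1e-12)
  }
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearsonR(1:2, 1:2), "length")
})

test_that("informative sites distinguish variable from parsimony-informative", {
  m0 <- DnaMsa(sprintf("r%d", 1:4), rep("ACGT", 4))
  expect_equal(informativeSites(m0), c(variable = 0L, parsimony = 0L))

  m1 <- DnaMsa(sprintf("r%d", 1:4), c("ACGT", "ACGA", "ACGA", "ACGT"))
  expect_equal(informativeSites(m1), c(variable = 1L, parsimony = 1L))

  m2 <- DnaMsa(sprintf("r%d", 1:4), c("ACGT", "ACGA", "ACGC", "ACGT"))
  expect_equal(informativeSites(m2), c(variable = 1L, parsimony = 0L))

  # N does not create variability; a gap does
  m3 <- DnaMsa(sprintf("r%d", 1:4), c("ACGT", "ACGN", "AC-T", "ACGT"))
  expect_equal(informativeSites(m3), c(variable = 1L, parsimony = 0L))
})

test_that("survival table reproduces the per-genus arithmetic", {
  counts <- data.frame(
    genus = c("Duganella", "Pedobacter"),
    initial = c(140L, 84L), largest = c(134L, 84L), final = c(92L, 66L))
  tab <- survivalTable(counts)
  expect_equal(tab$largest_cluster_pct[tab$genus == "Duganella"], 95.7)
  expect_equal(tab$survival_pct[tab$genus == "Duganella"], 65.7)
  expect_equal(tab$largest_cluster_pct[tab$genus == "Pedobacter"], 100.0)
  expect_equal(tab$survival_pct[tab$genus == "Pedobacter"], 78.6)
  expect_equal(tab$final[tab$genus == "Total"], 158L)

  # identity run: 100% everywhere
  idr <- survivalTable(data.frame(genus = "g", initial = 10L,
                                  largest = 10L, final = 10L))
  expect_equal(idr$largest_cluster_pct[1], 100)
  expect_equal(idr$survival_pct[1], 100)

  expect_error(survivalTable(data.frame(genus = "g", initial = 5L,
                                        largest = 6L, final = 2L)),
               "exceed")
  expect_error(survivalTable(data.frame(genus = "g", initial = 5L)),
               "missing columns")
})
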