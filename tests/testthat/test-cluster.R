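test_that("strict 16S extraction follows the primer motifs", {
  tpl <- fixTemplate(71, coreLen = 1250L, itsLen = 400L)
  s16 <- extract16S(tpl)
  # by construction the 16S spans the first coreLen bases
  expect_equal(s16, substr(tpl, 1, 1250))

  # missing reverse motif
  noRev <- substr(tpl, 1, 1200)
  expect_true(is.na(extract16S(noRev)))

  # one mutated primer base: found at maxMismatch 1, not at 0
  mut <- tpl
  substr(mut, 5, 5) <- if (substr(mut, 5, 5) == "A") "C" else "A"
  expect_true(is.na(extract16S(mut, maxMismatch = 0L)))
  expect_equal(extract16S(mut, maxMismatch = 1L), substr(mut, 1, 1250))
})

test_that("similarity rescue recovers primer-mutated sequences only", {
  set.seed(72)
  tpl <- fixTemplate(72)
  seeds <- extract16S(tpl)
  # 3 SNPs inside the forward motif defeat strict matching
  q <- tpl
  for (p in c(3, 9, 15)) {
    substr(q, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(q, p, p))[1]
  }
  expect_true(is.na(extract16S(q)))
  resc <- rescue16S(c(q = q), seeds)
  expect_false(is.na(resc[["q"]]))
  expect_lte(abs(nchar(resc[["q"]]) - nchar(seeds)), 4L)

  rand <- rcaits:::.randDna(2000)
  expect_true(is.na(rescue16S(c(r = rand), seeds)[["r"]]))
  expect_error(rescue16S(c(q = q), character(0)), "empty")
})

test_that("greedy clustering separates groups and partitions the input", {
  set.seed(73)
  # two 2-kb groups at ~90% inter-group identity
  a <- rcaits:::.randDna(2000)
  cc <- rcaits:::.chars(a)
  at <- sample(2000, 200)
  cc[at] <- vapply(cc[at], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                      b), 1), "")
  b <- paste(cc, collapse = "")
  em <- errorModel(mismatch = 0.005, ins = 0, del = 0, jitter = 0)
  seqs <- c(vapply(1:5, function(i) rcaits:::.mutateSeq(a, em), ""),
            vapply(1:5, function(i) rcaits:::.mutateSeq(b, em), ""))
  names(seqs) <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  cl <- greedyCluster(seqs, identity = 0.95)
  expect_length(cl, 2L)
  grp <- lapply(cl, members)
  expect_true(setequal(grp[[1]], sprintf("a%d", 1:5)) ||
                setequal(grp[[1]], sprintf("b%d", 1:5)))
  # partition property
  expect_setequal(unlist(grp), names(seqs))

  # identical sequences collapse; distinct sequences at identity 1 stay apart
  same <- stats::setNames(rep(a, 10), sprintf("s%d", 1:10))
  expect_length(greedyCluster(same, 0.95), 1L)
  distinct <- stats::setNames(c(a, b, rcaits:::.randDna(2000)), c("x", "y", "z"))
  expect_length(greedyCluster(distinct, 1.0), 3L)

  # cluster count is non-decreasing in the threshold
  counts <- vapply(c(0.90, 0.93, 0.96, 0.99),
                   function(t) length(greedyCluster(seqs, t)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("small-cluster exclusion applies the right floor at each level", {
  mkCl <- function(n, id) new("SeqCluster", clusterId = id, level = "genus",
                              identityThreshold = 0.95,
                              memberIds = sprintf("%s_%d", id, seq_len(n)),
                              representativeId = sprintf("%s_1", id))
  cls <- list(mkCl(10, "c1"), mkCl(4, "c2"))
  f <- filterSmallClusters(cls, minMembers = 5)
  expect_length(f$kept, 1L)
  expect_length(f$excludedIds, 4L)

  # rrn stage: 5% of 200 = 10
  cls2 <- list(mkCl(150, "r1"), mkCl(40, "r2"), mkCl(8, "r3"))
  f2 <- filterSmallClusters(cls2, inputN = 200, minFraction = 0.05)
  expect_length(f2$kept, 2L)
  expect_length(f2$excludedIds, 8L)
  # rescue floor keeps all three
  f3 <- filterSmallClusters(cls2, inputN = 200, minFraction = 0.05,
                            rescueMinMembers = 6)
  expect_length(f3$kept, 3L)
})

test_that("taxonomy labels come from the modal member assignment", {
  set.seed(74)
  tplA <- fixTemplate(74)
  tplB <- fixTemplate(75)
  v4A <- rcaits:::.extractV4(tplA)
  v4B <- rcaits:::.extractV4(tplB)
  expect_false(is.na(v4A))
  refs <- c(Bacillus = v4A, Pseudomonas = v4B)

  seqs <- stats::setNames(c(rep(tplA, 9), tplB), sprintf("m%d", 1:10))
  cl <- new("SeqCluster", clusterId = "g1", level = "genus",
            identityThreshold = 0.95, memberIds = names(seqs),
            representativeId = "m1")
  out <- assignTaxonomy(cl, seqs, refs)
  expect_equal(out@taxonomy, "Bacillus")
  expect_equal(out@modalFraction, 0.9)

  allA <- new("SeqCluster", clusterId = "g2", level = "genus",
              identityThreshold = 0.95,
              memberIds = sprintf("m%d", 1:9),
              representativeId = "m1")
  outA <- assignTaxonomy(allA, seqs, refs)
  expect_equal(outA@modalFraction, 1.0)
  expect_error(assignTaxonomy(cl, seqs, character(0)), "empty")

  # members without a V4 span -> unassigned
  noV4 <- stats::setNames(rep(rcaits:::.randDna(500), 2), c("m1", "m2"))
  clN <- new("SeqCluster", clusterId = "g3", level = "genus",
             identityThreshold = 0.95, memberIds = c("m1", "m2"),
             representativeId = "m1")
  expect_equal(assignTaxonomy(clN, noV4, refs)@taxonomy, "unassigned")
})

test_that("global-identity prefilter keeps near-references, not chimeras out", {
  set.seed(76)
  refA <- fixTemplate(76)
  refB <- fixTemplate(77)
  em <- errorModel(mismatch = 0.001, ins = 5e-4, del = 5e-4, jitter = 0)
  near <- rcaits:::.mutateSeq(refA, em)
  rand <- rcaits:::.randDna(2500)
  # 50/50 crossover of two refs: ~high identity to either parent half
  n1 <- nchar(refA); n2 <- nchar(refB)
  chim <- paste0(substr(refA, 1, n1 %/% 2), substr(refB, n2 %/% 2 + 1, n2))
  out <- globalIdentityPrefilter(c(near = near, rand = rand),
                                 c(refA, refB), minIdentity = 0.95)
  expect_equal(names(out$kept), "near")
  expect_equal(out$discardedIds, "rand")
  # the filter is not a chimera filter when parents are similar: document by
  # checking a crossover of two 95%-similar parents survives
  ccA <- rcaits:::.chars(refA)
  at <- sample(n1, round(0.05 * n1))
  ccA[at] <- vapply(ccA[at], function(b) sample(setdiff(c("A","C","G","T"), b),
                                                1), "")
  refA2 <- paste(ccA, collapse = "")
  chim2 <- paste0(substr(refA, 1, n1 %/% 2), substr(refA2, n1 %/% 2 + 1, n1))
  out2 <- globalIdentityPrefilter(c(ch = chim2), c(refA, refA2), 0.95)
  expect_equal(names(out2$kept), "ch")
})
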