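test_that("variable columns follow the 95 percent majority rule", {
  tpl <- rcaits:::.randDna(500)
  m <- buildGenusMsa(stats::setNames(rep(tpl, 50), sprintf("i%02d", 1:50)))
  expect_length(variableColumns(m), 0L)

  # boundary: 94/100 included, 96/100 excluded
  col94 <- c(rep("A", 94), rep("C", 6))
  col96 <- c(rep("A", 96), rep("C", 4))
  rows <- paste0(col94, col96)
  m2 <- DnaMsa(sprintf("r%03d", 1:100), rows)
  expect_equal(variableColumns(m2), 1L)

  # engineered SNP columns at 30% minor allele are detected exactly
  set.seed(91)
  base <- rcaits:::.randDna(600)
  alt <- base
  for (p in c(100, 300, 500)) {
    substr(alt, p, p) <- setdiff(c("A", "C", "G", "T"), substr(alt, p, p))[1]
  }
  seqs <- stats::setNames(c(rep(base, 70), rep(alt, 30)),
                          sprintf("v%03d", 1:100))
  m3 <- buildGenusMsa(seqs)
  expect_equal(variableColumns(m3), c(100L, 300L, 500L))
})

test_that("sub-sequence windows merge, clip, and keep gaps", {
  m <- DnaMsa(c("a", "b"), c(strrep("A", 30), strrep("A", 30)))
  p <- ResolveParam()
  # single variable column at 11 (1-based), flank 4 -> 9 columns
  s1 <- extractSubsequences(m, 11L, p)
  expect_true(all(nchar(s1) == 9L))
  # overlapping windows merge: columns 11 and 13 -> [7..17]
  s2 <- extractSubsequences(m, c(11L, 13L), p)
  expect_true(all(nchar(s2) == 11L))
  # clipped at the left bound: column 2 -> [1..6]
  s3 <- extractSubsequences(m, 2L, p)
  expect_true(all(nchar(s3) == 6L))
  expect_error(extractSubsequences(m, integer(0), p), "no_variable_columns")

  # gaps are retained as characters
  mg <- DnaMsa(c("a", "b"), c("AAAA-AAAAAA", "AAAAAAAAAAA"))
  sg <- extractSubsequences(mg, 5L, ResolveParam(flankColumns = 1L))
  expect_equal(unname(sg["a"]), "A-A")
})

test_that("the identity sweep resolves rrn structure and partitions input", {
  set.seed(92)
  base <- rcaits:::.randDna(800)
  onesnp <- base
  substr(onesnp, 400, 400) <- setdiff(c("A", "C", "G", "T"),
                                      substr(onesnp, 400, 400))[1]
  seqs <- stats::setNames(c(rep(base, 30), rep(onesnp, 30)),
                          sprintf("q%02d", 1:60))
  m <- buildGenusMsa(seqs)
  vc <- variableColumns(m)
  expect_equal(vc, 400L)
  ss <- extractSubsequences(m, vc)
  full <- stats::setNames(ungap(m), msaIds(m))
  call <- sweepCluster(ss, full, genus = "g")
  # one SNP in a 9-column window: identity 8/9 < 0.90, so 2 clusters at
  # every ladder point (window-length arithmetic oracle)
  expect_true(all(call@curve$count == 2L))
  expect_length(call@clusters, 2L)
  # cluster-count curve is non-decreasing in identity
  expect_true(all(diff(call@curve$count) >= 0))
  # partition: members + excluded = input
  got <- c(unlist(lapply(call@clusters, members)), call@excludedIds)
  expect_setequal(got, names(seqs))
  # consensus of each cluster equals its template
  cons <- sort(vapply(call@clusters, function(cl) cl@consensus, ""))
  expect_setequal(cons, c(base, onesnp))

  # single template: 1 cluster everywhere
  single <- stats::setNames(rep(base, 20), sprintf("s%02d", 1:20))
  mS <- buildGenusMsa(single)
  expect_length(variableColumns(mS), 0L)
})

test_that("cluster consensus is exact for clean members", {
  tpl <- fixTemplate(93)
  expect_equal(clusterConsensus(c(x = as.character(tpl))), as.character(tpl))
  noisy <- fixConsensusSet(list(tpl), 30, mismatch = 1e-3, indel = 5e-4,
                           seed = 93)
  expect_equal(clusterConsensus(noisy), as.character(tpl))
  two <- clusterConsensus(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(two, "ACGTACGT")
})

test_that("ITS-only variants vanish when the ITS is stripped", {
  # three rrn copies distinguished only inside the ITS
  tpl <- fixTemplate(94, coreLen = 1250L, itsLen = 400L)
  its <- attr(tpl, "itsStart")
  rr <- makeRrnSet(tpl, 3, edits = list(NULL, list(snps = 0, ins = 0),
                                        list(snps = 0)), seed = 94)
  # hand-place 3 SNPs in the ITS of copies 2 and 3
  mutAt <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                              substr(s, p, p))[1]
    s
  }
  rr[2] <- mutAt(rr[1], its + c(50, 120, 200))
  rr[3] <- mutAt(rr[1], its + c(80, 160, 240))
  seqs <- fixConsensusSet(as.list(rr), 20, mismatch = 0, indel = 0, seed = 95)
  res <- resolveGenus(seqs, genus = "full", reportRule = "terminal")
  nFull <- length(res$call@clusters)
  # 16S-only view: cut at the end of the 16S gene
  seqs16 <- vapply(seqs, function(s) substr(s, 1, 1250), "")
  m16 <- buildGenusMsa(seqs16)
  n16 <- length(variableColumns(m16))
  expect_equal(nFull, 3L)
  expect_equal(n16, 0L)   # no 16S signal -> at most one 16S-only cluster
})

test_that("two-parent chimera detection flags crossovers against references", {
  set.seed(96)
  spec <- randomCommunity(nTaxa = 3, rrnCounts = 1, seed = 96)
  refs <- vapply(spec, function(t) t$templates[1], "")
  names(refs) <- vapply(spec, function(t) t$taxonId, "")

  # candidate equal to a reference is clean
  v0 <- detectChimera(refs[[2]], refs)
  expect_false(v0$isChimera)
  expect_equal(v0$editsSaved, 0)

  # 50/50 crossover: flagged, breakpoint within +/- 20 bp of truth
  n1 <- nchar(refs[1]); n2 <- nchar(refs[2])
  bp <- n1 %/% 2
  chim <- paste0(substr(refs[1], 1, bp), substr(refs[2], bp + 1, n2))
  v1 <- detectChimera(chim, refs)
  expect_true(v1$isChimera)
  expect_equal(v1$parents, c(names(refs)[1], names(refs)[2]))
  expect_lte(abs(v1$breakpoint - bp), 20L)

  expect_error(detectChimera(chim, refs[1]), "at least 2")

  # seeded panel: sensitivity and specificity
  em <- errorModel(mismatch = 0.002, ins = 0.001, del = 0.001, jitter = 0)
  isChim <- function(s) detectChimera(s, refs)$isChimera
  sens <- mean(vapply(1:15, function(i) {
    ab <- sample(3, 2)
    f <- runif(1, 0.25, 0.75)
    cs <- paste0(substr(refs[ab[1]], 1, round(f * nchar(refs[ab[1]]))),
                 substr(refs[ab[2]], round(f * nchar(refs[ab[2]])) + 1,
                        nchar(refs[ab[2]])))
    isChim(rcaits:::.mutateSeq(cs, em))
  }, TRUE))
  spc <- mean(!vapply(1:15, function(i)
    isChim(rcaits:::.mutateSeq(refs[[sample(3, 1)]], em)), TRUE))
  expect_gte(sens, 0.95)
  expect_gte(spc, 0.95)
})
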