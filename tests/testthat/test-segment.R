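test_that("junctions are found exactly on clean reads and not in random DNA", {
  con <- fixConstruct()
  tpl <- fixTemplate(31)
  r <- simulateConcatemerRead(tpl, con, kRepeats = 5, error = noError(),
                              seed = 41)
  j <- findJunctions(unname(r$seq), con, readId = "c1")
  expect_equal(nrow(j), 6L)
  expect_true(all(diff(j$start) > 0))
  expect_true(all(j$identity > 0.99))

  set.seed(42)
  rand <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  expect_equal(nrow(findJunctions(rand, con)), 0L)
})

test_that("split honors the sub-read size window and records barcodes", {
  con <- fixConstruct()
  set.seed(43)
  mkUnit <- function(ins, bc5, bc3) paste0(con@fwdUnique, bc5, ins, bc3,
                                           rcaits:::.revcomp(con@revUnique))
  shortIns <- rcaits:::.randDna(1190)     # interval 1200 < minSubLen
  longIns <- rcaits:::.randDna(2490)      # interval 2500, valid
  read <- paste0(con@splint, mkUnit(shortIns, "ACGTT", "GGATC"), con@splint,
                 mkUnit(longIns, "ACGTT", "GGATC"), con@splint)
  j <- findJunctions(read, con, readId = "sz")
  expect_equal(nrow(j), 3L)
  s <- splitRead(read, j, con, readId = "sz")
  expect_equal(length(s@subReads), 1L)
  expect_equal(nchar(s@subReads), 2500L)
  expect_equal(s@bc5Obs, "ACGTT")
  expect_equal(s@bc3Obs, "GGATC")

  # no junctions -> discarded with reason
  s0 <- splitRead(read, j[0, ], con, readId = "nj")
  expect_equal(s0@discardReason, "no_junction")
})

test_that("barcode gapped consensus accepts consistent tags and rejects mixtures", {
  expect_equal(barcodeConsensus(rep("ACGTT", 5)), "ACGTT")
  # 3:2 split above the 0.6 cutoff in the last column
  expect_equal(barcodeConsensus(c(rep("ACGTT", 3), rep("ACGTA", 2)),
                                cutoff = 0.6), "ACGTT")
  # two different molecules: ambiguity columns are kept as N, gaps dropped,
  # and the over-long consensus flags a mixed barcode
  expect_equal(barcodeConsensus(c(rep("ACGTT", 3), rep("TTGCA", 3))),
               "REJECTED")
  # indel-bearing observation resolved by the alignment
  expect_equal(barcodeConsensus(c("ACGTT", "ACGTT", "ACTT", "ACGTT",
                                  "ACGTT")), "ACGTT")
  expect_error(barcodeConsensus(character(0)), "at least one")
})

test_that("barcode validation clips tags and discards mixed reads", {
  con <- fixConstruct()
  tpl <- fixTemplate(32)
  r <- simulateConcatemerRead(tpl, con, kRepeats = 4, error = noError(),
                              barcodes = c("ACGTT", "TGCAA"), seed = 44)
  j <- findJunctions(unname(r$seq), con)
  s <- splitRead(unname(r$seq), j, con)
  raw <- nchar(s@subReads[1])
  v <- validateAndClip(s, barcodeLen = con@barcodeLen)
  expect_true(isRetained(v))
  expect_equal(nchar(v@subReads[1]), raw - 10L)
  expect_true(all(v@subReads == tpl))

  # conflicting 5' observations (two molecules in one read) -> mixed_barcode
  mixed <- new("SubReadSet", readId = "m", subReads = rep(tpl, 6),
               bc5Obs = c(rep("ACGTT", 3), rep("TGCAA", 3)),
               bc3Obs = rep("GGGGG", 6))
  vm <- validateAndClip(mixed)
  expect_equal(vm@discardReason, "mixed_barcode")

  # a single sub-read with consistent barcodes is retained here
  # (support filtering happens at the consensus stage)
  single <- new("SubReadSet", readId = "s", subReads = tpl,
                bc5Obs = "ACGTT", bc3Obs = "GGGGG")
  expect_true(isRetained(validateAndClip(single)))
})

test_that("noisy reads keep their repeat count and pass splint hygiene", {
  con <- fixConstruct()
  tpl <- fixTemplate(33)
  set.seed(45)
  ok <- 0L
  splintKmers <- substring(con@splint, 1:(nchar(con@splint) - 14),
                           15:nchar(con@splint))
  for (i in 1:10) {
    r <- simulateConcatemerRead(tpl, con, kRepeats = 5,
                                error = errorModel(jitter = 0.2),
                                readId = sprintf("n%d", i))
    s <- segmentRead(unname(r$seq), con, readId = sprintf("n%d", i))
    if (length(s@subReads) == 5L) ok <- ok + 1L
    # no emitted sub-read contains a splint 15-mer
    for (sr in s@subReads) {
      expect_false(any(vapply(splintKmers, grepl, TRUE, x = sr,
                              fixed = TRUE)))
    }
  }
  expect_gte(ok, 9L)
})

test_that("segmentation is invariant to reverse-complementing the read", {
  con <- fixConstruct()
  tpl <- fixTemplate(34)
  r <- simulateConcatemerRead(tpl, con, kRepeats = 3, error = noError(),
                              seed = 46)
  fwd <- segmentRead(unname(r$seq), con, readId = "f")
  rev <- segmentRead(rcaits:::.revcomp(unname(r$seq)), con, readId = "r")
  expect_equal(fwd@subReads, rev@subReads)
  expect_equal(fwd@bc5, rev@bc5)
  expect_equal(fwd@bc3, rev@bc3)
})

test_that("segmentReads ledger conserves reads", {
  con <- fixConstruct()
  tpl <- fixTemplate(35)
  set.seed(47)
  reads <- c(
    vapply(1:3, function(i)
      unname(simulateConcatemerRead(tpl, con, kRepeats = 2,
                                    error = errorModel())$seq), ""),
    rand = paste(sample(c("A", "C", "G", "T"), 9000, TRUE), collapse = ""))
  names(reads) <- sprintf("r%d", 1:4)
  out <- segmentReads(reads, con)
  tab <- ledgerTable(out$ledger)
  expect_equal(tab$input, 4L)
  expect_equal(tab$retained + tab$discarded, 4L)
  expect_match(tab$reasons, "no_junction")
})
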