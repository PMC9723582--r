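test_that("genus MSA is clean for identical inputs and places indels consistently", {
  tpl <- fixTemplate(81)
  same <- stats::setNames(rep(as.character(tpl), 20), sprintf("s%02d", 1:20))
  m <- buildGenusMsa(same)
  expect_false(any(grepl("-", msaRows(m))))

  # two templates differing by one 3-bp indel: one 3-column gap block,
  # consistently placed in every row of the shorter group
  del <- paste0(substr(tpl, 1, 799), substr(tpl, 803, nchar(tpl)))
  seqs <- stats::setNames(c(rep(as.character(tpl), 10), rep(del, 10)),
                          sprintf("x%02d", 1:20))
  m2 <- buildGenusMsa(seqs)
  mat <- rcaits:::.msaMatrix(m2)
  gapCols <- which(colSums(mat == "-") > 0)
  expect_length(gapCols, 3L)
  expect_equal(diff(gapCols), c(1L, 1L))
  gapRows <- rowSums(mat[, gapCols, drop = FALSE] == "-")
  expect_true(all(gapRows %in% c(0L, 3L)))
  expect_equal(sum(gapRows == 3L), 10L)

  expect_error(buildGenusMsa(c(a = "ACGT")), "at least 2")
})

test_that("column analysis implements the dominant / minority-to-N branches", {
  p <- RefineParam()
  a <- analyzeColumn(c(rep("A", 99), "G"), p)
  expect_equal(a$action, "corrected_to_dominant")
  expect_equal(a$replacement, "A")
  expect_equal(sum(a$change), 1L)

  b <- analyzeColumn(c(rep("A", 60), rep("C", 39), "T"), p)
  expect_equal(b$action, "minority_to_N")
  expect_equal(b$replacement, "N")
  expect_equal(sum(b$change), 1L)

  none <- analyzeColumn(c(rep("A", 50), rep("C", 50)), p)
  expect_equal(none$action, "none")

  # a dominant gap may overwrite a minority base
  g <- analyzeColumn(c(rep("-", 99), "A"), p)
  expect_equal(g$action, "corrected_to_dominant")
  expect_equal(g$replacement, "-")

  # N never counts as dominant
  nn <- analyzeColumn(c(rep("N", 99), "A"), p)
  expect_equal(nn$action, "none")
})

test_that("two-pass correction excludes outliers then applies corrections", {
  set.seed(82)
  tpl <- rcaits:::.randDna(2500)
  clean <- stats::setNames(rep(tpl, 100), sprintf("c%03d", 1:100))

  # one row with a 30-bp foreign block: 30 > 0.05% * 2500 = 1.25 -> excluded
  bad <- paste0(substr(tpl, 1, 1000), rcaits:::.randDna(30),
                substr(tpl, 1031, 2500))
  seqs <- c(clean, bad = bad)
  m <- buildGenusMsa(seqs)
  out <- correctMsa(m)
  expect_equal(out$excludedIds, "bad")
  expect_false("bad" %in% msaIds(out$msa))
  expect_true(all(out$report$corrections_applied[
    out$report$id != "bad"] == 0L))

  # one stray substitution (1 <= 1.25): retained and corrected
  one <- tpl
  substr(one, 1200, 1200) <- setdiff(c("A", "C", "G", "T"),
                                     substr(one, 1200, 1200))[1]
  seqs2 <- c(clean, fix = one)
  out2 <- correctMsa(buildGenusMsa(seqs2))
  expect_length(out2$excludedIds, 0L)
  rep2 <- out2$report[out2$report$id == "fix", ]
  expect_equal(rep2$corrections_counted, 1L)
  expect_equal(rep2$corrections_applied, 1L)
  expect_equal(unname(ungap(out2$msa, "fix")), tpl)

  # idempotence: a second pass applies nothing
  again <- correctMsa(out2$msa)
  expect_length(again$excludedIds, 0L)
  expect_true(all(again$report$corrections_applied == 0L))

  # identical rows: nothing counted, nothing excluded
  out3 <- correctMsa(buildGenusMsa(clean[1:10]))
  expect_true(all(out3$report$corrections_counted == 0L))
})

test_that("excluded outliers never influence the applied corrections", {
  set.seed(83)
  tpl <- rcaits:::.randDna(2500)
  clean <- stats::setNames(rep(tpl, 60), sprintf("c%02d", 1:60))
  # outlier carries a divergent block; its bases at those columns must not
  # leak into the survivors' corrected cells
  bad <- paste0(substr(tpl, 1, 500), rcaits:::.randDna(40),
                substr(tpl, 541, 2500))
  out <- correctMsa(buildGenusMsa(c(clean, bad = bad)))
  expect_equal(out$excludedIds, "bad")
  expect_true(all(ungap(out$msa) == tpl))
})

test_that("a true variant at >= 2% minority frequency is never altered", {
  set.seed(84)
  tpl <- rcaits:::.randDna(2000)
  alt <- tpl
  substr(alt, 900, 900) <- setdiff(c("A", "C", "G", "T"),
                                   substr(alt, 900, 900))[1]
  seqs <- stats::setNames(c(rep(tpl, 80), rep(alt, 20)),
                          sprintf("v%03d", 1:100))
  out <- correctMsa(buildGenusMsa(seqs))
  expect_length(out$excludedIds, 0L)
  expect_true(all(ungap(out$msa)[81:100] == alt))
  expect_true(all(ungap(out$msa)[1:80] == tpl))
})

test_that("trimming keeps the span satisfying the 98 percent non-gap rule", {
  set.seed(85)
  tpl <- rcaits:::.randDna(1000)
  full <- stats::setNames(rep(tpl, 100), sprintf("t%03d", 1:100))
  m <- buildGenusMsa(full)
  tr <- trimMsa(m)
  expect_equal(tr$left, 1L)
  expect_equal(tr$right, msaWidth(m))

  # 5 of 100 rows start 20 columns late: leading 20 columns fall below 98%
  late <- c(stats::setNames(rep(tpl, 95), sprintf("a%02d", 1:95)),
            stats::setNames(rep(substr(tpl, 21, 1000), 5),
                            sprintf("b%d", 1:5)))
  m2 <- buildGenusMsa(late)
  tr2 <- trimMsa(m2)
  expect_equal(tr2$left, 21L)
  mat <- rcaits:::.msaMatrix(tr2$msa)
  nonGap <- colSums(mat != "-") / nrow(mat)
  expect_gte(nonGap[1], 0.98)
  expect_gte(nonGap[length(nonGap)], 0.98)

  # ragged staircase on both ends: boundary columns satisfy the rule (oracle:
  # direct scan of the column tallies)
  stair <- c(stats::setNames(rep(tpl, 96), sprintf("s%02d", 1:96)),
             st1 = substr(tpl, 16, 1000), st2 = substr(tpl, 1, 985),
             st3 = substr(tpl, 11, 990), st4 = substr(tpl, 6, 995))
  m3 <- buildGenusMsa(stair)
  tr3 <- trimMsa(m3)
  mat3 <- rcaits:::.msaMatrix(m3)
  ng <- colSums(mat3 != "-") / nrow(mat3)
  expect_equal(tr3$left, min(which(ng >= 0.98)))
  expect_equal(tr3$right, max(which(ng >= 0.98)))

  # everything below threshold -> error
  thin <- DnaMsa(c("a", "b", "c"), c("A---", "-C--", "--G-"))
  expect_error(trimMsa(thin), "empty_after_trim")
})
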