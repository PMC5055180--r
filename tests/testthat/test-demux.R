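ref <- syntheticGermline()

test_that("reads parse into index, tag and payload", {
  set.seed(21)
  payload <- rdna(180)
  read <- paste0("AAGCT", rdna(12), SPACER, payload)
  p <- parseReads(read, "AAGCT")
  expect_equal(p$status, "ok")
  expect_equal(nchar(p$tag), 12L)
  expect_equal(p$payload, payload)
  expect_equal(p$payload_plus_spacer_len, 195L)
  # unknown index is rejected by exact 5-bp match
  p2 <- parseReads(read, "CCCCC")
  expect_equal(p2$status, "unknown_index")
  # a deletion inside the tag shifts the spacer; tag comes out 11 bp
  read3 <- paste0("AAGCT", rdna(11), SPACER, payload)
  p3 <- parseReads(read3, "AAGCT")
  expect_equal(p3$status, "ok")
  expect_equal(nchar(p3$tag), 11L)
  # one substitution inside the spacer is tolerated
  sp <- SPACER; substr(sp, 7, 7) <- "A"
  p4 <- parseReads(paste0("AAGCT", rdna(12), sp, payload), "AAGCT")
  expect_equal(p4$status, "ok")
  expect_equal(nchar(p4$tag), 12L)
  # no spacer anywhere
  p5 <- parseReads(paste0("AAGCT", rdna(200)), "AAGCT")
  expect_equal(p5$status, "no_spacer")
})

test_that("the 150-base spacer+payload filter is a sharp boundary", {
  set.seed(22)
  mk <- function(n) paste0("AAGCT", rdna(12), SPACER, rdna(n))
  p <- parseReads(c(mk(134), mk(135), mk(385)), "AAGCT")
  expect_equal(p$payload_plus_spacer_len, c(149L, 150L, 400L))
  expect_equal(lengthFilter(p), c(FALSE, TRUE, TRUE))
})

test_that("every read is rejected, dropped or in exactly one tag group", {
  cfg <- simConfig(nClones = 100, nMolecules = 1500, seed = 13)
  run <- generateRun(simulateRepertoire(cfg, ref), cfg)
  parsed <- parseReads(run$reads, cfg$sampleIndex, run$readIds)
  g <- tagGroups(parsed)
  nRejected <- sum(parsed$status != "ok")
  nDropped <- sum(parsed$status == "ok" & !lengthFilter(parsed))
  expect_equal(nRejected + nDropped + sum(readCounts(g)), length(run$reads))
})

test_that("single-indel length variants are merged with stated tie-breaks", {
  t12a <- strrep("A", 12)
  g <- makeGroups(c(t12a, strrep("A", 11)), c(20, 1))
  m <- mergeLengthVariants(g)
  expect_equal(unname(derivativeOf(m)[2]), t12a)
  expect_true(is.na(derivativeOf(m)[1]))
  # 13-bp single-insertion derivative
  g2 <- makeGroups(c(t12a, paste0(strrep("A", 12), "T")), c(5, 2))
  expect_equal(unname(derivativeOf(mergeLengthVariants(g2))[2]), t12a)
  # tie between two 12-bp parents resolves to the higher read count
  p1 <- paste0("C", strrep("A", 11)); p2 <- paste0(strrep("A", 11), "G")
  d11 <- strrep("A", 11)              # one deletion from either parent
  g3 <- makeGroups(c(p1, p2, d11), c(5, 9, 1))
  expect_equal(unname(derivativeOf(mergeLengthVariants(g3))[3]), p2)
  # equal read counts: lexicographically smallest parent
  g4 <- makeGroups(c(p1, p2, d11), c(7, 7, 1))
  expect_equal(unname(derivativeOf(mergeLengthVariants(g4))[3]),
               min(p1, p2))
  # an unrelated 11-bp tag stays underived
  g5 <- makeGroups(c(t12a, strrep("G", 11)), c(4, 1))
  expect_true(is.na(derivativeOf(mergeLengthVariants(g5))[2]))
})

test_that("the 90% rule picks the smallest passing threshold", {
  set.seed(23)
  mkTags <- function(n, w) vapply(seq_len(n), function(i) rdna(w),
                                  character(1))
  # bins: r=1 11/20 (0.55), r=2 8/10 (0.80), r=3 23/25 (0.92),
  #       r=4 32/33 (0.97), r=5 10/10 (1.0)  ->  r* = 3
  n12 <- c(11, 8, 23, 32, 10); nd <- c(9, 2, 2, 1, 0)
  tags <- c(mkTags(sum(n12), 12), mkTags(sum(nd), 11))
  nr <- c(rep(1:5, n12), rep(1:5, nd))
  der <- c(rep(NA_character_, sum(n12)), rep(strrep("A", 12), sum(nd)))
  g <- makeGroups(tags, nr, der)
  prof <- tagErrorProfile(g)
  expect_equal(readThreshold(prof), 3L)
  expect_equal(prof@table$fraction[1:2], c(0.55, 0.80))
  # no erroneous tags: every defined bin is 1.0 and r* = 1
  g0 <- makeGroups(mkTags(30, 12), rep(c(1, 4, 9), 10))
  p0 <- tagErrorProfile(g0)
  expect_equal(readThreshold(p0), 1L)
  expect_true(all(p0@table$fraction %in% c(1, NA)))
  # every bin failing aborts with a diagnostic
  gbad <- makeGroups(c(mkTags(2, 12), mkTags(18, 11)),
                     rep(1, 20),
                     c(rep(NA_character_, 2), rep(strrep("C", 12), 18)))
  expect_error(tagErrorProfile(gbad), "no threshold")
})

test_that("thresholding retains only 12-bp non-derivative tags", {
  set.seed(24)
  t12 <- vapply(1:4, function(i) rdna(12), character(1))
  t13 <- paste0(t12[1], "A")
  g <- makeGroups(c(t12, t13), c(5, 3, 2, 1, 6),
                  c(rep(NA_character_, 4), t12[1]))
  ret <- applyThreshold(g, 3L)
  expect_setequal(tags(ret), t12[1:2])        # >= 3 reads, 12 bp, underived
  expect_false(t13 %in% tags(ret))            # derivatives never retained
})

test_that("zero-error counting recovers the molecule count exactly", {
  cfg <- simConfig(nClones = 100, nMolecules = 1000, subRate = 0,
                   insRate = 0, delRate = 0, distinctBarcodes = TRUE,
                   seed = 1)
  run <- generateRun(simulateRepertoire(cfg, ref), cfg)
  res <- countMolecules(run, cfg)
  expect_equal(readThreshold(res$profile), 1L)
  expect_equal(length(res$retained), nrow(run$truth))
  expect_setequal(tags(res$retained), run$truth$barcode)
})

test_that("error-free fraction rises with reads per tag", {
  cfg <- simConfig(nClones = 200, nMolecules = 3000, seed = 17)
  run <- generateRun(simulateRepertoire(cfg, ref), cfg)
  res <- countMolecules(run, cfg)
  tab <- res$profile@table
  solid <- which(!is.na(tab$fraction) & (tab$n12 + tab$n_derivative) >= 30)
  f <- tab$fraction[solid]
  n <- (tab$n12 + tab$n_derivative)[solid]
  se <- sqrt(pmax(f * (1 - f), 0.25 / n) / n)
  # non-decreasing up to 3 binomial SEs
  expect_true(all(diff(f) > -3 * (se[-1] + se[-length(se)])))
  expect_lt(tab$fraction[1], 0.9)
})
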