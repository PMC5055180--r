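ref <- syntheticGermline()

test_that("uniform repertoires have equal frequencies and distinct CDR3s", {
  cfg <- simConfig(nClones = 100, seed = 1)
  rep <- simulateRepertoire(cfg, ref)
  expect_equal(nrow(rep), 100L)
  expect_equal(rep$frequency, rep(0.01, 100))
  expect_equal(length(unique(rep$cdr3_nt)), 100L)
  expect_equal(sum(rep$frequency), 1, tolerance = 1e-9)
  # anchors and productivity by construction
  expect_true(all(substr(rep$cdr3_nt, 1, 3) %in% c("TGT", "TGC")))
  expect_true(all(substring(rep$cdr3_nt, nchar(rep$cdr3_nt) - 2) %in%
                    c("TTT", "TTC")))
  expect_true(all(nchar(rep$cdr3_nt) %% 3 == 0))
  expect_false(any(grepl("*", rep$cdr3_aa, fixed = TRUE)))
})

test_that("repertoire generation is deterministic given the seed", {
  cfg <- simConfig(nClones = 200, abundance = "power_law", seed = 7)
  expect_identical(simulateRepertoire(cfg, ref), simulateRepertoire(cfg, ref))
})

test_that("power-law abundances are rank-monotone", {
  cfg <- simConfig(nClones = 1000, abundance = "power_law", alpha = 1.5,
                   seed = 7)
  rep <- simulateRepertoire(cfg, ref)
  expect_gt(rep$frequency[1], rep$frequency[1000])
  expect_true(all(diff(rep$frequency) <= 0))
  expect_equal(sum(rep$frequency), 1, tolerance = 1e-9)
})

test_that("recombination respects anchors, trims and frame", {
  vSeq <- as.character(segmentSeqs(ref, "V")[["V01"]])
  jSeq <- as.character(segmentSeqs(ref, "J")[["J01"]])
  va <- anchorPos(ref)[["V01"]]; ja <- anchorPos(ref)[["J01"]]
  # identity recombination: no trimming, no insertion
  r0 <- recombine(ref, "V01", "J01", vTrimRange = 0L, jTrimRange = 0L,
                  insRange = 0L)
  expect_equal(r0$cdr3_nt,
               paste0(substring(vSeq, va + 1), substr(jSeq, 1, ja + 3)))
  expect_equal(r0$junction_nt, "")
  set.seed(5)
  for (i in 1:50) {
    r <- recombine(ref, sample(segmentNames(ref)[1:8], 1),
                   sample(segmentNames(ref)[9:14], 1))
    expect_true(substr(r$cdr3_nt, 1, 3) %in% c("TGT", "TGC"))
    expect_true(substring(r$cdr3_nt, nchar(r$cdr3_nt) - 2) %in%
                  c("TTT", "TTC"))
    expect_equal(nchar(r$cdr3_nt) %% 3, 0)
  }
  set.seed(11); a <- recombine(ref, "V02", "J03")
  set.seed(11); b <- recombine(ref, "V02", "J03")
  expect_identical(a, b)
  expect_error(recombine(ref, "V01", "J01", vTrimRange = 50L), "anchor")
})

test_that("zero-error reads reproduce the template and the read layout", {
  cfg <- simConfig(nClones = 1, nMolecules = 1, meanReads = 3,
                   readDispersion = 1e9, subRate = 0, insRate = 0,
                   delRate = 0, seed = 2)
  rep <- simulateRepertoire(cfg, ref)
  run <- generateRun(rep, cfg)
  expect_gte(length(run$reads), 1L)
  expect_equal(length(unique(run$reads)), 1L)
  r <- run$reads[1]
  expect_equal(substr(r, 1, 5), cfg$sampleIndex)
  expect_equal(substr(r, 6, 17), run$truth$barcode[1])
  expect_equal(substr(r, 18, 32), "GTACATATTGTCGTT")
  expect_equal(substr(r, 33, 54), "CTCTGCTTCTGATGGCTCAAAC")
  # payload is the antisense of the molecule's sense sequence
  expect_equal(substr(r, 33, nchar(r)),
               substr(revComp(rep$sense_nt[1]), 1, cfg$readLength - 32))
})

test_that("read and molecule counts are conserved", {
  cfg <- simConfig(nClones = 100, nMolecules = 5000, subRate = 0,
                   insRate = 0, delRate = 0, seed = 3)
  rep <- simulateRepertoire(cfg, ref)
  run <- generateRun(rep, cfg)
  expect_equal(nrow(run$truth), 5000L)
  expect_equal(length(run$reads), sum(run$truth$n_reads))
  expect_equal(length(run$readIds), length(run$reads))
  cfg0 <- cfg; cfg0$nMolecules <- 0L
  expect_warning(empty <- generateRun(rep, cfg0), "empty")
  expect_length(empty$reads, 0L)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("deletions shorten barcode tags to the 11-bp class", {
  cfg <- simConfig(nClones = 50, nMolecules = 800, subRate = 0, insRate = 0,
                   delRate = 0.01, seed = 4)
  run <- generateRun(simulateRepertoire(cfg, ref), cfg)
  parsed <- parseReads(run$reads, cfg$sampleIndex, run$readIds)
  expect_true(any(nchar(parsed$tag[parsed$status == "ok"]) == 11L))
})

test_that("empirical per-base error rates match the configuration", {
  n <- 5000L; w <- 250L   # 1.25e6 template bases
  set.seed(8)
  seqs <- vapply(seq_len(n), function(i) rdna(w), character(1))
  tot <- as.numeric(n) * w
  se <- function(p) 3 * sqrt(p * (1 - p) * tot) / tot
  # substitutions only: lengths unchanged, mismatch count binomial
  set.seed(9)
  sub <- noirss:::.C_inject_errors(seqs, 0.002, 0, 0)
  mism <- sum(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), seqs, sub))
  expect_true(all(nchar(sub) == w))
  expect_lt(abs(mism / tot - 0.002), se(0.002))
  # deletions only: length deficit binomial
  set.seed(10)
  del <- noirss:::.C_inject_errors(seqs, 0, 0, 0.004)
  expect_lt(abs(sum(w - nchar(del)) / tot - 0.004), se(0.004))
  # insertions only: length excess binomial
  set.seed(11)
  ins <- noirss:::.C_inject_errors(seqs, 0, 0.004, 0)
  expect_lt(abs(sum(nchar(ins) - w) / tot - 0.004), se(0.004))
})

test_that("barcode collisions follow the uniform 12-mer birthday bound", {
  cfg <- simConfig(nClones = 20, nMolecules = 20000, meanReads = 1,
                   readDispersion = 1e9, subRate = 0, insRate = 0,
                   delRate = 0, seed = 6)
  run <- generateRun(simulateRepertoire(cfg, ref), cfg)
  colliding <- sum(duplicated(run$truth$barcode))
  lambda <- choose(20000, 2) / 4^12    # expected colliding pairs ~ 11.9
  expect_gt(colliding, 0)
  expect_lt(colliding, qpois(0.9999, lambda) + 1)
  # distinct-barcode mode removes collisions entirely
  cfg$distinctBarcodes <- TRUE
  run2 <- generateRun(simulateRepertoire(cfg, ref), cfg)
  expect_equal(sum(duplicated(run2$truth$barcode)), 0L)
})
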