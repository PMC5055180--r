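test_that("abundance spectra count frequencies of frequencies", {
  s <- abundanceSpectrum(c(1, 1, 2, 3, 15))
  expect_equal(s$f, c("1" = 2L, "2" = 1L, "3" = 1L, "15" = 1L))
  expect_equal(s$N, 22L)
  expect_equal(s$S_obs, 5L)
  s2 <- abundanceSpectrum(rep(1, 7))
  expect_equal(s2$f, c("1" = 7L))
  expect_equal(s2$N, 7L)
  expect_equal(abundanceSpectrum(c(20, 20))$f, c("20" = 2L))
  expect_error(abundanceSpectrum(integer(0)), "empty")
  expect_error(abundanceSpectrum(c(1, 0)), "positive")
})

test_that("ACE reproduces hand-checked and degenerate cases", {
  r <- aceRichness(c(1, 1, 1, 2, 2, 5, 20))
  expect_equal(r$c_ace, 0.75)
  expect_equal(r$gamma2, 5 / 11)
  expect_equal(r$s_ace, 10.81818, tolerance = 1e-5)
  # F1 = 0 forces coverage 1 and no correction
  expect_equal(aceRichness(c(2, 2, 3))$s_ace, 3)
  # no rare group at all: the estimate is the abundant count
  expect_equal(aceRichness(rep(20, 5))$s_ace, 5)
  # all-singleton rare group falls back to Chao1 with a warning
  expect_warning(ch <- aceRichness(c(1, 1, 1)), "Chao1")
  expect_equal(ch$s_ace, 3 + 3 * 2 / 2)
  expect_equal(ch$method, "Chao1")
  expect_error(aceRichness(c(1)), "undefined")
})

test_that("ACE matches vegan's estimator on random spectra", {
  library(vegan)
  set.seed(51)
  worst <- 0
  for (i in 1:200) {
    cnt <- pmax(1L, rnbinom(sample(10:80, 1), mu = sample(c(2, 6, 15), 1),
                            size = 0.7))
    r <- withCallingHandlers(
      tryCatch(aceRichness(cnt), error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(r) || r$method != "ACE" || r$s_rare == 0) next
    v <- suppressWarnings(unname(estimateR(cnt)["S.ACE"]))
    worst <- max(worst, abs(r$s_ace - v))
  }
  expect_lt(worst, 1e-9)
})

test_that("ACE is at least the observed richness off the degenerate cases", {
  set.seed(52)
  for (i in 1:50) {
    cnt <- pmax(1L, rpois(sample(20:100, 1), sample(c(1, 3, 8), 1)))
    r <- suppressWarnings(aceRichness(cnt))
    expect_gte(r$s_ace + 1e-9, r$s_obs)
  }
})

test_that("rarefaction matches enumeration, vegan and boundary identities", {
  # counts [3,1], m = 2: all 6 two-molecule subsets -> E = 1.5
  expect_equal(rarefactionCurve(c(3, 1), 2)$expected_richness, 1.5)
  expect_equal(rarefactionCurve(c(3, 1), 1)$expected_richness, 1)
  expect_equal(rarefactionCurve(c(3, 1), 4)$expected_richness, 2)
  cnt <- c(5, 3, 2, 1)
  expect_equal(rarefactionCurve(cnt, sum(cnt))$expected_richness, 4)
  library(vegan)
  for (m in c(2, 5, 8))
    expect_equal(rarefactionCurve(cnt, m)$expected_richness,
                 as.numeric(rarefy(cnt, m)), tolerance = 1e-9)
  expect_error(rarefactionCurve(cnt, 12), "between")
  grid <- rarefactionCurve(cnt, 1:11)$expected_richness
  expect_true(all(diff(grid) > 0))
})

test_that("hypergeometric subsampling is exact in distribution", {
  cnt <- c(a = 30, b = 10, c = 5)
  expect_equal(subsampleCounts(cnt, sum(cnt)), cnt)
  expect_equal(subsampleCounts(cnt, 20, seed = 3),
               subsampleCounts(cnt, 20, seed = 3))
  expect_error(subsampleCounts(cnt, 100), "exceeds")
  set.seed(53)
  draws <- replicate(1000, subsampleCounts(cnt, 20)[1])
  expect_equal(sum(draws != round(draws)), 0)
  m <- 20; N <- 45; K <- 30
  mu <- m * K / N
  v <- m * (K / N) * (1 - K / N) * (N - m) / (N - 1)
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(v / 1000))
})

test_that("abundance class boundaries are left-closed at 0.01% and 0.1%", {
  cls <- frequencyClasses(c(9, 10, 99, 100, 5000), N = 1e5)
  expect_equal(as.character(cls), c("low", "middle", "middle", "high",
                                    "high"))
  sm <- attr(cls, "summary")
  expect_equal(sum(sm$fraction), 1)
})

test_that("V/J usage fractions normalise and respond to weighting", {
  tab <- data.frame(sample_id = "s", v_name = c("V01", "V01", "V02"),
                    j_name = c("J01", "J02", "J02"),
                    n_molecules = c(100, 1, 1))
  u <- vjUsage(tab)
  expect_equal(sum(u$v$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(u$j$fraction), 1, tolerance = 1e-12)
  expect_equal(u$v$fraction[u$v$segment == "V01"], 101 / 102)
  uc <- vjUsage(tab, "by_clonotype")
  expect_equal(uc$v$fraction[uc$v$segment == "V01"], 2 / 3)
  single <- vjUsage(data.frame(sample_id = "s", v_name = "V05",
                               j_name = "J03", n_molecules = 7))
  expect_equal(single$v$fraction, 1)
})

test_that("sharing tables follow the two category rules", {
  mk <- function(id, aa, n) data.frame(sample_id = id, cdr3_aa = aa,
                                       n_molecules = n,
                                       stringsAsFactors = FALSE)
  # sample sets {A,B}, {B,C}, {B}: B shared by 3, nothing shared by 2
  s1 <- mk("p1", c("A", "B"), c(5, 5))
  s2 <- mk("p2", c("B", "C"), c(5, 5))
  s3 <- mk("p3", "B", 5)
  sh <- sharingTable(list(s1, s2, s3))
  expect_equal(sum(sh$in_all[sh$n_samples == 2]), 0)
  expect_equal(sum(sh$in_all[sh$n_samples == 3]), 1)
  expect_equal(sum(sh$at_least_one[sh$n_samples == 3]), 1)
  expect_error(sharingTable(list(s1, s1)), "duplicate")
  # class rules: low in one sample, high in the other
  t1 <- mk("p1", c("Z", "W"), c(1, 99999))        # Z: 1e-5 -> low
  t2 <- mk("p2", c("Z", "Y"), c(5000, 5000))      # Z: 0.5  -> high
  sh2 <- sharingTable(list(t1, t2))
  expect_equal(sh2$in_all[sh2$n_samples == 2 & sh2$class == "low"], 1)
  expect_equal(sh2$at_least_one[sh2$n_samples == 2 & sh2$class == "high"], 1)
  expect_equal(sum(sh2$in_all[sh2$n_samples == 2]),
               sum(sh2$at_least_one[sh2$n_samples == 2]))
})

test_that("aa-level sharing catches convergent nt-disjoint clonotypes", {
  nt1 <- data.frame(sample_id = "p1", v_name = "V01", j_name = "J01",
                    cdr3_nt = "TGTTTT", cdr3_aa = "CF", n_molecules = 3)
  nt2 <- data.frame(sample_id = "p2", v_name = "V02", j_name = "J01",
                    cdr3_nt = "TGCTTC", cdr3_aa = "CF", n_molecules = 4)
  shAA <- sharingTable(list(nt1, nt2), level = "aa")
  expect_equal(sum(shAA$in_all), 1)
  shNT <- sharingTable(list(nt1, nt2), level = "nt")
  expect_equal(sum(shNT$in_all), 0)
})
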