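#' Abundance spectrum (frequency of frequencies)
#'
#' Condenses clonotype molecule counts into the frequency-of-frequencies
#' vector `F_i` = number of clonotypes observed with exactly `i` molecules,
#' the basis of the ACE richness estimator and of rarefaction.
#'
#' @param counts integer vector of molecules per clonotype (all >= 1).
#' @param k rare-group cutoff: clonotypes with 1..k molecules form the rare
#'   group (default 10, matching an estimator fed by the counts of
#'   sequences appearing as 1-10 molecules).
#' @return list of class `AbundanceSpectrum`: `f` (named integer vector,
#'   names are abundances `i` with `F_i > 0`), `N` (total molecules),
#'   `S_obs` (total clonotypes), `k`.
#' @export
abundanceSpectrum <- function(counts, k = 10L) {
  if (!length(counts)) stop("empty clonotype table")
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 1L))
    stop("counts must be positive integers")
  tb <- table(counts)
  f <- setNames(as.integer(tb), names(tb))
  spec <- list(f = f, N = sum(counts), S_obs = length(counts),
               k = as.integer(k))
  class(spec) <- "AbundanceSpectrum"
  spec
}

.asSpectrum <- function(x, k = 10L) {
  if (inherits(x, "AbundanceSpectrum")) x else abundanceSpectrum(x, k)
}

# expand a spectrum back to one count per clonotype
.spectrumCounts <- function(spec) {
  rep(as.integer(names(spec$f)), spec$f)
}

#' ACE richness estimate (Chao & Lee abundance-based coverage estimator)
#'
#' Estimates total clonotype richness from the abundance spectrum. With
#' `F_i` the number of clonotypes seen `i` times and rare cutoff `k`:
#' `S_rare = sum_{i<=k} F_i`, `N_rare = sum_{i<=k} i F_i`, sample coverage
#' `C_ACE = 1 - F_1 / N_rare`, squared coefficient of variation
#' `gamma^2 = max((S_rare / C_ACE) * sum_{i<=k} i (i-1) F_i /
#' (N_rare (N_rare - 1)) - 1, 0)`, and
#' `S_ACE = S_abund + S_rare / C_ACE + (F_1 / C_ACE) * gamma^2`.
#'
#' Degenerate cases: with no rare clonotypes the estimate is `S_abund`;
#' when every rare clonotype is a singleton (`C_ACE = 0`) the estimator is
#' undefined and the Chao1 estimate `S_obs + F_1 (F_1 - 1) / 2` is returned
#' with a warning.
#'
#' @param x an `AbundanceSpectrum` or a vector of clonotype counts.
#' @param k rare-group cutoff (used when `x` is a count vector).
#' @return list of class `RichnessEstimate`: `s_ace`, `s_obs`, `s_rare`,
#'   `s_abund`, `c_ace`, `gamma2`, `method` (`"ACE"` or `"Chao1"`).
#' @export
aceRichness <- function(x, k = 10L) {
  spec <- .asSpectrum(x, k)
  i <- as.integer(names(spec$f)); f <- as.numeric(spec$f)
  rare <- i <= spec$k
  sRare <- sum(f[rare]); sAbund <- sum(f[!rare])
  nRare <- sum(i[rare] * f[rare])
  f1 <- if (any(i == 1L)) f[i == 1L] else 0
  res <- list(s_ace = NA_real_, s_obs = spec$S_obs, s_rare = sRare,
              s_abund = sAbund, c_ace = NA_real_, gamma2 = NA_real_,
              method = "ACE")
  if (sRare == 0) {
    res$s_ace <- sAbund
    class(res) <- "RichnessEstimate"
    return(res)
  }
  if (nRare <= 1)
    stop("rare group holds a single molecule; ACE is undefined")
  cAce <- 1 - f1 / nRare
  if (cAce == 0) {
    warning("all rare clonotypes are singletons; falling back to Chao1")
    res$method <- "Chao1"
    res$c_ace <- 0
    res$s_ace <- spec$S_obs + f1 * (f1 - 1) / 2
    class(res) <- "RichnessEstimate"
    return(res)
  }
  g2 <- max((sRare / cAce) * sum(i[rare] * (i[rare] - 1) * f[rare]) /
              (nRare * (nRare - 1)) - 1, 0)
  res$c_ace <- cAce
  res$gamma2 <- g2
  res$s_ace <- sAbund + sRare / cAce + (f1 / cAce) * g2
  class(res) <- "RichnessEstimate"
  res
}

#' Rarefaction: expected richness in a random subsample
#'
#' Closed-form expected number of distinct clonotypes in a random draw of
#' `m` molecules without replacement:
#' `E[S_m] = sum_j (1 - choose(N - N_j, m) / choose(N, m))`, computed with
#' log-binomials for numerical stability.
#'
#' @param x an `AbundanceSpectrum` or a vector of clonotype counts.
#' @param m integer vector of subsample sizes (each `<= N`).
#' @return data.frame with columns `m` and `expected_richness`.
#' @export
rarefactionCurve <- function(x, m) {
  spec <- .asSpectrum(x)
  N <- spec$N
  if (any(m < 0L | m > N)) stop("m must be between 0 and N = ", N)
  i <- as.integer(names(spec$f)); f <- as.numeric(spec$f)
  es <- vapply(m, function(mm) {
    p <- exp(lchoose(N - i, mm) - lchoose(N, mm))  # P(clonotype missed)
    sum(f * (1 - p))
  }, numeric(1))
  data.frame(m = m, expected_richness = es)
}

#' Default log-spaced rarefaction grid
#' @param N total molecules.
#' @param points number of grid points (default 20).
#' @return integer vector of subsample sizes ending at `N`.
#' @export
rarefactionGrid <- function(N, points = 20L) {
  unique(pmin(N, c(round(exp(seq(log(1), log(N), length.out = points))))))
}

#' Random subsample of molecules without replacement
#'
#' Multivariate hypergeometric draw of `m` of the `N` molecules; the
#' counterpart of a fixed-size subsample (e.g. 100,000 molecules) used to
#' compare abundance distributions across samples of unequal depth.
#'
#' @param counts integer vector of molecules per clonotype.
#' @param m subsample size (`<= sum(counts)`).
#' @param seed optional integer seed for a deterministic draw.
#' @return integer vector of subsampled counts (same length/names as
#'   `counts`; zeros are kept so positions still line up).
#' @export
subsampleCounts <- function(counts, m, seed = NULL) {
  counts <- setNames(as.integer(counts), names(counts))
  N <- sum(counts)
  if (m > N) stop("m exceeds the number of molecules (", N, ")")
  if (!is.null(seed)) set.seed(seed)
  if (m == N) return(counts)
  picked <- sample.int(N, m)
  cum <- cumsum(counts)
  idx <- findInterval(picked - 1L, cum) + 1L
  out <- tabulate(idx, nbins = length(counts))
  names(out) <- names(counts)
  out
}

#' Abundance classes (low / middle / high)
#'
#' Classifies clonotypes by their frequency `n_molecules / N`:
#' low `< 0.01%`, middle `0.01-0.1%` (left-closed), high `>= 0.1%`.
#'
#' @param counts integer vector of molecules per clonotype.
#' @param N total molecules used as the denominator (default
#'   `sum(counts)`).
#' @return factor of classes (levels `low`, `middle`, `high`) with a
#'   `summary` attribute: data.frame of per-class clonotype counts and
#'   fractions of unique clonotypes.
#' @export
frequencyClasses <- function(counts, N = sum(counts)) {
  fr <- counts / N
  cls <- cut(fr, breaks = c(-Inf, 1e-4, 1e-3, Inf),
             labels = c("low", "middle", "high"), right = FALSE)
  tb <- table(cls)
  attr(cls, "summary") <- data.frame(
    class = names(tb), n_clonotypes = as.integer(tb),
    fraction = as.numeric(tb) / length(counts))
  cls
}

#' V/J segment usage
#'
#' Fraction of the repertoire attributed to each observed segment, either
#' weighted by molecule counts (`by_molecule`) or counting each clonotype
#' once (`by_clonotype`). Fractions sum to 1 per kind.
#'
#' @param clonotypes nucleotide clonotype table from
#'   [aggregateClonotypes()] (columns `v_name`, `j_name`, `n_molecules`).
#' @param weighting `"by_molecule"` or `"by_clonotype"`.
#' @return list with data.frames `v` and `j` (columns `segment`,
#'   `fraction`).
#' @export
vjUsage <- function(clonotypes, weighting = c("by_molecule", "by_clonotype")) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "by_molecule") clonotypes$n_molecules
       else rep(1, nrow(clonotypes))
  one <- function(seg) {
    tb <- tapply(w, seg, sum)
    data.frame(segment = names(tb), fraction = as.numeric(tb) / sum(w),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(v = one(clonotypes$v_name), j = one(clonotypes$j_name))
}

#' Cross-sample clonotype sharing table
#'
#' For every clonotype present in at least two samples, the abundance class
#' ([frequencyClasses()], computed within each sample) is evaluated in each
#' sample where it occurs. Sharing counts are reported for each number of
#' sharing samples `m = 2..n` under two category rules: `in_all` assigns
#' the clonotype to the minimum class over the samples sharing it (the
#' class it reaches in all of them), `at_least_one` to the maximum class
#' attained in any sample.
#'
#' @param samples list of clonotype tables (nt or aa level, from
#'   [aggregateClonotypes()]), each with a distinct `sample_id`.
#' @param level `"aa"` (key: `cdr3_aa`) or `"nt"` (key: `v_name`, `j_name`,
#'   `cdr3_nt`).
#' @return data.frame with columns `n_samples`, `class`, `in_all`,
#'   `at_least_one`.
#' @export
sharingTable <- function(samples, level = c("aa", "nt")) {
  level <- match.arg(level)
  if (length(samples) < 2L) stop("sharing requires at least two samples")
  ids <- vapply(samples, function(s) s$sample_id[1L], character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  keyOf <- function(s) {
    if (level == "aa") s$cdr3_aa
    else paste(s$v_name, s$j_name, s$cdr3_nt, sep = "\r")
  }
  long <- do.call(rbind, lapply(samples, function(s) {
    cls <- frequencyClasses(s$n_molecules)
    data.frame(key = keyOf(s), cls = as.integer(cls),
               stringsAsFactors = FALSE)
  }))
  byKey <- split(long$cls, long$key)
  nShared <- lengths(byKey)
  shared <- byKey[nShared >= 2L]
  lv <- c("low", "middle", "high")
  grid <- expand.grid(n_samples = 2:length(samples),
                      class = factor(lv, levels = lv))
  cnt <- function(m, cls, rule) {
    sel <- shared[lengths(shared) == m]
    if (!length(sel)) return(0L)
    val <- vapply(sel, rule, integer(1))
    sum(val == cls)
  }
  grid$in_all <- mapply(function(m, cl) cnt(m, match(cl, lv),
                                            function(x) min(x)),
                        grid$n_samples, grid$class)
  grid$at_least_one <- mapply(function(m, cl) cnt(m, match(cl, lv),
                                                  function(x) max(x)),
                              grid$n_samples, grid$class)
  grid$class <- as.character(grid$class)
  grid
}
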