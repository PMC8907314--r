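# Drift-based power simulation for detecting genetic differentiation: the
# classical design of simulating subpopulations diverged to a target F_ST by
# binomial drift, sampling study-sized genotype samples, and testing the
# null of no differentiation with chi-square or Fisher exact tests summed or
# combined over loci.

#' Power-simulation configuration
#'
#' @param base_freqs matrix (loci x alleles) of base allele frequencies, or
#'   `NULL` to draw `n_loci` loci with `alleles_per_locus` near-uniform
#'   alleles (Dirichlet with concentration `freq_concentration`)
#' @param n_loci,alleles_per_locus,freq_concentration base-frequency draw
#'   settings when `base_freqs` is `NULL`
#' @param s subpopulations
#' @param sample_sizes diploid individuals sampled per subpopulation
#'   (recycled to length `s`)
#' @param Ne effective size for the drift mechanism
#' @param t drift generations; `NULL` solves t from `target_fst` at the
#'   configured Ne. When both `t` and `target_fst` are given they must agree
#'   through 1 - (1 - 1/(2*Ne))^t to within 1e-9.
#' @param target_fst expected differentiation; 0 means no drift (size/type-I
#'   configuration)
#' @param n_reps simulation replicates
#' @param alpha test level
#' @param test `"chi2_sum"`, `"fisher_combined"`, or both
#' @param fisher_mc Monte-Carlo tables per locus for the Fisher exact test
#' @param seed RNG seed
#' @return list of class `power_config`
#' @export
power_config <- function(base_freqs = NULL, n_loci = 10,
                         alleles_per_locus = 8, freq_concentration = 100,
                         s = 4, sample_sizes = 40, Ne = 1000, t = NULL,
                         target_fst = 0.05, n_reps = 500, alpha = 0.05,
                         test = "chi2_sum", fisher_mc = 2000, seed = 1L) {
  stopifnot(s >= 2, Ne >= 1, n_reps >= 1, alpha > 0, alpha < 1,
            all(test %in% c("chi2_sum", "fisher_combined")))
  if (!is.null(t) && !is.null(target_fst)) {
    if (abs(expected_fst_drift(Ne, t) - target_fst) > 1e-9)
      stop("t and target_fst disagree under the drift expectation")
  } else if (is.null(t)) {
    t <- drift_generations(target_fst, Ne)
  } else target_fst <- expected_fst_drift(Ne, t)
  structure(list(base_freqs = base_freqs, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus,
                 freq_concentration = freq_concentration, s = s,
                 sample_sizes = rep(sample_sizes, length.out = s),
                 Ne = Ne, t = as.integer(t), target_fst = target_fst,
                 n_reps = n_reps, alpha = alpha, test = test,
                 fisher_mc = fisher_mc, seed = as.integer(seed)),
            class = "power_config")
}

#' Drift base frequencies into independent subpopulations
#'
#' Each subpopulation undergoes `t` rounds of multinomial resampling of
#' 2*Ne gene copies, independently per locus. `t = 0` returns the base
#' frequencies unchanged for every subpopulation.
#'
#' @param base matrix (loci x alleles) of base frequencies
#' @param Ne effective size
#' @param t generations
#' @param s subpopulations
#' @return array `[locus, allele, subpop]`
#' @export
drift_frequencies <- function(base, Ne, t, s) {
  L <- nrow(base); k <- ncol(base)
  out <- array(NA_real_, c(L, k, s))
  for (pop in seq_len(s)) for (l in seq_len(L)) {
    p <- base[l, ]
    if (t > 0) for (g in seq_len(t))
      p <- as.vector(stats::rmultinom(1, 2 * Ne, p)) / (2 * Ne)
    out[l, , pop] <- p
  }
  out
}

#' Test the null of no differentiation on allele-count tables
#'
#' `chi2_sum`: per-locus Pearson chi-square on the subpopulation x allele
#' count table (all-zero allele columns dropped), statistics and degrees of
#' freedom summed over loci, p from the chi-square tail. `fisher_combined`:
#' per-locus Monte-Carlo Fisher exact p on the same table, combined over loci
#' by -2 * sum(log p) against chi-square with 2 * n_loci df.
#'
#' @param counts list per locus of integer matrices (subpop x allele)
#' @param method `"chi2_sum"` or `"fisher_combined"`
#' @param fisher_mc Monte-Carlo tables per locus (Fisher method)
#' @return p-value
#' @export
differentiation_test <- function(counts, method = c("chi2_sum",
                                                    "fisher_combined"),
                                 fisher_mc = 2000) {
  method <- match.arg(method)
  keep <- vapply(counts, function(tab) sum(tab) > 0 &&
                   sum(colSums(tab) > 0) >= 2L, logical(1))
  counts <- counts[keep]
  if (!length(counts)) stop("no usable locus table")
  if (method == "chi2_sum") {
    stat <- 0; df <- 0
    for (tab in counts) {
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      stat <- stat + sum((tab - e)^2 / e)
      df <- df + (nrow(tab) - 1) * (ncol(tab) - 1)
    }
    stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    lp <- vapply(counts, function(tab) {
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      log(stats::fisher.test(tab, simulate.p.value = TRUE,
                             B = fisher_mc)$p.value)
    }, numeric(1))
    stats::pchisq(-2 * sum(lp), df = 2 * length(lp), lower.tail = FALSE)
  }
}

#' Estimate power of the differentiation tests by simulation
#'
#' Each replicate drifts the base frequencies to the target differentiation,
#' samples 2n gene copies per subpopulation per locus (multinomial genotype
#' sampling under within-population Hardy-Weinberg), and applies the
#' requested tests; power is the fraction of replicates rejecting at
#' `alpha`. With `target_fst = 0` (t = 0) the same machinery estimates the
#' type-I error.
#'
#' @param cfg a [power_config()]
#' @return list of class `power_result`: per test, `power`, `se` (Monte-Carlo
#'   standard error sqrt(p(1-p)/n_reps)) and the replicate p-values; plus the
#'   drift settings used
#' @export
estimate_power <- function(cfg) {
  set.seed(cfg$seed)
  base <- cfg$base_freqs
  if (is.null(base))
    base <- t(vapply(seq_len(cfg$n_loci), function(l)
      rdirichlet1(cfg$alleles_per_locus, cfg$freq_concentration),
      numeric(cfg$alleles_per_locus)))
  L <- nrow(base)
  pvals <- lapply(cfg$test, function(m) numeric(cfg$n_reps))
  names(pvals) <- cfg$test
  for (rep_i in seq_len(cfg$n_reps)) {
    fr <- drift_frequencies(base, cfg$Ne, cfg$t, cfg$s)
    counts <- lapply(seq_len(L), function(l) {
      t(vapply(seq_len(cfg$s), function(pop)
        as.vector(stats::rmultinom(1, 2 * cfg$sample_sizes[pop],
                                   fr[l, , pop])),
        numeric(ncol(base))))
    })
    for (m in cfg$test)
      pvals[[m]][rep_i] <- differentiation_test(counts, m, cfg$fisher_mc)
  }
  res <- lapply(cfg$test, function(m) {
    pw <- mean(pvals[[m]] < cfg$alpha)
    list(power = pw, se = sqrt(pw * (1 - pw) / cfg$n_reps),
         p_values = pvals[[m]])
  })
  names(res) <- cfg$test
  structure(c(res, list(target_fst = cfg$target_fst, Ne = cfg$Ne,
                        t = cfg$t, n_reps = cfg$n_reps, alpha = cfg$alpha)),
            class = "power_result")
}
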