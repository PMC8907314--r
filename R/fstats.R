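# Multilocus Weir-Cockerham F-statistics with bootstrap confidence
# intervals, and rarefaction-standardized allelic richness. All F-statistic
# computations use diploid females (post sister-dedup); males are excluded.

fem_rows <- function(ds) {
  which(ds$meta$sex == "female" & ds$meta$ploidy == 2L)
}

#' Weir-Cockerham variance components for one locus
#'
#' The among-population (a), among-individual-within-population (b) and
#' within-individual (c) variance components of the Weir-Cockerham
#' differentiation estimator, computed per allele and summed, with the
#' standard n_c correction for unequal sample sizes. Sites are the
#' subpopulations; only typed diploid females enter.
#'
#' @param ds a [genotype_dataset()] slice for one species
#' @param locus locus name or index
#' @return list with `a`, `b`, `c` (summed over alleles) and `monomorphic`
#'   flag; monomorphic loci return zeros
#' @export
wc_components <- function(ds, locus) {
  j <- if (is.character(locus)) match(locus, ds$loci) else as.integer(locus)
  rows <- fem_rows(ds)
  rows <- rows[!is.na(ds$a1[rows, j])]
  sites <- split(rows, ds$meta$site[rows])
  sites <- sites[vapply(sites, length, 1L) >= 2L]
  if (length(sites) < 2L)
    stop("need >= 2 sites with >= 2 typed diploid females")
  r <- length(sites)
  n_i <- vapply(sites, length, 1L)
  alleles <- sort(unique(c(ds$a1[rows, j], ds$a2[rows, j])))
  if (length(alleles) < 2L)
    return(list(a = 0, b = 0, c = 0, monomorphic = TRUE))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  A <- B <- C <- 0
  for (al in alleles) {
    p_i <- vapply(sites, function(rr)
      (sum(ds$a1[rr, j] == al) + sum(ds$a2[rr, j] == al)) /
        (2 * length(rr)), numeric(1))
    h_i <- vapply(sites, function(rr)
      mean(ds$a1[rr, j] != ds$a2[rr, j] &
             (ds$a1[rr, j] == al | ds$a2[rr, j] == al)), numeric(1))
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    A <- A + (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    B <- B + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    C <- C + hbar / 2
  }
  list(a = A, b = B, c = C, monomorphic = FALSE)
}

# per-locus component matrix; loci that cannot be computed get NA rows
fstat_component_matrix <- function(ds) {
  out <- matrix(NA_real_, n_loci(ds), 3,
                dimnames = list(ds$loci, c("a", "b", "c")))
  for (j in seq_len(n_loci(ds))) {
    comp <- tryCatch(wc_components(ds, j), error = function(e) NULL)
    if (is.null(comp) || comp$monomorphic) next
    out[j, ] <- c(comp$a, comp$b, comp$c)
  }
  out
}

#' Multilocus Weir-Cockerham F_ST and F_IS
#'
#' theta = sum(a) / sum(a + b + c) and f = 1 - sum(c) / sum(b + c), with the
#' sums over alleles and loci. Negative estimates are reported as computed
#' (no truncation at zero).
#'
#' @param ds a [genotype_dataset()] slice for one species (sites as
#'   subpopulations, diploid females only)
#' @return list with `theta` (F_ST), `f` (F_IS), `components` (per-locus
#'   matrix), `n_loci_used`
#' @export
multilocus_fstats <- function(ds) {
  comp <- fstat_component_matrix(ds)
  use <- stats::complete.cases(comp)
  if (!any(use)) stop("no polymorphic locus usable for F-statistics")
  s <- colSums(comp[use, , drop = FALSE])
  list(theta = s["a"] / sum(s),
       f = 1 - s["c"] / (s["b"] + s["c"]),
       components = comp, n_loci_used = sum(use))
}

#' Bootstrap confidence interval for multilocus F-statistics
#'
#' Percentile interval from resampling loci with replacement — the statistic
#' is a ratio of per-locus component sums, so the locus is the natural
#' resampling unit.
#'
#' @param ds a [genotype_dataset()] slice for one species
#' @param statistic `"theta"` (F_ST) or `"f"` (F_IS)
#' @param n_boot bootstrap replicates
#' @param seed RNG seed
#' @param level confidence level
#' @return numeric `c(lo, hi)`
#' @export
bootstrap_ci <- function(ds, statistic = c("theta", "f"), n_boot = 1000,
                         seed = 1L, level = 0.95) {
  statistic <- match.arg(statistic)
  comp <- fstat_component_matrix(ds)
  comp <- comp[stats::complete.cases(comp), , drop = FALSE]
  if (nrow(comp) < 2L) stop("need >= 2 usable loci for a bootstrap CI")
  set.seed(seed)
  stat <- function(m) {
    s <- colSums(m)
    if (statistic == "theta") s["a"] / sum(s) else 1 - s["c"] / (s["b"] + s["c"])
  }
  reps <- vapply(seq_len(n_boot), function(b)
    stat(comp[sample.int(nrow(comp), replace = TRUE), , drop = FALSE]),
    numeric(1))
  as.numeric(stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                             na.rm = TRUE, names = FALSE))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies: AR = sum over alleles of 1 - C(N - N_a, g) / C(N, g), where N is
#' the number of typed gene copies and N_a the count of allele a. Loci with
#' fewer than `g` copies in the stratum are excluded with a flag.
#'
#' @param ds a [genotype_dataset()]
#' @param g rarefaction depth in gene copies
#' @param rows optional individual subset defining the stratum
#' @return list with `per_locus` (named AR values, `NA` where excluded),
#'   `mean`, `se` (simple SE over loci), `g`, `excluded` (locus names)
#' @export
rarefied_ar <- function(ds, g, rows = NULL) {
  stopifnot(g >= 1)
  rows <- rows %||% seq_len(n_ind(ds))
  per <- stats::setNames(rep(NA_real_, n_loci(ds)), ds$loci)
  for (j in seq_len(n_loci(ds))) {
    cnt <- allele_counts_at(ds, j, rows)
    N <- sum(cnt)
    if (N < g || N == 0L) next
    per[j] <- sum(1 - exp(lchoose(N - cnt, g) - lchoose(N, g)))
  }
  vals <- per[!is.na(per)]
  list(per_locus = per,
       mean = if (length(vals)) mean(vals) else NA_real_,
       se = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals))
            else NA_real_,
       g = g, excluded = names(per)[is.na(per)])
}

#' Population-genetic summary per species
#'
#' The full Table-3-shaped summary: multilocus F_ST and F_IS with bootstrap
#' CIs, per-site rarefied allelic richness at depth `g_sub`, and global AR at
#' depth `g_glob`. Sites with fewer than `min_pop` genotyped diploid females
#' are excluded from F-statistics and site AR (but all females still enter
#' global AR, mirroring standard practice). Rarefaction depths default to
#' twice the smallest retained subpopulation size and twice the smallest
#' species total, computed from the data.
#'
#' @param ds a [genotype_dataset()] (may span several species)
#' @param min_pop minimum genotyped females for a site to enter
#'   F-statistics/site AR
#' @param g_sub,g_glob rarefaction depths in gene copies (`NULL`: computed
#'   from the data across species)
#' @param n_boot,seed bootstrap settings
#' @return list of class `popgen_summary`, one element per species, each with
#'   `theta`, `f`, `theta_ci`, `f_ci`, `ar_site` (list per retained site),
#'   `ar_global`, `excluded_sites`, `g_sub`, `g_glob`
#' @export
popgen_summary <- function(ds, min_pop = 25, g_sub = NULL, g_glob = NULL,
                           n_boot = 1000, seed = 1L) {
  rows_all <- fem_rows(ds)
  meta <- ds$meta[rows_all, ]
  site_n <- stats::aggregate(list(n = meta$id),
                             by = meta[c("species", "site")], FUN = length)
  retained <- site_n[site_n$n >= min_pop, , drop = FALSE]
  # smallest typed gene-copy count per locus within a set of strata; caps
  # the rarefaction depth so missing calls cannot exclude every locus
  min_copies <- function(strata_rows) {
    mins <- vapply(strata_rows, function(rr)
      min(vapply(seq_len(n_loci(ds)), function(j)
        sum(allele_counts_at(ds, j, rr)), numeric(1))), numeric(1))
    if (length(mins)) min(mins) else Inf
  }
  if (is.null(g_sub) && nrow(retained)) {
    ret_rows <- lapply(seq_len(nrow(retained)), function(k)
      rows_all[meta$species == retained$species[k] &
                 meta$site == retained$site[k]])
    g_sub <- min(2L * min(retained$n), min_copies(ret_rows))
  } else if (is.null(g_sub)) g_sub <- NA_integer_
  sp_n <- stats::aggregate(list(n = meta$id), by = meta["species"],
                           FUN = length)
  if (is.null(g_glob)) {
    sp_rows <- lapply(sp_n$species, function(sp)
      rows_all[meta$species == sp])
    g_glob <- min(2L * min(sp_n$n), min_copies(sp_rows))
  }
  out <- list()
  for (sp in unique(meta$species)) {
    keep_sites <- retained$site[retained$species == sp]
    excl <- setdiff(site_n$site[site_n$species == sp], keep_sites)
    sel <- ds$meta$species == sp & ds$meta$sex == "female" &
      ds$meta$ploidy == 2L
    sel_f <- sel & ds$meta$site %in% keep_sites
    res <- list(excluded_sites = excl, g_sub = g_sub, g_glob = g_glob)
    if (length(keep_sites) >= 2L) {
      slice <- subset_dataset(ds, ind = sel_f)
      fs <- tryCatch(multilocus_fstats(slice), error = function(e) NULL)
      if (!is.null(fs)) {
        res$theta <- as.numeric(fs$theta); res$f <- as.numeric(fs$f)
        res$theta_ci <- tryCatch(bootstrap_ci(slice, "theta", n_boot, seed),
                                 error = function(e) c(NA, NA))
        res$f_ci <- tryCatch(bootstrap_ci(slice, "f", n_boot, seed),
                             error = function(e) c(NA, NA))
      }
      res$ar_site <- lapply(stats::setNames(keep_sites, keep_sites),
                            function(s)
                              rarefied_ar(slice, g_sub,
                                          rows = which(slice$meta$site == s)))
    }
    res$ar_global <- rarefied_ar(subset_dataset(ds, ind = sel), g_glob)
    out[[sp]] <- res
  }
  structure(out, class = "popgen_summary")
}
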