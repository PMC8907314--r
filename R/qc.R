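# Genotyping quality control: missingness and null-allele filters,
# Monte-Carlo exact HWE and LD tests, LD pruning, one-sister-per-colony
# deduplication. Filters are stratified per species (each species has its
# own usable locus panel); a locus is removed from the shared matrix only
# when no species retains it, and the per-species retained panels live in
# the QC report.

qc_report <- function(dropped_individuals = NULL, dropped_loci = NULL,
                      retained_panel = NULL, ld_pairs = NULL, hwe = NULL) {
  structure(list(dropped_individuals = dropped_individuals %||%
                   data.frame(id = character(), species = character(),
                              reason = character(), stringsAsFactors = FALSE),
                 dropped_loci = dropped_loci %||%
                   data.frame(species = character(), locus = character(),
                              reason = character(), estimate = numeric(),
                              stringsAsFactors = FALSE),
                 retained_panel = retained_panel %||% list(),
                 ld_pairs = ld_pairs, hwe = hwe),
            class = "qc_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

species_rows <- function(ds, sp) which(ds$meta$species == sp)

#' Filter individuals and loci by genotyping failure
#'
#' Per species, drops loci with a missing-call fraction at or above the
#' threshold, then individuals missing at or above the threshold of the
#' retained loci (loci first, because individual failure rates depend on the
#' panel). The default 0.20 enforces the standard "20% or greater genotyping
#' failure" rule; note the boundary is inclusive.
#'
#' @param ds a [genotype_dataset()]
#' @param threshold failure fraction in (0, 1]
#' @return list with `dataset` (filtered) and `report` (a `qc_report` whose
#'   `retained_panel` gives the per-species locus panel)
#' @export
filter_missingness <- function(ds, threshold = 0.20) {
  stopifnot(threshold > 0, threshold <= 1)
  drop_ind <- list(); drop_loc <- list(); panel <- list()
  keep_ind <- rep(TRUE, n_ind(ds))
  for (sp in unique(ds$meta$species)) {
    rows <- species_rows(ds, sp)
    if (!length(rows)) { warning("empty species stratum ", sp); next }
    miss_l <- colMeans(is.na(ds$a1[rows, , drop = FALSE]))
    bad_l <- miss_l >= threshold
    panel[[sp]] <- ds$loci[!bad_l]
    for (j in which(bad_l))
      drop_loc[[length(drop_loc) + 1L]] <-
        data.frame(species = sp, locus = ds$loci[j],
                   reason = "missingness", estimate = miss_l[j],
                   stringsAsFactors = FALSE)
    jj <- which(!bad_l)
    if (length(jj)) {
      miss_i <- rowMeans(is.na(ds$a1[rows, jj, drop = FALSE]))
      bad_i <- miss_i >= threshold
      keep_ind[rows[bad_i]] <- FALSE
      for (i in which(bad_i))
        drop_ind[[length(drop_ind) + 1L]] <-
          data.frame(id = ds$meta$id[rows[i]], species = sp,
                     reason = "missingness", stringsAsFactors = FALSE)
    }
  }
  keep_loc <- ds$loci %in% unique(unlist(panel))
  out <- subset_dataset(ds, ind = keep_ind, loci = which(keep_loc),
                        note = sprintf("filter_missingness(%.2f)", threshold))
  rep <- qc_report(
    dropped_individuals = if (length(drop_ind)) do.call(rbind, drop_ind)
                          else NULL,
    dropped_loci = if (length(drop_loc)) do.call(rbind, drop_loc) else NULL,
    retained_panel = panel)
  list(dataset = out, report = rep)
}

allele_counts_at <- function(ds, j, rows) {
  dip <- rows[ds$meta$ploidy[rows] == 2L]
  hap <- rows[ds$meta$ploidy[rows] == 1L]
  tab <- table(c(ds$a1[dip, j], ds$a2[dip, j], ds$a1[hap, j]), useNA = "no")
  stats::setNames(as.integer(tab), names(tab))
}

#' Null-allele frequency estimate from heterozygote deficit
#'
#' The heterozygote-deficit estimator r = (He - Ho) / (He + Ho), with He the
#' unbiased expected heterozygosity from sample allele frequencies and Ho the
#' observed heterozygote fraction, computed from diploid individuals in the
#' stratum. Negative values (heterozygote excess) are permitted; a
#' monomorphic locus returns 0 with attribute `monomorphic = TRUE`.
#'
#' @param ds a [genotype_dataset()]
#' @param locus locus name or index
#' @param rows optional individual subset (defaults to all diploids)
#' @return estimate in [-1, 1]
#' @export
estimate_null_freq <- function(ds, locus, rows = NULL) {
  j <- if (is.character(locus)) match(locus, ds$loci) else as.integer(locus)
  if (is.na(j)) stop("unknown locus")
  rows <- rows %||% seq_len(n_ind(ds))
  rows <- rows[ds$meta$ploidy[rows] == 2L & !is.na(ds$a1[rows, j])]
  n <- length(rows)
  if (n < 2L) stop("need >= 2 typed diploid individuals")
  a <- c(ds$a1[rows, j], ds$a2[rows, j])
  p <- as.vector(table(a)) / (2 * n)
  if (length(p) < 2L) return(structure(0, monomorphic = TRUE))
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  ho <- mean(ds$a1[rows, j] != ds$a2[rows, j])
  if (he + ho == 0) return(structure(0, monomorphic = TRUE))
  (he - ho) / (he + ho)
}

#' Drop loci with excessive null-allele frequency
#'
#' Per species, removes loci whose heterozygote-deficit null estimate is at
#' or above the threshold (default 0.25, the standard ">= 25% null allele
#' frequency" screen applied ahead of sibship reconstruction).
#'
#' @param ds a [genotype_dataset()]
#' @param threshold null-frequency cutoff (inclusive)
#' @return list with `dataset` and `report`
#' @export
filter_null_loci <- function(ds, threshold = 0.25) {
  drop_loc <- list(); panel <- list()
  for (sp in unique(ds$meta$species)) {
    rows <- species_rows(ds, sp)
    keep <- rep(TRUE, n_loci(ds))
    for (j in seq_len(n_loci(ds))) {
      rj <- rows[ds$meta$ploidy[rows] == 2L & !is.na(ds$a1[rows, j])]
      if (length(rj) < 2L) next
      r <- estimate_null_freq(ds, j, rows)
      if (!isTRUE(attr(r, "monomorphic")) && r >= threshold) {
        keep[j] <- FALSE
        drop_loc[[length(drop_loc) + 1L]] <-
          data.frame(species = sp, locus = ds$loci[j],
                     reason = "null_allele", estimate = as.numeric(r),
                     stringsAsFactors = FALSE)
      }
    }
    panel[[sp]] <- ds$loci[keep]
  }
  keep_loc <- ds$loci %in% unique(unlist(panel))
  out <- subset_dataset(ds, loci = which(keep_loc),
                        note = sprintf("filter_null_loci(%.2f)", threshold))
  list(dataset = out,
       report = qc_report(dropped_loci = if (length(drop_loc))
         do.call(rbind, drop_loc) else NULL, retained_panel = panel))
}

# log conditional probability kernel of a genotype array given its allele
# counts: -sum(log n_g!) + n_het*log 2 (terms constant under permutation of
# the allele multiset are dropped)
hwe_kernel <- function(g1, g2) {
  het <- sum(g1 != g2)
  key <- paste(pmin(g1, g2), pmax(g1, g2))
  -sum(lfactorial(tabulate(match(key, unique(key))))) + het * log(2)
}

#' Monte-Carlo exact Hardy-Weinberg test
#'
#' Exact-test style: the statistic is the conditional probability of the
#' observed genotype array given its allele counts; the null distribution is
#' generated by randomly re-pairing the observed allele multiset. The
#' two-sided p-value is the fraction of pairings no more probable than the
#' observed array, with the add-one correction (never exactly 0).
#'
#' @param ds a [genotype_dataset()]
#' @param locus locus name or index
#' @param rows optional individual subset (diploids used)
#' @param n_perm Monte-Carlo pairings
#' @param seed RNG seed
#' @return p-value; a monomorphic locus returns 1 by convention
#' @export
hwe_test <- function(ds, locus, rows = NULL, n_perm = 999, seed = 1L) {
  j <- if (is.character(locus)) match(locus, ds$loci) else as.integer(locus)
  rows <- rows %||% seq_len(n_ind(ds))
  rows <- rows[ds$meta$ploidy[rows] == 2L & !is.na(ds$a1[rows, j])]
  n <- length(rows)
  if (n < 5L) stop("need >= 5 typed diploid individuals")
  g1 <- ds$a1[rows, j]; g2 <- ds$a2[rows, j]
  if (length(unique(c(g1, g2))) < 2L) return(1)
  obs <- hwe_kernel(g1, g2)
  pool <- c(g1, g2)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- matrix(sample(pool), nrow = 2L)
    if (hwe_kernel(perm[1, ], perm[2, ]) <= obs + 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

g_stat <- function(f1, f2) {
  tab <- table(f1, f2)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  idx <- tab > 0
  2 * sum(tab[idx] * log(tab[idx] / e[idx]))
}

#' Pairwise linkage-disequilibrium tests with deterministic pruning
#'
#' For every locus pair (per species), a G-statistic on the joint genotype
#' contingency table with a permutation null (one locus's genotypes shuffled
#' across individuals). Connected components of significant pairs
#' (p < `alpha`, unadjusted, as is standard for this screen) collapse to a
#' single retained locus: the one with least missingness, ties broken by
#' locus name.
#'
#' @param ds a [genotype_dataset()] (one-sister-per-colony already applied)
#' @param alpha significance level for a pair
#' @param n_perm permutations per pair
#' @param seed RNG seed
#' @return list with `dataset` (pruned) and `report` (`ld_pairs` holds every
#'   tested pair with its p-value; untested pairs recorded with `NA`)
#' @export
ld_test_and_prune <- function(ds, alpha = 0.05, n_perm = 499, seed = 1L) {
  set.seed(seed)
  pairs <- list(); panel <- list(); drop_loc <- list()
  for (sp in unique(ds$meta$species)) {
    rows <- species_rows(ds, sp)
    rows <- rows[ds$meta$ploidy[rows] == 2L]
    L <- n_loci(ds)
    sig <- matrix(FALSE, L, L)
    for (ja in seq_len(L - 1L)) for (jb in seq(ja + 1L, L)) {
      ok <- rows[!is.na(ds$a1[rows, ja]) & !is.na(ds$a1[rows, jb])]
      if (length(ok) < 5L) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(species = sp, locus1 = ds$loci[ja],
                     locus2 = ds$loci[jb], p = NA_real_, tested = FALSE,
                     stringsAsFactors = FALSE)
        next
      }
      fa <- paste(ds$a1[ok, ja], ds$a2[ok, ja])
      fb <- paste(ds$a1[ok, jb], ds$a2[ok, jb])
      gobs <- g_stat(fa, fb)
      hits <- 0L
      for (b in seq_len(n_perm))
        if (g_stat(fa, sample(fb)) >= gobs - 1e-12) hits <- hits + 1L
      p <- (1 + hits) / (1 + n_perm)
      sig[ja, jb] <- sig[jb, ja] <- p < alpha
      pairs[[length(pairs) + 1L]] <-
        data.frame(species = sp, locus1 = ds$loci[ja], locus2 = ds$loci[jb],
                   p = p, tested = TRUE, stringsAsFactors = FALSE)
    }
    # connected components of the significance graph -> keep one locus each
    comp <- seq_len(L)
    repeat {
      changed <- FALSE
      for (ja in seq_len(L)) for (jb in seq_len(L)) if (sig[ja, jb]) {
        m <- min(comp[ja], comp[jb])
        if (comp[ja] != m || comp[jb] != m) {
          comp[ja] <- comp[jb] <- m; changed <- TRUE
        }
      }
      if (!changed) break
    }
    keep <- rep(TRUE, L)
    miss <- colMeans(is.na(ds$a1[rows, , drop = FALSE]))
    for (cc in unique(comp)) {
      members <- which(comp == cc)
      if (length(members) < 2L) next
      ord <- members[order(miss[members], ds$loci[members])]
      for (j in ord[-1L]) {
        keep[j] <- FALSE
        drop_loc[[length(drop_loc) + 1L]] <-
          data.frame(species = sp, locus = ds$loci[j], reason = "ld",
                     estimate = NA_real_, stringsAsFactors = FALSE)
      }
    }
    panel[[sp]] <- ds$loci[keep]
  }
  keep_loc <- ds$loci %in% unique(unlist(panel))
  out <- subset_dataset(ds, loci = which(keep_loc),
                        note = sprintf("ld_test_and_prune(%.2f)", alpha))
  list(dataset = out,
       report = qc_report(dropped_loci = if (length(drop_loc))
         do.call(rbind, drop_loc) else NULL,
         retained_panel = panel,
         ld_pairs = do.call(rbind, pairs)))
}

#' Keep one randomly chosen sister per colony
#'
#' Collapses each inferred full-sib family to a single female, chosen
#' uniformly at random with a seeded RNG; males are untouched.
#'
#' @param ds a [genotype_dataset()]
#' @param partition a [sibship_partition] (or a named vector mapping female
#'   id -> family label) covering every female in `ds`
#' @param seed RNG seed
#' @return the deduplicated [genotype_dataset()]
#' @export
dedupe_sisters <- function(ds, partition, seed = 1L) {
  fam <- if (inherits(partition, "sibship_partition"))
    partition$assignment else partition
  females <- ds$meta$id[ds$meta$sex == "female"]
  missing <- setdiff(females, names(fam))
  if (length(missing))
    stop("females absent from partition: ", paste(missing, collapse = ", "))
  set.seed(seed)
  keep <- ds$meta$sex != "female"
  for (f in unique(fam[females])) {
    members <- females[fam[females] == f]
    chosen <- if (length(members) == 1L) members
              else members[sample.int(length(members), 1L)]
    keep[ds$meta$id == chosen] <- TRUE
  }
  subset_dataset(ds, ind = keep, note = "dedupe_sisters")
}
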