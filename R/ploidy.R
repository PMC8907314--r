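# Diploid-male detection from multilocus heterozygosity. A haploid male can
# never be heterozygous (absent mistyping), so males heterozygous at three or
# more scored loci are classified diploid — an inbreeding signal under
# single-locus complementary sex determination.

#' Count heterozygous loci for a male
#'
#' Number of successfully scored loci with two distinct alleles; missing loci
#' are excluded. Recorded-haploid calls (single allele) are never
#' heterozygous.
#'
#' @param ds a [genotype_dataset()]
#' @param id male individual id
#' @return integer count
#' @export
count_het_loci <- function(ds, id) {
  i <- match(id, ds$meta$id)
  if (is.na(i)) stop("unknown individual id")
  typed <- !is.na(ds$a1[i, ])
  if (!any(typed)) stop("individual ", id, " has zero typed loci")
  sum(typed & !is.na(ds$a2[i, ]) & ds$a1[i, ] != ds$a2[i, ])
}

#' Classify a male as haploid or diploid
#'
#' Diploid iff heterozygous at `min_het` or more scored loci (default 3, the
#' standard rule). Males typed at fewer than `min_het` loci can never be
#' classified diploid under the rule; they are still classified (haploid)
#' but flagged indeterminate in [summarize_diploidy()].
#'
#' @param ds a [genotype_dataset()]
#' @param id male individual id
#' @param min_het heterozygous-locus threshold
#' @return `"haploid"` or `"diploid"`
#' @export
classify_male <- function(ds, id, min_het = 3) {
  if (count_het_loci(ds, id) >= min_het) "diploid" else "haploid"
}

#' Diploid-male summary table
#'
#' Per species by site and globally: N_i (males sampled), N_g (males with at
#' least one scored locus), N_d (males with `min_het` or more heterozygous
#' loci) and percent diploid = 100 * N_d / N_g to two decimals. Strata with
#' no genotyped males get `NA` (reported as a dash).
#'
#' @param ds a [genotype_dataset()]
#' @param min_het heterozygous-locus threshold for diploidy
#' @return data.frame with columns `species`, `site` (`"Global"` rows
#'   included), `N_i`, `N_g`, `N_d`, `percent`, `indeterminate` (males scored
#'   at fewer than `min_het` loci, counted haploid)
#' @export
summarize_diploidy <- function(ds, min_het = 3) {
  males <- which(ds$meta$sex == "male")
  out <- list()
  summarize_cell <- function(rows, sp, si) {
    typed <- rowSums(!is.na(ds$a1[rows, , drop = FALSE]))
    geno <- rows[typed > 0]
    nd <- sum(vapply(ds$meta$id[geno],
                     function(id) count_het_loci(ds, id) >= min_het,
                     logical(1)))
    ind <- sum(typed > 0 & typed < min_het)
    data.frame(species = sp, site = si,
               N_i = length(rows), N_g = length(geno), N_d = nd,
               percent = if (length(geno)) round(100 * nd / length(geno), 2)
                         else NA_real_,
               indeterminate = ind, stringsAsFactors = FALSE)
  }
  for (sp in sort(unique(ds$meta$species[males]))) {
    msp <- males[ds$meta$species[males] == sp]
    for (si in sort(unique(ds$meta$site[msp])))
      out[[length(out) + 1L]] <-
        summarize_cell(msp[ds$meta$site[msp] == si], sp, si)
    out[[length(out) + 1L]] <- summarize_cell(msp, sp, "Global")
  }
  if (!length(out))
    return(data.frame(species = character(), site = character(),
                      N_i = integer(), N_g = integer(), N_d = integer(),
                      percent = numeric(), indeterminate = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
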