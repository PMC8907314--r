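# Haplodiploid colony genotype simulator with known truth.
#
# The generator emulates the sampling structure the downstream analyses
# assume: monogynous, monoandrous colonies at discrete sites, workers as full
# sisters sharing the drone's allele at every locus, single-locus
# complementary sex determination (csd) so that inbred matings produce
# diploid males, and an observation layer adding mistyping, null alleles and
# whole-locus genotyping failure.

#' Simulator configuration
#'
#' Builds a validated configuration for the haplodiploid colony simulator.
#' Defaults describe a study-like design: four sites, twenty colonies per
#' site, a handful of sampled sisters per colony, a 10-18 locus microsatellite
#' panel, and no genetic differentiation between sites (drift can be switched
#' on via `target_fst`).
#'
#' @param n_sites number of sites (subpopulations)
#' @param colonies_per_site colonies available per site
#' @param workers_per_colony mean sampled workers per colony
#' @param workers_dist `"fixed"` or `"ztpois"` (zero-truncated Poisson with
#'   the given mean)
#' @param males_per_colony sampled males per colony (0 disables male sampling)
#' @param n_loci number of microsatellite loci (csd simulated separately)
#' @param alleles_per_locus alleles segregating per locus
#' @param base_freq_concentration Dirichlet concentration for base allele
#'   frequencies (> 0; 1 = uniform simplex)
#' @param target_fst expected differentiation among sites in [0, 1); generated
#'   by binomial drift of 2*Ne gene copies for t generations with
#'   1 - (1 - 1/(2*Ne))^t equal to the target
#' @param Ne effective size used by the drift mechanism
#' @param csd_allele_count alleles at the csd locus (>= 2)
#' @param related_mating probability a queen mates with her brother (raises
#'   csd homozygosity, hence diploid-male production)
#' @param mistype_rate per-allele-call mistyping rate (allele replaced by a
#'   frequency-weighted random allele); the study-standard assumed value is
#'   0.05
#' @param null_allele_freq per-locus hidden null-allele frequency (scalar or
#'   vector of length `n_loci`)
#' @param failure_rate probability a whole locus call fails (missing)
#' @param body_mean grand mean worker thorax width, mm
#' @param site_effect,species_effect,interaction_effect planted fixed effects
#'   on thorax width (mm): length-`n_sites` vector, length-`n_species` vector,
#'   and `n_sites` x `n_species` matrix
#' @param colony_sd,residual_sd body-size random components (mm): shared
#'   colony effect and within-colony residual
#' @param n_species species simulated per run (independent gene pools)
#' @param seed integer master seed; each stage derives its own sub-seed
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_sites = 4, colonies_per_site = 20,
                       workers_per_colony = 3, workers_dist = "fixed",
                       males_per_colony = 0,
                       n_loci = 12, alleles_per_locus = 8,
                       base_freq_concentration = 1,
                       target_fst = 0, Ne = 1000,
                       csd_allele_count = 20, related_mating = 0,
                       mistype_rate = 0.05, null_allele_freq = 0,
                       failure_rate = 0.05,
                       body_mean = 4.5, site_effect = NULL,
                       species_effect = NULL, interaction_effect = NULL,
                       colony_sd = 0.25, residual_sd = 0.3,
                       n_species = 1, seed = 1L) {
  stopifnot(n_sites >= 1, colonies_per_site >= 1, n_loci >= 1,
            alleles_per_locus >= 2, base_freq_concentration > 0,
            target_fst >= 0, target_fst < 1, csd_allele_count >= 2,
            mistype_rate >= 0, mistype_rate < 1,
            all(null_allele_freq >= 0), all(null_allele_freq < 1),
            failure_rate >= 0, failure_rate <= 1,
            related_mating >= 0, related_mating <= 1,
            workers_dist %in% c("fixed", "ztpois"))
  if (is.null(site_effect)) site_effect <- rep(0, n_sites)
  if (is.null(species_effect)) species_effect <- rep(0, n_species)
  if (is.null(interaction_effect))
    interaction_effect <- matrix(0, n_sites, n_species)
  nulls <- if (length(null_allele_freq) == 1L)
    rep(null_allele_freq, n_loci) else null_allele_freq
  stopifnot(length(nulls) == n_loci, length(site_effect) == n_sites,
            length(species_effect) == n_species,
            all(dim(interaction_effect) == c(n_sites, n_species)))
  structure(list(n_sites = n_sites, colonies_per_site = colonies_per_site,
                 workers_per_colony = workers_per_colony,
                 workers_dist = workers_dist,
                 males_per_colony = males_per_colony,
                 n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 base_freq_concentration = base_freq_concentration,
                 target_fst = target_fst, Ne = Ne,
                 csd_allele_count = csd_allele_count,
                 related_mating = related_mating,
                 mistype_rate = mistype_rate, null_allele_freq = nulls,
                 failure_rate = failure_rate,
                 body_mean = body_mean, site_effect = site_effect,
                 species_effect = species_effect,
                 interaction_effect = interaction_effect,
                 colony_sd = colony_sd, residual_sd = residual_sd,
                 n_species = n_species, seed = as.integer(seed)),
            class = "sim_config")
}

rdirichlet1 <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

rztpois <- function(n, lambda) {
  stats::qpois(stats::runif(n, stats::ppois(0, lambda), 1), lambda)
}

#' Number of drift generations matching a target differentiation
#'
#' Under pure drift of 2*Ne gene copies, expected differentiation after t
#' generations is 1 - (1 - 1/(2*Ne))^t; this inverts that relation.
#'
#' @param target_fst target value in [0, 1)
#' @param Ne effective size
#' @return integer generation count (0 when the target is 0)
#' @export
drift_generations <- function(target_fst, Ne) {
  if (target_fst == 0) return(0L)
  as.integer(round(log1p(-target_fst) / log1p(-1 / (2 * Ne))))
}

#' Expected differentiation after drift
#' @param Ne effective size
#' @param t generations
#' @return 1 - (1 - 1/(2*Ne))^t
#' @export
expected_fst_drift <- function(Ne, t) 1 - (1 - 1 / (2 * Ne))^t

#' Parametric Weir-Cockerham differentiation of known site frequencies
#'
#' The large-sample limit of the Weir-Cockerham estimator applied to known
#' per-site allele frequencies with Hardy-Weinberg genotype proportions
#' within sites and equal site weights: theta = sum(s2) / sum(pbar*qbar +
#' s2/r) over loci and alleles, where s2 is the among-site sample variance of
#' the allele frequency and r the number of sites.
#'
#' @param freqs 3-d array `[locus, allele, site]` of allele frequencies
#' @return realized differentiation (can be slightly negative for r finite)
#' @export
realized_theta <- function(freqs) {
  r <- dim(freqs)[3]
  num <- den <- 0
  for (l in seq_len(dim(freqs)[1])) {
    p <- freqs[l, , , drop = TRUE]           # alleles x sites
    if (is.null(dim(p))) p <- matrix(p, ncol = r)
    pbar <- rowMeans(p)
    s2 <- apply(p, 1, stats::var)
    num <- num + sum(s2)
    den <- den + sum(pbar * (1 - pbar) + s2 / r)
  }
  if (den == 0) return(0)
  num / den
}

#' Draw per-site allele frequencies by drift from a common base
#'
#' Base frequencies per locus are Dirichlet draws; each site then drifts
#' independently for t generations of binomial (multinomial) resampling of
#' 2*Ne gene copies, with t chosen so the expected differentiation equals
#' `target_fst`. With `target_fst = 0` all sites share the base frequencies
#' exactly.
#'
#' @param cfg a [sim_config()]
#' @return list with `freqs` (array `[locus, allele, site]`), `base` (matrix
#'   locus x allele), `allele_codes` (integer fragment lengths), `Ne`, `t`,
#'   and `realized_fst` (from [realized_theta()] on the generated
#'   frequencies)
#' @export
draw_site_frequencies <- function(cfg) {
  set.seed(cfg$seed + 11L)
  L <- cfg$n_loci; k <- cfg$alleles_per_locus; r <- cfg$n_sites
  base <- t(vapply(seq_len(L), function(l)
    rdirichlet1(k, cfg$base_freq_concentration), numeric(k)))
  t_gen <- drift_generations(cfg$target_fst, cfg$Ne)
  freqs <- array(NA_real_, c(L, k, r))
  for (s in seq_len(r)) for (l in seq_len(L)) {
    p <- base[l, ]
    if (t_gen > 0) for (g in seq_len(t_gen))
      p <- as.vector(stats::rmultinom(1, 2 * cfg$Ne, p)) / (2 * cfg$Ne)
    freqs[l, , s] <- p
  }
  list(freqs = freqs, base = base,
       allele_codes = as.integer(98 + 2 * seq_len(k)),
       Ne = cfg$Ne, t = t_gen,
       realized_fst = if (t_gen > 0) realized_theta(freqs) else 0)
}

sample_allele <- function(p) sample.int(length(p), 1L, prob = p)

# queen must be heterozygous at csd (csd homozygotes are not queens)
draw_queen_family <- function(site_p, csd_p, related, L) {
  repeat {
    gm <- vapply(seq_len(L), function(l)
      sample.int(length(site_p[l, ]), 2L, replace = TRUE,
                 prob = site_p[l, ]), integer(2))   # 2 x L grandmother
    gf <- vapply(seq_len(L), function(l) sample_allele(site_p[l, ]),
                 integer(1))                         # grandfather (haploid)
    gm_csd <- sample.int(length(csd_p), 2L, replace = TRUE, prob = csd_p)
    gf_csd <- sample_allele(csd_p)
    q <- rbind(gm[cbind(sample.int(2L, L, replace = TRUE), seq_len(L))], gf)
    q_csd <- c(gm_csd[sample.int(2L, 1L)], gf_csd)
    if (q_csd[1] == q_csd[2]) next                   # csd homozygote: retry
    if (stats::runif(1) < related) {                 # brother of the queen
      d <- gm[cbind(sample.int(2L, L, replace = TRUE), seq_len(L))]
      d_csd <- gm_csd[sample.int(2L, 1L)]
    } else {
      d <- vapply(seq_len(L), function(l) sample_allele(site_p[l, ]),
                  integer(1))
      d_csd <- sample_allele(csd_p)
    }
    return(list(queen = q, queen_csd = q_csd, drone = d, drone_csd = d_csd))
  }
}

#' Simulate colony-structured genotypes
#'
#' One singly-mated queen per colony (monogyny, monoandry): the queen carries
#' two alleles per locus drawn from her site's frequencies, her mate one.
#' Every sampled worker inherits the drone allele plus one random queen
#' allele per locus, so full sisters always share the paternal allele. The
#' csd locus is transmitted the same way; fertilized eggs homozygous at csd
#' develop as diploid males, and sampled males are haploid (unfertilized,
#' queen-derived) or diploid with probability equal to the parental csd
#' homozygosity rate. Males are recorded as a fragment analyzer would score
#' them — two allele slots, identical for true haploids — with true ploidy
#' kept in the truth object.
#'
#' @param cfg a [sim_config()]
#' @param freqs output of [draw_site_frequencies()] (drawn internally when
#'   omitted); for `n_species > 1` a list of such objects, one per species
#' @return list with `dataset` (a [genotype_dataset()], error-free) and
#'   `truth` (family labels, parental genotypes, true ploidy per male,
#'   realized differentiation, true colony counts)
#' @export
simulate_colonies <- function(cfg, freqs = NULL) {
  if (is.null(freqs)) {
    freqs <- lapply(seq_len(cfg$n_species), function(sp) {
      c2 <- cfg; c2$seed <- cfg$seed + 1000L * sp
      draw_site_frequencies(c2)
    })
  } else if (!is.null(freqs$freqs)) freqs <- list(freqs)
  set.seed(cfg$seed + 23L)
  L <- cfg$n_loci
  loci <- sprintf("L%02d", seq_len(L))
  csd_p <- rep(1 / cfg$csd_allele_count, cfg$csd_allele_count)
  rows <- list(); fam <- list(); parents <- list()
  for (sp in seq_len(cfg$n_species)) {
    spname <- sprintf("Sp%d", sp)
    fr <- freqs[[sp]]
    for (s in seq_len(cfg$n_sites)) {
      site <- sprintf("S%d", s)
      site_p <- fr$freqs[, , s, drop = TRUE]
      if (is.null(dim(site_p))) site_p <- matrix(site_p, nrow = L)
      for (cid in seq_len(cfg$colonies_per_site)) {
        cz <- draw_queen_family(site_p, csd_p, cfg$related_mating, L)
        colony <- sprintf("%s_%s_C%02d", spname, site, cid)
        parents[[colony]] <- cz
        nw <- if (cfg$workers_dist == "fixed") cfg$workers_per_colony
              else rztpois(1, cfg$workers_per_colony)
        for (w in seq_len(nw)) {
          mat <- cz$queen[cbind(sample.int(2L, L, replace = TRUE),
                                seq_len(L))]
          id <- sprintf("%s_W%02d", colony, w)
          rows[[id]] <- list(a1 = pmin(mat, cz$drone),
                             a2 = pmax(mat, cz$drone),
                             species = spname, site = site, sex = "female",
                             caste = "worker", ploidy = 2L, codes = fr$allele_codes)
          fam[[id]] <- list(colony = colony, true_ploidy = 2L,
                            diploid_male = FALSE)
        }
        for (m in seq_len(cfg$males_per_colony)) {
          p_dm <- 0.5 * (cz$drone_csd == cz$queen_csd[1]) +
                  0.5 * (cz$drone_csd == cz$queen_csd[2])
          id <- sprintf("%s_M%02d", colony, m)
          if (stats::runif(1) < p_dm) {      # fertilized csd homozygote
            mat <- cz$queen[cbind(sample.int(2L, L, replace = TRUE),
                                  seq_len(L))]
            rows[[id]] <- list(a1 = pmin(mat, cz$drone),
                               a2 = pmax(mat, cz$drone),
                               species = spname, site = site, sex = "male",
                               caste = "male", ploidy = 2L,
                               codes = fr$allele_codes)
            fam[[id]] <- list(colony = colony, true_ploidy = 2L,
                              diploid_male = TRUE)
          } else {                            # unfertilized: queen-haploid
            hap <- cz$queen[cbind(sample.int(2L, L, replace = TRUE),
                                  seq_len(L))]
            rows[[id]] <- list(a1 = hap, a2 = hap,  # scored as two equal peaks
                               species = spname, site = site, sex = "male",
                               caste = "male", ploidy = 2L,
                               codes = fr$allele_codes)
            fam[[id]] <- list(colony = colony, true_ploidy = 1L,
                              diploid_male = FALSE)
          }
        }
      }
    }
  }
  ids <- names(rows)
  a1 <- matrix(unlist(lapply(rows, function(r) r$codes[r$a1])),
               ncol = L, byrow = TRUE)
  a2 <- matrix(unlist(lapply(rows, function(r) r$codes[r$a2])),
               ncol = L, byrow = TRUE)
  meta <- data.frame(id = ids,
                     species = vapply(rows, `[[`, "", "species"),
                     site = vapply(rows, `[[`, "", "site"),
                     sex = vapply(rows, `[[`, "", "sex"),
                     caste = vapply(rows, `[[`, "", "caste"),
                     ploidy = vapply(rows, function(r) r$ploidy, integer(1)),
                     thorax_width = NA_real_, stringsAsFactors = FALSE)
  ds <- genotype_dataset(a1, a2, meta, loci,
                         provenance = "simulate_colonies")
  attr(ds, "site_freqs") <- freqs
  truth <- list(colony = vapply(fam, `[[`, "", "colony"),
                true_ploidy = vapply(fam, function(f) f$true_ploidy,
                                     integer(1)),
                diploid_male = vapply(fam, function(f) f$diploid_male,
                                      logical(1)),
                parents = parents, freqs = freqs,
                realized_fst = vapply(freqs, `[[`, numeric(1),
                                      "realized_fst"),
                colonies_per_site = cfg$colonies_per_site)
  list(dataset = ds, truth = truth)
}

#' Apply the observation model (mistyping, null alleles, failure)
#'
#' Degrades error-free simulated genotypes the way real fragment data are
#' degraded: each allele call is independently mistyped with probability
#' `mistype_rate` (replaced by a frequency-weighted random allele); each
#' underlying allele copy is independently a hidden null with probability
#' `null_allele_freq` (null homozygotes come out missing, null heterozygotes
#' appear homozygous for the visible allele); finally whole-locus calls fail
#' with probability `failure_rate`. With all rates zero the dataset is
#' returned unchanged.
#'
#' @param ds error-free [genotype_dataset()] from [simulate_colonies()]
#' @param cfg a [sim_config()]
#' @return a degraded copy of `ds`
#' @export
apply_observation_model <- function(ds, cfg) {
  if (cfg$mistype_rate == 0 && all(cfg$null_allele_freq == 0) &&
      cfg$failure_rate == 0) return(ds)
  set.seed(cfg$seed + 37L)
  freqs <- attr(ds, "site_freqs")
  sitelab <- sort(unique(ds$meta$site))
  splab <- sort(unique(ds$meta$species))
  a1 <- ds$a1; a2 <- ds$a2
  for (i in seq_len(n_ind(ds))) {
    s <- match(ds$meta$site[i], sitelab)
    sp <- match(ds$meta$species[i], splab)
    fr <- if (!is.null(freqs)) freqs[[min(sp, length(freqs))]] else NULL
    for (j in seq_len(n_loci(ds))) {
      if (is.na(a1[i, j])) next
      nu <- cfg$null_allele_freq[min(j, length(cfg$null_allele_freq))]
      if (nu > 0) {                          # hidden null per underlying copy
        het <- !is.na(a2[i, j]) && a1[i, j] != a2[i, j]
        if (ds$meta$sex[i] == "female" || het) {  # two underlying copies
          n1 <- stats::runif(1) < nu
          n2 <- stats::runif(1) < nu
          if (n1 && n2) a1[i, j] <- a2[i, j] <- NA_integer_
          else if (het && n1) a1[i, j] <- a2[i, j]
          else if (het && n2) a2[i, j] <- a1[i, j]
          # homozygote with one null copy: unchanged (still visible)
        } else if (stats::runif(1) < nu) {   # male record, one copy
          a1[i, j] <- NA_integer_
          a2[i, j] <- NA_integer_
        }
      }
      if (is.na(a1[i, j])) next
      if (cfg$mistype_rate > 0 && !is.null(fr)) {
        p <- fr$freqs[j, , s]
        if (stats::runif(1) < cfg$mistype_rate)
          a1[i, j] <- fr$allele_codes[sample_allele(p)]
        if (!is.na(a2[i, j]) && stats::runif(1) < cfg$mistype_rate)
          a2[i, j] <- fr$allele_codes[sample_allele(p)]
      }
      if (cfg$failure_rate > 0 && stats::runif(1) < cfg$failure_rate) {
        a1[i, j] <- NA_integer_
        a2[i, j] <- NA_integer_
      }
    }
  }
  # re-sort diploid calls so the unordered-pair representation stays canonical
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  out <- genotype_dataset(a1, a2, ds$meta, ds$loci,
                          species_bins = ds$species_bins,
                          provenance = c(ds$provenance,
                                         "apply_observation_model"))
  attr(out, "site_freqs") <- freqs
  out
}

#' Simulate worker thorax widths
#'
#' Thorax width = cell mean (grand mean + site + species + interaction
#' effects) + a Normal colony effect shared by colony-mates + a Normal
#' residual, truncated below at zero. Only female workers receive widths.
#'
#' @param ds a [genotype_dataset()] from [simulate_colonies()]
#' @param truth matching truth object (supplies colony labels)
#' @param cfg a [sim_config()]
#' @return `ds` with `thorax_width` filled for workers
#' @export
simulate_body_size <- function(ds, truth, cfg) {
  set.seed(cfg$seed + 51L)
  colonies <- unique(truth$colony)
  ceff <- stats::setNames(stats::rnorm(length(colonies), 0, cfg$colony_sd),
                          colonies)
  sitelab <- sort(unique(ds$meta$site))
  splab <- sort(unique(ds$meta$species))
  w <- ds$meta$thorax_width
  for (i in seq_len(n_ind(ds))) {
    if (ds$meta$sex[i] != "female") next
    s <- match(ds$meta$site[i], sitelab)
    sp <- match(ds$meta$species[i], splab)
    mu <- cfg$body_mean + cfg$site_effect[s] + cfg$species_effect[sp] +
      cfg$interaction_effect[s, sp]
    w[i] <- max(mu + ceff[[truth$colony[ds$meta$id[i]]]] +
                  stats::rnorm(1, 0, cfg$residual_sd), 1e-6)
  }
  ds$meta$thorax_width <- w
  ds
}

#' Run the full generator
#'
#' Frequencies -> colonies -> body size -> observation model, each stage
#' seeded deterministically from the master seed.
#'
#' @param cfg a [sim_config()]
#' @return list with `dataset` (observed, degraded), `clean` (pre-noise
#'   dataset) and `truth`
#' @export
simulate_dataset <- function(cfg) {
  sim <- simulate_colonies(cfg)
  clean <- simulate_body_size(sim$dataset, sim$truth, cfg)
  obs <- apply_observation_model(clean, cfg)
  list(dataset = obs, clean = clean, truth = sim$truth)
}
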