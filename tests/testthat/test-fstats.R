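test_that("variance components vanish between identical subpopulations", {
  set.seed(4)
  g1 <- sample(c(101L, 103L, 105L), 30, replace = TRUE)
  g2 <- sample(c(101L, 103L, 105L), 30, replace = TRUE)
  a1 <- matrix(pmin(g1, g2), 30, 1); a2 <- matrix(pmax(g1, g2), 30, 1)
  ds <- make_manual_ds(rbind(a1, a1), rbind(a2, a2),
                       site = rep(c("S1", "S2"), each = 30), loci = "L1")
  comp <- wc_components(ds, 1)
  # s2 = 0; what remains of a is only the O(1/n) finite-sample correction
  expect_lt(abs(comp$a), 0.02)
  expect_lt(comp$a / (comp$a + comp$b + comp$c), 0)
  # monomorphic flag
  m <- matrix(101L, 20, 1)
  dsm <- make_manual_ds(m, m, site = rep(c("S1", "S2"), 10), loci = "L1")
  expect_true(wc_components(dsm, 1)$monomorphic)
})

test_that("multilocus theta and f match an independent evaluation", {
  cfg <- sim_config(n_sites = 3, colonies_per_site = 25,
                    workers_per_colony = 1, n_loci = 3,
                    alleles_per_locus = 5, target_fst = 0.05,
                    mistype_rate = 0, failure_rate = 0, seed = 71)
  sim <- simulate_colonies(cfg)
  fs <- multilocus_fstats(sim$dataset)
  orc <- oracle_fstats(sim$dataset)
  expect_equal(as.numeric(fs$theta), orc$theta, tolerance = 1e-10)
  expect_equal(as.numeric(fs$f), orc$f, tolerance = 1e-10)
})

test_that("complete homozygosity gives f = 1 and panmixia centers theta at 0", {
  set.seed(12)
  hom <- matrix(sample(c(101L, 103L), 80, replace = TRUE), 40, 2)
  ds <- make_manual_ds(hom, hom, site = rep(c("S1", "S2"), each = 20))
  fs <- multilocus_fstats(ds)
  expect_equal(as.numeric(fs$f), 1)
  thetas <- vapply(1:20, function(r) {
    cfg <- sim_config(n_sites = 4, colonies_per_site = 30,
                      workers_per_colony = 1, n_loci = 10,
                      alleles_per_locus = 6, target_fst = 0,
                      mistype_rate = 0, failure_rate = 0, seed = 900 + r)
    as.numeric(multilocus_fstats(simulate_colonies(cfg)$dataset)$theta)
  }, numeric(1))
  expect_lt(abs(mean(thetas)), 0.01)
  expect_true(any(thetas < 0))          # negative estimates are admissible
})

test_that("theta is invariant to allele relabeling and locus order", {
  cfg <- sim_config(n_sites = 2, colonies_per_site = 20,
                    workers_per_colony = 1, n_loci = 4,
                    alleles_per_locus = 4, target_fst = 0.05,
                    mistype_rate = 0, failure_rate = 0, seed = 19)
  ds <- simulate_colonies(cfg)$dataset
  base <- as.numeric(multilocus_fstats(ds)$theta)
  perm <- subset_dataset(ds, loci = c(3, 1, 4, 2))
  expect_equal(as.numeric(multilocus_fstats(perm)$theta), base)
  relab <- ds
  relab$a1 <- ds$a1 + 1000L; relab$a2 <- ds$a2 + 1000L
  expect_equal(as.numeric(multilocus_fstats(relab)$theta), base)
})

test_that("locus bootstrap CIs degenerate correctly and are reproducible", {
  cfg <- sim_config(n_sites = 2, colonies_per_site = 25,
                    workers_per_colony = 1, n_loci = 1,
                    alleles_per_locus = 5, target_fst = 0.02,
                    mistype_rate = 0, failure_rate = 0, seed = 23)
  ds1 <- simulate_colonies(cfg)$dataset
  # duplicate the single locus: per-locus components identical, CI width 0
  ds2 <- ds1
  ds2$a1 <- cbind(ds1$a1, ds1$a1); ds2$a2 <- cbind(ds1$a2, ds1$a2)
  ds2$loci <- c("L01", "L02")
  colnames(ds2$a1) <- colnames(ds2$a2) <- ds2$loci
  ci <- bootstrap_ci(ds2, "theta", n_boot = 100, seed = 3)
  expect_equal(ci[1], ci[2])
  expect_equal(ci[1], as.numeric(multilocus_fstats(ds2)$theta))
  cfgb <- sim_config(n_sites = 2, colonies_per_site = 25,
                     workers_per_colony = 1, n_loci = 6,
                     alleles_per_locus = 5, target_fst = 0.02,
                     mistype_rate = 0, failure_rate = 0, seed = 29)
  dsb <- simulate_colonies(cfgb)$dataset
  expect_identical(bootstrap_ci(dsb, "theta", n_boot = 200, seed = 11),
                   bootstrap_ci(dsb, "theta", n_boot = 200, seed = 11))
})

test_that("rarefied allelic richness matches combinatorial expectations", {
  # counts {A:3, B:1}, g = 2: 1 + (1 - C(3,2)/C(4,2)) = 1.5
  a1 <- matrix(c(101L, 101L), 2, 1)
  a2 <- matrix(c(101L, 103L), 2, 1)
  ds <- make_manual_ds(a1, a2, loci = "L1")
  ar <- rarefied_ar(ds, g = 2)
  expect_equal(unname(ar$per_locus["L1"]), 1.5)
  expect_equal(unname(ar$per_locus["L1"]), oracle_ar(c(3, 1), 2))
  # g = N recovers the observed allele count; g = 1 gives 1
  expect_equal(unname(rarefied_ar(ds, g = 4)$per_locus["L1"]), 2)
  expect_equal(unname(rarefied_ar(ds, g = 1)$per_locus["L1"]), 1)
  # N < g excludes the locus
  ar5 <- rarefied_ar(ds, g = 5)
  expect_true(is.na(ar5$per_locus["L1"]))
  expect_equal(ar5$excluded, "L1")
})

test_that("rarefied AR equals exhaustive subsample enumeration for N <= 12", {
  set.seed(7)
  for (rep_i in 1:12) {
    k <- sample(2:4, 1)
    counts <- as.vector(stats::rmultinom(1, 2 * sample(2:6, 1),
                                         rep(1 / k, k)))
    counts <- counts[counts > 0]
    if (length(counts) < 2) next
    N <- sum(counts)
    g <- sample(seq_len(N), 1)
    copies <- rep(100L + 2L * seq_along(counts), counts)
    half <- N / 2
    ds <- make_manual_ds(matrix(copies[seq_len(half)], half, 1),
                         matrix(copies[half + seq_len(half)], half, 1),
                         loci = "L1")
    expect_equal(unname(rarefied_ar(ds, g)$per_locus["L1"]),
                 oracle_ar(counts, g), tolerance = 1e-12)
  }
})

test_that("rarefied AR is monotone non-decreasing in depth", {
  set.seed(8)
  for (rep_i in 1:5) {
    counts <- as.vector(stats::rmultinom(1, 40, rep(0.2, 5)))
    counts <- counts[counts > 0]
    N <- sum(counts)
    copies <- rep(100L + 2L * seq_along(counts), counts)
    ds <- make_manual_ds(matrix(copies[seq_len(N / 2)], N / 2, 1),
                         matrix(copies[N / 2 + seq_len(N / 2)], N / 2, 1),
                         loci = "L1")
    vals <- vapply(seq_len(N), function(g)
      unname(rarefied_ar(ds, g)$per_locus["L1"]), numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("small populations are excluded from F-statistics but not global AR", {
  cfg <- sim_config(n_sites = 3, colonies_per_site = 30,
                    workers_per_colony = 1, n_loci = 5,
                    alleles_per_locus = 5, mistype_rate = 0,
                    failure_rate = 0, seed = 37)
  sim <- simulate_colonies(cfg)
  ds <- sim$dataset
  keep <- !(ds$meta$site == "S3" & seq_len(n_ind(ds)) %in%
              which(ds$meta$site == "S3")[11:30])   # S3 down to 10 bees
  ds <- subset_dataset(ds, ind = keep)
  ps <- popgen_summary(ds, min_pop = 25, n_boot = 50, seed = 1)
  expect_equal(ps$Sp1$excluded_sites, "S3")
  expect_false("S3" %in% names(ps$Sp1$ar_site))
  # global AR uses every female including the excluded site's
  expect_equal(ps$Sp1$g_glob, 2L * 70L)
  expect_equal(ps$Sp1$g_sub, 2L * 30L)
  expect_true(is.finite(ps$Sp1$theta))
})
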