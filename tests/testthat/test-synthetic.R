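test_that("site frequencies are normalized and identical without drift", {
  cfg <- sim_config(n_sites = 4, n_loci = 6, alleles_per_locus = 5,
                    target_fst = 0, seed = 3)
  fr <- draw_site_frequencies(cfg)
  expect_equal(apply(fr$freqs, c(1, 3), sum),
               matrix(1, 6, 4), tolerance = 1e-12)
  for (s in 2:4) expect_equal(fr$freqs[, , s], fr$freqs[, , 1])
  expect_equal(fr$realized_fst, 0)
})

test_that("drift generations hit the expected differentiation", {
  expect_equal(expected_fst_drift(1000, 103), 1 - (1 - 1 / 2000)^103)
  expect_equal(round(expected_fst_drift(1000, 103), 4), 0.0502)
  expect_equal(drift_generations(0, 1000), 0L)
  # mean realized theta across replicate frequency draws tracks the target
  reals <- vapply(1:150, function(r) {
    cfg <- sim_config(n_sites = 4, n_loci = 20, alleles_per_locus = 8,
                      target_fst = 0.05, seed = 5000 + r)
    draw_site_frequencies(cfg)$realized_fst
  }, numeric(1))
  expect_lt(abs(mean(reals) - 0.05), 0.01)
})

test_that("monoandry forces a shared paternal allele in every sib pair", {
  cfg <- sim_config(n_sites = 2, colonies_per_site = 6,
                    workers_per_colony = 4, n_loci = 8,
                    alleles_per_locus = 6, mistype_rate = 0,
                    failure_rate = 0, seed = 21)
  sim <- simulate_colonies(cfg)
  ds <- sim$dataset
  for (colony in unique(sim$truth$colony)) {
    ids <- names(sim$truth$colony)[sim$truth$colony == colony]
    rows <- match(ids, ds$meta$id)
    for (j in seq_len(n_loci(ds))) {
      # the drone allele appears in every sib's genotype at every locus
      shared <- Reduce(intersect, lapply(rows, function(i)
        c(ds$a1[i, j], ds$a2[i, j])))
      expect_gte(length(shared), 1L)
    }
  }
})

test_that("sib pairs share more alleles identical-in-state than unrelated pairs", {
  cfg <- sim_config(n_sites = 1, colonies_per_site = 40,
                    workers_per_colony = 2, n_loci = 10,
                    alleles_per_locus = 8, mistype_rate = 0,
                    failure_rate = 0, seed = 8)
  sim <- simulate_colonies(cfg)
  ds <- sim$dataset
  ibs <- function(i1, i2) mean(vapply(seq_len(n_loci(ds)), function(j)
    length(intersect(c(ds$a1[i1, j], ds$a2[i1, j]),
                     c(ds$a1[i2, j], ds$a2[i2, j]))) > 0, logical(1)))
  colonies <- split(seq_len(n_ind(ds)), sim$truth$colony[ds$meta$id])
  sib_ibs <- vapply(colonies, function(rr) ibs(rr[1], rr[2]), numeric(1))
  set.seed(1)
  unrel_ibs <- vapply(1:500, function(b) {
    pick <- sample(names(colonies), 2)
    ibs(colonies[[pick[1]]][1], colonies[[pick[2]]][1])
  }, numeric(1))
  expect_gt(mean(sib_ibs), mean(unrel_ibs))
})

test_that("csd with two alleles and a matched mating yields ~50% diploid males", {
  # csd_allele_count = 2: the queen is always A/B, so any drone matches one
  # of her alleles and half the fertilized eggs are csd homozygotes
  cfg <- sim_config(n_sites = 1, colonies_per_site = 150,
                    workers_per_colony = 1, males_per_colony = 4,
                    n_loci = 4, alleles_per_locus = 4, csd_allele_count = 2,
                    mistype_rate = 0, failure_rate = 0, seed = 13)
  sim <- simulate_colonies(cfg)
  males <- sim$truth$true_ploidy[grepl("_M", names(sim$truth$true_ploidy))]
  expect_equal(mean(males == 2L), 0.5, tolerance = 0.06)
})

test_that("observation model is identity at zero rates and total at failure 1", {
  cfg <- sim_config(n_sites = 2, colonies_per_site = 4,
                    workers_per_colony = 3, n_loci = 6,
                    alleles_per_locus = 5, mistype_rate = 0,
                    failure_rate = 0, seed = 5)
  sim <- simulate_colonies(cfg)
  expect_identical(apply_observation_model(sim$dataset, cfg)$a1,
                   sim$dataset$a1)
  cfg$failure_rate <- 1
  out <- apply_observation_model(sim$dataset, cfg)
  expect_true(all(is.na(out$a1)))
})

test_that("the generator is reproducible under a fixed seed", {
  cfg <- sim_config(n_sites = 2, colonies_per_site = 5,
                    workers_per_colony = 3, n_loci = 6,
                    alleles_per_locus = 5, mistype_rate = 0.05,
                    failure_rate = 0.05, seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$a1, s2$dataset$a1)
  expect_identical(s1$dataset$a2, s2$dataset$a2)
  expect_identical(s1$dataset$meta$thorax_width, s2$dataset$meta$thorax_width)
  expect_identical(s1$truth$colony, s2$truth$colony)
})

test_that("null alleles create a heterozygote deficit the estimator recovers", {
  cfg <- sim_config(n_sites = 1, colonies_per_site = 500,
                    workers_per_colony = 1, n_loci = 2,
                    alleles_per_locus = 8, null_allele_freq = c(0.2, 0),
                    mistype_rate = 0, failure_rate = 0, seed = 31)
  sim <- simulate_colonies(cfg)
  obs <- apply_observation_model(sim$dataset, cfg)
  est <- estimate_null_freq(obs, 1)
  expect_lt(abs(as.numeric(est) - 0.2), 0.05)
  expect_lt(abs(as.numeric(estimate_null_freq(obs, 2))), 0.05)
})

test_that("body sizes hit the planted cell structure", {
  # zero variance: widths equal the cell mean exactly
  cfg <- sim_config(n_sites = 2, colonies_per_site = 3,
                    workers_per_colony = 2, n_loci = 2,
                    alleles_per_locus = 3, site_effect = c(0.5, -0.5),
                    colony_sd = 0, residual_sd = 0, mistype_rate = 0,
                    failure_rate = 0, seed = 17)
  sim <- simulate_colonies(cfg)
  ds <- simulate_body_size(sim$dataset, sim$truth, cfg)
  w <- ds$meta
  expect_equal(unique(w$thorax_width[w$site == "S1"]), 5.0)
  expect_equal(unique(w$thorax_width[w$site == "S2"]), 4.0)

  # planted 0.5 mm site difference is recovered within ±0.15 most of the time
  hits <- vapply(1:40, function(r) {
    cfg2 <- sim_config(n_sites = 2, colonies_per_site = 50,
                       workers_per_colony = 1, n_loci = 2,
                       alleles_per_locus = 3, site_effect = c(0.25, -0.25),
                       colony_sd = 0, residual_sd = 0.3, mistype_rate = 0,
                       failure_rate = 0, seed = 700 + r)
    sim2 <- simulate_colonies(cfg2)
    d2 <- simulate_body_size(sim2$dataset, sim2$truth, cfg2)
    m <- tapply(d2$meta$thorax_width, d2$meta$site, mean)
    abs((m["S1"] - m["S2"]) - 0.5) <= 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.85)

  # colony random effect induces within-colony correlation
  icc_at <- function(csd, seed) {
    cfg3 <- sim_config(n_sites = 1, colonies_per_site = 60,
                       workers_per_colony = 4, n_loci = 2,
                       alleles_per_locus = 3, colony_sd = csd,
                       residual_sd = 0.3, mistype_rate = 0,
                       failure_rate = 0, seed = seed)
    sim3 <- simulate_colonies(cfg3)
    d3 <- simulate_body_size(sim3$dataset, sim3$truth, cfg3)
    a <- stats::aov(d3$meta$thorax_width ~
                      factor(sim3$truth$colony[d3$meta$id]))
    ms <- summary(a)[[1]]$`Mean Sq`
    (ms[1] - ms[2]) / (ms[1] + 3 * ms[2])
  }
  expect_gt(icc_at(0.4, 41), icc_at(0, 41))
})
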