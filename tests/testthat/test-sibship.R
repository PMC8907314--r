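test_that("pairwise full-sib LLR has the forced signs", {
  # identical multilocus genotypes at informative loci: evidence for sibship
  set.seed(3)
  g1 <- sample(100:115, 10); g2 <- sample(100:115, 10)
  a1 <- rbind(pmin(g1, g2), pmin(g1, g2))
  a2 <- rbind(pmax(g1, g2), pmax(g1, g2))
  ds <- make_manual_ds(a1, a2)
  freqs <- lapply(stats::setNames(ds$loci, ds$loci), function(l)
    stats::setNames(rep(1 / 16, 16), as.character(100:115)))
  expect_gt(pair_fullsib_llr(ds, "ind01", "ind02", freqs, eps = 0.05), 0)

  # no shared alleles anywhere at eps = 0: impossible as full sibs
  a1 <- rbind(rep(101L, 5), rep(105L, 5))
  a2 <- rbind(rep(103L, 5), rep(107L, 5))
  ds2 <- make_manual_ds(a1, a2)
  freqs2 <- lapply(stats::setNames(ds2$loci, ds2$loci), function(l)
    stats::setNames(rep(0.25, 4), c("101", "103", "105", "107")))
  expect_equal(pair_fullsib_llr(ds2, "ind01", "ind02", freqs2, eps = 0),
               -Inf)
  expect_error(pair_fullsib_llr(ds2, "ind01", "nope", freqs2), "unknown")
})

test_that("single-locus LLR matches exhaustive parental enumeration", {
  # 1 locus, 2 equifrequent alleles A=101, B=103, eps = 0, both bees A/B
  ds <- make_manual_ds(matrix(c(101L, 101L), 2, 1),
                       matrix(c(103L, 103L), 2, 1), loci = "L1")
  freqs <- list(L1 = stats::setNames(c(0.5, 0.5), c("101", "103")))
  # enumeration: queens AA/AB/BB with HWE prior, drones A/B
  q_list <- list(c("A", "A"), c("A", "B"), c("B", "B"))
  q_w <- c(0.25, 0.5, 0.25)
  p_fs <- 0
  for (qi in 1:3) for (d in c("A", "B")) {
    # P(child observed as A/B | queen, drone), error-free
    child_p <- mean(vapply(q_list[[qi]], function(mat)
      setequal(c(mat, d), c("A", "B")), numeric(1)))
    p_fs <- p_fs + q_w[qi] * 0.5 * child_p^2
  }
  p_un <- (2 * 0.5 * 0.5)^2
  expect_equal(pair_fullsib_llr(ds, "ind01", "ind02", freqs, eps = 0),
               log(p_fs / p_un), tolerance = 1e-12)
})

test_that("trivial partitions come out right", {
  # all females identical at 12 informative loci: one family
  set.seed(5)
  g1 <- sample(100:130, 12); g2 <- sample(100:130, 12)
  a1 <- matrix(pmin(g1, g2), 6, 12, byrow = TRUE)
  a2 <- matrix(pmax(g1, g2), 6, 12, byrow = TRUE)
  ds <- make_manual_ds(a1, a2)
  freqs <- lapply(stats::setNames(ds$loci, ds$loci), function(l)
    stats::setNames(rep(1 / 31, 31), as.character(100:130)))
  p <- infer_partition(ds, freqs = freqs, eps = 0.02)
  expect_equal(p$n_families, 1L)
  # one female: one family
  p1 <- infer_partition(subset_dataset(ds, ind = 1), freqs = freqs)
  expect_equal(p1$n_families, 1L)
  expect_equal(unname(p1$assignment), "F001")
})

true_freq_list <- function(sim) {
  fr <- sim$truth$freqs[[1]]
  out <- lapply(seq_len(nrow(fr$base)), function(j)
    stats::setNames(fr$freqs[j, , 1], as.character(fr$allele_codes)))
  names(out) <- sim$dataset$loci
  out
}

test_that("error-free small cases recover the exact colony structure", {
  for (seed in 61:64) {
    cfg <- sim_config(n_sites = 1, colonies_per_site = 3,
                      workers_per_colony = 2, n_loci = 12,
                      alleles_per_locus = 10, mistype_rate = 0,
                      failure_rate = 0, seed = seed)
    sim <- simulate_colonies(cfg)
    p <- infer_partition(sim$dataset, freqs = true_freq_list(sim),
                         eps = 0.01)
    truth <- sim$truth$colony[names(p$assignment)]
    expect_equal(p$n_families, length(unique(truth)))
    # inferred families map 1:1 onto true colonies
    expect_equal(anyDuplicated(unique(cbind(p$assignment, truth))[, 1]), 0L)
  }
})

test_that("the greedy partition attains the brute-force maximum-likelihood
           partition over all set partitions of six females", {
  cfg <- sim_config(n_sites = 1, colonies_per_site = 3,
                    workers_per_colony = 2, n_loci = 12,
                    alleles_per_locus = 10, mistype_rate = 0,
                    failure_rate = 0, seed = 61)
  sim <- simulate_colonies(cfg)
  ds <- sim$dataset
  freqs <- true_freq_list(sim)
  eps <- 0.01
  p <- infer_partition(ds, freqs = freqs, eps = eps)

  # independent family likelihood: direct enumeration over (queen, drone)
  # parent genotypes, memoized over family subsets
  memo <- new.env()
  fam_ll <- function(rows) {
    key <- paste(sort(rows), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    tot <- 0
    for (j in seq_len(n_loci(ds))) {
      f <- unname(freqs[[j]])
      als <- as.integer(names(freqs[[j]]))
      K <- length(als)
      E <- (1 - eps) * diag(K) + eps * matrix(f, K, K)  # E[obs, true]
      xi <- match(ds$a1[rows, j], als); yi <- match(ds$a2[rows, j], als)
      s <- 0
      for (q1 in 1:K) for (q2 in 1:K) for (d in 1:K) {
        pr <- f[q1] * f[q2] * f[d]
        for (m in seq_along(rows)) {
          x <- xi[m]; y <- yi[m]
          pobs <- function(a, b)
            if (x == y) E[x, a] * E[x, b]
            else E[x, a] * E[y, b] + E[y, a] * E[x, b]
          pr <- pr * (0.5 * pobs(d, q1) + 0.5 * pobs(d, q2))
        }
        s <- s + pr
      }
      tot <- tot + log(s)
    }
    memo[[key]] <- tot
    tot
  }
  parts <- list(list(1))
  for (i in 2:6) {
    new <- list()
    for (pp in parts) {
      for (k in seq_along(pp))
        new[[length(new) + 1L]] <- { q <- pp; q[[k]] <- c(q[[k]], i); q }
      new[[length(new) + 1L]] <- c(pp, list(i))
    }
    parts <- new
  }
  lls <- vapply(parts, function(pp)
    sum(vapply(pp, fam_ll, numeric(1))), numeric(1))
  best <- parts[[which.max(lls)]]
  key <- function(groups) {
    lab <- character(6)
    for (k in seq_along(groups))
      lab[groups[[k]]] <- paste(groups[[k]], collapse = ",")
    lab
  }
  ours <- split(seq_len(6), p$assignment)
  expect_setequal(key(best), key(unname(ours)))
})

test_that("standardized colony counts reproduce the worked anchors", {
  expect_equal(standardize_colony_count(54, 54, 56), 56.0)
  x <- standardize_colony_count(45, 48, 53)
  expect_equal(x, 49.6875)
  expect_equal(round(x, 1), 49.7)
  expect_equal(standardize_colony_count(7, 7, 7), 7)
  expect_error(standardize_colony_count(5, 0, 10), "N_g")
})

test_that("the Crozier chain anchors and invariants hold", {
  expect_equal(crozier_nc(56.0), 84.0)
  nns <- standardize_colony_count(11, 16, 19)
  expect_equal(nns, 13.0625)
  expect_equal(round(crozier_nc(nns), 1), 19.6)
  expect_equal(crozier_nc(0), 0)
  expect_equal(crozier_nc(1, n = 1, m = 1), 1.5)
  # linearity and the monogyny/monoandry simplification
  N <- c(0.5, 7, 33.25)
  expect_equal(crozier_nc(2 * N), 2 * crozier_nc(N))
  expect_equal(crozier_nc(N), 1.5 * N)
  expect_equal(crozier_nc(10, n = 2, m = 3), 4.5 * 10 * 2 * 3 / 7)
})

test_that("the density table applies the skip rule and rounding policy", {
  counts <- data.frame(species = "sp", site = c("A", "B", "C"),
                       N_i = c(19, 20, 16), N_g = c(16, 15, 16),
                       N_nr = c(11, 10, 12))
  tab <- colony_density_table(counts)
  expect_false(tab$skipped[1])
  expect_true(tab$skipped[2])                    # N_g = 15 <= 15: dash
  expect_true(is.na(tab$N_c[2]) && is.na(tab$N_ns_1[2]))
  expect_equal(tab$N_c_1[1], 19.6)
  expect_equal(tab$N_c[3], 1.5 * tab$N_ns[3])
})
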