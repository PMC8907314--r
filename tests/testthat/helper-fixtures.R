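# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# small hand-built diploid dataset
make_manual_ds <- function(a1, a2, species = "SpA", site = "S1",
                           sex = "female", loci = NULL) {
  n <- nrow(a1)
  loci <- loci %||% sprintf("L%02d", seq_len(ncol(a1)))
  meta <- data.frame(id = sprintf("ind%02d", seq_len(n)),
                     species = rep(species, length.out = n),
                     site = rep(site, length.out = n),
                     sex = rep(sex, length.out = n),
                     caste = ifelse(rep(sex, length.out = n) == "male",
                                    "male", "worker"),
                     ploidy = 2L, thorax_width = NA_real_,
                     stringsAsFactors = FALSE)
  genotype_dataset(a1, a2, meta, loci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random valid dataset for round-trip property tests
rand_ds <- function(seed, n = 12, L = 5) {
  set.seed(seed)
  a1 <- matrix(sample(100:120, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample(100:120, n * L, replace = TRUE), n, L)
  swap <- a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  miss <- matrix(runif(n * L) < 0.1, n, L)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.8, 0.2))
  ploidy <- ifelse(sex == "male" & runif(n) < 0.5, 1L, 2L)
  a2[ploidy == 1L, ] <- NA_integer_
  meta <- data.frame(id = sprintf("b%03d", seq_len(n)),
                     species = sample(c("SpA", "SpB"), n, replace = TRUE),
                     site = sample(c("CC", "CW"), n, replace = TRUE),
                     sex = sex,
                     caste = ifelse(sex == "male", "male", "worker"),
                     ploidy = ploidy, thorax_width = NA_real_,
                     stringsAsFactors = FALSE)
  genotype_dataset(a1, a2, meta, sprintf("loc%d", seq_len(L)))
}

# male dataset whose heterozygosity structure reproduces the printed
# per-site diploid-male counts for the one species with diploid males
# (synthetic stand-in for the unavailable deposited male genotype file)
make_table2_males <- function() {
  cells <- list(CC = c(dip = 1L, hap = 0L), CW = c(dip = 9L, hap = 0L),
                ED = c(dip = 10L, hap = 3L), SNR = c(dip = 1L, hap = 1L))
  L <- 8L
  a1 <- NULL; a2 <- NULL; site <- character(); id <- character()
  k <- 0L
  for (s in names(cells)) {
    for (i in seq_len(cells[[s]]["dip"])) {
      k <- k + 1L
      r1 <- rep(100L, L); r2 <- rep(100L, L)
      r2[1:4] <- 102L                       # heterozygous at 4 loci
      a1 <- rbind(a1, r1); a2 <- rbind(a2, r2)
      site <- c(site, s); id <- c(id, sprintf("M%02d", k))
    }
    for (i in seq_len(cells[[s]]["hap"])) {
      k <- k + 1L
      a1 <- rbind(a1, rep(104L, L)); a2 <- rbind(a2, rep(104L, L))
      site <- c(site, s); id <- c(id, sprintf("M%02d", k))
    }
  }
  meta <- data.frame(id = id, species = "B_griseocollis", site = site,
                     sex = "male", caste = "male", ploidy = 2L,
                     thorax_width = NA_real_, stringsAsFactors = FALSE)
  genotype_dataset(a1, a2, meta, sprintf("L%02d", seq_len(L)))
}

# independent Weir-Cockerham evaluation in plain scalar style (oracle);
# sites as subpopulations, diploid females only
oracle_fstats <- function(ds) {
  rows <- which(ds$meta$sex == "female" & ds$meta$ploidy == 2L)
  SA <- SB <- SC <- 0
  for (j in seq_along(ds$loci)) {
    rr <- rows[!is.na(ds$a1[rows, j])]
    bysite <- split(rr, ds$meta$site[rr])
    bysite <- bysite[sapply(bysite, length) >= 2]
    if (length(bysite) < 2) next
    als <- sort(unique(c(ds$a1[rr, j], ds$a2[rr, j])))
    if (length(als) < 2) next
    r <- length(bysite)
    ni <- sapply(bysite, length)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (al in als) {
      pi <- hi <- numeric(r)
      for (q in seq_len(r)) {
        g1 <- ds$a1[bysite[[q]], j]; g2 <- ds$a2[bysite[[q]], j]
        pi[q] <- mean(c(g1 == al, g2 == al))
        hi[q] <- mean(g1 != g2 & (g1 == al | g2 == al))
      }
      pbar <- sum(ni * pi) / sum(ni)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / sum(ni)
      SA <- SA + (nbar / nc) * (s2 - (pbar * (1 - pbar) -
             (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      SB <- SB + (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
             (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      SC <- SC + hbar / 2
    }
  }
  list(theta = SA / (SA + SB + SC), f = 1 - SC / (SB + SC))
}

# exhaustive rarefaction oracle: average distinct alleles over all
# subsets of size g of the gene-copy vector
oracle_ar <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# all perfect matchings of 2n positions (for the exact HWE oracle)
all_pairings <- function(v) {
  if (length(v) == 0) return(list(matrix(integer(0), nrow = 2)))
  out <- list()
  for (k in 2:length(v)) {
    rest <- all_pairings(v[-c(1, k)])
    for (m in rest)
      out[[length(out) + 1L]] <- cbind(c(v[1], v[k]), m)
  }
  out
}
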