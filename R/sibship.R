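# Full-sib colony reconstruction under haplodiploidy, and the colony-density
# chain N_nr -> N_ns -> N_c.
#
# Full sisters in a monogynous, monoandrous colony share the drone's allele
# at every locus and draw their maternal allele from the queen (IBD 1/2).
# Likelihoods marginalize over the unobserved queen (diploid, HWE at the
# supplied frequencies) and drone (haploid), with a per-allele mistyping
# model: an observed allele is the true one with probability 1 - e and a
# frequency-weighted random allele with probability e.

# ---- likelihood machinery --------------------------------------------------

# per-locus model: mistyping matrix E[obs, true], parent configurations
# (queen ordered pair q1 <= q2, drone d) and their prior weights
build_locus_model <- function(f, eps) {
  K <- length(f)
  E <- (1 - eps) * diag(K) + eps * matrix(f, K, K)
  qp <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  q1 <- rep(qp[, 1], each = K); q2 <- rep(qp[, 2], each = K)
  d <- rep(seq_len(K), times = nrow(qp))
  wq <- ifelse(q1 == q2, f[q1]^2, 2 * f[q1] * f[q2])
  list(E = E, f = f, q1 = q1, q2 = q2, d = d, w = wq * f[d], K = K)
}

# observation kernel of one individual's genotype at one locus:
# P_obs[a, b] = P(observed unordered pair | true ordered genotype (a, b))
obs_kernel <- function(model, x, y) {
  E <- model$E
  if (x == y) outer(E[x, ], E[x, ])
  else outer(E[x, ], E[y, ]) + outer(E[y, ], E[x, ])
}

# config vector of one member: P(obs | queen (q1,q2), drone d) under full-sib
# transmission (drone allele certain, maternal allele IBD 1/2)
member_vec <- function(model, P) {
  0.5 * P[cbind(model$d, model$q1)] + 0.5 * P[cbind(model$d, model$q2)]
}

#' Allele frequencies per locus from a dataset slice
#'
#' Plug-in frequencies from diploid calls (both allele copies) plus
#' recorded-haploid calls, as used for sibship likelihoods and HWE-style
#' expectations.
#'
#' @param ds a [genotype_dataset()]
#' @param rows optional individual subset
#' @return named list locus -> named numeric frequency vector
#' @export
site_allele_freqs <- function(ds, rows = NULL) {
  rows <- rows %||% seq_len(n_ind(ds))
  out <- list()
  for (j in seq_along(ds$loci)) {
    cnt <- allele_counts_at(ds, j, rows)
    out[[ds$loci[j]]] <- if (length(cnt)) cnt / sum(cnt) else numeric(0)
  }
  out
}

# map one individual's observed alleles into model index space, extending the
# frequency support (tiny frequency) for alleles unseen in the reference
prep_slice <- function(ds, rows, freqs, eps) {
  miss <- setdiff(ds$loci, names(freqs))
  if (length(miss))
    stop("frequencies missing for locus ", paste(miss, collapse = ", "))
  models <- list(); G <- list(); logU <- matrix(0, length(rows), n_loci(ds))
  for (j in seq_along(ds$loci)) {
    f <- freqs[[ds$loci[j]]]
    seen <- unique(stats::na.omit(c(ds$a1[rows, j], ds$a2[rows, j])))
    extra <- setdiff(as.character(seen), names(f))
    if (length(extra)) {
      eps_f <- if (length(f)) min(f) / 2 else 1
      f <- c(f, stats::setNames(rep(eps_f, length(extra)), extra))
      f <- f / sum(f)
    }
    m <- build_locus_model(as.numeric(f), eps)
    m$alleles <- names(f)
    models[[j]] <- m
    g <- matrix(1, length(m$w), length(rows))
    for (ii in seq_along(rows)) {
      i <- rows[ii]
      if (is.na(ds$a1[i, j])) next
      x <- match(as.character(ds$a1[i, j]), m$alleles)
      y <- if (is.na(ds$a2[i, j])) x
           else match(as.character(ds$a2[i, j]), m$alleles)
      P <- obs_kernel(m, x, y)
      g[, ii] <- member_vec(m, P)
      logU[ii, j] <- log(as.numeric(t(m$f) %*% P %*% m$f))
    }
    G[[j]] <- g
  }
  list(models = models, G = G, logU = logU)
}

#' Pairwise full-sib log-likelihood ratio
#'
#' Log-likelihood ratio of "full sisters" versus "unrelated" for two diploid
#' females, summed over jointly typed loci. The full-sib likelihood
#' marginalizes over one queen and one drone; the unrelated likelihood is the
#' product of marginal observed-genotype probabilities. Both sides share the
#' mistyping model.
#'
#' @param ds a [genotype_dataset()]
#' @param id1,id2 individual ids
#' @param freqs per-locus allele frequencies ([site_allele_freqs()])
#' @param eps per-allele mistyping rate
#' @return the log-likelihood ratio (natural log); `-Inf` is possible at
#'   `eps = 0` when the pair cannot be full sibs
#' @export
pair_fullsib_llr <- function(ds, id1, id2, freqs, eps = 0.05) {
  rows <- match(c(id1, id2), ds$meta$id)
  if (anyNA(rows)) stop("unknown individual id")
  shared <- which(!is.na(ds$a1[rows[1], ]) & !is.na(ds$a1[rows[2], ]))
  if (!length(shared)) stop("no shared typed loci between ", id1, " and ", id2)
  env <- prep_slice(ds, rows, freqs, eps)
  llr <- 0
  for (j in shared) {
    m <- env$models[[j]]
    lfs <- log(sum(m$w * env$G[[j]][, 1] * env$G[[j]][, 2]))
    llr <- llr + lfs - env$logU[1, j] - env$logU[2, j]
  }
  llr
}

# ---- agglomerative maximum-likelihood partitioning -------------------------

#' Infer a full-sib partition for one species-site slice
#'
#' Deterministic agglomerative maximum-likelihood clustering: every female
#' starts as her own family; at each step the family pair whose merge most
#' increases the total partition log-likelihood is merged, provided the
#' best linking pair between the two families has posterior probability of
#' being full sibs (uniform prior over full-sib/unrelated) at or above
#' `threshold`. Stops when no admissible merge improves the likelihood.
#' Family likelihood integrates member genotypes over a single shared queen
#' and drone. Ties are broken toward the smallest family indices, so the
#' result is reproducible.
#'
#' @param ds a [genotype_dataset()] slice holding the females of one species
#'   at one site (other individuals are ignored)
#' @param freqs per-locus allele frequencies; defaults to plug-in estimates
#'   from the slice's females
#' @param eps assumed per-allele genotyping error rate (study default 0.05)
#' @param threshold full-sib posterior admission threshold (study default
#'   0.95)
#' @param seed accepted for interface stability; the algorithm is
#'   deterministic
#' @return an object of class `sibship_partition`: `assignment` (named
#'   character vector id -> family label), `n_families` (N_nr),
#'   `pair_posterior` (matrix of pairwise full-sib posteriors), `eps`,
#'   `threshold`
#' @export
infer_partition <- function(ds, freqs = NULL, eps = 0.05, threshold = 0.95,
                            seed = 1L) {
  rows <- which(ds$meta$sex == "female")
  if (!length(rows)) stop("no females in slice")
  ids <- ds$meta$id[rows]
  if (is.null(freqs)) freqs <- site_allele_freqs(ds, rows)
  n <- length(rows)
  if (n == 1L) {
    part <- stats::setNames("F001", ids)
    return(structure(list(assignment = part, n_families = 1L,
                          pair_posterior = matrix(1, 1, 1,
                                                  dimnames = list(ids, ids)),
                          eps = eps, threshold = threshold),
                     class = "sibship_partition"))
  }
  env <- prep_slice(ds, rows, freqs, eps)
  L <- n_loci(ds)

  # family state: per locus a (n_config x F) product table with log offsets
  M <- lapply(env$G, identity)
  O <- matrix(0, n, L)
  fam_ll <- rep(0, n)
  for (l in seq_len(L)) {
    w <- env$models[[l]]$w
    fam_ll <- fam_ll + log(as.vector(w %*% M[[l]])) + O[, l]
  }

  # pairwise joint log-likelihoods and posteriors between singletons
  pairlog <- matrix(0, n, n)
  for (l in seq_len(L)) {
    w <- env$models[[l]]$w
    C <- crossprod(M[[l]], w * M[[l]])
    C[C <= 0] <- .Machine$double.xmin
    pairlog <- pairlog + log(C) + outer(O[, l], O[, l], "+")
  }
  indU <- rowSums(env$logU)
  llr <- pairlog - outer(indU, indU, "+")
  post <- stats::plogis(llr)
  gate <- post                      # family-level: max over member pairs

  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  repeat {
    delta <- pairlog - outer(fam_ll, fam_ll, "+")
    delta[!active, ] <- -Inf; delta[, !active] <- -Inf
    diag(delta) <- -Inf
    delta[gate < threshold] <- -Inf
    best <- max(delta)
    if (!is.finite(best) || best <= 1e-9) break
    hit <- which(delta == best, arr.ind = TRUE)
    hit <- hit[order(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2])), ,
               drop = FALSE]
    A <- min(hit[1, ]); B <- max(hit[1, ])
    # merge B into A
    for (l in seq_len(L)) {
      col <- M[[l]][, A] * M[[l]][, B]
      mx <- max(col)
      if (mx > 0) { O[A, l] <- O[A, l] + O[B, l] + log(mx); col <- col / mx }
      else O[A, l] <- -Inf
      M[[l]][, A] <- col
    }
    members[[A]] <- c(members[[A]], members[[B]])
    active[B] <- FALSE
    gate[A, ] <- pmax(gate[A, ], gate[B, ]); gate[, A] <- gate[A, ]
    new_ll <- 0
    for (l in seq_len(L)) {
      w <- env$models[[l]]$w
      v <- sum(w * M[[l]][, A])
      new_ll <- new_ll + (if (v > 0) log(v) + O[A, l] else -Inf)
    }
    stopifnot(new_ll >= fam_ll[A] + fam_ll[B] - 1e-6)  # monotone likelihood
    fam_ll[A] <- new_ll
    # refresh pair log-likelihoods of A against all active families
    vA <- rep(0, n)
    for (l in seq_len(L)) {
      w <- env$models[[l]]$w
      cv <- as.vector(crossprod(M[[l]], w * M[[l]][, A]))
      cv[cv <= 0] <- .Machine$double.xmin
      vA <- vA + log(cv) + O[, l] + O[A, l]
    }
    pairlog[A, ] <- vA; pairlog[, A] <- vA
  }
  fams <- which(active)
  assignment <- character(n)
  for (k in seq_along(fams))
    assignment[members[[fams[k]]]] <- sprintf("F%03d", k)
  names(assignment) <- ids
  dimnames(post) <- list(ids, ids)
  structure(list(assignment = assignment, n_families = length(fams),
                 pair_posterior = post, eps = eps, threshold = threshold),
            class = "sibship_partition")
}

#' @export
print.sibship_partition <- function(x, ...) {
  cat("sibship_partition:", length(x$assignment), "females in",
      x$n_families, "families (eps =", x$eps,
      ", threshold =", x$threshold, ")\n")
  invisible(x)
}

#' Infer sibships for every species-site stratum
#'
#' Convenience wrapper running [infer_partition()] within each species x site
#' slice and combining the assignments under stratum-unique family labels.
#'
#' @inheritParams infer_partition
#' @return list with `assignment` (named vector over all females),
#'   `n_families` (data.frame species, site, N_nr), `partitions` (per-stratum
#'   `sibship_partition` objects)
#' @export
infer_sibships <- function(ds, eps = 0.05, threshold = 0.95, seed = 1L) {
  females <- ds$meta[ds$meta$sex == "female", ]
  strata <- unique(females[c("species", "site")])
  assignment <- character(0)
  parts <- list(); nf <- list()
  for (k in seq_len(nrow(strata))) {
    sp <- strata$species[k]; si <- strata$site[k]
    sel <- ds$meta$species == sp & ds$meta$site == si &
      ds$meta$sex == "female"
    slice <- subset_dataset(ds, ind = sel)
    p <- infer_partition(slice, eps = eps, threshold = threshold, seed = seed)
    lab <- paste0(sp, "_", si, "_", p$assignment)
    names(lab) <- names(p$assignment)
    assignment <- c(assignment, lab)
    parts[[paste(sp, si, sep = "_")]] <- p
    nf[[k]] <- data.frame(species = sp, site = si, N_nr = p$n_families,
                          stringsAsFactors = FALSE)
  }
  list(assignment = assignment, n_families = do.call(rbind, nf),
       partitions = parts)
}

# ---- colony-density chain --------------------------------------------------

#' Standardize detected colony count for genotyping success
#'
#' N_ns = (N_nr / N_g) * N_i: the detected colony count scaled from the
#' genotyped females up to all sampled females. Returned unrounded; the
#' reporting layer rounds to one decimal.
#'
#' @param N_nr colonies detected among genotyped females
#' @param N_g successfully genotyped females (>= 1)
#' @param N_i sampled females
#' @return N_ns (real)
#' @export
standardize_colony_count <- function(N_nr, N_g, N_i) {
  if (any(N_g < 1)) stop("N_g must be >= 1")
  stopifnot(all(N_nr <= N_g), all(N_g <= N_i))
  (N_nr / N_g) * N_i
}

#' Crozier effective colony number
#'
#' N_c = 4.5 * N * n * m / (1 + 2m) for detected colony number N, queens per
#' colony n, and mating frequency m; with monogyny and monoandry
#' (n = m = 1) this is 1.5 * N. Computed from unrounded inputs.
#'
#' @param N detected (standardized) colony number
#' @param n queens per colony
#' @param m mating frequency
#' @return N_c (real)
#' @export
crozier_nc <- function(N, n = 1, m = 1) {
  stopifnot(all(N >= 0), all(n >= 1), all(m >= 1))
  4.5 * N * n * m / (1 + 2 * m)
}

#' Colony-density table from sampled/genotyped/detected counts
#'
#' Applies the full chain N_i, N_g, N_nr -> N_ns -> N_c per species x site,
#' with the skip rule: no estimates for strata with 15 or fewer successfully
#' genotyped females. Chain values are computed unrounded and additionally
#' reported rounded to one decimal (`N_ns_1`, `N_c_1`), with `NA` where
#' skipped.
#'
#' @param counts data.frame with columns `species`, `site`, `N_i`, `N_g`,
#'   `N_nr` (`N_nr` may be `NA` for skipped strata)
#' @param n,m queens per colony and mating frequency for [crozier_nc()]
#' @param skip_max skip threshold: strata with `N_g <= skip_max` get no
#'   estimates
#' @return the input with columns `N_ns`, `N_c`, `N_ns_1`, `N_c_1`,
#'   `skipped` appended
#' @export
colony_density_table <- function(counts, n = 1, m = 1, skip_max = 15) {
  stopifnot(all(c("species", "site", "N_i", "N_g", "N_nr") %in%
                  names(counts)))
  out <- counts
  out$skipped <- out$N_g <= skip_max | is.na(out$N_g)
  out$N_ns <- out$N_c <- NA_real_
  ok <- !out$skipped & !is.na(out$N_nr)
  out$N_ns[ok] <- standardize_colony_count(out$N_nr[ok], out$N_g[ok],
                                           out$N_i[ok])
  out$N_c[ok] <- crozier_nc(out$N_ns[ok], n = n, m = m)
  out$N_ns_1 <- round(out$N_ns, 1)
  out$N_c_1 <- round(out$N_c, 1)
  out
}
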