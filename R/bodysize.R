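# Body-size cline analysis: two-way fixed-effects ANOVA on worker thorax
# width with species, site and their interaction, least-squares-means
# contrasts between intraspecific subpopulations, and Bonferroni correction.
# Input is expected to be one randomly chosen sister per colony.

#' Exclude under-sampled subpopulations from body-size analysis
#'
#' Removes species x site cells with 15 or fewer workers carrying a thorax
#' width measurement (the inclusive "<= 15" rule; a cell of 16 is retained).
#'
#' @param measurements data.frame with columns `species`, `site`,
#'   `thorax_width` (one row per measured worker)
#' @param min_workers smallest retained cell size (default 16, i.e. exclude
#'   cells with <= 15)
#' @return list with `data` (retained rows) and `excluded` (data.frame
#'   `species`, `site`, `n`, `reason`)
#' @export
filter_size_cells <- function(measurements, min_workers = 16) {
  m <- measurements[!is.na(measurements$thorax_width), , drop = FALSE]
  if (!nrow(m))
    return(list(data = m,
                excluded = data.frame(species = character(),
                                      site = character(), n = integer(),
                                      reason = character(),
                                      stringsAsFactors = FALSE)))
  n_cell <- stats::aggregate(list(n = m$thorax_width),
                             by = m[c("species", "site")], FUN = length)
  bad <- n_cell[n_cell$n < min_workers, , drop = FALSE]
  key <- paste(m$species, m$site)
  keep <- !(key %in% paste(bad$species, bad$site))
  excluded <- if (nrow(bad))
    data.frame(bad, reason = sprintf("<= %d workers", min_workers - 1L),
               stringsAsFactors = FALSE)
  else data.frame(species = character(), site = character(), n = integer(),
                  reason = character(), stringsAsFactors = FALSE)
  list(data = m[keep, , drop = FALSE], excluded = excluded)
}

#' Fit the two-way body-size model
#'
#' Ordinary least squares with species, site and their interaction as fixed
#' factors under sum-to-zero coding. F tests are partial (Type-III-style)
#' when every retained cell is observed; with missing cells the interaction
#' model is rank-deficient and the tests fall back to nested-model (Type-II)
#' comparisons, flagged in the result. Least-squares means are
#' model-predicted cell means with SEs from the coefficient covariance.
#'
#' @param measurements retained measurement rows ([filter_size_cells()])
#' @return list of class `size_model`: `fit` (the lm), `anova` (data.frame
#'   `term`, `F`, `df`, `p`), `anova_type`, `cell_means` (data.frame
#'   `species`, `site`, `lsmean`, `SE`, `df`)
#' @export
fit_size_model <- function(measurements) {
  m <- measurements
  m$species <- factor(m$species); m$site <- factor(m$site)
  if (nlevels(m$species) < 2L || nlevels(m$site) < 2L)
    stop("need >= 2 species and >= 2 sites after cell exclusion")
  fit <- stats::lm(thorax_width ~ species * site, data = m,
                   contrasts = list(species = "contr.sum",
                                    site = "contr.sum"))
  aliased <- anyNA(stats::coef(fit))
  if (fit$df.residual == 0L) {
    # saturated design (one observation per cell): no F tests possible
    anova_tab <- data.frame(term = c("species", "site", "species:site"),
                            F = NA_real_, df = NA_real_, p = NA_real_,
                            stringsAsFactors = FALSE)
    type <- "saturated"
  } else if (!aliased) {
    a3 <- car::Anova(fit, type = 3)
    rows <- c("species", "site", "species:site")
    anova_tab <- data.frame(term = rows,
                            F = a3[rows, "F value"],
                            df = a3[rows, "Df"],
                            p = a3[rows, "Pr(>F)"],
                            stringsAsFactors = FALSE)
    type <- "III"
  } else {
    # missing cells: partial tests are undefined; nested comparisons instead
    add <- stats::lm(thorax_width ~ species + site, data = m)
    cmp <- function(small, big) {
      a <- stats::anova(small, big)
      c(F = a$F[2], df = a$Df[2], p = a$`Pr(>F)`[2])
    }
    r_int <- cmp(add, fit)
    r_sp <- cmp(stats::lm(thorax_width ~ site, data = m), add)
    r_si <- cmp(stats::lm(thorax_width ~ species, data = m), add)
    anova_tab <- data.frame(term = c("species", "site", "species:site"),
                            F = c(r_sp["F"], r_si["F"], r_int["F"]),
                            df = c(r_sp["df"], r_si["df"], r_int["df"]),
                            p = c(r_sp["p"], r_si["p"], r_int["p"]),
                            stringsAsFactors = FALSE)
    type <- "II (nested)"
  }
  cm <- if (type == "saturated")   # SEs/CIs are NaN at 0 residual df
    suppressWarnings(as.data.frame(emmeans::emmeans(fit, ~ species * site)))
  else as.data.frame(emmeans::emmeans(fit, ~ species * site))
  cell_means <- data.frame(species = as.character(cm$species),
                           site = as.character(cm$site),
                           lsmean = cm$emmean, SE = cm$SE, df = cm$df,
                           stringsAsFactors = FALSE)
  structure(list(fit = fit, anova = anova_tab, anova_type = type,
                 cell_means = cell_means, data = m),
            class = "size_model")
}

#' Intraspecific least-squares-means contrasts with Bonferroni correction
#'
#' One contrast per unordered same-species site pair among retained cells
#' (difference of LS means, t test on the residual degrees of freedom). The
#' Bonferroni threshold is `alpha` divided by the number of contrasts
#' produced; comparisons use the exact value, display rounds to five
#' decimals.
#'
#' @param model a `size_model` from [fit_size_model()]
#' @param alpha family-wise level
#' @return list with `contrasts` (data.frame `species`, `site1`, `site2`,
#'   `estimate`, `SE`, `t`, `p`, `significant`), `n_contrasts`,
#'   `alpha_bonferroni`
#' @export
intraspecific_contrasts <- function(model, alpha = 0.05) {
  emm <- emmeans::emmeans(model$fit, ~ site | species)
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"),
                 infer = c(FALSE, TRUE))
  prs <- as.data.frame(prs)
  prs <- prs[!is.na(prs$estimate), , drop = FALSE]
  sides <- do.call(rbind, strsplit(as.character(prs$contrast), " - "))
  clean <- function(x) sub("^site", "", x)
  out <- data.frame(species = as.character(prs$species),
                    site1 = clean(sides[, 1]), site2 = clean(sides[, 2]),
                    estimate = prs$estimate, SE = prs$SE, t = prs$t.ratio,
                    p = prs$p.value, stringsAsFactors = FALSE)
  n_con <- nrow(out)
  alpha_b <- if (n_con) alpha / n_con else NA_real_
  out$significant <- out$p < alpha_b
  list(contrasts = out, n_contrasts = n_con, alpha_bonferroni = alpha_b)
}

#' Bonferroni-corrected alpha for a contrast family
#'
#' @param alpha family-wise level
#' @param n_contrasts number of contrasts
#' @return `alpha / n_contrasts` (exact value; round to 5 decimals for
#'   display)
#' @export
bonferroni_alpha <- function(alpha, n_contrasts) {
  stopifnot(n_contrasts >= 1)
  alpha / n_contrasts
}
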