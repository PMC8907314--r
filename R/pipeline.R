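# End-to-end orchestration: simulate/ingest -> QC -> sibship -> colony
# density -> F-statistics/AR -> male ploidy -> body size, with one master
# seed and a replayable provenance log.

#' Run the full analysis pipeline
#'
#' Stages, in the order the analyses require: missingness filter (loci then
#' individuals, per species) -> null-allele locus screen -> full-sib
#' reconstruction per species x site -> colony-density chain with skip rule
#' -> one-sister-per-colony dedup -> LD prune -> HWE report -> multilocus
#' F-statistics, bootstrap CIs and rarefied allelic richness with the
#' small-population exclusion -> diploid-male summary -> body-size ANOVA and
#' intraspecific LS-means contrasts. Every stage RNG is derived
#' deterministically from `seed`.
#'
#' @param input a [genotype_dataset()] or a [sim_config()] (simulated
#'   internally)
#' @param missing_threshold,null_threshold QC thresholds (study defaults
#'   0.20 and 0.25)
#' @param eps,sib_threshold sibship error rate and posterior admission
#'   threshold (study defaults 0.05 and 0.95)
#' @param skip_max colony-density skip rule: no estimates when N_g <=
#'   `skip_max` (study default 15)
#' @param min_pop small-population exclusion for F-statistics/site AR (study
#'   default 25)
#' @param min_workers smallest retained body-size cell (study default 16,
#'   i.e. exclude cells of <= 15 measured workers)
#' @param ld_alpha,ld_perm LD screen settings
#' @param n_boot bootstrap replicates for F-statistic CIs
#' @param alpha contrast family-wise level
#' @param seed master seed
#' @param output_dir optional directory; when given, report tables are
#'   written as CSV/JSON
#' @return list of class `pipeline_result` with elements `density`
#'   (Table-1-shaped), `ploidy` (Table-2-shaped), `popgen` (Table-3-shaped
#'   summary), `body_size` (anova + contrasts or NULL), `qc` (reports),
#'   `sibships`, `provenance`
#' @export
run_pipeline <- function(input,
                         missing_threshold = 0.20, null_threshold = 0.25,
                         eps = 0.05, sib_threshold = 0.95,
                         skip_max = 15, min_pop = 25, min_workers = 16,
                         ld_alpha = 0.05, ld_perm = 199, n_boot = 200,
                         alpha = 0.05, seed = 1L, output_dir = NULL) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  if (inherits(input, "sim_config")) {
    input$seed <- seed
    sim <- simulate_dataset(input)
    ds0 <- sim$dataset
    note("simulated dataset: %d individuals, %d loci", n_ind(ds0),
         n_loci(ds0))
  } else {
    stopifnot(inherits(input, "genotype_dataset"))
    ds0 <- input
    sim <- NULL
  }
  # sampled females per stratum (N_i), before any QC
  fem <- ds0$meta[ds0$meta$sex == "female", ]
  ni <- stats::aggregate(list(N_i = fem$id), by = fem[c("species", "site")],
                         FUN = length)

  fm <- filter_missingness(ds0, missing_threshold)
  note("missingness filter: dropped %d individuals, %d locus x species",
       nrow(fm$report$dropped_individuals), nrow(fm$report$dropped_loci))
  fn <- filter_null_loci(fm$dataset, null_threshold)
  ds_sib <- fn$dataset
  note("null-allele screen: dropped %d locus x species",
       nrow(fn$report$dropped_loci))

  fem_g <- ds_sib$meta[ds_sib$meta$sex == "female", ]
  ng <- stats::aggregate(list(N_g = fem_g$id),
                         by = fem_g[c("species", "site")], FUN = length)
  sib <- infer_sibships(ds_sib, eps = eps, threshold = sib_threshold,
                        seed = seed)
  counts <- merge(merge(ni, ng, all = TRUE), sib$n_families, all = TRUE)
  counts$N_g[is.na(counts$N_g)] <- 0L
  density <- colony_density_table(counts, skip_max = skip_max)
  note("sibship + density chain over %d strata", nrow(density))

  ds_one <- dedupe_sisters(ds_sib, sib$assignment, seed = seed + 1L)
  note("dedupe sisters: %d -> %d individuals", n_ind(ds_sib), n_ind(ds_one))
  ld <- ld_test_and_prune(ds_one, alpha = ld_alpha, n_perm = ld_perm,
                          seed = seed + 2L)
  ds_final <- ld$dataset
  hwe <- list()
  for (sp in unique(ds_final$meta$species)) {
    rows <- which(ds_final$meta$species == sp)
    hwe[[sp]] <- vapply(seq_len(n_loci(ds_final)), function(j) {
      rj <- rows[!is.na(ds_final$a1[rows, j]) &
                   ds_final$meta$ploidy[rows] == 2L]
      if (length(rj) < 5L) return(NA_real_)
      hwe_test(ds_final, j, rows = rows, n_perm = 499, seed = seed + 3L + j)
    }, numeric(1))
    names(hwe[[sp]]) <- ds_final$loci
  }
  popgen <- tryCatch(popgen_summary(ds_final, min_pop = min_pop,
                                    n_boot = n_boot, seed = seed + 4L),
                     error = function(e) { note("popgen skipped: %s",
                                                conditionMessage(e)); NULL })
  ploidy <- summarize_diploidy(ds_final)

  body <- NULL
  meas <- ds_final$meta[ds_final$meta$sex == "female" &
                          !is.na(ds_final$meta$thorax_width),
                        c("species", "site", "thorax_width")]
  if (nrow(meas)) {
    fc <- filter_size_cells(meas, min_workers = min_workers)
    body <- tryCatch({
      mod <- fit_size_model(fc$data)
      con <- intraspecific_contrasts(mod, alpha = alpha)
      list(anova = mod$anova, anova_type = mod$anova_type,
           cell_means = mod$cell_means, contrasts = con$contrasts,
           n_contrasts = con$n_contrasts,
           alpha_bonferroni = con$alpha_bonferroni,
           excluded_cells = fc$excluded)
    }, error = function(e) { note("body size skipped: %s",
                                  conditionMessage(e)); NULL })
  }

  out <- structure(list(density = density, ploidy = ploidy, popgen = popgen,
                        body_size = body,
                        qc = list(missingness = fm$report,
                                  null_alleles = fn$report, ld = ld$report,
                                  hwe = hwe),
                        sibships = sib, dataset = ds_final,
                        truth = if (!is.null(sim)) sim$truth else NULL,
                        provenance = c(ds_final$provenance, log)),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_result(out, output_dir)
  out
}

#' Write pipeline report tables to a directory
#'
#' Emits `density.csv`, `ploidy.csv`, `contrasts.csv` and a JSON bundle
#' (`report.json`) with the population-genetic summary and provenance log.
#' Dashes (skipped strata) are encoded as empty cells.
#'
#' @param result a `pipeline_result`
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$density, file.path(dir, "density.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(result$ploidy, file.path(dir, "ploidy.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(result$body_size))
    utils::write.csv(result$body_size$contrasts,
                     file.path(dir, "contrasts.csv"), row.names = FALSE,
                     na = "")
  bundle <- list(popgen = result$popgen,
                 body_size = result$body_size[c("anova", "anova_type",
                                                "n_contrasts",
                                                "alpha_bonferroni")],
                 provenance = result$provenance)
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat("  density strata:", nrow(x$density), "(skipped:",
      sum(x$density$skipped), ")\n")
  if (!is.null(x$popgen))
    cat("  popgen species:", paste(names(x$popgen), collapse = ", "), "\n")
  if (!is.null(x$body_size))
    cat("  body-size contrasts:", x$body_size$n_contrasts,
        "at Bonferroni alpha", signif(x$body_size$alpha_bonferroni, 3), "\n")
  invisible(x)
}
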