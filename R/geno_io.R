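# ---- genotype_dataset: individuals x loci allele calls + metadata ----------

#' Construct a genotype dataset
#'
#' The central container of the package: multilocus microsatellite allele
#' calls for a set of individuals together with per-individual metadata.
#' Allele calls are integer fragment lengths (bp). Diploid calls occupy both
#' allele slots; recorded-haploid calls (males scored from a single peak and
#' stored with ploidy 1) occupy only the first. A missing call has both slots
#' `NA` — missingness is never encoded as allele 0.
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele codes; `NA`
#'   for missing. `a2` is `NA` across the board for individuals recorded
#'   haploid.
#' @param meta data.frame with columns `id`, `species`, `site`, `sex`
#'   ("female"/"male"), `caste` ("worker"/"queen"/"male"), `ploidy` (1 or 2,
#'   the *recorded* ploidy of the allele calls) and optionally
#'   `thorax_width` (mm) and `forage_genus`.
#' @param loci character vector of locus names (unique).
#' @param species_bins optional named list: species -> named list of
#'   locus -> integer vector of permitted allele codes.
#' @param provenance character vector logging applied filters.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(a1, a2, meta, loci,
                             species_bins = NULL,
                             provenance = character()) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  stopifnot(nrow(a1) == nrow(meta), ncol(a1) == length(loci),
            all(dim(a1) == dim(a2)), !anyDuplicated(loci))
  if (any(c(a1, a2) <= 0L, na.rm = TRUE))
    stop("allele codes must be positive integers")
  if (anyDuplicated(meta$id)) stop("individual ids must be unique")
  need <- c("id", "species", "site", "sex", "caste", "ploidy")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("meta lacks column(s): ", paste(miss, collapse = ", "))
  if (!"thorax_width" %in% names(meta)) meta$thorax_width <- NA_real_
  if (any(meta$thorax_width <= 0, na.rm = TRUE))
    stop("thorax_width must be positive when present")
  meta$id <- as.character(meta$id)
  rownames(a1) <- rownames(a2) <- meta$id
  colnames(a1) <- colnames(a2) <- loci
  # ploidy-2 calls: slots jointly present or jointly missing; ploidy-1: a2 NA
  dip <- meta$ploidy == 2L
  if (any(dip) && any(xor(is.na(a1[dip, , drop = FALSE]),
                          is.na(a2[dip, , drop = FALSE]))))
    stop("diploid individuals must carry 0 or 2 alleles per locus")
  if (any(!dip) && any(!is.na(a2[!dip, , drop = FALSE])))
    stop("recorded-haploid individuals cannot carry a second allele")
  structure(list(a1 = a1, a2 = a2, meta = meta, loci = loci,
                 species_bins = species_bins, provenance = provenance),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$a1), "individuals x", length(x$loci),
      "loci\n")
  cat("  species:", paste(sort(unique(x$meta$species)), collapse = ", "), "\n")
  cat("  sites:  ", paste(sort(unique(x$meta$site)), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$a1))
  cat("  missing calls:", nmiss,
      sprintf("(%.1f%%)", 100 * nmiss / length(x$a1)), "\n")
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' Number of individuals / loci
#' @param ds a `genotype_dataset`
#' @return integer count
#' @export
n_ind <- function(ds) nrow(ds$a1)

#' @rdname n_ind
#' @export
n_loci <- function(ds) length(ds$loci)

#' Subset a genotype dataset by individuals and/or loci
#'
#' @param ds a `genotype_dataset`
#' @param ind individual selector (logical/integer index or character ids)
#' @param loci locus selector (index or names)
#' @param note optional provenance note appended to the log
#' @return the subsetted `genotype_dataset`
#' @export
subset_dataset <- function(ds, ind = NULL, loci = NULL, note = NULL) {
  ii <- if (is.null(ind)) seq_len(n_ind(ds)) else
    if (is.character(ind)) match(ind, ds$meta$id) else which_idx(ind, n_ind(ds))
  jj <- if (is.null(loci)) seq_along(ds$loci) else
    if (is.character(loci)) match(loci, ds$loci) else which_idx(loci, n_loci(ds))
  if (anyNA(ii)) stop("unknown individual id")
  if (anyNA(jj)) stop("unknown locus")
  genotype_dataset(ds$a1[ii, jj, drop = FALSE], ds$a2[ii, jj, drop = FALSE],
                   ds$meta[ii, , drop = FALSE], ds$loci[jj],
                   species_bins = ds$species_bins,
                   provenance = c(ds$provenance, note))
}

which_idx <- function(i, n) {
  if (is.logical(i)) { stopifnot(length(i) == n); which(i) } else as.integer(i)
}

#' Per-individual fraction of missing locus calls
#' @param ds a `genotype_dataset`
#' @return numeric vector named by individual id
#' @export
missing_by_ind <- function(ds) rowMeans(is.na(ds$a1))

#' @rdname missing_by_ind
#' @return for `missing_by_locus`, numeric vector named by locus
#' @export
missing_by_locus <- function(ds) colMeans(is.na(ds$a1))

# ---- GenePop I/O -----------------------------------------------------------

#' Read a GenePop file
#'
#' Parses the GenePop 4.x dialect: a title line, locus names (one per line or
#' comma-separated), `POP` block separators, and per-individual rows
#' `id , 0xx0yy ...` in the 2- or 3-digit allele encoding (`0000`/`000000`
#' missing). POP blocks become sites `Pop1..PopK` unless a metadata table
#' supplies `site` (and species/sex/caste/ploidy) per id. A sidecar written by
#' [write_genepop()] (`<path>.meta.csv`) is picked up automatically so that
#' write/read round-trips are lossless.
#'
#' @param path GenePop file path
#' @param metadata_path optional CSV with columns `id` and any of `species`,
#'   `site`, `sex`, `caste`, `ploidy`, `thorax_width`
#' @return a [genotype_dataset()]
#' @export
read_genepop <- function(path, metadata_path = NULL) {
  lines <- readLines(path)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 2L) stop("GenePop file too short")
  is_pop <- toupper(trimws(lines)) %in% c("POP")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP separator found")
  header <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("duplicate locus names in header")
  L <- length(loci)

  ids <- character(); pops <- integer(); rows <- list(); width <- NA_integer_
  popnum <- 0L
  for (k in seq(first_pop, length(lines))) {
    ln <- lines[k]
    if (toupper(trimws(ln)) == "POP") { popnum <- popnum + 1L; next }
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L)
      stop("malformed GenePop row (no comma) at line ", k)
    id <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(calls) != L)
      stop("row for '", id, "' (line ", k, ") has ", length(calls),
           " calls; expected ", L)
    w <- unique(nchar(calls))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop("unknown allele encoding width in row '", id, "' (line ", k, ")")
    if (is.na(width)) width <- w else if (w != width)
      stop("inconsistent allele widths within file (line ", k, ")")
    ids <- c(ids, id); pops <- c(pops, popnum); rows[[length(rows) + 1L]] <- calls
  }
  d <- width / 2L
  a1 <- matrix(NA_integer_, length(ids), L)
  a2 <- matrix(NA_integer_, length(ids), L)
  for (i in seq_along(rows)) {
    x <- rows[[i]]
    v1 <- as.integer(substr(x, 1L, d)); v2 <- as.integer(substr(x, d + 1L, width))
    v1[v1 == 0L] <- NA_integer_; v2[v2 == 0L] <- NA_integer_
    bad <- xor(is.na(v1), is.na(v2))
    v1[bad] <- NA_integer_; v2[bad] <- NA_integer_  # half-missing -> missing
    a1[i, ] <- v1; a2[i, ] <- v2
  }
  meta <- data.frame(id = ids,
                     species = "unknown",
                     site = paste0("Pop", pops),
                     sex = "female", caste = "worker", ploidy = 2L,
                     thorax_width = NA_real_,
                     stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".meta.csv")
  if (is.null(metadata_path) && file.exists(sidecar)) metadata_path <- sidecar
  if (!is.null(metadata_path)) {
    md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    md$id <- as.character(md$id)
    j <- match(meta$id, md$id)
    for (col in intersect(names(md), c("species", "site", "sex", "caste",
                                       "ploidy", "thorax_width"))) {
      ok <- !is.na(j)
      meta[[col]][ok] <- md[[col]][j[ok]]
    }
  }
  meta$ploidy <- as.integer(meta$ploidy)
  hap <- meta$ploidy == 1L
  a2[hap, ] <- NA_integer_  # haploids were exported as homozygotes
  genotype_dataset(a1, a2, meta, loci,
                   provenance = paste0("read_genepop(", basename(path), ")"))
}

#' Write a GenePop file
#'
#' Emits the 3-digit dialect with one `POP` block per site (sites in first
#' appearance order, individuals in dataset order). Recorded-haploid
#' individuals are written as homozygotes — GenePop has no haploid encoding
#' for diploid-coded loci — and a sidecar metadata CSV (`<path>.meta.csv`,
#' including recorded ploidy) is written alongside so [read_genepop()]
#' round-trips losslessly.
#'
#' @param ds a [genotype_dataset()]
#' @param path output path
#' @param title title line (first line of the file)
#' @return invisibly, `path`
#' @export
write_genepop <- function(ds, path, title = "bombusgen export") {
  if (any(c(ds$a1, ds$a2) > 999L, na.rm = TRUE))
    stop("allele code exceeds 999; cannot encode in the 3-digit dialect")
  enc <- function(v) { v[is.na(v)] <- 0L; sprintf("%03d", v) }
  out <- c(title, ds$loci)
  sites <- unique(ds$meta$site)
  for (s in sites) {
    out <- c(out, "POP")
    for (i in which(ds$meta$site == s)) {
      v1 <- ds$a1[i, ]; v2 <- ds$a2[i, ]
      if (ds$meta$ploidy[i] == 1L) v2 <- v1
      out <- c(out, paste0(ds$meta$id[i], " ,  ",
                           paste0(enc(v1), enc(v2), collapse = " ")))
    }
  }
  writeLines(out, path)
  utils::write.csv(ds$meta, paste0(path, ".meta.csv"), row.names = FALSE)
  invisible(path)
}

# ---- tabular I/O -----------------------------------------------------------

#' Read a genotype table (CSV dialect)
#'
#' Ingests supplementary-style genotype tables: one row per individual, two
#' allele columns per locus (one for recorded-haploid males). The column
#' layout is supplied as a schema map because such tables have no fixed
#' layout.
#'
#' @param path CSV path
#' @param schema named list: entries `id`, `species`, `site`, `sex` (required
#'   column names), optional `caste`, `thorax_width`, and `loci`, itself a
#'   named list mapping locus name -> character vector of 1 (haploid) or 2
#'   allele column names. Blank/NA allele cells are missing calls.
#' @return a [genotype_dataset()]
#' @export
read_genotype_table <- function(path, schema) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  for (f in c("id", "species", "site", "sex")) {
    if (is.null(schema[[f]]) || !(schema[[f]] %in% names(tab)))
      stop("schema error: required column mapping '", f, "' absent from table")
  }
  for (lc in unlist(schema$loci))
    if (!lc %in% names(tab))
      stop("schema error: allele column '", lc, "' absent from table")
  loci <- names(schema$loci)
  n <- nrow(tab)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  ploidy <- rep(2L, n)
  if (!is.null(schema$ploidy) && schema$ploidy %in% names(tab))
    ploidy <- as.integer(tab[[schema$ploidy]])
  if (all(lengths(schema$loci) == 1L)) ploidy <- rep(1L, n)  # haploid panel
  for (j in seq_along(loci)) {
    cols <- schema$loci[[j]]
    v1 <- suppressWarnings(as.integer(tab[[cols[1]]]))
    v2 <- if (length(cols) >= 2L)
      suppressWarnings(as.integer(tab[[cols[2]]])) else rep(NA_integer_, n)
    # half-missing diploid calls collapse to missing; haploid rows keep v1
    bad <- xor(is.na(v1), is.na(v2)) & ploidy == 2L & length(cols) >= 2L
    v1[bad] <- NA_integer_; v2[bad] <- NA_integer_
    a1[, j] <- v1; a2[, j] <- v2
  }
  get <- function(f, default) {
    if (!is.null(schema[[f]]) && schema[[f]] %in% names(tab))
      tab[[schema[[f]]]] else rep(default, n)
  }
  sex <- as.character(tab[[schema$sex]])
  # a male with only first-slot calls at every typed locus is recorded haploid
  meta <- data.frame(id = as.character(tab[[schema$id]]),
                     species = as.character(tab[[schema$species]]),
                     site = as.character(tab[[schema$site]]),
                     sex = sex,
                     caste = as.character(get("caste",
                                              ifelse(sex == "male", "male",
                                                     "worker"))[1:n]),
                     ploidy = ploidy,
                     thorax_width = suppressWarnings(
                       as.numeric(get("thorax_width", NA_real_))),
                     stringsAsFactors = FALSE)
  hap <- meta$ploidy == 1L
  a2[hap, ] <- NA_integer_
  genotype_dataset(a1, a2, meta, loci,
                   provenance = paste0("read_genotype_table(",
                                       basename(path), ")"))
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: two allele columns per locus
#' (`<locus>.1`, `<locus>.2`), blank cells for missing calls, plus metadata
#' columns. Re-reading with the matching schema reproduces the dataset.
#'
#' @param ds a [genotype_dataset()]
#' @param path output CSV path
#' @return invisibly, the schema list suitable for [read_genotype_table()]
#' @export
write_genotype_table <- function(ds, path) {
  tab <- ds$meta[c("id", "species", "site", "sex", "caste", "ploidy",
                   "thorax_width")]
  schema_loci <- list()
  for (j in seq_along(ds$loci)) {
    c1 <- paste0(ds$loci[j], ".1"); c2 <- paste0(ds$loci[j], ".2")
    tab[[c1]] <- ds$a1[, j]; tab[[c2]] <- ds$a2[, j]
    schema_loci[[ds$loci[j]]] <- c(c1, c2)
  }
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(list(id = "id", species = "species", site = "site", sex = "sex",
                 caste = "caste", ploidy = "ploidy",
                 thorax_width = "thorax_width", loci = schema_loci))
}

# ---- species-bin verification ---------------------------------------------

#' Verify individuals against species-specific allele bins
#'
#' Cross-checks every allele call against the permitted allele set for the
#' individual's species at that locus — the standard post-scoring sanity check
#' that catches species misidentification or cross-contamination. The dataset
#' is not modified.
#'
#' @param ds a [genotype_dataset()] whose `species_bins` is populated
#' @return data.frame with columns `id`, `species`, `locus`, `allele`, one row
#'   per offending call (zero rows when everything is in-bin)
#' @export
verify_species_bins <- function(ds) {
  if (is.null(ds$species_bins)) stop("species_bins not populated")
  out <- list()
  for (i in seq_len(n_ind(ds))) {
    sp <- ds$meta$species[i]
    bins <- ds$species_bins[[sp]]
    if (is.null(bins)) { warning("no bins for species ", sp, "; skipped"); next }
    for (j in seq_along(ds$loci)) {
      bin <- bins[[ds$loci[j]]]
      if (is.null(bin) || !length(bin)) next
      for (al in stats::na.omit(c(ds$a1[i, j], ds$a2[i, j])))
        if (!(al %in% bin))
          out[[length(out) + 1L]] <-
            data.frame(id = ds$meta$id[i], species = sp,
                       locus = ds$loci[j], allele = al,
                       stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id = character(), species = character(),
                      locus = character(), allele = integer(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}
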