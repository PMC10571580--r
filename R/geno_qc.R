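#' Genotype quality control
#'
#' Applies the marker and individual filters in a fixed order: (1) minor
#' allele frequency strictly lower than `maf`, (2) per-marker missing rate
#' strictly greater than `marker_missing`, (3) per-individual missing rate
#' strictly greater than `indiv_missing`, (4) markers mapped to sex
#' chromosomes (`X`, `Y`, `XY`, `MT` labels and common numeric aliases).
#' Boundary values are kept: MAF exactly at the threshold passes, missing
#' rate exactly at the threshold passes.  MAF is computed on observed
#' alleles only (missing genotypes excluded from the denominator).
#'
#' @param genotypes Integer matrix, individuals x markers, codes 0/1/2
#'   with `NA` for missing; dimnames identify individuals and markers.
#' @param map Tibble with columns `marker`, `chrom`, `pos` aligned with
#'   the genotype columns.
#' @param maf,marker_missing,indiv_missing Thresholds (defaults 0.05,
#'   0.05, 0.03).
#' @return A list with `genotypes`, `map` (filtered), and `report`
#'   (a `qc_report`: counts removed per filter in application order,
#'   final dimensions, and notes).
#' @export
apply_qc <- function(genotypes, map, maf = 0.05, marker_missing = 0.05,
                     indiv_missing = 0.03) {
  stopifnot(ncol(genotypes) == nrow(map))
  n0 <- nrow(genotypes); k0 <- ncol(genotypes)
  steps <- list()

  # 1. MAF strictly lower than threshold
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  maf_obs <- pmin(p, 1 - p)
  maf_obs[is.nan(maf_obs)] <- 0
  drop1 <- maf_obs < maf
  steps$maf <- sum(drop1)
  genotypes <- genotypes[, !drop1, drop = FALSE]
  map <- map[!drop1, , drop = FALSE]

  # 2. marker missing rate strictly greater than threshold
  mr <- colMeans(is.na(genotypes))
  drop2 <- mr > marker_missing
  steps$marker_missing <- sum(drop2)
  genotypes <- genotypes[, !drop2, drop = FALSE]
  map <- map[!drop2, , drop = FALSE]

  # 3. individual missing rate strictly greater than threshold
  ir <- rowMeans(is.na(genotypes))
  if (ncol(genotypes) == 0) ir <- rep(0, nrow(genotypes))
  drop3 <- ir > indiv_missing
  steps$indiv_missing <- sum(drop3)
  genotypes <- genotypes[!drop3, , drop = FALSE]

  # 4. sex chromosomes
  sexchr <- toupper(as.character(map$chrom)) %in%
    c("X", "Y", "XY", "MT", "23", "24", "25", "26")
  steps$sex_chrom <- sum(sexchr)
  genotypes <- genotypes[, !sexchr, drop = FALSE]
  map <- map[!sexchr, , drop = FALSE]

  if (ncol(genotypes) == 0) warn("all markers removed by QC")
  report <- structure(list(
    initial = list(n_individuals = n0, n_markers = k0),
    removed = steps,
    final = list(n_individuals = nrow(genotypes), n_markers = ncol(genotypes)),
    thresholds = list(maf = maf, marker_missing = marker_missing,
                      indiv_missing = indiv_missing),
    notes = "imputation (if any) is naive expected-genotype rounding, see impute_naive()"
  ), class = "qc_report")
  list(genotypes = genotypes, map = map, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d x %d -> %d x %d\n",
              x$initial$n_individuals, x$initial$n_markers,
              x$final$n_individuals, x$final$n_markers))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed by %-15s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  }
  invisible(x)
}

#' Naive expected-genotype imputation
#'
#' Replaces each missing code by the marker's rounded expected code
#' `round(2 * p_hat)` where `p_hat` is the observed allele frequency.
#' Non-missing codes are never altered.  This is a deliberately simple
#' stand-in for haplotype-based imputation, suitable for the low missing
#' rates left after [apply_qc()].
#'
#' @param genotypes Integer matrix with possible `NA`s.
#' @return The matrix without missing values.
#' @export
impute_naive <- function(genotypes) {
  miss <- is.na(genotypes)
  if (!any(miss)) return(genotypes)
  all_missing <- colSums(!miss) == 0
  if (any(all_missing)) {
    abort(paste0("marker entirely missing (should have been filtered): ",
                 colnames(genotypes)[which(all_missing)[1]]))
  }
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  imp <- as.integer(round(2 * p))
  idx <- which(miss, arr.ind = TRUE)
  genotypes[idx] <- imp[idx[, 2]]
  genotypes
}

#' Assign markers to 1-Mb genomic windows
#'
#' Windows are consecutive megabase bins per chromosome: a marker at
#' 1-based position `pos` falls in window index `floor((pos - 1) / 1e6)`,
#' i.e. the bin covering `[mb * 1e6 + 1, (mb + 1) * 1e6]`.  Only
#' non-empty windows are returned.
#'
#' @param map Tibble with `marker`, `chrom`, `pos` (autosomes only).
#' @param size_bp Window size (default 1 Mb).
#' @return A list of two tibbles: `windows` (one row per non-empty
#'   window: `window`, `chrom`, `mb_index`, `n_markers`, `start`, `end` =
#'   min/max marker positions) and `markers` (`marker` -> `window`).
#' @export
build_windows <- function(map, size_bp = 1e6) {
  if (nrow(map) == 0) {
    return(list(
      windows = tibble(window = character(0), chrom = character(0),
                       mb_index = integer(0), n_markers = integer(0),
                       start = integer(0), end = integer(0)),
      markers = tibble(marker = character(0), window = character(0))
    ))
  }
  mb <- floor((map$pos - 1) / size_bp)
  wid <- paste0(map$chrom, "_", mb)
  markers <- tibble(marker = map$marker, window = wid)
  windows <- tibble(window = wid, chrom = as.character(map$chrom),
                    mb_index = as.integer(mb), pos = map$pos) |>
    group_by(.data$window, .data$chrom, .data$mb_index) |>
    summarise(n_markers = n(), start = min(.data$pos), end = max(.data$pos),
              .groups = "drop") |>
    arrange(.data$chrom, .data$mb_index)
  list(windows = windows, markers = markers)
}

#' Read and write PLINK text files and the 0/1/2 TSV dialect
#'
#' `read_plink()` reads `<prefix>.ped` / `<prefix>.map`; allele pairs are
#' converted to 0/1/2 counts of the `A` allele (`0 0` = missing).
#' `write_plink()` writes the reverse encoding.  `read_genotype_tsv()`
#' reads a plain matrix dialect: first column individual id, remaining
#' columns marker codes 0/1/2 (`NA` for missing), with a companion map
#' TSV (`marker`, `chrom`, `pos`).
#'
#' @param prefix Path prefix for `.ped`/`.map` files.
#' @param genotypes Matrix of 0/1/2 codes with dimnames.
#' @param map Marker map tibble.
#' @return `read_plink()` returns `list(genotypes, map)`.
#' @export
read_plink <- function(prefix) {
  map <- readr::read_tsv(paste0(prefix, ".map"),
                         col_names = c("chrom", "marker", "cm", "pos"),
                         col_types = "ccdi")
  lines <- readr::read_lines(paste0(prefix, ".ped"))
  parts <- strsplit(trimws(lines), "[ \t]+")
  k <- nrow(map)
  G <- matrix(NA_integer_, length(parts), k)
  ids <- character(length(parts))
  for (i in seq_along(parts)) {
    v <- parts[[i]]
    if (length(v) != 6 + 2 * k) {
      abort(sprintf("ped line %d has %d fields, expected %d",
                    i, length(v), 6 + 2 * k))
    }
    ids[i] <- v[2]
    al <- v[-(1:6)]
    a1 <- al[seq(1, 2 * k, by = 2)]
    a2 <- al[seq(2, 2 * k, by = 2)]
    g <- (a1 == "A") + (a2 == "A")
    g[a1 == "0" | a2 == "0"] <- NA_integer_
    G[i, ] <- g
  }
  dimnames(G) <- list(ids, map$marker)
  list(genotypes = G, map = map[, c("marker", "chrom", "pos")])
}

#' @rdname read_plink
#' @export
write_plink <- function(genotypes, map, prefix) {
  readr::write_tsv(
    tibble(chrom = map$chrom, marker = map$marker, cm = 0, pos = map$pos),
    paste0(prefix, ".map"), col_names = FALSE)
  code <- c(`0` = "B B", `1` = "A B", `2` = "A A")
  ids <- rownames(genotypes)
  lines <- vapply(seq_len(nrow(genotypes)), function(i) {
    g <- genotypes[i, ]
    al <- ifelse(is.na(g), "0 0", code[as.character(g)])
    paste(c(ids[i], ids[i], "0", "0", "0", "-9", al), collapse = " ")
  }, "")
  readr::write_lines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' @rdname read_plink
#' @param path,map_path Paths for the TSV matrix and map.
#' @export
read_genotype_tsv <- function(path, map_path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_integer(),
    id = readr::col_character()
  ))
  map <- readr::read_tsv(map_path, col_types = "cci")
  G <- as.matrix(g[, -1, drop = FALSE])
  rownames(G) <- g$id
  bad <- !(G %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) abort("genotype codes must be 0/1/2 or NA")
  list(genotypes = G, map = map)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report` from [apply_qc()].
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
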