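#' Manhattan-plot table
#'
#' One row per SNP with its chromosome, position, Bayes factor and the
#' percentage of genomic variance of its window, sorted by chromosome then
#' position.  The Bayes-factor threshold used for calling (10) is carried
#' as attribute `"bf_threshold"`.
#'
#' @param snp Per-SNP tibble (from `fit_mgwa()$snp`), with `marker`,
#'   `chrom`, `pos`, `bf`.
#' @param windows A [build_windows()] result.
#' @param window_tbl Window tibble with `pct_genomic_variance`.
#' @param trait Trait label carried in the table.
#' @param bf_threshold Threshold recorded in metadata (default 10).
#' @return A tibble `marker`, `chrom`, `pos`, `bf`,
#'   `pct_genomic_variance`, `trait`.
#' @export
manhattan_table <- function(snp, windows, window_tbl, trait = NA_character_,
                            bf_threshold = 10) {
  if (nrow(snp) == 0) {
    out <- tibble(marker = character(0), chrom = character(0),
                  pos = integer(0), bf = numeric(0),
                  pct_genomic_variance = numeric(0), trait = character(0))
    attr(out, "bf_threshold") <- bf_threshold
    return(out)
  }
  out <- snp |>
    left_join(windows$markers, by = "marker") |>
    left_join(window_tbl[, c("window", "pct_genomic_variance")],
              by = "window") |>
    mutate(trait = trait) |>
    select("marker", "chrom", "pos", "bf", "pct_genomic_variance", "trait") |>
    arrange(.data$chrom, .data$pos)
  attr(out, "bf_threshold") <- bf_threshold
  out
}

#' Merge runs of consecutive associated windows
#'
#' Adjacent (consecutive megabase index, same chromosome) associated
#' windows are merged into regions with the run's min start and max end.
#' Non-associated windows break runs.  Merging is idempotent.
#'
#' @param window_tbl Window tibble with `chrom`, `mb_index`, `start`,
#'   `end` and `associated` (e.g. from [call_associated_windows()]).
#'   Rows with `associated = FALSE` are ignored.
#' @return A tibble `chrom`, `start`, `end`, `n_windows`,
#'   `pct_genomic_variance` (sum over merged windows when present).
#' @export
merge_consecutive_windows <- function(window_tbl) {
  w <- window_tbl
  if ("associated" %in% names(w)) w <- w[w$associated, , drop = FALSE]
  if (nrow(w) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  n_windows = integer(0), pct_genomic_variance = numeric(0)))
  }
  w <- arrange(w, .data$chrom, .data$mb_index)
  run <- cumsum(c(1, diff(w$mb_index) != 1 |
                     w$chrom[-1] != w$chrom[-nrow(w)]))
  w |>
    mutate(run = run) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = n(),
              pct_genomic_variance = if ("pct_genomic_variance" %in% names(w))
                sum(.data$pct_genomic_variance) else NA_real_,
              .groups = "drop") |>
    select(-"run") |>
    arrange(.data$chrom, .data$start)
}

#' Read gene features from a GFF3 file
#'
#' Parses an Ensembl-style GFF3 and returns the gene features as a tibble
#' (1-based closed coordinates, as in the format).
#'
#' @param path GFF3 file path.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @return A tibble `gene_id`, `name`, `chrom`, `start`, `end`,
#'   `biotype`.
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature_type]
  md <- S4Vectors::mcols(gr)
  pick <- function(nm) if (nm %in% names(md)) as.character(md[[nm]])
                       else rep(NA_character_, length(gr))
  tibble(
    gene_id = dplyr::coalesce(pick("gene_id"), pick("ID")),
    name = dplyr::coalesce(pick("Name"), pick("gene_id"), pick("ID")),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    biotype = dplyr::coalesce(pick("biotype"), pick("gene_biotype"))
  )
}

#' Annotate associated regions with overlapping genes
#'
#' Intersects each region (1-based closed interval) with the gene set and
#' lists the overlapping genes.  Overlap is closed-coordinate interval
#' intersection, the GFF3 convention; a gene ending 1 bp before a region
#' starts does not overlap.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (e.g. from
#'   [merge_consecutive_windows()]); extra columns are carried through.
#' @param genes Gene tibble from [read_gff_genes()] (or equivalent with
#'   `gene_id`, `chrom`, `start`, `end`, optional `biotype`).
#' @param protein_coding_only Keep only `biotype == "protein_coding"`.
#' @return `regions` with list-column `genes` (gene ids), `n_genes`, and
#'   a collapsed `gene_list` string.
#' @export
annotate_windows <- function(regions, genes, protein_coding_only = FALSE) {
  if (protein_coding_only && "biotype" %in% names(genes)) {
    genes <- genes[!is.na(genes$biotype) & genes$biotype == "protein_coding", ]
  }
  if (nrow(regions) == 0) {
    regions$genes <- list()
    regions$n_genes <- integer(0)
    regions$gene_list <- character(0)
    return(regions)
  }
  rgr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start, regions$end))
  ggr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(rgr, ggr)
  gl <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) gl[[i]] <- character(0)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (h in seq_along(qh)) {
    gl[[qh[h]]] <- c(gl[[qh[h]]], genes$gene_id[sh[h]])
  }
  regions$genes <- gl
  regions$n_genes <- lengths(gl)
  regions$gene_list <- vapply(gl, paste, "", collapse = ", ")
  regions
}

#' Write the association summary tables
#'
#' Writes the associated-window table (region, trait, percent variance,
#' relevant SNP counts), the annotated-region table and the Manhattan
#' table as TSV files.
#'
#' @param window_tbl Window tibble from [call_associated_windows()].
#' @param regions Annotated regions from [annotate_windows()] (optional).
#' @param manhattan Manhattan table (optional).
#' @param dir Output directory.
#' @export
write_report_tables <- function(window_tbl, regions = NULL, manhattan = NULL,
                                dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(window_tbl[window_tbl$associated, , drop = FALSE],
                   file.path(dir, "associated_windows.tsv"))
  if (!is.null(regions)) {
    readr::write_tsv(select(regions, -dplyr::any_of("genes")),
                     file.path(dir, "annotated_regions.tsv"))
  }
  if (!is.null(manhattan)) {
    readr::write_tsv(manhattan, file.path(dir, "manhattan.tsv"))
  }
  invisible(dir)
}
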