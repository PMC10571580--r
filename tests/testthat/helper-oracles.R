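# Independent oracles used across tests.  These deliberately avoid the
# package's own algorithms: kinship by naive recursion with memoisation,
# HPD by all-pairs search, interval overlap by O(n*m) enumeration.

# additive relationship by direct recursion on a parents-first pedigree
oracle_kinship_A <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      a <- 0
      if (si[i] > 0) a <- a + 0.5 * A[j, si[i]]
      if (di[i] > 0) a <- a + 0.5 * A[j, di[i]]
      A[i, j] <- A[j, i] <- a
    }
    A[i, i] <- 1 + 0.5 * (if (si[i] > 0 && di[i] > 0) A[si[i], di[i]] else 0)
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

# random valid pedigree: animals pick parents among earlier animals
random_pedigree <- function(n, p_known = 0.7, seed = 1) {
  set.seed(seed)
  animal <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (stats::runif(1) < p_known) sire[i] <- animal[sample.int(i - 1, 1)]
    if (stats::runif(1) < p_known) dam[i] <- animal[sample.int(i - 1, 1)]
  }
  data.frame(animal = animal, sire = sire, dam = dam)
}

# shortest interval covering >= ceiling(p*n) draws, by all-pairs search
oracle_hpd <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(prob * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i + 1 >= k && (x[j] - x[i]) < (best[2] - best[1])) {
        best <- c(x[i], x[j])
      }
    }
  }
  best
}

# closed-coordinate interval overlap by enumeration
oracle_overlap <- function(regions, genes) {
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hits <- character(0)
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] == regions$chrom[i] &&
          genes$start[g] <= regions$end[i] &&
          genes$end[g] >= regions$start[i]) {
        hits <- c(hits, genes$gene_id[g])
      }
    }
    out[[i]] <- hits
  }
  out
}
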