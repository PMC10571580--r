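#' Validate and sort a pedigree
#'
#' Takes a raw pedigree table (one row per animal with its sire and dam) and
#' returns a validated, parents-first ordered pedigree.  Unknown parents are
#' coded `"0"`, `""` or `NA` and treated as unrelated, non-inbred founders.
#' Animals that appear only as a sire or dam of another animal are inserted
#' as founder records, as real pedigree files routinely omit them.
#'
#' @param ped A data frame with columns `animal`, `sire`, `dam` and
#'   optionally `generation` (integer) and `line` (character).  All ids are
#'   coerced to character.
#' @return A tibble of class `"pedigree"` with columns `animal`, `sire`,
#'   `dam`, `generation`, `line`, ordered so every parent precedes its
#'   offspring.  `sire`/`dam` are `NA` for unknown parents.
#' @examples
#' ped <- data.frame(animal = c("o", "s", "d"),
#'                   sire   = c("s", NA, NA),
#'                   dam    = c("d", NA, NA))
#' as_pedigree(ped)
#' @export
as_pedigree <- function(ped) {
  if (inherits(ped, "pedigree")) return(ped)
  ped <- as_tibble(ped)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped))) {
    abort(paste("pedigree must have columns:", paste(need, collapse = ", ")))
  }
  norm_id <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
    x
  }
  ped$animal <- as.character(ped$animal)
  ped$sire <- norm_id(ped$sire)
  ped$dam <- norm_id(ped$dam)
  if (anyNA(ped$animal) || any(ped$animal == "0" | ped$animal == "")) {
    abort("animal ids must be non-missing and not '0'")
  }
  if (anyDuplicated(ped$animal)) {
    abort(paste0("duplicate animal id: ",
                 ped$animal[duplicated(ped$animal)][1]))
  }
  if (!"generation" %in% names(ped)) ped$generation <- NA_integer_
  if (!"line" %in% names(ped)) ped$line <- NA_character_
  ped$generation <- as.integer(ped$generation)
  ped$line <- as.character(ped$line)
  ped <- ped[, c("animal", "sire", "dam", "generation", "line")]

  # auto-insert parents that never appear as animals, as founders
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(parents)) {
    ped <- bind_rows(
      tibble(animal = parents, sire = NA_character_, dam = NA_character_,
             generation = NA_integer_, line = NA_character_),
      ped
    )
  }

  # Kahn-style topological sort (parents first), stable for founders
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  if (any(si == seq_len(n), na.rm = TRUE) || any(di == seq_len(n), na.rm = TRUE)) {
    bad <- ped$animal[which(si == seq_len(n) | di == seq_len(n))[1]]
    abort(paste0("pedigree cycle detected at animal: ", bad))
  }
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  # stable Kahn: always emit the lowest-index available animal, so an
  # already valid parents-first ordering is returned unchanged
  order_out <- integer(0)
  avail <- indeg == 0L
  for (step in seq_len(n)) {
    i <- which(avail)[1]
    if (is.na(i)) break
    avail[i] <- FALSE
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail[ch] <- TRUE
    }
  }
  if (length(order_out) < n) {
    bad <- ped$animal[setdiff(seq_len(n), order_out)[1]]
    abort(paste0("pedigree cycle detected at animal: ", bad))
  }
  out <- ped[order_out, ]
  class(out) <- c("pedigree", class(out))
  out
}

#' @rdname as_pedigree
#' @export
sort_and_validate <- as_pedigree

#' Read a pedigree CSV
#'
#' Reads a pedigree file with columns `animal,sire,dam[,generation][,line]`;
#' `"0"` or an empty field marks an unknown parent.
#'
#' @param path Path to a CSV file.
#' @return A validated [as_pedigree()] tibble.
#' @export
read_pedigree <- function(path) {
  as_pedigree(readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  )))
}

# 1-based parent index vectors (0 = unknown) for a validated pedigree
ped_indices <- function(ped) {
  idx <- setNames(seq_len(nrow(ped)), ped$animal)
  list(
    sire = ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire])),
    dam  = ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam]))
  )
}

#' Inbreeding coefficients
#'
#' Computes the inbreeding coefficient F for every animal using the
#' Meuwissen and Luo (1992) recursion.  Founders (and animals with an
#' unknown parent) have F = 0; otherwise F equals half the additive
#' relationship between the parents.
#'
#' @param ped A pedigree accepted by [as_pedigree()].
#' @return A tibble with columns `animal` and `F`.
#' @export
inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  pi <- ped_indices(ped)
  tibble(animal = ped$animal, F = .inbreeding_cpp(pi$sire, pi$dam))
}

#' Additive relationship matrix A
#'
#' Builds the dense numerator relationship matrix by the tabular method:
#' for j earlier than i, `a(i,j) = 0.5 (a(j, sire_i) + a(j, dam_i))` and
#' `a(i,i) = 1 + 0.5 a(sire_i, dam_i)`, with unknown parents contributing 0.
#'
#' @param ped A pedigree accepted by [as_pedigree()].
#' @return A symmetric dense matrix with dimnames equal to the animal ids,
#'   in pedigree order.  Intended for pedigrees up to a few thousand
#'   animals; use [relationship_inverse()] for model fitting.
#' @export
relationship_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  if (nrow(ped) > 5000) {
    warn("dense A for > 5000 animals is large; consider relationship_inverse()")
  }
  pi <- ped_indices(ped)
  A <- .tabular_A_cpp(pi$sire, pi$dam)
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' @rdname relationship_matrix
#' @export
build_A <- relationship_matrix

#' Sparse inverse of the additive relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules, accounting for
#' inbreeding: each animal contributes `alpha = 1/d` to the diagonal, where
#' `d` is its Mendelian-sampling variance given the parents' inbreeding
#' (`d = 0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one, 1 for founders), plus the usual
#' `-alpha/2` parent-offspring and `alpha/4` parent-parent terms.
#'
#' @param ped A pedigree accepted by [as_pedigree()].
#' @return A sparse symmetric [Matrix::dsCMatrix-class] with animal-id
#'   dimnames, equal to the inverse of [relationship_matrix()].
#' @export
relationship_inverse <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  pi <- ped_indices(ped)
  Fv <- .inbreeding_cpp(pi$sire, pi$dam)
  s <- pi$sire; d <- pi$dam
  fs <- ifelse(s > 0, Fv[pmax(s, 1L)], 0)
  fd <- ifelse(d > 0, Fv[pmax(d, 1L)], 0)
  dvar <- ifelse(s > 0 & d > 0, 0.5 - 0.25 * (fs + fd),
          ifelse(s > 0, 0.75 - 0.25 * fs,
          ifelse(d > 0, 0.75 - 0.25 * fd, 1)))
  alpha <- 1 / dvar

  ii <- seq_len(n)
  tri_i <- ii; tri_j <- ii; tri_x <- alpha
  add <- function(i, j, x) {
    tri_i <<- c(tri_i, i); tri_j <<- c(tri_j, j); tri_x <<- c(tri_x, x)
  }
  ks <- which(s > 0)
  if (length(ks)) {
    add(ks, s[ks], -alpha[ks] / 2); add(s[ks], ks, -alpha[ks] / 2)
    add(s[ks], s[ks], alpha[ks] / 4)
  }
  kd <- which(d > 0)
  if (length(kd)) {
    add(kd, d[kd], -alpha[kd] / 2); add(d[kd], kd, -alpha[kd] / 2)
    add(d[kd], d[kd], alpha[kd] / 4)
  }
  kb <- which(s > 0 & d > 0)
  if (length(kb)) {
    add(s[kb], d[kb], alpha[kb] / 4); add(d[kb], s[kb], alpha[kb] / 4)
  }
  Ainv <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                               dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' @rdname relationship_inverse
#' @export
build_A_inverse <- relationship_inverse

#' Export a matrix in coordinate (i, j, value) format
#'
#' Writes the non-zero entries of a dense or sparse matrix as a TSV with
#' columns `i`, `j`, `value` (1-based indices, pedigree order).
#'
#' @param m A matrix or Matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_coo <- function(m, path) {
  tm <- as(as(m, "generalMatrix"), "TsparseMatrix")
  keep <- tm@x != 0
  readr::write_tsv(
    tibble(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L, value = tm@x[keep]),
    path
  )
  invisible(path)
}
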