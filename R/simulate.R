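#' Configuration for the synthetic maternal-effects dataset
#'
#' Describes a divergent-selection breeding design and the generating
#' parameters of the maternal animal model.  Defaults emulate the rabbit
#' design the package targets: a base population of 13 sires and 83 dams,
#' two lines of 8 sires and 40 dams per generation, litters around 8 kits,
#' and divergent selection on the first trait based on the mean phenotype
#' of two scored offspring per dam with the top (resp. bottom) 20% of dams
#' retained.
#'
#' Variance units are on the scale of the trait; with the default
#' single-trait parameters the total phenotypic variance is 1 and the
#' generating ratios are `h2d = 0.45`, `h2m = 0.09`, `c2 = 0.14` with a
#' direct-maternal genetic correlation of `-0.02` (the phenotypic variance
#' includes the direct-maternal covariance term once).
#'
#' @param n_generations Number of selected generations after the base.
#' @param base_sires,base_dams Size of the unrelated base population.
#' @param sires_per_gen,dams_per_gen Parents per line per generation.
#' @param n_lines Number of lines (2 = divergent High/Low).
#' @param litter_size List with `mean` and `min`; sizes are
#'   `min + Poisson(mean - min)` (a constant litter when `min == mean`).
#' @param n_parities Litters per dam (litter = dam x parity).
#' @param traits Character vector of 1 or 2 trait names.
#' @param trait_means Numeric vector of trait means.
#' @param G0_true Genetic covariance of (direct, maternal) effects; a
#'   `2t x 2t` matrix ordered (direct trait 1..t, maternal trait 1..t).
#' @param c2 Per-trait common-litter variances (or a `t x t` covariance
#'   matrix); `NULL` for no litter effect.
#' @param me2 Per-trait maternal-environment variances (or matrix); `NULL`
#'   for none.
#' @param R0_true Residual covariance (`t x t`).
#' @param fixed_effects Named list of per-level effect values.  The names
#'   `sex` and `parity` are bound to the record's own sex and parity; any
#'   other factor is assigned uniformly at random.  The first level of each
#'   factor acts as the reference (effect usually 0).
#' @param selection `"none"` or `"divergent"` (divergent truncation
#'   selection on trait 1: High line keeps top 20% of dams, Low line the
#'   bottom 20%).
#' @param phenotype_base Score the base population too (as the motivating
#'   study did).  Each base animal gets a phantom founder dam in the
#'   pedigree — the standard device for records with unknown parents — so
#'   its maternal genetic effect is defined; base records then provide the
#'   granddam-offspring contrasts that identify the direct-maternal
#'   covariance.
#' @param seed Optional integer seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_generations = 2,
                       base_sires = 13, base_dams = 83,
                       sires_per_gen = 8, dams_per_gen = 40,
                       n_lines = 2,
                       litter_size = list(mean = 8, min = 1),
                       n_parities = 1,
                       traits = "IMF",
                       trait_means = rep(0, length(traits)),
                       G0_true = NULL,
                       c2 = NULL,
                       me2 = NULL,
                       R0_true = NULL,
                       fixed_effects = list(
                         sex = c(0, 0.05),
                         month = c(0, 0.02, -0.02, 0.04, -0.04)
                       ),
                       selection = c("none", "divergent"),
                       phenotype_base = FALSE,
                       seed = NULL) {
  selection <- match.arg(selection)
  t <- length(traits)
  if (!t %in% 1:2) abort("traits must have length 1 or 2")
  if (is.null(G0_true)) {
    if (t == 1) {
      sdm <- -0.02 * sqrt(0.45 * 0.09)
      G0_true <- matrix(c(0.45, sdm, sdm, 0.09), 2, 2)
      if (is.null(c2)) c2 <- 0.14
      if (is.null(R0_true)) R0_true <- matrix(1 - 0.45 - 0.09 - 0.14 - sdm)
    } else {
      abort("G0_true must be supplied for bivariate configs")
    }
  }
  G0_true <- as.matrix(G0_true)
  if (!isTRUE(all.equal(dim(G0_true), c(2L * t, 2L * t)))) {
    abort("G0_true must be 2t x 2t with traits of length t")
  }
  as_cov <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) m <- x else m <- diag(x, nrow = t)
    if (!all(dim(m) == c(t, t))) abort(paste(what, "must be length-t or t x t"))
    m
  }
  Cc <- as_cov(c2, "c2")
  Cme <- as_cov(me2, "me2")
  if (is.null(R0_true)) abort("R0_true must be supplied")
  R0_true <- as.matrix(R0_true)
  for (nm in list(list(G0_true, "G0_true"), list(Cc, "c2"),
                  list(Cme, "me2"), list(R0_true, "R0_true"))) {
    m <- nm[[1]]
    if (is.null(m)) next
    if (!isSymmetric(unname(m), tol = 1e-8)) abort(paste(nm[[2]], "must be symmetric"))
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort(paste(nm[[2]], "must be positive semi-definite"))
    }
  }
  if (litter_size$mean < 1 || litter_size$min < 1) abort("litter size must be >= 1")
  if (dams_per_gen < sires_per_gen) abort("need at least one dam per sire")
  structure(list(
    n_generations = n_generations, base_sires = base_sires,
    base_dams = base_dams, sires_per_gen = sires_per_gen,
    dams_per_gen = dams_per_gen, n_lines = n_lines,
    litter_size = litter_size, n_parities = n_parities,
    traits = traits, trait_means = trait_means,
    G0_true = G0_true, Cc = Cc, Cme = Cme, R0_true = R0_true,
    fixed_effects = fixed_effects, selection = selection,
    phenotype_base = phenotype_base, seed = seed
  ), class = "sim_config")
}

# symmetric square root for (possibly singular) PSD covariance draws
mvn_draw <- function(n, Sigma) {
  Sigma <- as.matrix(Sigma)
  p <- ncol(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, p))
  ev <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  z <- matrix(rnorm(n * p), n, p)
  z %*% (ev$vectors %*% (sqrt(lam) * t(ev$vectors)))
}

# Mendelian-sampling variance multipliers given parent inbreeding
mend_k <- function(Fs, Fd, has_s, has_d) {
  ifelse(has_s & has_d, 0.5 - 0.25 * (Fs + Fd),
  ifelse(has_s, 0.75 - 0.25 * Fs,
  ifelse(has_d, 0.75 - 0.25 * Fd, 1)))
}

#' Simulate breeding values along a pedigree
#'
#' Draws joint (direct, maternal) breeding values so that the vector of all
#' effects has covariance `A` (the additive relationship matrix) Kronecker
#' `G0_true`.  Founders are drawn from `N(0, G0_true)`; each non-founder is
#' the parent average plus a Mendelian-sampling deviation with covariance
#' `k * G0_true`, `k = 0.5 (1 - (F_s + F_d)/2)` (reduced accordingly for
#' unknown parents).
#'
#' @param ped A pedigree accepted by [as_pedigree()].
#' @param G0_true Covariance of the stacked effects, ordered (direct trait
#'   1..t, maternal trait 1..t); `2 x 2` for one trait.
#' @param traits Trait names (length t); default infers t from `G0_true`.
#' @param seed Optional seed.
#' @return A tibble with column `animal` and one `a_d_<trait>` and
#'   `a_m_<trait>` column per trait, in pedigree order.
#' @export
simulate_breeding_values <- function(ped, G0_true, traits = NULL, seed = NULL) {
  ped <- as_pedigree(ped)
  if (!is.null(seed)) set.seed(seed)
  G0_true <- as.matrix(G0_true)
  if (min(eigen(G0_true, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("G0_true must be positive semi-definite")
  }
  m <- ncol(G0_true)
  if (m %% 2 != 0) abort("G0_true must be 2t x 2t")
  t <- m / 2
  if (is.null(traits)) traits <- paste0("t", seq_len(t))
  pi <- ped_indices(ped)
  Fv <- .inbreeding_cpp(pi$sire, pi$dam)
  n <- nrow(ped)
  bv <- matrix(0, n, m)
  founder <- pi$sire == 0 & pi$dam == 0
  bv[founder, ] <- mvn_draw(sum(founder), G0_true)
  for (i in which(!founder)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    pa <- numeric(m)
    if (s > 0) pa <- pa + 0.5 * bv[s, ]
    if (d > 0) pa <- pa + 0.5 * bv[d, ]
    k <- mend_k(if (s > 0) Fv[s] else 0, if (d > 0) Fv[d] else 0, s > 0, d > 0)
    bv[i, ] <- pa + drop(mvn_draw(1, k * G0_true))
  }
  out <- tibble(animal = ped$animal)
  for (j in seq_len(t)) out[[paste0("a_d_", traits[j])]] <- bv[, j]
  for (j in seq_len(t)) out[[paste0("a_m_", traits[j])]] <- bv[, t + j]
  out
}

# Draw phenotypes for a set of offspring records, reusing/creating litter,
# maternal-environment effects held in environments keyed by id.
# records: tibble with animal, dam, litter, sex, parity; bv: matrix rows
# aligned with ped order; returns list(phen, litter_new, me_new, resid)
compose_phenotypes <- function(records, ped, bv, cfg, lit_env, me_env) {
  t <- length(cfg$traits)
  n <- nrow(records)
  idx <- match(records$animal, ped$animal)
  dam_idx <- match(records$dam, ped$animal)
  if (anyNA(dam_idx)) {
    abort(paste0("record with dam absent from pedigree: ",
                 records$animal[which(is.na(dam_idx))[1]]))
  }
  y <- matrix(rep(cfg$trait_means, each = n), n, t)
  # direct (own) + maternal (dam's) genetic effects
  y <- y + bv[idx, seq_len(t), drop = FALSE] +
    bv[dam_idx, t + seq_len(t), drop = FALSE]

  phen <- records
  # fixed effects
  for (nm in names(cfg$fixed_effects)) {
    eff <- cfg$fixed_effects[[nm]]
    lev <- switch(nm,
      sex = match(records$sex, c("M", "F")),
      parity = pmin(records$parity, length(eff)),
      sample.int(length(eff), n, replace = TRUE)
    )
    if (!nm %in% c("sex", "parity")) phen[[nm]] <- lev
    y <- y + eff[lev]
  }
  # common litter effects
  if (!is.null(cfg$Cc)) {
    new_l <- setdiff(unique(records$litter), ls(lit_env))
    for (l in new_l) assign(l, drop(mvn_draw(1, cfg$Cc)), envir = lit_env)
    ce <- do.call(rbind, lapply(records$litter, get, envir = lit_env))
    y <- y + ce
  }
  # maternal environment effects
  if (!is.null(cfg$Cme)) {
    new_d <- setdiff(unique(records$dam), ls(me_env))
    for (d in new_d) assign(d, drop(mvn_draw(1, cfg$Cme)), envir = me_env)
    mee <- do.call(rbind, lapply(records$dam, get, envir = me_env))
    y <- y + mee
  }
  e <- mvn_draw(n, cfg$R0_true)
  y <- y + e
  for (j in seq_len(t)) phen[[cfg$traits[j]]] <- y[, j]
  resid <- tibble(animal = records$animal)
  for (j in seq_len(t)) resid[[paste0("e_", cfg$traits[j])]] <- e[, j]
  list(phen = phen, resid = resid)
}

#' Simulate a full maternal-effects dataset
#'
#' Runs the breeding design described by a [sim_config()]: an unrelated
#' base population, then `n_generations` of within-line matings (each sire
#' bred to `dams_per_gen / sires_per_gen` dams, litters of Poisson size),
#' with joint direct/maternal breeding values propagated by
#' Mendelian sampling, common-litter and (optionally) maternal-environment
#' effects, fixed effects, and correlated residuals.  Under
#' `selection = "divergent"` each dam is scored by the mean trait-1
#' phenotype of two of her first-parity offspring (one male, one female
#' where available) and the High (Low) line draws its next-generation dams
#' from the daughters of the top (bottom) 20% of scored dams.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_dataset"` with elements `pedigree`,
#'   `phenotypes` (one row per non-founder, all scored), `genotypes`
#'   (`NULL` until [simulate_genotypes()] is attached), `map`, and `truth`
#'   (breeding values, litter and maternal-environment effects, residuals,
#'   dam selection scores, QTL table), plus the `config`.
#' @export
sim_maternal_dataset <- function(config) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) abort("config must come from sim_config()")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  t <- length(cfg$traits)
  m <- 2L * t
  lines <- if (cfg$n_lines == 2) c("H", "L") else paste0("L", seq_len(cfg$n_lines))

  nb <- cfg$base_sires + cfg$base_dams
  base_ids <- sprintf("B%04d", seq_len(nb))
  base_sex <- c(rep("M", cfg$base_sires), rep("F", cfg$base_dams))
  lit_env <- new.env(); me_env <- new.env()
  phen_all <- list(); resid_all <- list(); scores_all <- list()

  if (cfg$phenotype_base) {
    # phantom founder dams give base records a defined maternal effect
    phantom <- sprintf("P%04d", seq_len(nb))
    ped <- bind_rows(
      tibble(animal = phantom, sire = NA_character_, dam = NA_character_,
             generation = 0L, line = NA_character_),
      tibble(animal = base_ids, sire = NA_character_, dam = phantom,
             generation = 0L, line = NA_character_)
    )
    sex <- c(rep("F", nb), base_sex)
    bv_ph <- mvn_draw(nb, cfg$G0_true)
    bv_base <- 0.5 * bv_ph + mvn_draw(nb, 0.75 * cfg$G0_true)
    bv <- rbind(bv_ph, bv_base)
    base_records <- tibble(
      animal = base_ids, sire = NA_character_, dam = phantom,
      generation = 0L, line = NA_character_, sex = base_sex, parity = 1L,
      litter = paste0(phantom, "_p1")
    )
    cp0 <- compose_phenotypes(base_records, ped, bv, cfg, lit_env, me_env)
    phen_all[["base"]] <- cp0$phen
    resid_all[["base"]] <- cp0$resid
  } else {
    ped <- tibble(
      animal = base_ids,
      sire = NA_character_, dam = NA_character_,
      generation = 0L, line = NA_character_
    )
    sex <- base_sex
    bv <- mvn_draw(nrow(ped), cfg$G0_true)
  }

  base_dam_ids <- base_ids[base_sex == "F"]
  base_sire_ids <- base_ids[base_sex == "M"]
  shuffled <- sample(base_dam_ids)
  pools <- list()
  for (li in seq_along(lines)) {
    take <- shuffled[seq_len(min(cfg$dams_per_gen, length(shuffled)))]
    shuffled <- setdiff(shuffled, take)
    if (length(take) < cfg$dams_per_gen) {
      take <- c(take, sample(base_dam_ids, cfg$dams_per_gen - length(take),
                             replace = TRUE))
    }
    pools[[lines[li]]] <- list(
      sires = sample(base_sire_ids, cfg$sires_per_gen,
                     replace = cfg$sires_per_gen > length(base_sire_ids)),
      dams = take
    )
  }

  counter <- 0L
  for (g in seq_len(cfg$n_generations)) {
    Fv <- .inbreeding_cpp(ped_indices(ped)$sire, ped_indices(ped)$dam)
    gen_records <- list()
    for (ln in lines) {
      sires <- pools[[ln]]$sires
      dams <- pools[[ln]]$dams
      # round-robin sire assignment, rotated across parities so repeat
      # litters of a dam have different sires (within-dam half-sib
      # families, which helps separate direct from dam-level effects)
      for (k in seq_along(dams)) {
        for (par in seq_len(cfg$n_parities)) {
          sire_k <- sires[((k - 1L + (par - 1L)) %% length(sires)) + 1L]
          # litter size = min + Poisson(mean - min); constant when min == mean
          size <- cfg$litter_size$min +
            rpois(1, max(0, cfg$litter_size$mean - cfg$litter_size$min))
          counter <- counter + size
          ids <- sprintf("G%d%s%05d", g, ln, (counter - size + 1):counter)
          gen_records[[length(gen_records) + 1L]] <- tibble(
            animal = ids, sire = sire_k, dam = dams[k],
            generation = g, line = ln,
            sex = sample(c("M", "F"), size, replace = TRUE),
            parity = par,
            litter = paste0(dams[k], "_p", par)
          )
        }
      }
    }
    gen_records <- bind_rows(gen_records)

    # extend pedigree and breeding values
    new_ped <- gen_records[, c("animal", "sire", "dam", "generation", "line")]
    si <- match(gen_records$sire, ped$animal)
    di <- match(gen_records$dam, ped$animal)
    kvec <- mend_k(Fv[si], Fv[di], TRUE, TRUE)
    w <- mvn_draw(nrow(gen_records), cfg$G0_true) * sqrt(kvec)
    bv_new <- 0.5 * (bv[si, , drop = FALSE] + bv[di, , drop = FALSE]) + w
    ped <- bind_rows(ped, new_ped)
    sex <- c(sex, gen_records$sex)
    bv <- rbind(bv, bv_new)

    cp <- compose_phenotypes(gen_records, ped, bv, cfg, lit_env, me_env)
    phen_all[[paste0("g", g)]] <- cp$phen
    resid_all[[paste0("g", g)]] <- cp$resid

    # dam scoring: two first-parity offspring (one M, one F if possible)
    ph <- cp$phen
    first <- ph[ph$parity == 1L, ]
    sc <- first |>
      group_by(.data$line, .data$dam) |>
      summarise(score = {
        ms <- .data[[cfg$traits[1]]][.data$sex == "M"]
        fs <- .data[[cfg$traits[1]]][.data$sex == "F"]
        picks <- c(if (length(ms)) ms[1] else NULL,
                   if (length(fs)) fs[1] else NULL)
        if (length(picks) < 2) picks <- .data[[cfg$traits[1]]][seq_len(min(2, n()))]
        mean(picks)
      }, .groups = "drop") |>
      mutate(generation = g)
    sel_list <- list()
    for (ln in lines) {
      s_ln <- sc[sc$line == ln, ]
      ntop <- max(1L, ceiling(0.2 * nrow(s_ln)))
      ord <- order(s_ln$score,
                   decreasing = !(cfg$selection == "divergent" && ln == "L"))
      s_ln$selected <- cfg$selection == "divergent" &
        seq_len(nrow(s_ln)) %in% ord[seq_len(ntop)]
      s_ln$sel_rank <- match(seq_len(nrow(s_ln)), ord)
      sel_list[[ln]] <- s_ln
    }
    sc <- bind_rows(sel_list)
    scores_all[[paste0("g", g)]] <- sc

    # next-generation parent pools
    if (g < cfg$n_generations) {
      for (ln in lines) {
        off <- gen_records[gen_records$line == ln, ]
        s_ln <- sc[sc$line == ln, ]
        if (cfg$selection == "divergent") {
          ranked_dams <- s_ln$dam[order(s_ln$sel_rank)]
        } else {
          ranked_dams <- sample(s_ln$dam)
        }
        females <- character(0); need <- cfg$dams_per_gen; di2 <- 1L
        while (length(females) < need && di2 <= length(ranked_dams)) {
          females <- c(females,
                       off$animal[off$dam == ranked_dams[di2] & off$sex == "F"])
          di2 <- di2 + 1L
        }
        if (length(females) < need) {
          abort("infeasible design: not enough female offspring for next generation")
        }
        next_dams <- females[seq_len(need)]
        # one male per sire family where possible
        males <- off[off$sex == "M", ]
        split_m <- split(males$animal, males$sire)
        cand <- vapply(split_m, function(x) x[sample.int(length(x), 1)], "")
        if (length(cand) < cfg$sires_per_gen) {
          extra <- setdiff(males$animal, cand)
          cand <- c(cand, sample(extra, cfg$sires_per_gen - length(cand)))
        }
        pools[[ln]] <- list(sires = unname(sample(cand, cfg$sires_per_gen)),
                            dams = next_dams)
      }
    }
  }

  construction_ids <- ped$animal # bv rows are in construction order
  ped <- as_pedigree(ped)
  bv_tbl <- tibble(animal = construction_ids)
  for (j in seq_len(t)) bv_tbl[[paste0("a_d_", cfg$traits[j])]] <- bv[, j]
  for (j in seq_len(t)) bv_tbl[[paste0("a_m_", cfg$traits[j])]] <- bv[, t + j]
  lit_ids <- ls(lit_env)
  lit_tbl <- tibble(litter = lit_ids)
  if (length(lit_ids)) {
    lm_ <- do.call(rbind, lapply(lit_ids, get, envir = lit_env))
    for (j in seq_len(t)) lit_tbl[[paste0("c_", cfg$traits[j])]] <- lm_[, j]
  }
  me_ids <- ls(me_env)
  me_tbl <- tibble(dam = me_ids)
  if (length(me_ids)) {
    mm_ <- do.call(rbind, lapply(me_ids, get, envir = me_env))
    for (j in seq_len(t)) me_tbl[[paste0("me_", cfg$traits[j])]] <- mm_[, j]
  }

  structure(list(
    pedigree = ped,
    phenotypes = bind_rows(phen_all),
    genotypes = NULL, map = NULL,
    truth = list(
      breeding_values = bv_tbl,
      litter_effects = lit_tbl,
      maternal_env_effects = me_tbl,
      residuals = bind_rows(resid_all),
      dam_scores = bind_rows(scores_all),
      qtl = NULL
    ),
    config = cfg
  ), class = "sim_dataset")
}

#' @rdname sim_maternal_dataset
#' @description `simulate_pedigree()` runs the same engine and returns only
#'   the pedigree, with the dam selection scores attached as attribute
#'   `"dam_scores"`.
#' @export
simulate_pedigree <- function(config) {
  ds <- sim_maternal_dataset(config)
  structure(ds$pedigree, dam_scores = ds$truth$dam_scores)
}

#' Simulate phenotypes for an existing pedigree and breeding values
#'
#' Composes phenotypes `y = mean + fixed effects + a_d(animal) +
#' a_m(dam) + c(litter) [+ me(dam)] + e` for every animal whose dam is in
#' the pedigree.  Litter is taken as dam x parity with a single parity;
#' sexes are assigned at random when not supplied.
#'
#' @param ped A pedigree accepted by [as_pedigree()].
#' @param truth A breeding-value table from [simulate_breeding_values()]
#'   (columns `animal`, `a_d_*`, `a_m_*`).
#' @param config A [sim_config()] supplying the variance components, fixed
#'   effects and trait names.
#' @return A phenotype tibble (one row per animal with a known dam).
#' @export
simulate_phenotypes <- function(ped, truth, config) {
  ped <- as_pedigree(ped)
  cfg <- config
  t <- length(cfg$traits)
  bv <- as.matrix(truth[, c(paste0("a_d_", cfg$traits),
                            paste0("a_m_", cfg$traits))])
  keep <- !is.na(ped$dam)
  if (!any(keep)) abort("no animal has a known dam; nothing to phenotype")
  records <- tibble(
    animal = ped$animal[keep], sire = ped$sire[keep], dam = ped$dam[keep],
    generation = ped$generation[keep], line = ped$line[keep],
    sex = sample(c("M", "F"), sum(keep), replace = TRUE),
    parity = 1L,
    litter = paste0(ped$dam[keep], "_p1")
  )
  cp <- compose_phenotypes(records, ped, bv, cfg,
                           lit_env = new.env(), me_env = new.env())
  cp$phen
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder genotypes are drawn as Binomial(2, p_j) with allele frequencies
#' uniform on `maf_range`; each non-founder receives one allele from each
#' parent (a heterozygous parent transmits either allele with probability
#' 1/2; an unknown parent side is drawn from the founder frequency).  Map
#' positions are uniform along each autosome.  Markers are in linkage
#' equilibrium (no recombination map), which keeps window-variance
#' expectations analytic.
#'
#' @param ped A pedigree accepted by [as_pedigree()].
#' @param n_snps Total marker count (split evenly across chromosomes).
#' @param n_chrom Number of autosomes (default 21).
#' @param maf_range Allele-frequency range, within (0, 0.5].
#' @param chrom_length_bp Length of each simulated autosome.
#' @param seed Optional seed.
#' @return A list with `genotypes` (integer matrix, animals x markers,
#'   dimnames set) and `map` (tibble `marker`, `chrom`, `pos`).
#' @export
simulate_genotypes <- function(ped, n_snps, n_chrom = 21,
                               maf_range = c(0.05, 0.5),
                               chrom_length_bp = 5e7, seed = NULL) {
  ped <- as_pedigree(ped)
  if (!is.null(seed)) set.seed(seed)
  if (n_chrom < 1) abort("n_chrom must be >= 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("maf_range must lie in (0, 0.5]")
  }
  n <- nrow(ped)
  if (n_snps == 0) {
    return(list(
      genotypes = matrix(integer(0), n, 0, dimnames = list(ped$animal, NULL)),
      map = tibble(marker = character(0), chrom = character(0),
                   pos = integer(0))
    ))
  }
  per <- diff(round(seq(0, n_snps, length.out = n_chrom + 1)))
  chrom <- rep(seq_len(n_chrom), per)
  pos <- unlist(lapply(per, function(k) sort(sample.int(chrom_length_bp, k))))
  map <- tibble(marker = sprintf("snp%06d", seq_len(n_snps)),
                chrom = as.character(chrom), pos = as.integer(pos))
  p <- runif(n_snps, maf_range[1], maf_range[2])
  pi_ <- ped_indices(ped)
  G <- matrix(0L, n, n_snps, dimnames = list(ped$animal, map$marker))
  for (i in seq_len(n)) {
    s <- pi_$sire[i]; d <- pi_$dam[i]
    ts <- if (s > 0) rbinom(n_snps, 1L, G[s, ] / 2) else rbinom(n_snps, 1L, p)
    td <- if (d > 0) rbinom(n_snps, 1L, G[d, ] / 2) else rbinom(n_snps, 1L, p)
    G[i, ] <- ts + td
  }
  list(genotypes = G, map = map)
}

#' Plant a maternal QTL in a simulated dataset
#'
#' Adds `sum_q alpha_q * dam_genotype(q)` to the chosen offspring trait for
#' every phenotyped record, using QTL markers drawn from one 1-Mb window of
#' the dam genotypes.  This creates a true dam-genotype association (the
#' maternal GWAS signal) with known effect sizes, recorded in
#' `truth$qtl`.
#'
#' @param dataset A `"sim_dataset"` carrying `genotypes` and `map` (attach
#'   the result of [simulate_genotypes()] first).
#' @param window Length-2 vector `c(chrom, mb)`: chromosome label and 1-Mb
#'   window index (0-based megabase, i.e. positions in
#'   `[mb*1e6 + 1, (mb+1)*1e6]`).
#' @param effect_size Allele substitution effect per QTL (recycled).
#' @param n_qtl Number of QTL markers to draw from the window.
#' @param trait Trait name or index to perturb (default first trait).
#' @return The dataset with perturbed phenotypes and a filled
#'   `truth$qtl` table.
#' @export
inject_dam_qtl <- function(dataset, window, effect_size, n_qtl = 1,
                           trait = 1) {
  if (is.null(dataset$genotypes)) abort("dataset has no genotypes")
  map <- dataset$map
  mb <- as.numeric(window[2])
  in_win <- map$chrom == as.character(window[1]) &
    floor((map$pos - 1) / 1e6) == mb
  if (!any(in_win)) abort("empty window: no markers on that chromosome/Mb")
  if (sum(in_win) < n_qtl) abort("window holds fewer markers than n_qtl")
  qtl <- sample(which(in_win), n_qtl)
  alpha <- rep_len(effect_size, n_qtl)
  tr <- if (is.numeric(trait)) dataset$config$traits[trait] else trait
  ph <- dataset$phenotypes
  dg <- dataset$genotypes[match(ph$dam, rownames(dataset$genotypes)),
                          qtl, drop = FALSE]
  if (anyNA(dg)) abort("some dams are not genotyped")
  ph[[tr]] <- ph[[tr]] + unname(drop(dg %*% alpha))
  dataset$phenotypes <- ph
  dataset$truth$qtl <- tibble(
    marker = map$marker[qtl], chrom = map$chrom[qtl], pos = map$pos[qtl],
    trait = tr, effect = alpha
  )
  dataset
}

# fatty-acid component sets for the composite traits
.sfa_parts <- c("C14:0", "C15:0", "C16:0", "C17:0", "C18:0")
.mufa_parts <- c("C16:1n7", "C18:1n7", "C18:1n9")
.pufa_parts <- c("C18:2n6", "C18:3n3", "C20:2n6", "C20:3n6", "C20:4n6",
                 "C20:5n3", "C22:4n6", "C22:5n3", "C22:6n3")

#' Derive composite fatty-acid traits
#'
#' Appends the composite traits to a table of individual fatty-acid
#' percentages: `SFA = C14:0 + C15:0 + C16:0 + C17:0 + C18:0`,
#' `MUFA = C16:1n7 + C18:1n7 + C18:1n9`,
#' `PUFA = C18:2n6 + C18:3n3 + C20:2n6 + C20:3n6 + C20:4n6 + C20:5n3 +
#' C22:4n6 + C22:5n3 + C22:6n3`, plus the ratios `MUFA_SFA` and
#' `PUFA_SFA`.  Component columns are matched ignoring punctuation (so
#' `C14.0` and `C14:0` both work); absent components contribute 0 and are
#' reported in the `"missing_components"` attribute with a warning.
#'
#' @param phen A data frame with fatty-acid columns (% of total fatty acids).
#' @return The input with `SFA`, `MUFA`, `PUFA`, `MUFA_SFA`, `PUFA_SFA`
#'   appended.
#' @export
derive_composite_traits <- function(phen) {
  norm <- function(x) toupper(gsub("[^0-9A-Za-z]", "", x))
  cols <- setNames(names(phen), norm(names(phen)))
  missing <- character(0)
  comp_sum <- function(parts) {
    out <- rep(0, nrow(phen))
    for (p in parts) {
      key <- norm(p)
      if (key %in% names(cols)) out <- out + phen[[cols[[key]]]]
      else missing <<- c(missing, p)
    }
    out
  }
  phen$SFA <- comp_sum(.sfa_parts)
  phen$MUFA <- comp_sum(.mufa_parts)
  phen$PUFA <- comp_sum(.pufa_parts)
  if (any(phen$SFA == 0)) {
    abort("SFA is zero for some rows; MUFA/SFA and PUFA/SFA are undefined")
  }
  phen$MUFA_SFA <- phen$MUFA / phen$SFA
  phen$PUFA_SFA <- phen$PUFA / phen$SFA
  if (length(missing)) {
    warn(paste("composite components absent, treated as 0:",
               paste(unique(missing), collapse = ", ")))
    attr(phen, "missing_components") <- unique(missing)
  }
  phen
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `pedigree.csv`, `phenotypes.tsv`, PLINK-style `genotypes.ped` /
#' `genotypes.map` (when genotypes are present) and the truth tables as
#' TSV into `dir`.
#'
#' @param dataset A `"sim_dataset"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dataset$pedigree, file.path(dir, "pedigree.csv"))
  readr::write_tsv(dataset$phenotypes, file.path(dir, "phenotypes.tsv"))
  if (!is.null(dataset$genotypes)) {
    write_plink(dataset$genotypes, dataset$map, file.path(dir, "genotypes"))
  }
  for (nm in names(dataset$truth)) {
    x <- dataset$truth[[nm]]
    if (!is.null(x) && is.data.frame(x) && nrow(x)) {
      readr::write_tsv(x, file.path(dir, paste0("truth_", nm, ".tsv")))
    }
  }
  invisible(dir)
}
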