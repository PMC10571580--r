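small_cfg <- function(...) {
  sim_config(n_generations = 1, base_sires = 2, base_dams = 4,
             sires_per_gen = 2, dams_per_gen = 4, n_lines = 1,
             litter_size = list(mean = 2, min = 2), seed = 1, ...)
}

test_that("pedigree counts and determinism follow the configuration", {
  # 1 generation, 2 sires, 4 dams, constant litters of 2: 6 + 8 animals
  ds <- sim_maternal_dataset(small_cfg())
  expect_equal(nrow(ds$pedigree), 6 + 8)
  expect_equal(nrow(ds$phenotypes), 8)
  expect_true(all(table(ds$phenotypes$litter) == 2))

  # same seed, bit-identical output
  ds2 <- sim_maternal_dataset(small_cfg())
  expect_identical(ds$phenotypes, ds2$phenotypes)
  expect_identical(ds$truth$breeding_values, ds2$truth$breeding_values)

  # every phenotyped animal has its dam in the pedigree
  expect_true(all(ds$phenotypes$dam %in% ds$pedigree$animal))
})

test_that("divergent selection retains top- and bottom-ranked dams", {
  cfg <- sim_config(n_generations = 2, sires_per_gen = 4, dams_per_gen = 10,
                    n_lines = 2, litter_size = list(mean = 6, min = 4),
                    selection = "divergent", seed = 33)
  ds <- sim_maternal_dataset(cfg)
  sc <- ds$truth$dam_scores
  # recompute the ranking per line x generation from the recorded scores
  for (g in unique(sc$generation)) {
    for (ln in unique(sc$line)) {
      s <- sc[sc$generation == g & sc$line == ln, ]
      sel <- s$score[s$selected]
      if (!length(sel)) next
      if (ln == "H") {
        expect_gte(min(sel), quantile(s$score, 0.8, names = FALSE) - 1e-12)
      } else {
        expect_lte(max(sel), quantile(s$score, 0.2, names = FALSE) + 1e-12)
      }
    }
  }
  # a dam's score is the mean of two of her first-parity offspring records
  ph <- ds$phenotypes[ds$phenotypes$parity == 1 & ds$phenotypes$generation == 1, ]
  one <- sc[sc$generation == 1, ][1, ]
  kids <- ph[ph$dam == one$dam, "IMF", drop = TRUE]
  combos <- combn(kids, 2, mean)
  expect_true(any(abs(combos - one$score) < 1e-12))
})

test_that("breeding values follow N(0, A x G0)", {
  ped <- data.frame(animal = c("s", "d", "o1", "o2"),
                    sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"))
  # zero genetic covariance -> all effects exactly zero
  bv0 <- simulate_breeding_values(ped, matrix(0, 2, 2), seed = 1)
  expect_true(all(bv0$a_d_t1 == 0) && all(bv0$a_m_t1 == 0))

  # founder covariance: many founder replicates vs G0 within 3 MC SE
  G0 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  founders <- data.frame(animal = sprintf("f%05d", 1:20000), sire = NA, dam = NA)
  bv <- simulate_breeding_values(founders, G0, seed = 2)
  emp <- cov(cbind(bv$a_d_t1, bv$a_m_t1))
  se <- 3 / sqrt(20000)
  expect_lt(max(abs(emp - G0)), 3 * se * max(diag(G0)) + 0.05)

  # full-sib covariance of direct effects ~ 0.5 sigma2_d
  nfam <- 4000
  ped <- data.frame(
    animal = c(sprintf("s%04d", 1:nfam), sprintf("d%04d", 1:nfam),
               sprintf("o%04da", 1:nfam), sprintf("o%04db", 1:nfam)),
    sire = c(rep(NA, 2 * nfam), sprintf("s%04d", 1:nfam), sprintf("s%04d", 1:nfam)),
    dam = c(rep(NA, 2 * nfam), sprintf("d%04d", 1:nfam), sprintf("d%04d", 1:nfam)))
  bv <- simulate_breeding_values(ped, diag(2), seed = 3)
  a <- bv$a_d_t1[(2 * nfam + 1):(3 * nfam)]
  b <- bv$a_d_t1[(3 * nfam + 1):(4 * nfam)]
  expect_equal(cov(a, b), 0.5, tolerance = 0.08)

  expect_error(simulate_breeding_values(ped, matrix(c(1, 2, 2, 1), 2, 2)),
               "positive semi-definite")
})

test_that("phenotype composition matches its deterministic limits", {
  # all random variances zero: y equals mean + fixed effects exactly
  cfg <- sim_config(n_generations = 1, base_sires = 2, base_dams = 4,
                    sires_per_gen = 2, dams_per_gen = 4, n_lines = 1,
                    litter_size = list(mean = 3, min = 3),
                    trait_means = 1.08,
                    G0_true = matrix(0, 2, 2), c2 = 0, R0_true = matrix(0),
                    fixed_effects = list(sex = c(0, 0.5)), seed = 5)
  ds <- sim_maternal_dataset(cfg)
  expect_equal(ds$phenotypes$IMF,
               1.08 + ifelse(ds$phenotypes$sex == "F", 0.5, 0))

  # only litter variance: littermates identical
  cfg2 <- sim_config(n_generations = 1, base_sires = 2, base_dams = 4,
                     sires_per_gen = 2, dams_per_gen = 4, n_lines = 1,
                     litter_size = list(mean = 3, min = 3),
                     G0_true = matrix(0, 2, 2), c2 = 0.3, R0_true = matrix(0),
                     fixed_effects = list(), seed = 6)
  ds2 <- sim_maternal_dataset(cfg2)
  spread <- tapply(ds2$phenotypes$IMF, ds2$phenotypes$litter,
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("large-cohort phenotypic variance decomposes into the components", {
  cfg <- sim_config(n_generations = 1, base_sires = 40, base_dams = 320,
                    sires_per_gen = 40, dams_per_gen = 320, n_lines = 1,
                    litter_size = list(mean = 8, min = 8), n_parities = 4,
                    fixed_effects = list(), seed = 8)
  ds <- sim_maternal_dataset(cfg)
  expect_gt(nrow(ds$phenotypes), 9000)
  vy <- var(ds$phenotypes$IMF)
  # rho_dm ~ 0, so components sum to ~1
  expect_equal(vy, 1, tolerance = 0.05)
})

test_that("simulated genotypes drop through the pedigree lawfully", {
  ped <- as_pedigree(random_pedigree(60, seed = 9))
  g <- simulate_genotypes(ped, n_snps = 0)
  expect_equal(ncol(g$genotypes), 0)
  expect_equal(nrow(g$map), 0)

  g <- simulate_genotypes(ped, n_snps = 120, n_chrom = 4, seed = 10)
  expect_equal(dim(g$genotypes), c(60, 120))
  expect_true(all(g$genotypes %in% 0:2))
  expect_true(all(diff(order(g$map$chrom, g$map$pos)) != 0))

  # Mendelian bounds: a parent with code 0 cannot transmit the alt allele
  idx <- setNames(seq_len(nrow(ped)), ped$animal)
  for (i in which(!is.na(ped$sire) & !is.na(ped$dam))) {
    gs <- g$genotypes[idx[ped$sire[i]], ]
    gd <- g$genotypes[idx[ped$dam[i]], ]
    go <- g$genotypes[i, ]
    lo <- (gs == 2) + (gd == 2)
    hi <- (gs >= 1) + (gd >= 1)
    expect_true(all(go >= lo & go <= hi))
  }

  expect_error(simulate_genotypes(ped, 10, maf_range = c(0, 0.6)), "maf")
})

test_that("planted dam QTL shifts offspring phenotypes by the dam genotype", {
  cfg <- sim_config(n_generations = 1, base_sires = 5, base_dams = 40,
                    sires_per_gen = 5, dams_per_gen = 40, n_lines = 1,
                    litter_size = list(mean = 6, min = 6), seed = 12)
  ds <- sim_maternal_dataset(cfg)
  g <- simulate_genotypes(ds$pedigree, n_snps = 50, n_chrom = 2, seed = 13)
  ds$genotypes <- g$genotypes; ds$map <- g$map
  w <- build_windows(g$map)
  win <- w$windows[which.max(w$windows$n_markers), ]

  ds0 <- inject_dam_qtl(ds, c(win$chrom, win$mb_index), effect_size = 0)
  expect_equal(ds0$phenotypes$IMF, ds$phenotypes$IMF)

  ds1 <- inject_dam_qtl(ds, c(win$chrom, win$mb_index), effect_size = 0.8)
  qm <- ds1$truth$qtl$marker
  expect_true(qm %in% w$markers$marker[w$markers$window == win$window])
  expect_equal(ds1$truth$qtl$effect, 0.8)
  dg <- g$genotypes[ds$phenotypes$dam, qm]
  # least-squares oracle: regressing the shift on dam genotype returns alpha
  shift <- ds1$phenotypes$IMF - ds$phenotypes$IMF
  expect_equal(shift, unname(0.8 * dg))
  fitb <- coef(lm(shift ~ dg))[2]
  expect_equal(unname(fitb), 0.8, tolerance = 1e-8)

  expect_error(inject_dam_qtl(ds, c("99", 0), 1), "empty window")
})

test_that("composite fatty-acid traits follow the summation formulas", {
  ph <- tibble::tibble(`C14:0` = 1, `C15:0` = 0.1, `C16:0` = 26,
                       `C17:0` = 0.2, `C18:0` = 9,
                       `C16:1n7` = 1.4, `C18:1n7` = 2, `C18:1n9` = 20,
                       `C18:2n6` = 0, `C18:3n3` = 0, `C20:4n6` = 0)
  expect_warning(out <- derive_composite_traits(ph), "absent")
  expect_equal(out$SFA, 36.3)
  expect_equal(out$MUFA, 23.4)
  expect_equal(out$PUFA, 0)
  expect_equal(out$PUFA_SFA, 0)

  # random tables match a naive independent summation
  set.seed(14)
  parts <- c("C14:0", "C15:0", "C16:0", "C17:0", "C18:0", "C16:1n7",
             "C18:1n7", "C18:1n9", "C18:2n6", "C18:3n3", "C20:2n6",
             "C20:3n6", "C20:4n6", "C20:5n3", "C22:4n6", "C22:5n3", "C22:6n3")
  tab <- as.data.frame(matrix(runif(length(parts) * 10, 0.1, 10), 10,
                              dimnames = list(NULL, parts)))
  out <- derive_composite_traits(tab)
  expect_equal(out$SFA, rowSums(tab[, c("C14:0", "C15:0", "C16:0",
                                        "C17:0", "C18:0")]))
  expect_equal(out$MUFA, rowSums(tab[, c("C16:1n7", "C18:1n7", "C18:1n9")]))
  expect_equal(out$PUFA, rowSums(tab[, parts[9:17]]))
  expect_equal(out$MUFA_SFA, out$MUFA / out$SFA)

  expect_error(derive_composite_traits(
    tibble::tibble(`C14:0` = 0, `C15:0` = 0, `C16:0` = 0, `C17:0` = 0,
                   `C18:0` = 0, `C16:1n7` = 1, `C18:1n7` = 1, `C18:1n9` = 1,
                   `C18:2n6` = 1, `C18:3n3` = 1, `C20:2n6` = 1, `C20:3n6` = 1,
                   `C20:4n6` = 1, `C20:5n3` = 1, `C22:4n6` = 1, `C22:5n3` = 1,
                   `C22:6n3` = 1)), "SFA is zero")
})

test_that("datasets write to plain-text files and PLINK round-trips", {
  cfg <- small_cfg()
  ds <- sim_maternal_dataset(cfg)
  g <- simulate_genotypes(ds$pedigree, n_snps = 30, n_chrom = 2, seed = 15)
  ds$genotypes <- g$genotypes; ds$map <- g$map
  dir <- tempfile()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "pedigree.csv")))
  expect_true(file.exists(file.path(dir, "phenotypes.tsv")))
  rt <- read_plink(file.path(dir, "genotypes"))
  expect_equal(unname(rt$genotypes), unname(ds$genotypes))
  expect_equal(rt$map$pos, ds$map$pos)
})
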