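test_that("pi follows the record-to-marker rule", {
  expect_equal(compute_pi(349, 88512), 0.9987)
  expect_equal(compute_pi(300, 3000), 0.9667)
  expect_error(compute_pi(3, 1), "outside")
  expect_error(compute_pi(0, 10), "at least one")
})

test_that("effect-variance scale divides V_g over expected heterozygosity", {
  p <- rep(0.25, 88512)
  expect_equal(derive_effect_variance(1, 0.9987, p),
               1 / (0.0013 * sum(2 * p * (1 - p))), tolerance = 1e-10)
  expect_equal(derive_effect_variance(1, 0.9987, p), 0.02318, tolerance = 1e-3)
  expect_equal(derive_effect_variance(0, 0.9, runif(10, 0.1, 0.4)), 0)
  # linear in the genetic variance
  p2 <- runif(50, 0.05, 0.5)
  expect_equal(derive_effect_variance(2, 0.95, p2),
               2 * derive_effect_variance(1, 0.95, p2))
  expect_error(derive_effect_variance(1, 0.9, c(0, 1)), "frequencies")
})

test_that("Bayes factors are posterior odds over prior odds", {
  pi <- 0.9987
  expect_equal(compute_bayes_factor(1 - pi, pi), 1)
  expect_equal(compute_bayes_factor(0, pi), 0)
  expect_true(is.infinite(compute_bayes_factor(1, pi)))
  # BF > 10 threshold in pip terms: p/(1-p) = 10 (1-pi)/pi
  thr <- 10 * (1 - pi) / pi
  p_thr <- thr / (1 + thr)
  expect_gt(compute_bayes_factor(p_thr + 1e-5, pi), 10)
  expect_lt(compute_bayes_factor(p_thr - 1e-5, pi), 10)
  expect_equal(p_thr, 0.01285, tolerance = 1e-3)
  # monotone increasing in pip
  pips <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(compute_bayes_factor(pips, 0.9)) > 0))
})

test_that("the BayesB sampler detects a strong dam QTL and keeps books", {
  set.seed(70)
  n <- 200; k <- 100
  G <- matrix(rbinom(n * k, 2, 0.3), n, k,
              dimnames = list(paste0("d", 1:n), sprintf("s%03d", 1:k)))
  y <- 0.8 * G[, 17] + rnorm(n)
  dat <- tibble::tibble(y = y, dam = rownames(G))
  fit <- fit_mgwa(dat, G, trait = "y", fixed = character(0),
                  iterations = 4000, burn_in = 500, thin = 5, seed = 71)
  expect_equal(fit$chain$n_retained, n_retained(4000, 500, 5))
  expect_equal(fit$config$pi, compute_pi(n, k))
  expect_equal(which.max(fit$snp$pip), 17)
  expect_gt(fit$snp$bf[17], 10)
  # reproducible with the same seed
  fit2 <- fit_mgwa(dat, G, trait = "y", fixed = character(0),
                   iterations = 4000, burn_in = 500, thin = 5, seed = 71)
  expect_identical(fit$snp, fit2$snp)
})

test_that("constant SNP columns keep their prior inclusion probability", {
  set.seed(72)
  n <- 150
  G <- cbind(matrix(rbinom(n * 30, 2, 0.3), n, 30), const = 1L)
  colnames(G) <- c(sprintf("s%02d", 1:30), "const")
  rownames(G) <- paste0("d", 1:n)
  dat <- tibble::tibble(y = rnorm(n), dam = rownames(G))
  fit <- suppressWarnings(
    fit_mgwa(dat, G, trait = "y", fixed = character(0), pi = 0.9,
             iterations = 6000, burn_in = 1000, thin = 5, seed = 73))
  expect_warning(
    fit_mgwa(dat, G, trait = "y", fixed = character(0), pi = 0.9,
             iterations = 60, burn_in = 10, thin = 5, seed = 73),
    "constant")
  # data carry no signal through a centered constant: pip ~ 1 - pi
  expect_lt(abs(fit$snp$pip[fit$snp$marker == "const"] - 0.1), 0.03)
})

test_that("window variance shares behave as variance ratios", {
  set.seed(74)
  n <- 120; k <- 40
  G <- matrix(rbinom(n * k, 2, 0.3), n, k,
              dimnames = list(paste0("d", 1:n), sprintf("s%03d", 1:k)))
  map1 <- tibble::tibble(marker = colnames(G), chrom = "1",
                         pos = as.integer(seq(1e5, 9e5, length.out = k)))
  dat <- tibble::tibble(y = 0.7 * G[, 5] + rnorm(n), dam = rownames(G))
  # a single window holding all SNPs explains 100% whenever anything is in
  fit <- fit_mgwa(dat, G, map = map1, trait = "y", fixed = character(0),
                  pi = 0.8, iterations = 3000, burn_in = 500, thin = 5,
                  seed = 75)
  expect_equal(nrow(fit$windows), 1)
  nonzero <- fit$shares[1, fit$shares[1, ] > 0]
  expect_true(all(abs(nonzero - 1) < 1e-12))

  # an all-zero chain yields all-zero shares
  sh0 <- maternalfx:::.window_shares_cpp(
    matrix(0.5, 10, 4), integer(0), integer(0), numeric(0),
    rep(1L, 4), 2L, 5L)
  expect_true(all(sh0 == 0))

  # shares lie in [0, 1] and sum to ~1 under linkage equilibrium
  mapm <- tibble::tibble(marker = colnames(G),
                         chrom = as.character(rep(1:4, each = 10)),
                         pos = rep(as.integer(seq(2e5, 38e6, length.out = 10)), 4))
  fitm <- fit_mgwa(dat, G, map = mapm, trait = "y", fixed = character(0),
                   pi = 0.8, iterations = 4000, burn_in = 1000, thin = 5,
                   seed = 76)
  expect_true(all(fitm$shares >= 0))
  # individual shares stay essentially within [0, 1]; rare small overshoots
  # arise from finite-sample anticorrelation between windows
  expect_gt(mean(fitm$shares <= 1 + 1e-9), 0.99)
  sums <- colSums(fitm$shares)
  expect_gt(mean(sums[sums > 0] < 1.6), 0.9)
})

test_that("association calling follows the two-tier window rule", {
  wt <- tibble::tibble(window = c("w1", "w2", "w3", "w4"),
                       chrom = "1", mb_index = 1:4, n_markers = 1L,
                       start = 1L, end = 2L,
                       pct_genomic_variance = c(1.2, 2.0, 0.7, 0.4))
  snp <- tibble::tibble(marker = paste0("m", 1:4),
                        bf = c(12, 9, 11, 50))
  wins <- list(markers = tibble::tibble(marker = paste0("m", 1:4),
                                        window = c("w1", "w2", "w3", "w4")))
  out <- call_associated_windows(wt, snp, wins)
  expect_equal(out$tier, c("primary", NA, "secondary", NA))
  expect_equal(out$associated, c(TRUE, FALSE, TRUE, FALSE))
  # >= 10 table convention counted separately from the strict rule
  snp2 <- snp; snp2$bf[2] <- 10
  out2 <- call_associated_windows(wt, snp2, wins)
  expect_equal(out2$n_snps_bf_gt[2], 0)
  expect_equal(out2$n_snps_bf_ge[2], 1)
  expect_false(out2$associated[2])
})
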