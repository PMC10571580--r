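# a small model-4 dataset shared across tests
sim_small <- function(seed = 20, dams = 8, parities = 2) {
  cfg <- sim_config(n_generations = 2, base_sires = 4, base_dams = 12,
                    sires_per_gen = 4, dams_per_gen = dams, n_lines = 1,
                    litter_size = list(mean = 5, min = 3),
                    n_parities = parities, seed = seed)
  sim_maternal_dataset(cfg)
}

test_that("design matrices map records to the right effect columns", {
  ds <- sim_small()
  ph <- ds$phenotypes
  spec <- model_spec(4, "IMF")
  d <- build_design(ph, ds$pedigree, spec)
  n <- nrow(ph); q <- nrow(ds$pedigree)
  expect_equal(dim(d$Zd), c(n, q))
  expect_equal(dim(d$Zm), c(n, q))
  expect_equal(ncol(d$W_iid), length(unique(ph$litter)))
  # one nonzero per row, rows of a litter hit the same column
  expect_true(all(Matrix::rowSums(d$Zd) == 1))
  expect_true(all(Matrix::rowSums(d$W_iid) == 1))
  same_litter <- which(ph$litter == ph$litter[1])
  cols <- apply(as.matrix(d$W_iid[same_litter, , drop = FALSE]), 1, which.max)
  expect_true(all(cols == cols[1]))
  # intercept + treatment contrasts: X rows sum to 1 + number of non-reference
  expect_true(all(Matrix::rowSums(d$X != 0) >= 1))

  # model 1 drops the maternal and litter structures
  d1 <- build_design(ph, ds$pedigree, model_spec(1, "IMF"))
  expect_null(d1$Zm); expect_null(d1$W_iid)

  # a record with an unknown dam is rejected
  bad <- ph; bad$dam[1] <- "nobody"
  expect_error(build_design(bad, ds$pedigree, spec), "dam absent")
})

test_that("chain bookkeeping and reproducibility are exact", {
  expect_equal(n_retained(300000, 20000, 200), 1400L)
  expect_equal(n_retained(500000, 100000, 10), 40000L)
  ds <- sim_small()
  fit <- fit_animal_model(ds$phenotypes, ds$pedigree, traits = "IMF",
                          model = 4, iterations = 1000, burn_in = 100,
                          thin = 9, seed = 1)
  expect_equal(fit$settings$n_retained, n_retained(1000, 100, 9))
  fit2 <- fit_animal_model(ds$phenotypes, ds$pedigree, traits = "IMF",
                           model = 4, iterations = 1000, burn_in = 100,
                           thin = 9, seed = 1)
  expect_identical(fit$draws, fit2$draws)
  expect_error(fit_animal_model(ds$phenotypes, ds$pedigree, traits = "IMF",
                                iterations = 100, burn_in = 100), "burn_in")
})

test_that("residual-only sampler matches the closed-form posterior", {
  set.seed(2)
  n <- 150
  y <- rnorm(n, 5, 2)
  ph <- tibble::tibble(animal = paste0("a", 1:n), dam = NA_character_, y = y)
  ped <- data.frame(animal = ph$animal, sire = NA, dam = NA)
  fit <- fit_animal_model(ph, ped, traits = "y", model = 0,
                          fixed = character(0), iterations = 51000,
                          burn_in = 1000, thin = 5, seed = 3)
  s2 <- fit$draws$r_y_y
  # flat priors on (mu, s2): marginal posterior is SSE / chisq_{n-3}
  SSE <- sum((y - mean(y))^2)
  ks <- suppressWarnings(
    stats::ks.test(s2, function(x) 1 - stats::pchisq(SSE / x, df = n - 3)))
  expect_gt(ks$p.value, 0.01)
})

test_that("inverse-Wishart draws have the flat-prior conditional moments", {
  # E[IW(df, S)] = S / (df - m - 1); df = q - m - 1 as used for G0
  S <- matrix(c(5, 1, 1, 3), 2, 2)
  q <- 120
  df <- q - 2 - 1
  set.seed(4)
  acc <- matrix(0, 2, 2)
  R <- 4000
  for (i in seq_len(R)) acc <- acc + maternalfx:::.riwish_cpp(df, S)
  expect_equal(acc / R, S / (df - 3), tolerance = 0.05)
})

test_that("derived genetic parameters follow the ratio definitions", {
  # mirror of a model-4 scale: components (0.45, 0.09, 0.14, 0.32), cov 0
  G0 <- matrix(c(0.45, 0, 0, 0.09), 2, 2)
  out <- derive_parameters(G0, Cc = 0.14 * diag(1), R0 = matrix(0.32))
  expect_equal(out$h2d, 0.45)
  expect_equal(out$h2m, 0.09)
  expect_equal(out$c2, 0.14)
  expect_equal(out$sigma2_P, 1)
  # perfect covariance gives correlation 1
  G1 <- matrix(c(0.4, sqrt(0.4 * 0.1), sqrt(0.4 * 0.1), 0.1), 2, 2)
  expect_equal(derive_parameters(G1, R0 = matrix(0.5))$rho_dm, 1)
  # ratios plus the residual ratio renormalize to 1
  set.seed(5)
  for (i in 1:5) {
    L <- matrix(rnorm(4), 2); G <- crossprod(L) + diag(0.1, 2)
    cc <- runif(1, 0.01, 0.5); rr <- runif(1, 0.1, 1)
    o <- derive_parameters(G, Cc = cc * diag(1), R0 = matrix(rr))
    resid_ratio <- rr / o$sigma2_P
    cov_ratio <- G[1, 2] / o$sigma2_P
    expect_equal(o$h2d + o$h2m + o$c2 + resid_ratio + cov_ratio, 1,
                 tolerance = 1e-12)
  }
  # zero variance flags the correlation as undefined
  expect_true(is.na(derive_parameters(matrix(c(0.4, 0, 0, 0), 2, 2),
                                      R0 = matrix(0.5))$rho_dm))
})

test_that("posterior summaries match brute-force oracles", {
  x <- 1:100
  s <- posterior_summary(x)
  expect_equal(s$mean, 50.5)
  expect_equal(s$median, 50.5)

  # skewed draws: HPD equals the all-pairs search oracle
  set.seed(6)
  z <- rexp(400)
  s <- posterior_summary(z)
  o <- oracle_hpd(z)
  expect_equal(c(s$hpd_lower, s$hpd_upper), o, tolerance = 1e-12)

  # constant chain: degenerate spread
  s0 <- posterior_summary(rep(2.5, 50))
  expect_equal(s0$sd, 0)
  expect_equal(s0$hpd_lower, 2.5)
  expect_equal(s0$hpd_upper, 2.5)
  expect_equal(s0$mode, 2.5)

  expect_error(posterior_summary(1:10), "at least 30")
})

test_that("model 4 recovers its generating structure on a small dataset", {
  ds <- sim_small(seed = 30, dams = 16, parities = 3)
  fit <- fit_animal_model(ds$phenotypes, ds$pedigree, traits = "IMF",
                          model = 4, iterations = 8000, burn_in = 1000,
                          thin = 10, seed = 7)
  td <- tidy(fit)
  h2d <- td[td$term == "h2d", ]
  # generous sanity bounds at this small scale
  expect_gt(h2d$mean, 0.1); expect_lt(h2d$mean, 0.85)
  expect_true(all(td$hpd_lower <= td$median & td$median <= td$hpd_upper))
  g <- glance(fit)
  expect_equal(g$n_retained, n_retained(8000, 1000, 10))
})

test_that("ignoring maternal effects inflates direct heritability", {
  # fitting model 1 to model-4 data pushes h2d above the generating value
  inflated <- logical(3)
  for (r in 1:3) {
    ds <- sim_small(seed = 40 + r, dams = 12, parities = 2)
    fit1 <- fit_animal_model(ds$phenotypes, ds$pedigree, traits = "IMF",
                             model = 1, iterations = 6000, burn_in = 1000,
                             thin = 10, seed = r)
    inflated[r] <- tidy(fit1)$mean[tidy(fit1)$term == "h2d"] > 0.45
  }
  expect_gte(sum(inflated), 2)
})

test_that("bivariate battery fits one model per companion trait", {
  sdm <- 0.9 * sqrt(0.4 * 0.35)
  G0 <- diag(c(0.4, 0.35, 0.1, 0.1))
  G0[1, 2] <- G0[2, 1] <- sdm # strong direct cross-trait correlation
  cfg <- sim_config(n_generations = 2, base_sires = 4, base_dams = 12,
                    sires_per_gen = 6, dams_per_gen = 18, n_lines = 1,
                    litter_size = list(mean = 6, min = 4), n_parities = 2,
                    traits = c("IMF", "FA"), trait_means = c(0, 0),
                    G0_true = G0, c2 = c(0.1, 0.1),
                    R0_true = diag(c(0.4, 0.45)), seed = 50)
  ds <- sim_maternal_dataset(cfg)
  out <- fit_bivariate_battery(ds$phenotypes, ds$pedigree,
                               traits = c("IMF", "FA"), iterations = 12000,
                               burn_in = 2000, thin = 10, seed = 8)
  expect_equal(nrow(out), 1) # n traits - 1 rows
  expect_true(all(c("h2d", "rho_d", "rho_m") %in% names(out)))
  # generating rho_d = 0.9 inside the HPD interval
  expect_gte(0.9, out$rho_d_lo)
  expect_lte(out$rho_d_lo, out$rho_d_hi)
  expect_gte(out$rho_d_hi + 0.05, 0.9)
})
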