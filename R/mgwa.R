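#' Prior exclusion probability for the BayesB mixture
#'
#' The proportion of SNPs assumed to have no effect is tied to the number
#' of records and markers by `pi = 1 - n / (3 k)`: the model then expects
#' about one third as many non-zero SNP effects as there are records.
#' Reported values are rounded to 4 decimals.
#'
#' @param n_records Number of phenotype records.
#' @param n_snps Number of markers after QC.
#' @return `pi`, rounded to 4 decimals.
#' @examples
#' compute_pi(349, 88512) # 0.9987
#' @export
compute_pi <- function(n_records, n_snps) {
  if (n_records < 1 || n_snps < 1) abort("need at least one record and one SNP")
  pi <- 1 - n_records / (3 * n_snps)
  if (pi <= 0 || pi >= 1) {
    abort("pi = 1 - n/(3k) falls outside (0, 1); too few SNPs for this n")
  }
  round(pi, 4)
}

#' Per-SNP effect-variance scale from the trait's genetic variance
#'
#' Divides the genetic variance across the expected number of included
#' SNPs weighted by their heterozygosity:
#' `sigma2_alpha = V_g / ((1 - pi) * sum_j 2 p_j (1 - p_j))`.
#'
#' @param genetic_variance Additive genetic variance of the trait.
#' @param pi Prior exclusion probability.
#' @param allele_freqs Vector of allele frequencies in (0, 1).
#' @return The scale `sigma2_alpha` of the t effect prior.
#' @export
derive_effect_variance <- function(genetic_variance, pi, allele_freqs) {
  het <- sum(2 * allele_freqs * (1 - allele_freqs))
  if (het <= 0) abort("all allele frequencies are 0 or 1; no variance to scale")
  genetic_variance / ((1 - pi) * het)
}

#' Bayes factor of SNP inclusion
#'
#' Posterior odds of inclusion divided by prior odds:
#' `BF = (p_hat / (1 - p_hat)) / ((1 - pi) / pi)`.  `p_hat = 1` maps to
#' `Inf`.
#'
#' @param pip Posterior inclusion probability (vector allowed).
#' @param pi Prior exclusion probability.
#' @return Bayes factors (non-negative, `Inf` for `pip = 1`).
#' @export
compute_bayes_factor <- function(pip, pi) {
  if (any(pip < 0 | pip > 1)) abort("pip must be in [0, 1]")
  prior_odds <- (1 - pi) / pi
  ifelse(pip == 1, Inf, (pip / (1 - pip)) / prior_odds)
}

#' Fit the maternal GWAS (BayesB) model
#'
#' Regresses offspring phenotypes on their dam's genotypes with the
#' mixture model `y = 1 mu + X b + sum_j z_j alpha_j delta_j + e`, where
#' `delta_j = 0` with probability `pi` and `alpha_j` has a `t_nu(0,
#' sigma2_alpha)` prior (implemented as a normal with per-locus
#' scaled-inverse-chi-squared variance).  Genotype covariates are
#' column-centered; constant loci carry no signal and keep their prior
#' inclusion probability.  Defaults mirror a 500,000-iteration chain with
#' 100,000 burn-in, keeping 1 draw in 10.
#'
#' @param data Data frame of offspring records: the trait column, the
#'   fixed factors and a `dam` column naming the genotyped dam.
#' @param genotypes 0/1/2 matrix with dam ids as rownames (no missing
#'   values; run [impute_naive()] first).
#' @param map Marker map (`marker`, `chrom`, `pos`); required for window
#'   summaries.
#' @param trait Trait column name.
#' @param fixed Fixed-factor column names (default sex, month, parity).
#' @param pi `"auto"` (from [compute_pi()]) or a numeric value.
#' @param nu Degrees of freedom of the t effect prior (default 4).
#' @param genetic_variance Trait genetic variance used to scale the
#'   effect prior; defaults to half the phenotypic variance.
#' @param sigma2_alpha Optional explicit effect-variance scale
#'   (overrides `genetic_variance`).
#' @param iterations,burn_in,thin MCMC settings.
#' @param seed Optional seed.
#' @param windows Optional result of [build_windows()]; computed from
#'   `map` when omitted.
#' @return An object of class `"mgwa_fit"` with elements `snp` (per-SNP
#'   tibble: `marker`, `chrom`, `pos`, `pip`, `alpha_mean`, `bf`),
#'   `windows` (per-window tibble with `pct_genomic_variance` and
#'   association calls from [call_associated_windows()]), `shares`
#'   (windows x retained samples matrix), `chain` (mu/b and residual
#'   variance draws), and the configuration.
#' @export
fit_mgwa <- function(data, genotypes, map = NULL, trait,
                     fixed = c("sex", "month", "parity"),
                     pi = "auto", nu = 4,
                     genetic_variance = NULL, sigma2_alpha = NULL,
                     iterations = 500000, burn_in = 100000, thin = 10,
                     seed = NULL, windows = NULL) {
  if (burn_in >= iterations) abort("burn_in must be smaller than iterations")
  if (!"dam" %in% names(data)) abort("data must have a 'dam' column")
  if (anyNA(genotypes)) abort("genotypes contain missing values; impute first")
  ridx <- match(data$dam, rownames(genotypes))
  if (anyNA(ridx)) {
    abort(paste0("dam not in genotype matrix: ", data$dam[which(is.na(ridx))[1]]))
  }
  y <- data[[trait]]
  n <- length(y)
  k <- ncol(genotypes)
  if (identical(pi, "auto")) pi <- compute_pi(n, k)
  if (pi <= 0 || pi >= 1) abort("pi must be in (0, 1)")

  Zraw <- genotypes[ridx, , drop = FALSE]
  storage.mode(Zraw) <- "double"
  if (!all(Zraw %in% c(0, 1, 2))) abort("genotype codes must be 0/1/2")
  Z <- scale(Zraw, center = TRUE, scale = FALSE)
  const <- apply(Z, 2, function(z) all(z == 0))
  if (any(const)) {
    warn(sprintf("%d constant SNP column(s) carry no signal (zero variance)",
                 sum(const)))
  }

  fixed <- intersect(fixed, names(data))
  X <- if (length(fixed)) {
    model.matrix(stats::as.formula(paste("~", paste(fixed, collapse = " + "))),
                 as.data.frame(lapply(data[fixed], factor)))
  } else {
    matrix(1, n, 1)
  }

  if (is.null(sigma2_alpha)) {
    if (is.null(genetic_variance)) genetic_variance <- 0.5 * var(y)
    pfreq <- colMeans(genotypes) / 2
    pfreq <- pfreq[pfreq > 0 & pfreq < 1]
    sigma2_alpha <- derive_effect_variance(genetic_variance, pi, pfreq)
  }

  if (!is.null(seed)) set.seed(seed)
  res <- .bayesb_cpp(y, X, Zraw, pi, nu, sigma2_alpha,
                     as.integer(iterations), as.integer(burn_in),
                     as.integer(thin))

  snp <- tibble(
    marker = colnames(genotypes) %||% sprintf("snp%06d", seq_len(k)),
    pip = as.numeric(res$pip),
    alpha_mean = as.numeric(res$alpha_mean),
    bf = compute_bayes_factor(as.numeric(res$pip), pi)
  )
  if (!is.null(map)) {
    snp <- left_join(snp, map, by = "marker") |>
      select("marker", "chrom", "pos", "pip", "alpha_mean", "bf")
  }

  fit <- structure(list(
    snp = snp,
    windows = NULL,
    shares = NULL,
    chain = list(b = res$b, sigma2_e = as.numeric(res$sigma2_e),
                 inc_locus = as.integer(res$inc_locus),
                 inc_sample = as.integer(res$inc_sample),
                 inc_alpha = as.numeric(res$inc_alpha),
                 n_retained = res$n_retained),
    Z = Z,
    trait = trait,
    config = list(pi = pi, nu = nu, sigma2_alpha = sigma2_alpha,
                  iterations = iterations, burn_in = burn_in, thin = thin,
                  seed = seed, n_records = n, n_snps = k)
  ), class = "mgwa_fit")

  if (!is.null(map)) {
    if (is.null(windows)) windows <- build_windows(map)
    wv <- window_variance(fit, windows)
    fit$shares <- wv$shares
    fit$windows <- call_associated_windows(wv$windows, snp, windows)
  }
  fit
}

#' Posterior window shares of the genomic variance
#'
#' For each retained sample, the genomic value of individual `i` is
#' `g_i = sum_j z_ij alpha_j delta_j`; the share of a window is the
#' variance (across individuals) of the window-restricted genomic value
#' divided by the variance of `g`.  Samples with zero total genomic
#' variance contribute zero shares.  The reported percentage is the
#' posterior mean share times 100.
#'
#' @param fit An `"mgwa_fit"`.
#' @param windows A [build_windows()] result.
#' @return A list with `windows` (tibble: window columns plus
#'   `pct_genomic_variance`) and `shares` (windows x samples matrix).
#' @export
window_variance <- function(fit, windows) {
  wtab <- windows$windows
  wassign <- windows$markers
  wid <- match(wassign$window[match(fit$snp$marker, wassign$marker)],
               wtab$window)
  wid[is.na(wid)] <- 0L
  ns <- fit$chain$n_retained
  shares <- .window_shares_cpp(fit$Z, fit$chain$inc_locus,
                               fit$chain$inc_sample, fit$chain$inc_alpha,
                               as.integer(wid), nrow(wtab), as.integer(ns))
  wtab$pct_genomic_variance <- 100 * rowMeans(shares)
  list(windows = wtab, shares = shares)
}

#' Call associated genomic windows
#'
#' A window is primary-associated when it explains at least `primary`
#' percent of the genomic variance and contains at least one SNP with
#' Bayes factor strictly greater than `bf`; windows reaching `secondary`
#' percent with such a SNP form the secondary tier.  SNP counts at the
#' non-strict `>= bf` convention are reported alongside (the table
#' convention), as `n_snps_bf_ge`.
#'
#' @param window_tbl Window tibble with `pct_genomic_variance` (from
#'   [window_variance()]).
#' @param snp SNP result tibble with `marker` and `bf`.
#' @param windows A [build_windows()] result (marker-window map).
#' @param primary,secondary,bf Thresholds (defaults 1.0, 0.5, 10).
#' @return The window tibble with `n_snps_bf_gt`, `n_snps_bf_ge`,
#'   `associated`, and `tier` (`"primary"`, `"secondary"` or `NA`).
#' @export
call_associated_windows <- function(window_tbl, snp, windows,
                                    primary = 1.0, secondary = 0.5, bf = 10) {
  bft <- left_join(windows$markers, snp[, c("marker", "bf")], by = "marker") |>
    group_by(.data$window) |>
    summarise(n_snps_bf_gt = sum(.data$bf > !!bf, na.rm = TRUE),
              n_snps_bf_ge = sum(.data$bf >= !!bf, na.rm = TRUE),
              .groups = "drop")
  out <- left_join(window_tbl, bft, by = "window") |>
    mutate(
      n_snps_bf_gt = ifelse(is.na(.data$n_snps_bf_gt), 0L, .data$n_snps_bf_gt),
      n_snps_bf_ge = ifelse(is.na(.data$n_snps_bf_ge), 0L, .data$n_snps_bf_ge),
      tier = dplyr::case_when(
        .data$pct_genomic_variance >= primary & .data$n_snps_bf_gt >= 1 ~ "primary",
        .data$pct_genomic_variance >= secondary & .data$n_snps_bf_gt >= 1 ~ "secondary",
        TRUE ~ NA_character_
      ),
      associated = !is.na(.data$tier)
    )
  out
}

#' @export
tidy.mgwa_fit <- function(x, ...) x$snp

#' @export
glance.mgwa_fit <- function(x, ...) {
  tibble(n_records = x$config$n_records, n_snps = x$config$n_snps,
         pi = x$config$pi, nu = x$config$nu,
         sigma2_alpha = x$config$sigma2_alpha,
         iterations = x$config$iterations, burn_in = x$config$burn_in,
         thin = x$config$thin, n_retained = x$chain$n_retained,
         n_windows = if (is.null(x$windows)) NA_integer_ else nrow(x$windows),
         n_associated = if (is.null(x$windows)) NA_integer_
                        else sum(x$windows$associated))
}

#' @export
print.mgwa_fit <- function(x, ...) {
  cat(sprintf("BayesB maternal GWAS: %d records x %d SNPs, pi = %.4f, %d draws\n",
              x$config$n_records, x$config$n_snps, x$config$pi,
              x$chain$n_retained))
  if (!is.null(x$windows)) {
    cat(sprintf("  %d windows, %d associated\n", nrow(x$windows),
                sum(x$windows$associated)))
  }
  invisible(x)
}
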