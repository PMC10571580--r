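#' Specify one of the five maternal-effects animal models
#'
#' The five models combine direct genetic effects (always present) with
#' maternal genetic effects, a common-litter effect and a
#' maternal-environment effect:
#'
#' * Model 1: direct genetic only
#' * Model 2: direct + maternal genetic
#' * Model 3: direct + common litter
#' * Model 4: direct + maternal genetic + common litter
#' * Model 5: direct + maternal genetic + maternal environment
#'
#' `model = 0` is a degenerate residual-only (mean + fixed effects) model,
#' useful as a calibration baseline for the sampler.
#'
#' @param model Integer 0--5.
#' @param traits Character vector of 1 or 2 trait names.
#' @return A list of class `"model_spec"` with `model_id`, `n_traits`,
#'   `direct`, `maternal`, `iid` (`"none"`, `"litter"` or `"me"`).
#' @export
model_spec <- function(model, traits) {
  if (!model %in% 0:5) abort("model must be one of 0..5")
  t <- length(traits)
  if (!t %in% 1:2) abort("traits must have length 1 or 2")
  structure(list(
    model_id = as.integer(model),
    n_traits = t,
    traits = traits,
    direct = model >= 1,
    maternal = model %in% c(2, 4, 5),
    iid = if (model %in% c(3, 4)) "litter" else if (model == 5) "me" else "none"
  ), class = "model_spec")
}

#' Build the design structures for an animal model
#'
#' Constructs the incidence matrices relating records to effects: `X` for
#' the fixed factors (treatment contrasts, so the first level of each
#' factor is the reference, plus an intercept), `Zd` mapping each record to
#' its own genetic effect, `Zm` mapping each record to its dam's maternal
#' genetic effect, and `W_iid` mapping records to litters (dam x parity)
#' or to dams for the maternal-environment term.
#'
#' @param phenotypes Data frame with one row per record: trait columns,
#'   the fixed factors, `animal`, `dam`, and (for litter models) `litter`.
#' @param ped A pedigree accepted by [as_pedigree()].
#' @param spec A [model_spec()].
#' @param fixed Character vector of fixed-factor column names.
#' @param litter_col Name of the litter id column.
#' @return A list with sparse matrices `X`, `Zd`, `Zm`, `W_iid` (absent
#'   terms are `NULL`), the index vectors behind them, and column labels.
#' @export
build_design <- function(phenotypes, ped, spec, fixed = c("sex", "month"),
                         litter_col = "litter") {
  ped <- as_pedigree(ped)
  n <- nrow(phenotypes)
  q <- nrow(ped)
  fixed <- intersect(fixed, names(phenotypes))
  df <- as.data.frame(lapply(phenotypes[fixed], factor))
  X <- if (length(fixed)) {
    Matrix::sparse.model.matrix(
      stats::as.formula(paste("~", paste(fixed, collapse = " + "))), df)
  } else {
    Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                         dims = c(n, 1), dimnames = list(NULL, "(Intercept)"))
  }

  animal_idx <- match(phenotypes$animal, ped$animal)
  if (anyNA(animal_idx)) {
    abort(paste0("record animal absent from pedigree: ",
                 phenotypes$animal[which(is.na(animal_idx))[1]]))
  }
  Zd <- Zm <- W_iid <- NULL
  dam_idx <- iid_idx <- NULL
  iid_levels <- character(0)
  if (spec$direct) {
    Zd <- Matrix::sparseMatrix(i = seq_len(n), j = animal_idx, x = 1,
                               dims = c(n, q))
  }
  if (spec$maternal) {
    dam_idx <- match(phenotypes$dam, ped$animal)
    if (anyNA(dam_idx)) {
      abort(paste0("record dam absent from pedigree: ",
                   phenotypes$animal[which(is.na(dam_idx))[1]]))
    }
    Zm <- Matrix::sparseMatrix(i = seq_len(n), j = dam_idx, x = 1,
                               dims = c(n, q))
  }
  if (spec$iid != "none") {
    key <- if (spec$iid == "litter") {
      if (!litter_col %in% names(phenotypes)) {
        abort(paste0("litter column '", litter_col, "' not found"))
      }
      phenotypes[[litter_col]]
    } else {
      phenotypes$dam
    }
    f <- factor(key)
    iid_idx <- as.integer(f)
    iid_levels <- levels(f)
    W_iid <- Matrix::sparseMatrix(i = seq_len(n), j = iid_idx, x = 1,
                                  dims = c(n, length(iid_levels)))
  }
  list(X = X, Zd = Zd, Zm = Zm, W_iid = W_iid,
       animal_idx = animal_idx, dam_idx = dam_idx, iid_idx = iid_idx,
       iid_levels = iid_levels, fixed = fixed, n = n, q = q)
}

# labels for the genetic covariance entries, ordered (d traits, m traits)
g0_labels <- function(spec) {
  lab <- character(0)
  if (spec$direct) lab <- paste0("d_", spec$traits)
  if (spec$maternal) lab <- c(lab, paste0("m_", spec$traits))
  lab
}

#' Fit a maternal-effects animal model by Gibbs sampling
#'
#' Runs a Markov chain for one of the [model_spec()] models.  Records with
#' a missing trait value are dropped (complete-case analysis).  The chain
#' stores every `(co)variance` component and the derived genetic
#' parameters for each retained draw; `floor((iterations - burn_in) /
#' thin)` draws are retained.  Default chain settings are 300,000
#' iterations with a 20,000-iteration burn-in, keeping 1 draw in 200.
#'
#' @inheritParams build_design
#' @param pedigree A pedigree accepted by [as_pedigree()].
#' @param traits Character vector of 1 or 2 trait column names.
#' @param model Model id 0--5 (see [model_spec()]).
#' @param iterations,burn_in,thin MCMC settings; `burn_in < iterations`.
#' @param seed Optional integer seed.
#' @param start Optional list of starting covariances `G0`, `C`, `R0`.
#' @return An object of class `"animal_model_fit"`: a list with `draws`
#'   (tibble of retained variance components and derived parameters),
#'   `spec`, `settings`, `dims`, and the posterior mean of the location
#'   effects.  Use [tidy()] / [glance()] for summaries.
#' @export
fit_animal_model <- function(phenotypes, pedigree, traits, model = 4,
                             fixed = c("sex", "month"),
                             litter_col = "litter",
                             iterations = 300000, burn_in = 20000,
                             thin = 200, seed = NULL, start = NULL) {
  if (burn_in >= iterations) abort("burn_in must be smaller than iterations")
  ped <- as_pedigree(pedigree)
  spec <- model_spec(model, traits)
  t <- spec$n_traits
  keep <- complete.cases(phenotypes[, traits, drop = FALSE])
  phenotypes <- phenotypes[keep, , drop = FALSE]
  Y <- as.matrix(phenotypes[, traits, drop = FALSE])
  storage.mode(Y) <- "double"
  n <- nrow(Y)

  d <- build_design(phenotypes, ped, spec, fixed = fixed,
                    litter_col = litter_col)
  blocks <- list(d$X)
  col_names <- colnames(d$X)
  if (spec$direct) {
    blocks <- c(blocks, list(d$Zd))
    col_names <- c(col_names, paste0("a_d:", ped$animal))
  }
  if (spec$maternal) {
    blocks <- c(blocks, list(d$Zm))
    col_names <- c(col_names, paste0("a_m:", ped$animal))
  }
  if (spec$iid != "none") {
    blocks <- c(blocks, list(d$W_iid))
    col_names <- c(col_names, paste0(spec$iid, ":", d$iid_levels))
  }
  W <- do.call(cbind, blocks)
  W <- as(W, "dgCMatrix")

  q <- if (spec$direct) d$q else 0L
  Ainv <- if (q > 0) {
    as(as(relationship_inverse(ped), "generalMatrix"), "CsparseMatrix")
  } else {
    as(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(1, 1)), "dgCMatrix")
  }

  vy <- apply(Y, 2, var)
  mt <- (spec$direct + spec$maternal) * t
  if (is.null(start)) start <- list()
  G0 <- start$G0 %||% {
    if (mt > 0) diag(rep(0.3 * vy, spec$direct + spec$maternal),
                     nrow = mt) else matrix(0, 0, 0)
  }
  C0 <- start$C %||% diag(0.1 * vy, nrow = t)
  R0 <- start$R0 %||% diag(0.4 * vy, nrow = t)

  if (!is.null(seed)) set.seed(seed)
  res <- .gibbs_animal_cpp(Y, W,
                           p_fixed = ncol(d$X), q = q,
                           has_maternal = spec$maternal,
                           n_iid = length(d$iid_levels),
                           Ainv = Ainv,
                           niter = as.integer(iterations),
                           burnin = as.integer(burn_in),
                           thin = as.integer(thin),
                           G0 = as.matrix(G0), C = as.matrix(C0),
                           R0 = as.matrix(R0), col_names = col_names)

  lab <- g0_labels(spec)
  nm <- character(0)
  if (mt > 0) {
    nm <- c(nm, as.vector(outer(lab, lab, function(a, b) paste0("g_", a, "_", b))))
  }
  if (spec$iid != "none") {
    pre <- if (spec$iid == "litter") "c_" else "me_"
    nm <- c(nm, as.vector(outer(spec$traits, spec$traits,
                                function(a, b) paste0(pre, a, "_", b))))
  }
  nm <- c(nm, as.vector(outer(spec$traits, spec$traits,
                              function(a, b) paste0("r_", a, "_", b))))
  draws <- as_tibble(as.data.frame(res$samples))
  names(draws) <- nm
  draws <- bind_cols(draws, derive_parameters_draws(draws, spec))

  structure(list(
    draws = draws,
    spec = spec,
    settings = list(iterations = iterations, burn_in = burn_in, thin = thin,
                    seed = seed, n_retained = res$n_retained),
    dims = list(n_records = n, n_animals = q, n_iid = length(d$iid_levels),
                p_fixed = ncol(d$X)),
    theta_mean = setNames(as.data.frame(res$theta_mean), spec$traits) |>
      mutate(effect = col_names, .before = 1) |> as_tibble(),
    design = d
  ), class = "animal_model_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Retained-draw bookkeeping
#'
#' Number of draws a chain retains: `floor((iterations - burn_in) / thin)`.
#' Both samplers keep iteration `i` (after burn-in) when
#' `(i - burn_in) %% thin == 0`.
#'
#' @param iterations,burn_in,thin Chain settings.
#' @return Integer count of retained draws.
#' @examples
#' n_retained(300000, 20000, 200) # 1400
#' n_retained(500000, 100000, 10) # 40000
#' @export
n_retained <- function(iterations, burn_in, thin) {
  as.integer(floor((iterations - burn_in) / thin))
}

# vectorized parameter derivation over a tibble of retained draws
derive_parameters_draws <- function(draws, spec) {
  t <- spec$n_traits
  traits <- spec$traits
  sfx <- function(base, s) if (t == 1) base else paste0(base, "_", traits[s])
  out <- tibble(.rows = nrow(draws))
  get0 <- function(nm) if (nm %in% names(draws)) draws[[nm]] else 0
  for (s in seq_len(t)) {
    tr <- traits[s]
    s2d <- if (spec$direct) get0(paste0("g_d_", tr, "_d_", tr)) else 0
    s2m <- if (spec$maternal) get0(paste0("g_m_", tr, "_m_", tr)) else 0
    sdm <- if (spec$maternal) get0(paste0("g_d_", tr, "_m_", tr)) else 0
    s2c <- if (spec$iid == "litter") get0(paste0("c_", tr, "_", tr)) else 0
    s2me <- if (spec$iid == "me") get0(paste0("me_", tr, "_", tr)) else 0
    s2e <- get0(paste0("r_", tr, "_", tr))
    # total phenotypic variance includes the direct-maternal covariance once
    sp2 <- s2d + s2m + sdm + s2c + s2me + s2e
    out[[sfx("sigma2_P", s)]] <- sp2
    if (spec$direct) out[[sfx("h2d", s)]] <- s2d / sp2
    if (spec$maternal) {
      out[[sfx("h2m", s)]] <- s2m / sp2
      out[[sfx("rho_dm", s)]] <-
        ifelse(s2d > 0 & s2m > 0, sdm / sqrt(s2d * s2m), NA_real_)
    }
    if (spec$iid == "litter") out[[sfx("c2", s)]] <- s2c / sp2
    if (spec$iid == "me") out[[sfx("me2", s)]] <- s2me / sp2
  }
  if (t == 2 && spec$direct) {
    d11 <- draws[[paste0("g_d_", traits[1], "_d_", traits[1])]]
    d22 <- draws[[paste0("g_d_", traits[2], "_d_", traits[2])]]
    d12 <- draws[[paste0("g_d_", traits[1], "_d_", traits[2])]]
    out$rho_d <- ifelse(d11 > 0 & d22 > 0, d12 / sqrt(d11 * d22), NA_real_)
    if (spec$maternal) {
      m11 <- draws[[paste0("g_m_", traits[1], "_m_", traits[1])]]
      m22 <- draws[[paste0("g_m_", traits[2], "_m_", traits[2])]]
      m12 <- draws[[paste0("g_m_", traits[1], "_m_", traits[2])]]
      out$rho_m <- ifelse(m11 > 0 & m22 > 0, m12 / sqrt(m11 * m22), NA_real_)
    }
  }
  out
}

#' Derive genetic parameters from variance components
#'
#' Converts one draw (or point estimate) of the covariance blocks into
#' heritabilities and ratios.  The total phenotypic variance is
#' `sigma2_P = sigma2_d + sigma2_m + sigma_dm + sigma2_c + sigma2_me +
#' sigma2_e` per trait --- the direct-maternal covariance enters once ---
#' and `h2d = sigma2_d / sigma2_P`, `h2m = sigma2_m / sigma2_P`,
#' `c2 = sigma2_c / sigma2_P`, `me2 = sigma2_me / sigma2_P`,
#' `rho_dm = sigma_dm / (sigma_d sigma_m)` (flagged `NA` when either
#' variance is 0).  With two traits, `rho_d` and `rho_m` are the
#' cross-trait correlations of the direct and maternal effects.
#'
#' @param G0 Genetic covariance, `2t x 2t` ordered (direct traits,
#'   maternal traits), or `t x t` when no maternal term.
#' @param Cc,Cme,R0 Litter, maternal-environment and residual covariances
#'   (`t x t`; `Cc`/`Cme` may be `NULL`).
#' @param traits Optional trait names.
#' @return A tibble with one row per trait; cross-trait correlations as
#'   columns `rho_d`, `rho_m` when two traits are given.
#' @export
derive_parameters <- function(G0, Cc = NULL, Cme = NULL, R0, traits = NULL) {
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  t <- nrow(R0)
  has_m <- nrow(G0) == 2 * t
  if (!has_m && nrow(G0) != t) abort("G0 must be t x t or 2t x 2t")
  if (is.null(traits)) traits <- paste0("t", seq_len(t))
  rows <- list()
  for (s in seq_len(t)) {
    s2d <- G0[s, s]
    s2m <- if (has_m) G0[t + s, t + s] else 0
    sdm <- if (has_m) G0[s, t + s] else 0
    s2c <- if (!is.null(Cc)) as.matrix(Cc)[s, s] else 0
    s2me <- if (!is.null(Cme)) as.matrix(Cme)[s, s] else 0
    s2e <- R0[s, s]
    sp2 <- s2d + s2m + sdm + s2c + s2me + s2e
    rows[[s]] <- tibble(
      trait = traits[s], sigma2_P = sp2,
      h2d = s2d / sp2,
      h2m = if (has_m) s2m / sp2 else NA_real_,
      c2 = if (!is.null(Cc)) s2c / sp2 else NA_real_,
      me2 = if (!is.null(Cme)) s2me / sp2 else NA_real_,
      rho_dm = if (has_m && s2d > 0 && s2m > 0) sdm / sqrt(s2d * s2m)
               else NA_real_
    )
  }
  out <- bind_rows(rows)
  if (t == 2) {
    out$rho_d <- if (G0[1, 1] > 0 && G0[2, 2] > 0) {
      G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2])
    } else NA_real_
    out$rho_m <- if (has_m && G0[t + 1, t + 1] > 0 && G0[t + 2, t + 2] > 0) {
      G0[t + 1, t + 2] / sqrt(G0[t + 1, t + 1] * G0[t + 2, t + 2])
    } else NA_real_
  }
  out
}

#' Shortest 95% highest-posterior-density interval
#'
#' Chen--Shao estimator: among all windows of `ceiling(prob * n)`
#' consecutive sorted draws, the shortest one.
#'
#' @param x Numeric vector of posterior draws.
#' @param prob Interval probability (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(prob * n)
  if (k >= n) return(c(x[1], x[n]))
  i <- seq_len(n - k + 1)
  w <- x[i + k - 1] - x[i]
  j <- which.min(w)
  c(x[j], x[j + k - 1])
}

# histogram-midpoint mode (50 equal bins); presentation-only summary
hist_mode <- function(x, bins = 50) {
  if (length(unique(x)) == 1) return(x[1])
  br <- seq(min(x), max(x), length.out = bins + 1)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  b <- which.max(cnt)
  (br[b] + br[b + 1]) / 2
}

#' Posterior summaries of retained draws
#'
#' Mean, median, histogram-midpoint mode (50 bins), posterior SD and the
#' shortest 95% HPD interval for each parameter.
#'
#' @param x A numeric vector of draws, or a data frame of draws (one
#'   column per parameter).
#' @param prob HPD probability.
#' @return A tibble with one row per parameter.
#' @export
posterior_summary <- function(x, prob = 0.95) {
  if (is.data.frame(x)) {
    num <- x[vapply(x, is.numeric, TRUE)]
    return(bind_rows(lapply(names(num), function(nm) {
      mutate(posterior_summary(num[[nm]], prob), term = nm, .before = 1)
    })))
  }
  x <- x[!is.na(x)]
  if (length(x) < 30) abort("need at least 30 retained samples to summarize")
  h <- hpd_interval(x, prob)
  tibble(mean = mean(x), median = median(x), mode = hist_mode(x),
         sd = sd(x), hpd_lower = h[1], hpd_upper = h[2], n = length(x))
}

#' @export
tidy.animal_model_fit <- function(x, parameters = c("derived", "all"), ...) {
  parameters <- match.arg(parameters)
  d <- x$draws
  if (parameters == "derived") {
    keep <- grep("^(h2d|h2m|c2|me2|rho_|sigma2_P)", names(d), value = TRUE)
    d <- d[, keep, drop = FALSE]
  }
  posterior_summary(d)
}

#' @export
glance.animal_model_fit <- function(x, ...) {
  tibble(model = x$spec$model_id, n_traits = x$spec$n_traits,
         n_records = x$dims$n_records, n_animals = x$dims$n_animals,
         iterations = x$settings$iterations, burn_in = x$settings$burn_in,
         thin = x$settings$thin, n_retained = x$settings$n_retained)
}

#' @export
print.animal_model_fit <- function(x, ...) {
  cat(sprintf("Animal model %d (%s), %d records, %d retained draws\n",
              x$spec$model_id, paste(x$spec$traits, collapse = " + "),
              x$dims$n_records, x$settings$n_retained))
  print(tidy(x))
  invisible(x)
}

#' Fit the bivariate battery against a reference trait
#'
#' Fits one bivariate Model 4 (direct + maternal genetic + litter) per
#' (reference trait, other trait) pair --- the reference is typically the
#' selection trait --- and summarises the genetic parameters of each fit:
#' per-trait heritabilities and ratios, the within-trait direct-maternal
#' correlation for the companion trait, and the cross-trait direct and
#' maternal correlations.
#'
#' @inheritParams fit_animal_model
#' @param traits Character vector; the first element is the reference
#'   trait included in every fit.
#' @param model Model id (default 4).
#' @return A tibble with one row per non-reference trait, giving posterior
#'   means and HPD95 bounds of `h2d`, `h2m`, `c2`, `rho_dm` (companion
#'   trait) and `rho_d`, `rho_m`.
#' @export
fit_bivariate_battery <- function(phenotypes, pedigree, traits, model = 4,
                                  fixed = c("sex", "month"),
                                  litter_col = "litter",
                                  iterations = 300000, burn_in = 20000,
                                  thin = 200, seed = NULL) {
  if (length(traits) < 2) abort("need the reference trait plus at least one other")
  ref <- traits[1]
  rows <- lapply(traits[-1], function(tr) {
    fit <- fit_animal_model(phenotypes, pedigree, traits = c(ref, tr),
                            model = model, fixed = fixed,
                            litter_col = litter_col,
                            iterations = iterations, burn_in = burn_in,
                            thin = thin, seed = seed)
    td <- tidy(fit)
    grab <- function(term) {
      r <- td[td$term == term, ]
      if (!nrow(r)) return(tibble(mean = NA_real_, lo = NA_real_, hi = NA_real_))
      tibble(mean = r$mean, lo = r$hpd_lower, hi = r$hpd_upper)
    }
    out <- tibble(trait = tr)
    for (p in c(paste0("h2d_", tr), paste0("h2m_", tr), paste0("c2_", tr),
                paste0("rho_dm_", tr), "rho_d", "rho_m")) {
      g <- grab(p)
      base <- sub(paste0("_", tr, "$"), "", p)
      out[[base]] <- g$mean
      out[[paste0(base, "_lo")]] <- g$lo
      out[[paste0(base, "_hi")]] <- g$hi
    }
    out
  })
  bind_rows(rows)
}
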