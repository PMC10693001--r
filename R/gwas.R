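#' Rank-based normal quantile transform
#'
#' Maps values to `qnorm((rank - 0.5) / m)` over the `m` non-missing values,
#' with average ranks for ties. Missing values stay missing.
#'
#' @param values Numeric vector with at least 5 non-missing values.
#' @return Transformed vector of the same length.
#' @export
quantile_normalize <- function(values) {
  ok <- !is.na(values)
  m <- sum(ok)
  if (m < 3) stop("need at least 3 non-missing values")
  if (length(unique(values[ok])) == 1) stop("all values identical: transform undefined")
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / m)
  out
}

#' Regress sex out of a trait
#'
#' Ordinary least-squares residuals of the trait on a sex indicator,
#' applied before the quantile transform. If only one sex is present the
#' trait is returned unchanged with a warning.
#'
#' @param values Numeric trait vector.
#' @param sex Factor/character of the same length (e.g. M/F).
#' @return Residual vector (missing values stay missing).
#' @export
regress_out_sex <- function(values, sex) {
  stopifnot(length(values) == length(sex))
  ok <- !is.na(values) & !is.na(sex)
  if (length(unique(sex[ok])) < 2) {
    warning("only one sex present: trait returned unchanged")
    return(values)
  }
  out <- rep(NA_real_, length(values))
  fit <- lm(values[ok] ~ factor(sex[ok]))
  out[ok] <- resid(fit)
  out
}

#' Prepare a trait for association analysis
#'
#' Sex regression followed by the rank-based normal quantile transform.
#'
#' @inheritParams regress_out_sex
#' @return Prepared trait vector (mean ~ 0, sd ~ 1 over non-missing values).
#' @export
prepare_trait <- function(values, sex = NULL) {
  if (!is.null(sex)) values <- regress_out_sex(values, sex)
  quantile_normalize(values)
}

as_dosage_matrix <- function(genotypes) {
  if (inherits(genotypes, "sv_cohort")) t(genotypes$geno) else as.matrix(genotypes)
}

# mean-impute and center per locus; optionally scale to unit variance.
# X: individuals x loci. Returns list(X, means, sds, kept).
standardize_loci <- function(X, scale = TRUE) {
  X <- apply(X, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  means <- colMeans(X)
  sds <- apply(X, 2, sd)
  kept <- sds > 0
  Xs <- sweep(X[, kept, drop = FALSE], 2, means[kept])
  if (scale) Xs <- sweep(Xs, 2, sds[kept], "/")
  list(X = Xs, means = means[kept], sds = sds[kept], kept = kept)
}

#' Genomic kinship matrix
#'
#' Centered cross-product of dosages: missing dosages are mean-imputed per
#' locus, loci are centered (not scaled) and `K = W W' / p` over the `p`
#' loci. Symmetric and positive semidefinite by construction.
#'
#' @param genotypes An [sv_cohort()] or an individuals x loci dosage matrix.
#' @return Individuals x individuals kinship matrix.
#' @export
kinship <- function(genotypes) {
  X <- as_dosage_matrix(genotypes)
  if (ncol(X) == 0) stop("no loci to compute kinship from")
  W <- standardize_loci(X, scale = FALSE)$X
  K <- W %*% t(W) / ncol(X)
  rownames(K) <- colnames(K) <- rownames(X)
  K
}

#' MCMC configuration for the sparse Bayesian LMM
#'
#' Desk-scale defaults: burn-in 10,000 steps, 100,000 sampling steps thinned
#' every 10, 4 chains. Each step performs `geno_updates` spike-slab locus
#' updates, a Gibbs sweep of the polygenic random effect and intercept, and
#' one random-walk Metropolis update of each hyperparameter. Setting a step
#' size to 0 holds that hyperparameter at its initial value (used to force
#' the model into its ridge-regression or pure-LMM limits).
#'
#' @param burnin,steps,thin,n_chains MCMC schedule; `thin <= steps`.
#' @param geno_updates Locus updates per step.
#' @param step_se,step_h,step_rho,step_logpi Random-walk step sizes.
#' @param init_h,init_rho Initial (or fixed) hyperparameter values.
#' @param init_pi Initial (or fixed) inclusion probability; default
#'   `min(10, p) / p`, chosen at fit time when `NULL`.
#' @return A `bslmm_control` list.
#' @export
bslmm_control <- function(burnin = 10000, steps = 100000, thin = 10,
                          n_chains = 4, geno_updates = 20, step_se = 0.25,
                          step_h = 0.1, step_rho = 0.15, step_logpi = 0.5,
                          init_h = 0.5, init_rho = 0.5, init_pi = NULL) {
  stopifnot(steps > 0, burnin >= 0, thin >= 1, thin <= steps, n_chains >= 1)
  structure(list(burnin = as.integer(burnin), steps = as.integer(steps),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 geno_updates = as.integer(geno_updates), step_se = step_se,
                 step_h = step_h, step_rho = step_rho,
                 step_logpi = step_logpi, init_h = init_h,
                 init_rho = init_rho, init_pi = init_pi),
            class = "bslmm_control")
}

#' Fit a Bayesian sparse linear mixed model
#'
#' Samples the posterior of `y = 1 mu + X beta + u + eps` with a spike-slab
#' prior on the per-locus effects (`beta_j` nonzero with probability `pi`,
#' normal slab) and a polygenic random effect `u ~ N(0, sigma_b^2 K)`.
#' Hyperpriors: `h ~ U(0,1)`, `rho ~ U(0,1)`,
#' `log pi ~ U(log 1/p, 0)`. Loci are mean-imputed, centered and scaled to
#' unit variance before fitting. Per posterior sample, PVE is the sample
#' variance of the genetic value `X beta + u` across individuals divided by
#' that variance plus `sigma_e^2`; the per-variant posterior inclusion
#' probability (PIP) is the fraction of samples including the variant, and
#' the model-averaged effect is the mean of `gamma_j beta_j`. Chains are
#' reproducible bit-for-bit given `(seed, control)`.
#'
#' @param y Numeric trait vector (no non-finite values).
#' @param genotypes An [sv_cohort()] or individuals x loci dosage matrix.
#' @param K Kinship matrix; computed from `genotypes` when `NULL`.
#' @param control A [bslmm_control()].
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @return Object of class `bslmm_fit` with posterior `samples` (tibble),
#'   per-variant tibble `variants` (`id`, `pip`, `beta_bar`), PVE summary and
#'   the standardization info needed for prediction.
#' @export
bslmm_fit <- function(y, genotypes, K = NULL, control = bslmm_control(),
                      seed = 1) {
  X <- as_dosage_matrix(genotypes)
  if (any(!is.finite(y))) stop("trait contains non-finite values")
  stopifnot(length(y) == nrow(X))
  if (is.null(K)) K <- kinship(X)
  std <- standardize_loci(X)
  Xs <- std$X
  p <- ncol(Xs)
  if (p == 0) stop("no polymorphic loci to fit")
  ids <- colnames(X)[std$kept] %||% paste0("locus_", which(std$kept))
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  kappa <- mean(diag(K))
  if (!(kappa > 0)) stop("kinship matrix has zero trace")
  ytil <- drop(crossprod(U, y))
  Xtil <- crossprod(U, Xs)
  onetil <- drop(crossprod(U, rep(1, length(y))))
  init_pi <- control$init_pi %||% (min(10, p) / p)
  chains <- lapply(seq_len(control$n_chains), function(ch) {
    set.seed(seed + ch - 1L)
    res <- bslmm_mcmc_cpp(ytil, Xtil, onetil, d, kappa, control$burnin,
                          control$steps, control$thin, control$geno_updates,
                          control$step_se, control$step_h, control$step_rho,
                          control$step_logpi, control$init_h,
                          control$init_rho, log(init_pi))
    res
  })
  acc <- Reduce(`+`, lapply(chains, `[[`, "accept"))
  prop <- Reduce(`+`, lapply(chains, `[[`, "proposed"))
  rate <- ifelse(prop > 0, acc / prop, NA_real_)
  samples <- dplyr::bind_rows(lapply(seq_along(chains), function(ch) {
    s <- tibble::as_tibble(as.data.frame(chains[[ch]]$samples))
    s$chain <- ch
    s
  }))
  # a hyperparameter whose posterior has collapsed to a point (boundary
  # posteriors under noise-free traits) legitimately stops moving; only an
  # unpinned parameter with ~zero acceptance signals divergence
  moving <- vapply(list(samples$h, samples$rho, samples$pi),
                   function(x) sd(x) > 1e-3, logical(1))
  if (control$steps >= 2000 && any(!is.na(rate[2:4]) & rate[2:4] < 0.01 & moving)) {
    stop("MCMC divergence: hyperparameter acceptance rates ",
         paste(sprintf("%.4f", rate[2:4]), collapse = ", "),
         " (h, rho, logpi); reduce step sizes")
  }
  pip <- Reduce(`+`, lapply(chains, `[[`, "pip")) / length(chains)
  beta_bar <- Reduce(`+`, lapply(chains, `[[`, "beta_bar")) / length(chains)
  sb2 <- (1 - samples$rho) * samples$h / (1 - samples$h) *
    samples$sigma_e2 / kappa
  structure(list(
    samples = samples,
    variants = tibble::tibble(id = ids, pip = pip, beta_bar = beta_bar),
    pve_mean = mean(samples$pve), pve_sd = sd(samples$pve),
    mu_mean = mean(samples$mu), se2_mean = mean(samples$sigma_e2),
    sb2_mean = mean(sb2),
    acceptance = rate, kappa = kappa,
    std = std, n = length(y), p = p, control = control, seed = seed
  ), class = "bslmm_fit")
}

#' @exportS3Method base::print
print.bslmm_fit <- function(x, ...) {
  cat(sprintf("<bslmm_fit> n = %d individuals, p = %d loci, %d samples\n",
              x$n, x$p, nrow(x$samples)))
  cat(sprintf("  PVE %.3f +/- %.3f | top PIP %.3f (%s)\n", x$pve_mean,
              x$pve_sd, max(x$variants$pip),
              x$variants$id[which.max(x$variants$pip)]))
  invisible(x)
}

#' @export
tidy.bslmm_fit <- function(x, ...) x$variants

#' @export
glance.bslmm_fit <- function(x, ...) {
  tibble::tibble(
    pve = x$pve_mean, pve_sd = x$pve_sd,
    pge = mean(x$samples$rho), pi = mean(x$samples$pi),
    n_gamma = mean(x$samples$n_gamma),
    n = x$n, p = x$p, n_samples = nrow(x$samples),
    n_chains = x$control$n_chains
  )
}

# standardize test genotypes with training means/sds and form the
# polygenic-score prediction mu + x beta_bar + E[u_test | training residual]
predict_masked <- function(fit, X_test, K_ct, K_tt, y_train, X_train) {
  Xs_te <- sweep(X_test[, fit$std$kept, drop = FALSE], 2, fit$std$means)
  Xs_te <- sweep(Xs_te, 2, fit$std$sds, "/")
  Xs_tr <- sweep(X_train[, fit$std$kept, drop = FALSE], 2, fit$std$means)
  Xs_tr <- sweep(Xs_tr, 2, fit$std$sds, "/")
  fixed <- fit$mu_mean + drop(Xs_te %*% fit$variants$beta_bar)
  r_tr <- y_train - fit$mu_mean - drop(Xs_tr %*% fit$variants$beta_bar)
  V <- fit$sb2_mean * K_tt + fit$se2_mean * diag(nrow(K_tt))
  u_hat <- fit$sb2_mean * drop(K_ct %*% solve(V, r_tr))
  fixed + u_hat
}

#' Polygenic-score cross-validation with masked phenotypes
#'
#' Splits individuals into `n_folds` random disjoint folds (sizes
#' `floor(n / n_folds)` with the remainder spread), refits the sparse
#' Bayesian LMM with each fold's phenotypes masked, and predicts the masked
#' individuals from the model-averaged effects plus the conditional mean of
#' the kinship random effect given the training residuals. Every individual
#' is predicted exactly once; the final correlation and p value come from an
#' ordinary linear model of observed on predicted values.
#'
#' @inheritParams bslmm_fit
#' @param n_folds Number of folds (default 4 = 25% masked per fold).
#' @param seed Seed controlling fold assignment and the fold fits.
#' @return Object of class `pgs_result` with `predictions` (tibble:
#'   `individual`, `fold`, `observed`, `predicted`), `r`, `p_value`.
#' @export
pgs_crossval <- function(y, genotypes, K = NULL, control = bslmm_control(),
                         n_folds = 4, seed = 1) {
  X <- as_dosage_matrix(genotypes)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(K)) K <- kinship(X)
  fold <- withr_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  if (min(table(fold)) < 2) stop("a fold has fewer than 2 individuals")
  pred <- rep(NA_real_, n)
  for (f in seq_len(n_folds)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    fit <- bslmm_fit(y[tr], X[tr, , drop = FALSE], K = K[tr, tr],
                     control = control, seed = seed + f)
    pred[te] <- predict_masked(fit, X[te, , drop = FALSE], K[te, tr],
                               K[tr, tr], y[tr], X[tr, , drop = FALSE])
  }
  lmfit <- lm(y ~ pred)
  r <- cor(y, pred)
  p_value <- summary(lmfit)$coefficients["pred", "Pr(>|t|)"]
  structure(list(
    predictions = tibble::tibble(
      individual = rownames(X) %||% paste0("ind_", seq_len(n)),
      fold = fold, observed = y, predicted = pred),
    r = r, p_value = p_value, n_folds = n_folds, seed = seed
  ), class = "pgs_result")
}

#' @exportS3Method base::print
print.pgs_result <- function(x, ...) {
  cat(sprintf("<pgs_result> %d individuals, %d folds: r = %.3f (p = %.3g)\n",
              nrow(x$predictions), x$n_folds, x$r, x$p_value))
  invisible(x)
}

#' @export
glance.pgs_result <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, n = nrow(x$predictions),
                 n_folds = x$n_folds)
}

#' Genetic correlations between traits from model-averaged effects
#'
#' For each trait pair, takes the union of variants whose PIP exceeds
#' `pip_threshold` in either trait and computes the Pearson correlation of
#' the model-averaged effects across those variants. Pairs with fewer than 3
#' selected variants are flagged undefined (`NA`).
#'
#' @param fits Named list of [bslmm_fit()] objects over the same loci.
#' @param pip_threshold Minimum PIP for a variant to enter a pair.
#' @return Trait x trait correlation matrix with unit diagonal.
#' @export
genetic_correlation <- function(fits, pip_threshold = 0.01) {
  stopifnot(length(fits) >= 2)
  nm <- names(fits) %||% paste0("trait_", seq_along(fits))
  out <- diag(1, length(fits))
  dimnames(out) <- list(nm, nm)
  for (i in seq_along(fits)) {
    for (j in seq_along(fits)) {
      if (j <= i) next
      vi <- fits[[i]]$variants
      vj <- fits[[j]]$variants
      common <- intersect(vi$id, vj$id)
      vi <- vi[match(common, vi$id), ]
      vj <- vj[match(common, vj$id), ]
      sel <- vi$pip > pip_threshold | vj$pip > pip_threshold
      out[i, j] <- out[j, i] <-
        if (sum(sel) < 3) NA_real_ else cor(vi$beta_bar[sel], vj$beta_bar[sel])
    }
  }
  out
}
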