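test_that("quantile normalization has its closed form and properties", {
  got <- quantile_normalize(c(7, 1, 4))
  expect_equal(sort(got), qnorm(c(1, 3, 5) / 6))
  expect_equal(order(got), order(c(7, 1, 4)))

  set.seed(51)
  x <- c(rlnorm(200), NA, NA)
  qn <- quantile_normalize(x)
  expect_equal(sum(is.na(qn)), 2)
  expect_lt(abs(mean(qn, na.rm = TRUE)), 1e-10)
  expect_equal(sd(qn, na.rm = TRUE), 1, tolerance = 0.05)
  expect_equal(order(x[1:200]), order(qn[1:200]))
  expect_error(quantile_normalize(rep(3, 10)), "identical")
})

test_that("sex regression leaves residuals orthogonal to sex", {
  sex <- rep(c("M", "F"), each = 20)
  flat <- ifelse(sex == "M", 3, -1)
  expect_equal(regress_out_sex(flat, sex), rep(0, 40), tolerance = 1e-12)

  set.seed(52)
  y <- rnorm(40) + (sex == "M") * 0.8
  r <- regress_out_sex(y, sex)
  expect_lt(abs(sum(r * (sex == "M"))), 1e-10)
  expect_warning(one <- regress_out_sex(y, rep("M", 40)), "one sex")
  expect_equal(one, y)
})

test_that("kinship is a PSD centered cross-product with the trace identity", {
  set.seed(53)
  X <- matrix(rbinom(30 * 100, 2, runif(100, 0.1, 0.9)), 30, 100,
              byrow = TRUE)
  X[2, ] <- X[1, ]
  K <- kinship(X)
  expect_equal(K, t(K))
  expect_equal(K[1, ], K[2, ])
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # trace = sum of per-locus dosage variances * (n-1)/p
  expect_equal(sum(diag(K)),
               sum(apply(X, 2, var)) * (nrow(X) - 1) / ncol(X),
               tolerance = 1e-10)
})

test_that("the sparse Bayesian LMM is reproducible and finds perfect signals", {
  set.seed(54)
  n <- 80; p <- 150
  X <- matrix(rbinom(n * p, 2, runif(p, 0.2, 0.8)), n, p, byrow = TRUE)
  colnames(X) <- paste0("v", seq_len(p))
  ctrl <- bslmm_control(burnin = 500, steps = 3000, thin = 5, n_chains = 2,
                        geno_updates = 30)
  y <- X[, 42] + rnorm(n, 0, 0.3)
  f1 <- bslmm_fit(y, X, control = ctrl, seed = 9)
  f2 <- bslmm_fit(y, X, control = ctrl, seed = 9)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$variants, f2$variants)
  expect_equal(f1$variants$id[which.max(f1$variants$pip)], "v42")
  expect_gt(max(f1$variants$pip), 0.9)
  expect_error(bslmm_fit(c(y[-1], NA), X, control = ctrl), "non-finite")
})

test_that("chains with different seeds agree on PVE within Monte Carlo error", {
  set.seed(55)
  n <- 120; p <- 300
  X <- matrix(rbinom(n * p, 2, runif(p, 0.2, 0.8)), n, p, byrow = TRUE)
  sim <- simulate_phenotypes(X, focal_share = 0, h2 = 0.5, seed = 56)
  ctrl <- bslmm_control(burnin = 2000, steps = 12000, thin = 10,
                        n_chains = 2, geno_updates = 30)
  fa <- bslmm_fit(sim$trait, X, control = ctrl, seed = 100)
  fb <- bslmm_fit(sim$trait, X, control = ctrl, seed = 900)
  mcse <- function(f) f$pve_sd / sqrt(nrow(f$samples) / 20)  # lag-adjusted
  expect_lt(abs(fa$pve_mean - fb$pve_mean), 2 * (mcse(fa) + mcse(fb)))
})

test_that("forcing pi = rho = 1 reduces the model to Bayesian ridge regression", {
  set.seed(57)
  n <- 120; p <- 5
  X <- matrix(rbinom(n * p, 2, 0.5), n, p)
  colnames(X) <- paste0("v", 1:p)
  beta <- c(0.8, -0.5, 0, 0.3, 0)
  y <- drop(scale(X) %*% beta) + rnorm(n, 0, 0.7)
  K <- diag(n)  # no polygenic structure
  h_fix <- 0.5
  ctrl <- bslmm_control(burnin = 3000, steps = 30000, thin = 10,
                        n_chains = 2, geno_updates = 25,
                        step_h = 0, step_rho = 0, step_logpi = 0,
                        init_h = h_fix, init_rho = 1, init_pi = 1)
  f <- bslmm_fit(y, X, K = K, control = ctrl, seed = 58)
  # closed form: with sa2/se2 = h/((1-h) p) fixed, the posterior mean of
  # beta is ridge with lambda = (1-h) p / h, independent of sigma_e^2
  Xs <- scale(X)
  lambda <- (1 - h_fix) * p / h_fix
  yc <- y - mean(y)
  ridge <- solve(crossprod(Xs) + lambda * diag(p), crossprod(Xs, yc))
  expect_equal(unname(f$variants$beta_bar), unname(drop(ridge)), tolerance = 0.05)
  expect_true(all(f$variants$pip == 1))
})

test_that("forcing rho = 0 reduces the fit to the kinship-only LMM", {
  set.seed(59)
  n <- 150; p <- 400
  X <- matrix(rbinom(n * p, 2, runif(p, 0.2, 0.8)), n, p, byrow = TRUE)
  sim <- simulate_phenotypes(X, focal_share = 0, h2 = 0.6, seed = 60)
  y <- sim$trait
  K <- kinship(X)
  ctrl <- bslmm_control(burnin = 2000, steps = 10000, thin = 10,
                        n_chains = 2, geno_updates = 5,
                        step_rho = 0, init_rho = 0)
  f <- bslmm_fit(y, X, K = K, control = ctrl, seed = 61)
  # the slab variance is driven to zero, so sparse effects vanish
  expect_lt(max(abs(f$variants$beta_bar)), 1e-4)
  # profile-likelihood LMM as the independent reference
  e <- eigen(K, symmetric = TRUE)
  d <- pmax(e$values, 0)
  yt <- drop(crossprod(e$vectors, y))
  ot <- drop(crossprod(e$vectors, rep(1, n)))
  nll <- function(par) {
    v <- exp(par[1]) * d + exp(par[2])
    mu <- sum(ot * yt / v) / sum(ot^2 / v)
    0.5 * sum(log(v)) + 0.5 * sum((yt - ot * mu)^2 / v)
  }
  o <- optim(c(0, 0), nll)
  sg2 <- exp(o$par[1]); se2 <- exp(o$par[2])
  h_ml <- sg2 * mean(diag(K)) / (sg2 * mean(diag(K)) + se2)
  expect_lt(abs(f$pve_mean - h_ml), 0.2)
})

test_that("PIP and PVE are invariant to locus permutation given one stream", {
  set.seed(62)
  n <- 80; p <- 120
  X <- matrix(rbinom(n * p, 2, runif(p, 0.2, 0.8)), n, p, byrow = TRUE)
  colnames(X) <- paste0("v", seq_len(p))
  y <- X[, 11] * 0.8 + rnorm(n, 0, 0.5)
  ctrl <- bslmm_control(burnin = 1000, steps = 8000, thin = 10,
                        n_chains = 2, geno_updates = 40)
  f1 <- bslmm_fit(y, X, control = ctrl, seed = 63)
  perm <- sample(p)
  f2 <- bslmm_fit(y, X[, perm], control = ctrl, seed = 63)
  expect_equal(f1$pve_mean, f2$pve_mean, tolerance = 0.05)
  top1 <- f1$variants$id[which.max(f1$variants$pip)]
  top2 <- f2$variants$id[which.max(f2$variants$pip)]
  expect_equal(top1, top2)
  expect_equal(max(f1$variants$pip), max(f2$variants$pip), tolerance = 0.1)
})

test_that("polygenic-score cross-validation partitions and reproduces", {
  set.seed(64)
  n <- 60; p <- 80
  X <- matrix(rbinom(n * p, 2, runif(p, 0.2, 0.8)), n, p, byrow = TRUE)
  sim <- simulate_phenotypes(X, focal_ids = 10, focal_effects = 1,
                             focal_share = 0.3, h2 = 0.4, seed = 65)
  ctrl <- bslmm_control(burnin = 300, steps = 1500, thin = 5, n_chains = 1,
                        geno_updates = 20)
  r1 <- pgs_crossval(sim$trait, X, control = ctrl, seed = 66)
  expect_equal(nrow(r1$predictions), n)
  expect_false(any(is.na(r1$predictions$predicted)))
  expect_equal(sort(unique(r1$predictions$fold)), 1:4)
  expect_equal(as.vector(table(r1$predictions$fold)), rep(15, 4))
  r2 <- pgs_crossval(sim$trait, X, control = ctrl, seed = 66)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("genetic correlations recover shared and independent architectures", {
  set.seed(67)
  n <- 150; p <- 250
  X <- matrix(rbinom(n * p, 2, runif(p, 0.2, 0.8)), n, p, byrow = TRUE)
  colnames(X) <- paste0("v", seq_len(p))
  Xs <- scale(X)
  b <- rnorm(20)
  idx <- sample(p, 20)
  g <- drop(Xs[, idx] %*% b)
  mk <- function(noise_seed) {
    set.seed(noise_seed)
    as.numeric(scale(g)) * sqrt(0.8) + rnorm(n, 0, sqrt(0.2))
  }
  ctrl <- bslmm_control(burnin = 1000, steps = 8000, thin = 10,
                        n_chains = 2, geno_updates = 50)
  f1 <- bslmm_fit(mk(1), X, control = ctrl, seed = 68)
  f2 <- bslmm_fit(mk(2), X, control = ctrl, seed = 69)
  gc <- genetic_correlation(list(t1 = f1, t2 = f2))
  expect_equal(diag(gc), c(t1 = 1, t2 = 1))
  expect_gt(gc["t1", "t2"], 0.8)

  # independent architectures: correlations stay small on average
  cors <- replicate(4, {
    sd1 <- sample.int(1e6, 1)
    y1 <- simulate_phenotypes(X, focal_share = 0, h2 = 0.6, seed = sd1)$trait
    y2 <- simulate_phenotypes(X, focal_share = 0, h2 = 0.6, seed = sd1 + 1)$trait
    fa <- bslmm_fit(y1, X, control = ctrl, seed = 70)
    fb <- bslmm_fit(y2, X, control = ctrl, seed = 71)
    genetic_correlation(list(a = fa, b = fb))["a", "b"]
  })
  expect_lt(mean(abs(cors), na.rm = TRUE), 0.35)
})
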