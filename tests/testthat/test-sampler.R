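make_state <- function(Z, W, H, pi, alpha, tau) gfa_state(Z, W, H, pi, alpha, tau)

test_that("the score conditional reduces to the prior when W = 0", {
  set.seed(31)
  st <- make_state(matrix(0, 500, 2), list(matrix(0, 3, 2)),
                   matrix(0L, 1, 2), c(0.5, 0.5),
                   list(matrix(1, 3, 2)), list(rep(1, 3)))
  X <- list(matrix(rnorm(1500), 500, 3))
  Z <- sample_Z_conditional(st, X)
  expect_lt(abs(mean(Z)), 3 / sqrt(1000))
  expect_lt(abs(var(as.vector(Z)) - 1), 3 * sqrt(2 / 1000))
})

test_that("the score conditional matches its closed form", {
  # M=1, D=1, K=1, w=1, tau=1, x=2: posterior N(1, 1/2)
  st1 <- make_state(matrix(0, 1, 1), list(matrix(1, 1, 1)),
                    matrix(1L, 1, 1), 0.5, list(matrix(1, 1, 1)),
                    list(1))
  X1 <- list(matrix(2, 1, 1))
  set.seed(32)
  draws <- replicate(40000, sample_Z_conditional(st1, prepare_views(X1))[1, 1])
  expect_lt(abs(mean(draws) - 1), 3 * sqrt(0.5 / 40000))
  expect_lt(abs(var(draws) - 0.5), 3 * 0.5 * sqrt(2 / 40000))

  # three-view toy state with a missing cell: analytic mean and covariance
  set.seed(33)
  W <- list(matrix(rnorm(4 * 2), 4, 2), matrix(rnorm(3 * 2), 3, 2),
            matrix(rnorm(2 * 2), 2, 2))
  tau <- list(c(1, 2, 0.5, 1.5), c(2, 2, 1), c(3, 0.5))
  st <- make_state(matrix(0, 1, 2), W, matrix(1L, 3, 2), c(0.5, 0.5),
                   lapply(W, function(w) matrix(1, nrow(w), 2)), tau)
  X <- list(matrix(rnorm(4), 1), matrix(rnorm(3), 1), matrix(rnorm(2), 1))
  X[[1]][1, 2] <- NA
  lam <- diag(2)
  b <- c(0, 0)
  for (m in 1:3) for (d in seq_len(ncol(X[[m]]))) {
    if (is.na(X[[m]][1, d])) next
    lam <- lam + tau[[m]][d] * tcrossprod(W[[m]][d, ])
    b <- b + tau[[m]][d] * X[[m]][1, d] * W[[m]][d, ]
  }
  Sig <- solve(lam); mu <- Sig %*% b
  gv <- prepare_views(X)
  draws <- t(replicate(100000, sample_Z_conditional(st, gv)[1, ]))
  se_m <- sqrt(diag(Sig) / 1e5)
  expect_true(all(abs(colMeans(draws) - mu) < 3 * se_m))
  emp <- cov(draws)
  expect_true(all(abs(emp - Sig) < 3 * sqrt(2 / 1e5) *
                    sqrt(tcrossprod(diag(Sig)))))
})

test_that("degenerate inclusion probabilities force the spike or the slab", {
  set.seed(34)
  st <- make_state(matrix(rnorm(3), 3, 1), list(matrix(0, 1, 1)),
                   matrix(0L, 1, 1), 0, list(matrix(1, 1, 1)), list(1))
  X <- list(matrix(rnorm(3), 3, 1))
  for (i in 1:20) {
    r <- sample_Wh_conditional(st, X, 1, 1)
    expect_equal(r$h, 0L)
    expect_true(all(r$w == 0))
  }
  st$pi <- 1
  hs <- replicate(20, sample_Wh_conditional(st, X, 1, 1)$h)
  expect_true(all(hs == 1L))
})

test_that("the blocked activation probability matches numerical quadrature", {
  # N=3, D=1, K=1: integrate the slab weight out numerically
  set.seed(35)
  z <- c(0.8, -1.4, 0.3)
  r <- c(1.2, -2.0, 0.7)
  tau <- 1.7; alpha <- 0.9; pi_k <- 0.35
  st <- make_state(matrix(z, 3, 1), list(matrix(0, 1, 1)),
                   matrix(0L, 1, 1), pi_k, list(matrix(alpha, 1, 1)),
                   list(tau))
  X <- list(matrix(r, 3, 1))
  got <- sample_Wh_conditional(st, X, 1, 1)$p1

  lik <- function(w) sapply(w, function(wi)
    prod(dnorm(r, z * wi, 1 / sqrt(tau))) * dnorm(wi, 0, 1 / sqrt(alpha)))
  m1 <- integrate(lik, -Inf, Inf, rel.tol = 1e-12)$value
  m0 <- prod(dnorm(r, 0, 1 / sqrt(tau)))
  want <- pi_k * m1 / (pi_k * m1 + (1 - pi_k) * m0)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("pi, alpha and tau conditionals are the stated conjugate updates", {
  set.seed(36)
  # pi: M = 5 views, sum h = 2, a = b = 1 -> Beta(3, 4)
  st <- make_state(matrix(0, 2, 1), rep(list(matrix(0, 1, 1)), 5),
                   matrix(c(1L, 1L, 0L, 0L, 0L), 5, 1), 0.5,
                   rep(list(matrix(1, 1, 1)), 5), rep(list(1), 5))
  hyper <- gfa_hyperparams(K = 1, a_pi = 1, b_pi = 1, a_alpha = 1,
                           b_alpha = 1, a_tau = 3, b_tau = 1)
  draws <- replicate(20000, sample_pi_conditional(st, hyper))
  expect_lt(abs(mean(draws) - 3 / 7), 3 * sqrt(3 / 7 * 4 / 7 / 8) / sqrt(20000))
  expect_lt(abs(var(draws) - 3 * 4 / (49 * 8)), 4 * var(draws) * sqrt(2 / 20000))
  # all h = 0 -> Beta(a, b + M)
  st0 <- st; st0$H[] <- 0L
  d0 <- replicate(20000, sample_pi_conditional(st0, hyper))
  expect_lt(abs(mean(d0) - 1 / 7), 3 * sd(d0) / sqrt(20000))

  # alpha: w = 0 under h = 1 -> Gamma(a + 1/2, b); h = 0 -> prior
  st_a <- make_state(matrix(0, 2, 2), list(matrix(0, 1, 2)),
                     matrix(c(1L, 0L), 1, 2), c(0.5, 0.5),
                     list(matrix(1, 1, 2)), list(1))
  da <- replicate(20000, as.vector(sample_alpha_conditional(st_a, hyper)[[1]]))
  a_on <- da[1, ]; a_off <- da[2, ]
  expect_lt(abs(mean(a_on) - 1.5), 3 * sqrt(1.5) / sqrt(20000))
  ks <- suppressWarnings(ks.test(a_off, pgamma, shape = 1, rate = 1))
  expect_gt(ks$p.value, 1e-3)
  # larger |w| shrinks alpha stochastically (the rate grows)
  st_b <- st_a; st_b$W[[1]][1, 1] <- 3
  db <- replicate(5000, sample_alpha_conditional(st_b, hyper)[[1]][1, 1])
  expect_lt(mean(db), mean(a_on))

  # tau: zero residuals over n obs -> Gamma(a_tau + n/2, b_tau); an
  # all-missing column keeps its prior
  Z <- matrix(rnorm(10), 10, 1)
  W <- list(matrix(c(1, 0.5), 2, 1))
  mu <- Z %*% t(W[[1]])
  Xt <- list(cbind(mu[, 1], rep(NA_real_, 10)))   # zero residual / all missing
  st_t <- make_state(Z, W, matrix(1L, 1, 1), 0.5,
                     list(matrix(1, 2, 1)), list(c(1, 1)))
  gv_t <- prepare_views(Xt)
  dt <- replicate(20000, sample_tau_conditional(st_t, gv_t, hyper)[[1]])
  t_fit <- dt[1, ]; t_prior <- dt[2, ]
  expect_lt(abs(mean(t_fit) - 8 / 1), 3 * sqrt(8) / sqrt(20000))     # Gamma(3+5, 1)
  expect_lt(abs(mean(t_prior) - 3 / 1), 3 * sqrt(3) / sqrt(20000))   # Gamma(3, 1)
})

test_that("repeated tau updates with Z, W clamped stay on the analytic conditional", {
  set.seed(37)
  hyper <- gfa_hyperparams(K = 1, a_tau = 3, b_tau = 1)
  Z <- matrix(rnorm(8), 8, 1)
  W <- list(matrix(1.2, 1, 1))
  X <- list(Z * 1.2 + matrix(rnorm(8, 0, 0.5), 8, 1))
  st <- make_state(Z, W, matrix(1L, 1, 1), 0.5, list(matrix(1, 1, 1)),
                   list(1))
  ssr <- sum((X[[1]] - Z * 1.2)^2)
  draws <- numeric(4000)
  for (i in seq_along(draws)) {
    st$tau <- sample_tau_conditional(st, X, hyper)
    draws[i] <- st$tau[[1]]
  }
  ks <- suppressWarnings(ks.test(draws, pgamma, shape = 3 + 4,
                                 rate = 1 + ssr / 2))
  expect_gt(ks$p.value, 1e-3)
})

test_that("chains are reproducible and validate their inputs", {
  sim <- tiny_sim(seed = 38)
  cfg <- chain_config(n_iter = 60, burnin_frac = 0.5, seed = 77)
  p1 <- run_chain(sim$views, gfa_hyperparams(K = 3), cfg)
  p2 <- run_chain(sim$views, gfa_hyperparams(K = 3), cfg)
  expect_identical(p1$H_draws, p2$H_draws)
  expect_identical(p1$Wmean, p2$Wmean)
  expect_identical(p1$logjoint, p2$logjoint)

  bad <- sim$views
  bad[[1]][2, 3] <- NaN
  expect_error(run_chain(bad, gfa_hyperparams(K = 3), cfg),
               class = "tgfa_nonfinite_data")
})

test_that("deterministic per-sweep quantities are permutation equivariant", {
  set.seed(39)
  sim <- tiny_sim(seed = 40)
  hyper <- gfa_hyperparams(K = 2, a_alpha = 2, b_alpha = 2, a_tau = 3,
                           b_tau = 1)
  st <- sample_prior(hyper, 30, c(6, 8))
  p_orig <- sample_Wh_conditional(st, sim$views, 1, 1)$p1
  perm <- c(4, 2, 6, 1, 5, 3)
  st_p <- st
  st_p$W[[1]] <- st$W[[1]][perm, ]
  st_p$alpha[[1]] <- st$alpha[[1]][perm, ]
  st_p$tau[[1]] <- st$tau[[1]][perm]
  views_p <- sim$views
  views_p[[1]] <- views_p[[1]][, perm]
  p_perm <- sample_Wh_conditional(st_p, views_p, 1, 1)$p1
  expect_equal(p_orig, p_perm, tolerance = 1e-12)
  expect_equal(as.numeric(log_joint(st, sim$views, hyper)),
               as.numeric(log_joint(st_p, views_p, hyper)),
               tolerance = 1e-10)
})

test_that("masking never-informative cells leaves component counts stable", {
  # a variable with zero loadings in truth carries no information; masking
  # half its entries should not move the posterior number of active
  # component-view pairs beyond seed noise
  tot <- function(views, seed) {
    post <- run_chain(views, gfa_hyperparams(K = 4),
                      chain_config(n_iter = 300, burnin_frac = 0.8,
                                   seed = seed))
    mean(rowSums(post$activity))
  }
  set.seed(41)
  mask <- rbind(c(1, 0), c(1, 1))
  sim <- simulate_difference_views(40, c(a = 6, b = 6), mask)
  # make variable 1 of view 1 pure noise in truth
  sim$views[[1]][, 1] <- rnorm(40) * sqrt(1 / 3)
  masked <- sim$views
  masked[[1]][seq(1, 39, by = 2), 1] <- NA
  a <- sapply(1:4, function(s) tot(sim$views, s))
  b <- sapply(1:4, function(s) tot(masked, 100 + s))
  expect_lt(abs(mean(a) - mean(b)),
            4 * sqrt(var(a) / 4 + var(b) / 4) + 0.25)
})
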