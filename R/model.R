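#' GFA hyperparameters
#'
#' Collects the number of components and every prior parameter of the
#' group factor analysis model
#' \deqn{x_n^{(m)} \sim N(W^{(m)} z_n, \Sigma^{(m)}), \quad z_n \sim N(0, I),}
#' \deqn{w_{d,k}^{(m)} \sim h_{m,k}\,N(0, 1/\alpha_{d,k}^{(m)}) + (1-h_{m,k})\,\delta_0,}
#' \deqn{h_{m,k} \sim \mathrm{Bernoulli}(\pi_k), \quad \pi_k \sim \mathrm{Beta}(a_\pi, b_\pi),
#'   \quad \alpha_{d,k}^{(m)} \sim \mathrm{Gamma}(a_\alpha, b_\alpha),}
#' with diagonal noise \eqn{\Sigma^{(m)} = \mathrm{diag}(1/\tau^{(m)})} and
#' \eqn{\tau_d^{(m)} \sim \mathrm{Gamma}(a_\tau, b_\tau(d))}. All Gamma
#' distributions use the shape--rate convention.
#'
#' The noise prior is informative: by default its rate is chosen per column
#' as \code{b_tau = noise_target * (a_tau - 1) * var(column)} so that the
#' prior mean residual variance equals \code{noise_target} (one-third by
#' default) of the observed column variance. Pass \code{b_tau} explicitly
#' (a scalar, or a list of per-column vectors, one per view) to override;
#' [run_chain()] resolves \code{b_tau = NULL} from the data.
#'
#' @param K number of latent components (study default 40).
#' @param a_pi,b_pi Beta prior parameters for the component inclusion
#'   probabilities \eqn{\pi_k}; defaults 1, 1 (uniform).
#' @param a_alpha,b_alpha Gamma shape and rate of the automatic relevance
#'   determination (ARD) prior on loading precisions; defaults 1e-3 (vague).
#' @param a_tau Gamma shape of the noise precision prior (strength of the
#'   informative noise prior); default 14.
#' @param noise_target prior-mean residual variance as a fraction of column
#'   variance, in (0,1); study default 1/3.
#' @param b_tau optional explicit Gamma rate(s) for the noise precisions:
#'   \code{NULL} (resolve from data), a scalar, or a list of numeric vectors
#'   (one per view, recycled along columns).
#' @return an object of class \code{gfa_hyper}.
#' @export
gfa_hyperparams <- function(K = 40, a_pi = 1, b_pi = 1,
                            a_alpha = 1e-3, b_alpha = 1e-3,
                            a_tau = 14, noise_target = 1 / 3,
                            b_tau = NULL) {
  stopifnot(K >= 1, a_pi > 0, b_pi > 0, a_alpha > 0, b_alpha > 0, a_tau > 0)
  if (!(noise_target > 0 && noise_target < 1))
    tgfa_stop("tgfa_bad_hyper", "noise_target must lie in (0, 1)")
  if (!is.null(b_tau) && !is.list(b_tau)) b_tau <- as.numeric(b_tau)
  structure(
    list(K = as.integer(K), a_pi = a_pi, b_pi = b_pi,
         a_alpha = a_alpha, b_alpha = b_alpha,
         a_tau = a_tau, noise_target = noise_target, b_tau = b_tau),
    class = "gfa_hyper"
  )
}

# Resolve hyper$b_tau into a list of per-column rate vectors, one per view.
# With b_tau = NULL the informative rule is applied per column:
# b_tau_d = noise_target * (a_tau - 1) * observed column variance, so that
# E[1/tau_d] = b_tau_d / (a_tau - 1) = noise_target * var_d. Unit-variance
# (standardized) columns then get the scalar rule; the unscaled genotype
# view gets a rate proportional to its own column variances.
resolve_b_tau <- function(hyper, views) {
  M <- length(views)
  if (is.null(hyper$b_tau)) {
    if (hyper$a_tau <= 1)
      tgfa_stop("tgfa_bad_hyper",
                "data-derived noise rate needs a_tau > 1; pass b_tau explicitly")
    lapply(views, function(X) {
      v <- apply(X, 2, stats::var, na.rm = TRUE)
      v[!is.finite(v) | v <= 0] <- 1
      hyper$noise_target * (hyper$a_tau - 1) * v
    })
  } else if (is.list(hyper$b_tau)) {
    stopifnot(length(hyper$b_tau) == M)
    lapply(seq_len(M), function(m) rep_len(hyper$b_tau[[m]], ncol(views[[m]])))
  } else {
    lapply(views, function(X) rep_len(hyper$b_tau, ncol(X)))
  }
}

#' Construct a latent state of the GFA model
#'
#' Low-level constructor used by the sampler and the simulator; validates
#' the spike convention (loading columns with \eqn{h_{m,k} = 0} are exactly
#' zero) and positivity constraints.
#'
#' @param Z N x K score matrix.
#' @param W list of D_m x K loading matrices.
#' @param H M x K binary component-activity matrix.
#' @param pi length-K inclusion probabilities in (0,1) (endpoints tolerated
#'   for degenerate tests).
#' @param alpha list of D_m x K positive ARD precision matrices.
#' @param tau list of length-D_m positive noise precision vectors.
#' @return an object of class \code{gfa_state}.
#' @export
gfa_state <- function(Z, W, H, pi, alpha, tau) {
  M <- length(W); K <- ncol(Z)
  stopifnot(is.matrix(Z), is.matrix(H), nrow(H) == M, ncol(H) == K,
            length(pi) == K, length(alpha) == M, length(tau) == M)
  for (m in seq_len(M)) {
    if (any(!is.finite(alpha[[m]])) || any(alpha[[m]] <= 0) ||
        any(!is.finite(tau[[m]])) || any(tau[[m]] <= 0))
      tgfa_stop("tgfa_bad_state", "alpha and tau entries must be positive")
    off <- which(H[m, ] == 0)
    if (length(off) && any(W[[m]][, off, drop = FALSE] != 0))
      tgfa_stop("tgfa_spike_violation", sprintf(
        "view %d has nonzero loadings in a component with h = 0", m))
  }
  structure(list(Z = Z, W = W, H = H, pi = pi, alpha = alpha, tau = tau),
            class = "gfa_state")
}

#' Draw a latent state from the prior
#'
#' Samples \eqn{\pi, H, \alpha, W, \tau, Z} from the model priors. Uses R's
#' global random number generator; call [set.seed()] for reproducibility.
#'
#' @param hyper a [gfa_hyperparams()] object with `b_tau` resolved (scalar
#'   or per-view list); a `NULL` `b_tau` defaults to
#'   `noise_target * (a_tau - 1)` per column (unit-variance convention).
#' @param n number of samples (twin pairs).
#' @param d integer vector of per-view dimensions D_1..D_M.
#' @return a \code{gfa_state}.
#' @export
sample_prior <- function(hyper, n, d) {
  stopifnot(n >= 1, all(d >= 1))
  M <- length(d); K <- hyper$K
  b_tau <- if (is.null(hyper$b_tau)) {
    lapply(d, function(dm) rep(hyper$noise_target * max(hyper$a_tau - 1, 1e-8), dm))
  } else if (is.list(hyper$b_tau)) {
    lapply(seq_len(M), function(m) rep_len(hyper$b_tau[[m]], d[m]))
  } else {
    lapply(d, function(dm) rep_len(hyper$b_tau, dm))
  }
  pi <- rbeta(K, hyper$a_pi, hyper$b_pi)
  H <- matrix(rbinom(M * K, 1L, rep(pi, each = M)), M, K)
  alpha <- lapply(seq_len(M), function(m)
    matrix(rgamma(d[m] * K, hyper$a_alpha, rate = hyper$b_alpha), d[m], K))
  W <- lapply(seq_len(M), function(m) {
    Wm <- matrix(0, d[m], K)
    for (k in seq_len(K)) if (H[m, k] == 1L)
      Wm[, k] <- rnorm(d[m], 0, 1 / sqrt(alpha[[m]][, k]))
    Wm
  })
  tau <- lapply(seq_len(M), function(m)
    rgamma(d[m], hyper$a_tau, rate = b_tau[[m]]))
  Z <- matrix(rnorm(n * K), n, K)
  gfa_state(Z, W, H, pi, alpha, tau)
}

#' Generate data views from a latent state
#'
#' Draws \eqn{X^{(m)}} with rows \eqn{x_n^{(m)} \sim N(W^{(m)} z_n,
#' \mathrm{diag}(1/\tau^{(m)}))}, independently across samples and views.
#'
#' @param state a \code{gfa_state}.
#' @return list of N x D_m matrices (no missing values).
#' @export
generate_from_state <- function(state) {
  n <- nrow(state$Z)
  lapply(seq_along(state$W), function(m) {
    W <- state$W[[m]]; dm <- nrow(W)
    mu <- state$Z %*% t(W)
    mu + matrix(rnorm(n * dm), n, dm) %*% diag(1 / sqrt(state$tau[[m]]),
                                               nrow = dm)
  })
}

#' Exact log joint density of state and data
#'
#' Sum of the observed-data Gaussian log likelihood (missing cells omitted)
#' and every prior log density. The spike is handled as the discrete
#' \eqn{h_{m,k}} term plus the slab density only where \eqn{h_{m,k} = 1};
#' a state with nonzero loadings under \eqn{h = 0} is an error.
#'
#' @param state a \code{gfa_state}.
#' @param views list of N x D_m matrices; \code{NA} marks missing cells.
#' @param hyper a [gfa_hyperparams()] object; \code{b_tau} resolved from the
#'   views if \code{NULL}.
#' @return scalar log density, with attribute \code{"terms"} giving the
#'   named components (likelihood, z, w, h, pi, alpha, tau).
#' @export
log_joint <- function(state, views, hyper) {
  M <- length(views); K <- hyper$K
  b_tau <- resolve_b_tau(hyper, views)
  for (m in seq_len(M)) {
    off <- which(state$H[m, ] == 0)
    if (length(off) && any(state$W[[m]][, off, drop = FALSE] != 0))
      tgfa_stop("tgfa_spike_violation",
                "nonzero loading in an inactive component")
  }
  lik <- 0
  for (m in seq_len(M)) {
    mu <- state$Z %*% t(state$W[[m]])
    sdv <- rep(1 / sqrt(state$tau[[m]]), each = nrow(views[[m]]))
    ll <- dnorm(views[[m]], mean = mu, sd = sdv, log = TRUE)
    lik <- lik + sum(ll[!is.na(views[[m]])])
  }
  lp_z <- sum(dnorm(state$Z, log = TRUE))
  lp_w <- 0; lp_h <- 0; lp_alpha <- 0; lp_tau <- 0
  for (m in seq_len(M)) {
    on <- which(state$H[m, ] == 1)
    if (length(on))
      lp_w <- lp_w + sum(dnorm(state$W[[m]][, on, drop = FALSE], 0,
                               1 / sqrt(state$alpha[[m]][, on, drop = FALSE]),
                               log = TRUE))
    lp_h <- lp_h + sum(dbinom(state$H[m, ], 1, state$pi, log = TRUE))
    lp_alpha <- lp_alpha + sum(dgamma(state$alpha[[m]], hyper$a_alpha,
                                      rate = hyper$b_alpha, log = TRUE))
    lp_tau <- lp_tau + sum(dgamma(state$tau[[m]], hyper$a_tau,
                                  rate = b_tau[[m]], log = TRUE))
  }
  lp_pi <- sum(dbeta(state$pi, hyper$a_pi, hyper$b_pi, log = TRUE))
  out <- lik + lp_z + lp_w + lp_h + lp_pi + lp_alpha + lp_tau
  attr(out, "terms") <- c(likelihood = lik, z = lp_z, w = lp_w, h = lp_h,
                          pi = lp_pi, alpha = lp_alpha, tau = lp_tau)
  out
}
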