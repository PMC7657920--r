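#' Chain configuration for the Gibbs sampler
#'
#' Defaults reproduce the study protocol: 2000 sweeps with the first 90%
#' discarded as burn-in, leaving 200 retained posterior draws.
#'
#' @param n_iter total Gibbs sweeps (default 2000).
#' @param burnin_frac fraction of sweeps discarded, in (0,1) (default 0.9).
#' @param thinning keep every `thinning`-th post-burn-in draw (default 1).
#' @param seed integer seed used for the whole chain, or `NULL` to leave
#'   the global RNG untouched.
#' @param record which loading/score draws to store in full; by default
#'   only streaming means and variances of `W` and `Z` are kept while `H`
#'   and `pi` draws are always stored in full.
#' @return an object of class \code{gfa_chain_config}.
#' @export
chain_config <- function(n_iter = 2000, burnin_frac = 0.9, thinning = 1,
                         seed = NULL, record = c("H", "pi")) {
  stopifnot(n_iter >= 1, thinning >= 1)
  if (!(burnin_frac > 0 && burnin_frac < 1))
    tgfa_stop("tgfa_bad_config", "burnin_frac must lie in (0, 1)")
  n_burn <- floor(n_iter * burnin_frac)
  n_ret <- length(seq.int(n_burn + 1, n_iter, by = thinning))
  if (n_ret < 1)
    tgfa_stop("tgfa_bad_config", "configuration retains no posterior draws")
  structure(list(n_iter = as.integer(n_iter), burnin_frac = burnin_frac,
                 thinning = as.integer(thinning), seed = seed,
                 record = record, n_burnin = n_burn, n_retained = n_ret),
            class = "gfa_chain_config")
}

#' Prepare data views for sampling
#'
#' Validates the views (equal row counts, finite values outside the missing
#' mask) and precomputes the zero-filled data matrices, observation masks
#' and per-row missing-cell indices the conditional updates need. `NA`
#' marks a missing cell; `NaN` or infinite values are a hard error.
#'
#' @param views named list of N x D_m numeric matrices (or
#'   \code{difference_view} objects).
#' @return an object of class \code{gfa_views}.
#' @export
prepare_views <- function(views) {
  if (inherits(views, "gfa_views")) return(views)
  vals <- lapply(views, function(v) {
    if (inherits(v, "difference_view")) v$values else as.matrix(v)
  })
  n <- unique(vapply(vals, nrow, 0L))
  if (length(n) != 1)
    tgfa_stop("tgfa_dim_mismatch", "all views must share the same samples")
  pv <- lapply(vals, function(X) {
    bad <- is.nan(X) | is.infinite(X)
    if (any(bad))
      tgfa_stop("tgfa_nonfinite_data",
                "NaN/Inf found outside the missing mask (use NA for missing)")
    O <- 1 - is.na(X)
    X0 <- X; X0[is.na(X)] <- 0
    miss_rows <- which(rowSums(O) < ncol(X))
    miss_idx <- lapply(seq_len(nrow(X)), function(i) which(O[i, ] == 0))
    list(X0 = X0, O = O, D = ncol(X), n_obs = colSums(O),
         has_missing = length(miss_rows) > 0, miss_idx = miss_idx,
         var_names = colnames(X) %||% sprintf("v%d", seq_len(ncol(X))))
  })
  structure(list(pv = pv, n = n, M = length(vals),
                 view_names = names(vals) %||% sprintf("view%d", seq_along(vals)),
                 values = vals),
            class = "gfa_views")
}

#' Gibbs update of the latent scores Z
#'
#' Draws each row \eqn{z_n} from its Gaussian full conditional
#' \eqn{N(\Lambda_n^{-1} b_n, \Lambda_n^{-1})} with
#' \eqn{\Lambda_n = I + \sum_m W^{(m)\top} \mathrm{diag}(\tau^{(m)}) W^{(m)}}
#' restricted to the cells observed for sample n, and
#' \eqn{b_n = \sum_m W^{(m)\top} \mathrm{diag}(\tau^{(m)}) x_n^{(m)}}.
#'
#' @param state a \code{gfa_state}.
#' @param views data views ([prepare_views()] output or a list of matrices).
#' @return the updated N x K score matrix.
#' @export
sample_Z_conditional <- function(state, views) {
  gv <- prepare_views(views)
  K <- ncol(state$Z); n <- gv$n
  A <- diag(K)
  B <- matrix(0, n, K)
  for (m in seq_len(gv$M)) {
    Wt <- state$W[[m]] * state$tau[[m]]
    A <- A + crossprod(state$W[[m]], Wt)
    B <- B + gv$pv[[m]]$X0 %*% Wt
  }
  if (!any(is.finite(A)) || any(!is.finite(A)))
    tgfa_stop("tgfa_nonfinite_precision", "non-finite score precision matrix")
  any_missing <- any(vapply(gv$pv, function(p) p$has_missing, TRUE))
  Z <- matrix(0, n, K)
  if (!any_missing) {
    ch <- chol(A)
    MU <- t(backsolve(ch, forwardsolve(t(ch), t(B))))
    Z <- MU + t(backsolve(ch, matrix(rnorm(n * K), K, n)))
  } else {
    for (i in seq_len(n)) {
      Ai <- A
      for (m in seq_len(gv$M)) {
        mis <- gv$pv[[m]]$miss_idx[[i]]
        if (length(mis)) {
          Wm <- state$W[[m]][mis, , drop = FALSE]
          Ai <- Ai - crossprod(Wm, Wm * state$tau[[m]][mis])
        }
      }
      ch <- chol(Ai)
      mu <- backsolve(ch, forwardsolve(t(ch), B[i, ]))
      Z[i, ] <- mu + backsolve(ch, rnorm(K))
    }
  }
  Z
}

# Core of the blocked (h, w) update for one view/component, given the
# residual statistics. Integrates the slab weights out variable by variable
# (valid under diagonal noise): with c_d = sum_{n obs} z_n r_{nd} and
# q_d = alpha_d + tau_d * sum_{n obs} z_n^2, the per-variable log Bayes
# factor slab-vs-spike is 0.5*log(alpha_d/q_d) + (tau_d c_d)^2 / (2 q_d).
# Draws h from the resulting odds, then w | h.
draw_hw <- function(pi_k, alpha_k, tau, cvec, zsq_obs) {
  q <- alpha_k + tau * zsq_obs
  log_bf <- 0.5 * (log(alpha_k) - log(q)) + 0.5 * (tau * cvec)^2 / q
  log_odds <- log(pi_k) - log1p(-pi_k) + sum(log_bf)
  p1 <- plogis(log_odds)
  h <- as.integer(runif(1) < p1)
  w <- if (h == 1L) rnorm(length(q), tau * cvec / q, 1 / sqrt(q)) else
    numeric(length(q))
  list(h = h, w = w, p1 = p1)
}

#' Blocked Gibbs update of one component's inclusion flag and loadings
#'
#' Updates \eqn{(h_{m,k}, w^{(m)}_{:,k})} jointly: the inclusion flag is
#' drawn from its conditional with the slab weights integrated out
#' (closed form under diagonal noise), then the loadings are drawn from
#' their Gaussian conditional when \eqn{h = 1}, or set exactly to zero.
#'
#' @param state a \code{gfa_state}.
#' @param views data views.
#' @param m view index.
#' @param k component index.
#' @return list with elements `h` (0/1), `w` (length-D_m vector) and `p1`
#'   (the conditional activation probability).
#' @export
sample_Wh_conditional <- function(state, views, m, k) {
  gv <- prepare_views(views)
  p <- gv$pv[[m]]
  z <- state$Z[, k]
  # residual excluding component k, zero-filled at missing cells
  mu <- state$Z %*% t(state$W[[m]]) - outer(z, state$W[[m]][, k])
  E0 <- (p$X0 - mu) * p$O
  cvec <- as.vector(crossprod(E0, z))
  zsq_obs <- as.vector(crossprod(p$O, z^2))
  draw_hw(state$pi[k], state$alpha[[m]][, k], state$tau[[m]], cvec, zsq_obs)
}

#' Gibbs update of the component inclusion probabilities
#'
#' Conjugate update \eqn{\pi_k \sim \mathrm{Beta}(a_\pi + s_k,\,
#' b_\pi + M - s_k)} with \eqn{s_k = \sum_m h_{m,k}}.
#'
#' @param state a \code{gfa_state}.
#' @param hyper a [gfa_hyperparams()] object.
#' @return updated length-K vector of inclusion probabilities.
#' @export
sample_pi_conditional <- function(state, hyper) {
  s <- colSums(state$H)
  M <- nrow(state$H)
  rbeta(length(s), hyper$a_pi + s, hyper$b_pi + M - s)
}

#' Gibbs update of the ARD precisions
#'
#' Where \eqn{h_{m,k} = 1}: \eqn{\alpha \sim \mathrm{Gamma}(a_\alpha + 1/2,
#' \, b_\alpha + w^2/2)}; where \eqn{h_{m,k} = 0} the precision is refreshed
#' from its prior, keeping the chain on the full joint.
#'
#' @param state a \code{gfa_state}.
#' @param hyper a [gfa_hyperparams()] object.
#' @return updated list of D_m x K precision matrices.
#' @export
sample_alpha_conditional <- function(state, hyper) {
  lapply(seq_along(state$W), function(m) {
    W <- state$W[[m]]; d <- nrow(W); K <- ncol(W)
    shape <- matrix(hyper$a_alpha, d, K)
    rate <- matrix(hyper$b_alpha, d, K)
    on <- which(state$H[m, ] == 1)
    if (length(on)) {
      shape[, on] <- hyper$a_alpha + 0.5
      rate[, on] <- hyper$b_alpha + W[, on, drop = FALSE]^2 / 2
    }
    matrix(rgamma(d * K, shape, rate = rate), d, K)
  })
}

#' Gibbs update of the noise precisions
#'
#' Conjugate update \eqn{\tau_d^{(m)} \sim \mathrm{Gamma}(a_\tau +
#' n_{obs}(d)/2,\; b_\tau(d) + \mathrm{SSR}_d / 2)} with the residual sum
#' of squares taken over observed cells only.
#'
#' @param state a \code{gfa_state}.
#' @param views data views.
#' @param hyper a [gfa_hyperparams()] object (`b_tau` resolved from the
#'   views when `NULL`).
#' @return updated list of noise precision vectors.
#' @export
sample_tau_conditional <- function(state, views, hyper) {
  gv <- prepare_views(views)
  b_tau <- resolve_b_tau(hyper, gv$values)
  lapply(seq_len(gv$M), function(m) {
    p <- gv$pv[[m]]
    E0 <- (p$X0 - state$Z %*% t(state$W[[m]])) * p$O
    ssr <- colSums(E0^2)
    rgamma(p$D, hyper$a_tau + p$n_obs / 2, rate = b_tau[[m]] + ssr / 2)
  })
}

#' One full Gibbs sweep
#'
#' Updates, in order: Z, then per view and component the blocked (h, w)
#' pair, then pi, alpha and tau. The blocked (h, w) update avoids the
#' mixing pathology of updating h with w fixed.
#'
#' @param state a \code{gfa_state}.
#' @param views data views (pass a [prepare_views()] object to avoid
#'   re-validation in tight loops).
#' @param hyper a [gfa_hyperparams()] object with `b_tau` resolved
#'   explicitly (a scalar or per-view list); required here so that repeated
#'   sweeps target a fixed joint distribution.
#' @return the updated \code{gfa_state}.
#' @export
gibbs_sweep <- function(state, views, hyper) {
  gv <- prepare_views(views)
  if (is.null(hyper$b_tau))
    tgfa_stop("tgfa_bad_hyper",
              "gibbs_sweep needs an explicit b_tau; see resolve_b_tau/run_chain")
  b_tau <- resolve_b_tau(hyper, gv$values)
  K <- hyper$K
  state$Z <- sample_Z_conditional(state, gv)
  for (m in seq_len(gv$M)) {
    p <- gv$pv[[m]]
    E0 <- (p$X0 - state$Z %*% t(state$W[[m]])) * p$O
    ZSQ <- crossprod(p$O, state$Z^2)             # D x K: obs-restricted sums
    for (k in seq_len(K)) {
      z <- state$Z[, k]
      w_old <- state$W[[m]][, k]
      cvec <- as.vector(crossprod(E0, z)) + w_old * ZSQ[, k]
      hw <- draw_hw(state$pi[k], state$alpha[[m]][, k], state$tau[[m]],
                    cvec, ZSQ[, k])
      delta <- w_old - hw$w
      if (any(delta != 0)) {
        upd <- outer(z, delta)
        if (p$has_missing) upd <- upd * p$O
        E0 <- E0 + upd
      }
      state$H[m, k] <- hw$h
      state$W[[m]][, k] <- hw$w
    }
  }
  state$pi <- sample_pi_conditional(state, hyper)
  state$alpha <- sample_alpha_conditional(state, hyper)
  # tau update reuses the final residual
  state$tau <- lapply(seq_len(gv$M), function(m) {
    p <- gv$pv[[m]]
    E0 <- (p$X0 - state$Z %*% t(state$W[[m]])) * p$O
    ssr <- colSums(E0^2)
    rgamma(p$D, hyper$a_tau + p$n_obs / 2, rate = b_tau[[m]] + ssr / 2)
  })
  state
}

# Deterministic, data-scale-free initial state: all components active,
# ARD precisions at their prior mean scale, small random loadings. A draw
# from the vague ARD prior would start the chain at astronomically large
# loadings; this initialization is standard for spike-and-slab samplers.
init_state <- function(hyper, n, d, b_tau) {
  M <- length(d); K <- hyper$K
  pi <- rep(0.5, K)
  H <- matrix(1L, M, K)
  alpha <- lapply(d, function(dm) matrix(1, dm, K))
  W <- lapply(d, function(dm) matrix(rnorm(dm * K, 0, 0.1), dm, K))
  tau <- lapply(seq_len(M), function(m)
    rep(hyper$a_tau, d[m]) / b_tau[[m]])
  Z <- matrix(rnorm(n * K), n, K)
  gfa_state(Z, W, H, pi, alpha, tau)
}

#' Fit the GFA model by Gibbs sampling
#'
#' Runs the full chain on preprocessed difference views: repeated
#' [gibbs_sweep()]s, burn-in discarded per the chain configuration,
#' posterior summarised by full draws of the activity indicators `H` and
#' inclusion probabilities `pi` plus streaming means and variances of the
#' loadings, scores, ARD and noise precisions. The log joint density is
#' recorded at every sweep as a convergence trace.
#'
#' @param views named list of N x D_m matrices or \code{difference_view}
#'   objects; `NA` marks missing cells.
#' @param hyper a [gfa_hyperparams()] object; default [gfa_hyperparams()]
#'   (K = 40, noise target 1/3). A `NULL` `b_tau` is resolved from the
#'   observed column variances (informative noise prior).
#' @param chain a [chain_config()] object; default 2000 sweeps, 90% burn-in.
#' @param verbose print progress every 100 sweeps.
#' @return an object of class \code{gfa_posterior} with elements
#'   `activity` (M x K posterior inclusion probabilities), `H_draws`,
#'   `pi_draws`, `Wmean`/`Wvar`, `Zmean`/`Zvar`, `tau_mean`, `sigma2_mean`
#'   (posterior mean residual variances), `alpha_mean`, `logjoint`,
#'   `config`, and the view/variable/sample names.
#' @export
run_chain <- function(views, hyper = gfa_hyperparams(),
                      chain = chain_config(), verbose = FALSE) {
  gv <- prepare_views(views)
  if (!is.null(chain$seed)) set.seed(chain$seed)
  b_tau <- resolve_b_tau(hyper, gv$values)
  hyper_res <- hyper
  hyper_res$b_tau <- b_tau
  d <- vapply(gv$pv, function(p) p$D, 0L)
  K <- hyper$K; M <- gv$M
  state <- init_state(hyper_res, gv$n, d, b_tau)

  R <- chain$n_retained
  H_draws <- array(0L, c(R, M, K),
                   dimnames = list(NULL, gv$view_names, NULL))
  pi_draws <- matrix(0, R, K)
  Wsum <- lapply(d, function(dm) matrix(0, dm, K))
  Wsq <- lapply(d, function(dm) matrix(0, dm, K))
  Zsum <- matrix(0, gv$n, K); Zsq <- matrix(0, gv$n, K)
  tausum <- lapply(d, function(dm) numeric(dm))
  s2sum <- lapply(d, function(dm) numeric(dm))
  alphasum <- lapply(d, function(dm) matrix(0, dm, K))
  logjoint <- numeric(chain$n_iter)
  keep_at <- seq.int(chain$n_burnin + 1, chain$n_iter, by = chain$thinning)
  r <- 0L
  for (it in seq_len(chain$n_iter)) {
    state <- gibbs_sweep(state, gv, hyper_res)
    logjoint[it] <- as.numeric(log_joint(state, gv$values, hyper_res))
    if (it %in% keep_at) {
      r <- r + 1L
      H_draws[r, , ] <- state$H
      pi_draws[r, ] <- state$pi
      for (m in seq_len(M)) {
        Wsum[[m]] <- Wsum[[m]] + state$W[[m]]
        Wsq[[m]] <- Wsq[[m]] + state$W[[m]]^2
        tausum[[m]] <- tausum[[m]] + state$tau[[m]]
        s2sum[[m]] <- s2sum[[m]] + 1 / state$tau[[m]]
        alphasum[[m]] <- alphasum[[m]] + state$alpha[[m]]
      }
      Zsum <- Zsum + state$Z; Zsq <- Zsq + state$Z^2
    }
    if (verbose && it %% 100 == 0)
      message(sprintf("sweep %d/%d  log joint %.1f", it, chain$n_iter,
                      logjoint[it]))
  }
  Wmean <- lapply(seq_len(M), function(m) {
    out <- Wsum[[m]] / R
    rownames(out) <- gv$pv[[m]]$var_names
    out
  })
  Wvar <- lapply(seq_len(M), function(m) pmax(Wsq[[m]] / R - (Wsum[[m]] / R)^2, 0))
  pair_ids <- rownames(if (inherits(views, "gfa_views")) gv$values[[1]] else
    (if (inherits(views[[1]], "difference_view")) views[[1]]$values else views[[1]]))
  structure(
    list(activity = apply(H_draws, c(2, 3), mean),
         H_draws = H_draws, pi_draws = pi_draws,
         Wmean = setNames(Wmean, gv$view_names),
         Wvar = setNames(Wvar, gv$view_names),
         Zmean = Zsum / R, Zvar = pmax(Zsq / R - (Zsum / R)^2, 0),
         tau_mean = setNames(lapply(tausum, function(x) x / R), gv$view_names),
         sigma2_mean = setNames(lapply(s2sum, function(x) x / R), gv$view_names),
         alpha_mean = setNames(lapply(alphasum, function(x) x / R), gv$view_names),
         logjoint = logjoint, n_retained = R,
         view_names = gv$view_names,
         var_names = setNames(lapply(gv$pv, function(p) p$var_names),
                              gv$view_names),
         pair_ids = pair_ids %||% sprintf("pair%02d", seq_len(gv$n)),
         config = list(chain = unclass(chain),
                       hyper = unclass(hyper),
                       b_tau = b_tau)),
    class = "gfa_posterior"
  )
}

#' @export
print.gfa_posterior <- function(x, ...) {
  cat(sprintf("GFA posterior: %d views, K = %d, %d retained draws\n",
              length(x$view_names), ncol(x$activity), x$n_retained))
  act <- colSums(x$activity > 0.5) > 0
  cat(sprintf("non-empty components (inclusion > 0.5 in >=1 view): %d\n",
              sum(act)))
  invisible(x)
}
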