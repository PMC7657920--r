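#' Component activity per view
#'
#' The posterior inclusion probability of component k in view m is the
#' posterior mean of the indicator \eqn{h_{m,k}}; a component is called
#' active in a view when that probability exceeds the threshold. A
#' component active in two or more views captures variation shared
#' between them; a view-specific component captures structured variation
#' within one view.
#'
#' @param posterior a \code{gfa_posterior}.
#' @param threshold activity call threshold in (0,1) (default 0.5).
#' @return list with `probability` (M x K matrix) and `active` (logical
#'   M x K matrix).
#' @export
component_activity <- function(posterior, threshold = 0.5) {
  prob <- posterior$activity
  rownames(prob) <- posterior$view_names
  list(probability = prob, active = prob > threshold)
}

#' Identify and drop empty components
#'
#' A component inactive in every view is empty: it models nothing, and
#' its presence indicates the chosen K was large enough. Returns the
#' retained (non-empty) component indices.
#'
#' @inheritParams component_activity
#' @return list with `retained` (integer indices), `n_retained`,
#'   `n_empty`, and the `activity` call matrix used.
#' @export
prune_empty_components <- function(posterior, threshold = 0.5) {
  act <- component_activity(posterior, threshold)
  nonempty <- which(colSums(act$active) > 0)
  list(retained = nonempty, n_retained = length(nonempty),
       n_empty = ncol(act$active) - length(nonempty), activity = act$active)
}

#' Variance explained per component and view
#'
#' For component k and view m the fraction is
#' \deqn{\frac{\sum_d \bar w_{d,k}^2}{\sum_{k'} \sum_d \bar w_{d,k'}^2 +
#'   \sum_d 1/\bar\tau_d},}
#' computed from posterior means: with unit-variance scores the expected
#' variance a component contributes to view m is the squared norm of its
#' loading column, and the denominator is the model's total expected
#' variance for that view (all components plus residual noise).
#'
#' @param posterior a \code{gfa_posterior}.
#' @return K x M matrix of fractions in \[0, 1\]; per-view column sums are
#'   at most 1.
#' @export
variance_explained <- function(posterior) {
  M <- length(posterior$Wmean)
  K <- ncol(posterior$activity)
  out <- matrix(vapply(seq_len(M), function(m) {
    comp <- colSums(posterior$Wmean[[m]]^2)
    comp / (sum(comp) + sum(posterior$sigma2_mean[[m]]))
  }, numeric(K)), K, M)
  colnames(out) <- posterior$view_names
  rownames(out) <- sprintf("comp%02d", seq_len(K))
  out
}

# |Pearson r| between score columns, with constant columns given r = 0 so
# degenerate components sort to the back of the assignment.
abs_cor_matrix <- function(A, B) {
  sa <- apply(A, 2, sd); sb <- apply(B, 2, sd)
  r <- matrix(0, ncol(A), ncol(B))
  okA <- sa > 0; okB <- sb > 0
  if (any(okA) && any(okB))
    r[okA, okB] <- abs(cor(A[, okA, drop = FALSE], B[, okB, drop = FALSE]))
  r
}

#' Match estimated components to a reference by score correlation
#'
#' The model is identifiable only up to permutation and sign of
#' components, so comparisons use an optimal one-to-one assignment
#' maximizing the summed absolute Pearson correlation between score
#' columns (solved exactly by the Hungarian algorithm). When the
#' reference carries an activity mask, per-match activity agreement
#' against the estimate's thresholded activity is reported too.
#'
#' @param est a \code{gfa_posterior} (posterior-mean scores used) or a
#'   numeric score matrix.
#' @param reference a \code{gfa_state} (simulation ground truth), another
#'   \code{gfa_posterior}, or a score matrix; must have the same number
#'   of rows (pairs).
#' @param threshold activity threshold for the agreement summary.
#' @return list with `matching` (data frame: est_component,
#'   ref_component, abs_r, sign), `mean_abs_r`, and (when masks are
#'   available) `activity_agreement`, the fraction of view x component
#'   activity calls agreeing with the reference mask over the matched
#'   reference components.
#' @export
match_components <- function(est, reference, threshold = 0.5) {
  scores <- function(x) {
    if (inherits(x, "gfa_posterior")) x$Zmean
    else if (inherits(x, "gfa_state")) x$Z
    else as.matrix(x)
  }
  Ze <- scores(est); Zr <- scores(reference)
  if (nrow(Ze) != nrow(Zr))
    tgfa_stop("tgfa_dim_mismatch", "score matrices must share their rows")
  r <- abs_cor_matrix(Ze, Zr)
  n <- max(dim(r))
  cost <- matrix(0, n, n)
  cost[seq_len(nrow(r)), seq_len(ncol(r))] <- 1 - r
  cost[is.na(cost)] <- 1
  sol <- as.integer(clue::solve_LSAP(cost))
  keep <- which(sol[seq_len(nrow(r))] <= ncol(r))
  keep <- keep[keep <= nrow(r)]
  matching <- data.frame(est_component = keep, ref_component = sol[keep])
  matching$abs_r <- r[cbind(matching$est_component, matching$ref_component)]
  sgn <- vapply(seq_len(nrow(matching)), function(i) {
    a <- Ze[, matching$est_component[i]]; b <- Zr[, matching$ref_component[i]]
    if (sd(a) == 0 || sd(b) == 0) 0 else sign(cor(a, b))
  }, 0)
  matching$sign <- sgn
  matching <- matching[order(matching$ref_component), ]
  out <- list(matching = matching, mean_abs_r = mean(matching$abs_r))
  mask_est <- if (inherits(est, "gfa_posterior"))
    (est$activity > threshold) * 1L
  mask_ref <- if (inherits(reference, "gfa_state")) reference$H
  else if (inherits(reference, "gfa_posterior"))
    (reference$activity > threshold) * 1L
  if (!is.null(mask_est) && !is.null(mask_ref) &&
      nrow(mask_est) == nrow(mask_ref)) {
    sub <- matching[matching$ref_component <= ncol(mask_ref) &
                      matching$est_component <= ncol(mask_est), ]
    out$activity_agreement <- mean(
      mask_est[, sub$est_component, drop = FALSE] ==
        mask_ref[, sub$ref_component, drop = FALSE])
  }
  out
}
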