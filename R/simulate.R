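#' Default view-by-component activity mask
#'
#' A K_true = 6 pattern over the five views (clinical, cytokine,
#' genotype, methylation, dietary) mixing shared and view-specific
#' components; used as the simulation default. With
#' `include_genotype = FALSE` (the twin-cohort generator, where the
#' genotype view is pair-identical dosage data carrying no within-pair
#' signal) the genotype row is all zero.
#'
#' @param views view labels (rows).
#' @param include_genotype allow components active in the genotype view.
#' @return binary matrix, views x 6 components.
#' @export
default_activity_mask <- function(views = c("clinical", "cytokine", "genotype",
                                            "methylation", "dietary"),
                                  include_genotype = TRUE) {
  mask <- rbind(
    clinical    = c(1, 1, 0, 1, 0, 0),
    cytokine    = c(1, 0, 0, 1, 1, 0),
    genotype    = c(0, 0, 1, 0, 0, 0),
    methylation = c(0, 1, 0, 1, 0, 1),
    dietary     = c(0, 0, 0, 0, 1, 1)
  )
  if (!include_genotype) {
    mask["genotype", ] <- 0
    mask["methylation", 3] <- 1   # keep component 3 non-empty
  }
  mask[views, , drop = FALSE]
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study cohort: 43 monozygotic pairs of which 25
#' are weight discordant (within-pair BMI difference above 3 kg/m^2),
#' five views, pair-identical genotype, one-third residual noise. The
#' scaled-down default dimensions (20/20/60/60/20) keep simulations
#' fast; `preset = "study"` switches to the study dimensions
#' 42/71/1587/1605/63.
#'
#' @param n_pairs number of twin pairs (default 43).
#' @param discordant_pairs pairs with BMI difference above the threshold
#'   (default 25).
#' @param bmi_threshold discordance threshold, kg/m^2 (default 3).
#' @param dims named per-view variable counts.
#' @param K_true number of truly active components.
#' @param mask binary views x K_true activity matrix; default
#'   [default_activity_mask()].
#' @param loading_scale slab standard deviation for the raw loadings.
#' @param noise_target residual variance fraction (default 1/3).
#' @param missing_rates named per-view MCAR missingness rates in \[0, 1).
#' @param preset `"default"` or `"study"` (study-scale dimensions).
#' @param seed optional integer seed.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_pairs = 43, discordant_pairs = 25, bmi_threshold = 3,
                       dims = c(clinical = 20, cytokine = 20, genotype = 60,
                                methylation = 60, dietary = 20),
                       K_true = 6, mask = NULL, loading_scale = 1,
                       noise_target = 1 / 3,
                       missing_rates = c(clinical = 0.02, cytokine = 0.05,
                                         genotype = 0, methylation = 0.02,
                                         dietary = 0.05),
                       preset = c("default", "study"), seed = NULL) {
  preset <- match.arg(preset)
  if (preset == "study")
    dims <- c(clinical = 42, cytokine = 71, genotype = 1587,
              methylation = 1605, dietary = 63)
  if (discordant_pairs > n_pairs)
    tgfa_stop("tgfa_bad_config", "discordant_pairs cannot exceed n_pairs")
  stopifnot(all(dims >= 1), noise_target > 0, noise_target < 1,
            all(missing_rates >= 0), all(missing_rates < 1))
  if (is.null(mask))
    mask <- default_activity_mask(names(dims), include_genotype = FALSE)
  if (ncol(mask) != K_true)
    tgfa_stop("tgfa_bad_config", "mask must have K_true columns")
  if (is.null(rownames(mask))) rownames(mask) <- names(dims)
  structure(list(n_pairs = as.integer(n_pairs),
                 discordant_pairs = as.integer(discordant_pairs),
                 bmi_threshold = bmi_threshold, dims = dims,
                 K_true = as.integer(K_true), mask = mask,
                 loading_scale = loading_scale, noise_target = noise_target,
                 missing_rates = missing_rates, preset = preset, seed = seed),
            class = "sim_config")
}

#' Simulate model-ready difference views with known ground truth
#'
#' Draws a latent state honouring a fixed activity mask and generates the
#' views from the model itself: active loadings come from the slab and
#' are then rescaled per variable so that every variable with at least
#' one active component has signal variance `1 - noise_target` and
#' residual variance `noise_target` (the unit-variance data convention);
#' variables with no active component are pure noise at variance
#' `noise_target`. Missingness is injected completely at random at the
#' per-view rates. The generating state is returned alongside the data.
#'
#' @param n number of samples (pairs).
#' @param dims named integer vector of per-view dimensions.
#' @param mask binary M x K_true activity matrix (views in `dims` order).
#' @param noise_target residual variance (default 1/3).
#' @param loading_scale slab standard deviation before normalization.
#' @param missing_rates per-view MCAR rates (default 0 everywhere).
#' @param normalize_signal rescale per-variable signal variance to
#'   `1 - noise_target` (default TRUE).
#' @return list with `views` (named list of matrices with NA for
#'   missing) and `truth` (a \code{gfa_state}).
#' @export
simulate_difference_views <- function(n, dims, mask,
                                      noise_target = 1 / 3,
                                      loading_scale = 1,
                                      missing_rates = NULL,
                                      normalize_signal = TRUE) {
  M <- length(dims); K <- ncol(mask)
  stopifnot(nrow(mask) == M)
  viewn <- names(dims) %||% sprintf("view%d", seq_len(M))
  W <- lapply(seq_len(M), function(m) {
    Wm <- matrix(0, dims[m], K)
    on <- which(mask[m, ] == 1)
    if (length(on))
      Wm[, on] <- rnorm(dims[m] * length(on), 0, loading_scale)
    if (normalize_signal) {
      s2 <- rowSums(Wm^2)
      hit <- s2 > 0
      Wm[hit, ] <- Wm[hit, , drop = FALSE] *
        sqrt((1 - noise_target) / s2[hit])
    }
    Wm
  })
  tau <- lapply(seq_len(M), function(m) rep(1 / noise_target, dims[m]))
  alpha <- lapply(seq_len(M), function(m)
    matrix(1 / loading_scale^2, dims[m], K))
  Z <- matrix(rnorm(n * K), n, K)
  truth <- gfa_state(Z, W, mask * 1L,
                     pi = pmin(pmax(colMeans(mask), 0.01), 0.99),
                     alpha = alpha, tau = tau)
  views <- generate_from_state(truth)
  names(views) <- viewn
  for (m in seq_len(M))
    colnames(views[[m]]) <- sprintf("%s_%03d", viewn[m], seq_len(dims[m]))
  if (!is.null(missing_rates)) {
    rates <- rep_len(0, M); names(rates) <- viewn
    rates[names(missing_rates)[names(missing_rates) %in% viewn]] <-
      missing_rates[names(missing_rates) %in% viewn]
    views <- inject_missingness(views, rates)
  }
  list(views = views, truth = truth)
}

#' Inject missingness completely at random
#'
#' Masks each cell of each view independently at the per-view rate;
#' selected columns can be forced to a higher rate to exercise the
#' missingness filters. A rate of 1 is an error (the column would be
#' empty).
#'
#' @param views named list of matrices.
#' @param rates per-view rates in \[0, 1) (scalar recycled).
#' @param force_columns optional named list (view -> column indices)
#'   masked at `force_frac` instead.
#' @param force_frac rate for forced columns (default 0.6).
#' @return the views with `NA` at masked cells.
#' @export
inject_missingness <- function(views, rates, force_columns = NULL,
                               force_frac = 0.6) {
  rates <- rep_len(rates, length(views))
  if (any(rates >= 1) || force_frac >= 1)
    tgfa_stop("tgfa_bad_config", "missingness rate must be below 1")
  out <- lapply(seq_along(views), function(m) {
    X <- views[[m]]
    if (rates[m] > 0)
      X[matrix(runif(length(X)) < rates[m], nrow(X), ncol(X))] <- NA
    fc <- force_columns[[names(views)[m] %||% m]]
    for (j in fc) {
      n_mask <- ceiling(force_frac * nrow(X))
      X[sample.int(nrow(X), n_mask), j] <- NA
    }
    X
  })
  setNames(out, names(views))
}

# Hardy-Weinberg risk-allele dosages shared by both co-twins.
simulate_genotype_pairs <- function(n_pairs, n_snp, maf_range = c(0.05, 0.5)) {
  maf <- runif(n_snp, maf_range[1], maf_range[2])
  vapply(maf, function(p) rbinom(n_pairs, 2, p), numeric(n_pairs))
}

#' Simulate a twin-level cohort with known ground truth
#'
#' Builds twin-level tables whose heavier-minus-leaner differences equal
#' a [simulate_difference_views()] draw: each pair gets a shared pair
#' mean plus/minus half the target difference. BMI is constructed so
#' that exactly `discordant_pairs` pairs exceed the discordance
#' threshold; genotype columns are pair-identical dosages in \{0,1,2\}
#' (so they carry no within-pair signal and enter the model as shared
#' values); methylation-like columns are affinely squashed into \[0,1\]
#' (with the ground-truth loadings and noise precisions rescaled to
#' match); the clinical view carries a three-level categorical smoking
#' variable and the pair-constant gender, age and study-year columns.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (a [twin_cohort()]), `views` (the planted
#'   per-view difference matrices that [preprocess_cohort()] recovers
#'   before scaling) and `truth` (the generating \code{gfa_state};
#'   loadings cover the factor-model columns, zero elsewhere).
#' @export
simulate_twin_cohort <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_pairs
  dims <- config$dims
  viewn <- names(dims)
  special_clin <- c("bmi", "smoking.never", "smoking.former",
                    "smoking.current", "gender", "age", "year")
  n_fac_clin <- dims["clinical"] - length(special_clin)
  if (n_fac_clin < 1)
    tgfa_stop("tgfa_bad_config", sprintf(
      "clinical view needs at least %d variables", length(special_clin) + 1))
  fac_dims <- c(clinical = unname(n_fac_clin), cytokine = unname(dims["cytokine"]),
                methylation = unname(dims["methylation"]),
                dietary = unname(dims["dietary"]))
  mask <- config$mask[c("clinical", "cytokine", "methylation", "dietary"), ,
                      drop = FALSE]
  sim <- simulate_difference_views(n, fac_dims, mask,
                                   noise_target = config$noise_target,
                                   loading_scale = config$loading_scale)
  diffs <- sim$views
  truth <- sim$truth

  pair_ids <- sprintf("pair%02d", seq_len(n))
  # BMI: pair means around the population mean; planted positive
  # differences with exactly the configured number of discordant pairs
  thr <- config$bmi_threshold
  disc <- rep(FALSE, n); disc[sample.int(n, config$discordant_pairs)] <- TRUE
  d_bmi <- ifelse(disc, thr + 0.2 + rexp(n, 1 / 2.5),
                  runif(n, 0.05, thr - 0.05))
  bmi_mean <- pmax(rnorm(n, 27.5, 3), 20)

  # smoking: per-twin categorical status
  levels <- c("never", "former", "current")
  smoke_h <- sample(levels, n, replace = TRUE, prob = c(0.4, 0.3, 0.3))
  smoke_l <- ifelse(runif(n) < 0.6, smoke_h,
                    sample(levels, n, replace = TRUE))
  onehot <- function(s) vapply(levels, function(l) as.numeric(s == l),
                               numeric(length(s)))
  smoke_diff <- onehot(smoke_h) - onehot(smoke_l)
  colnames(smoke_diff) <- paste("smoking", levels, sep = ".")

  # pair-constant clinical variables
  gender <- rbinom(n, 1, 0.5)
  age <- round(runif(n, 23, 36), 1)
  year <- sample(2006:2013, n, replace = TRUE)

  # methylation must live in [0,1] at the twin level: affine squash, with
  # the ground truth rescaled by the same factor so the planted view is
  # still an exact draw from the (rescaled) model
  meth_mean <- rnorm(dims["methylation"], 0, 0.5)
  meth_idx <- which(viewn == "methylation")
  meth_raw <- diffs$methylation
  extremes <- max(abs(sweep(rbind(meth_raw / 2, -meth_raw / 2), 2,
                            meth_mean, "+")))
  b <- 0.49 / max(extremes, 1e-8)
  diffs$methylation <- meth_raw * b
  m_meth <- which(rownames(mask) == "methylation")
  truth$W[[m_meth]] <- truth$W[[m_meth]] * b
  truth$tau[[m_meth]] <- truth$tau[[m_meth]] / b^2

  # genotype: pair-identical Hardy-Weinberg dosages (no within-pair signal)
  geno <- simulate_genotype_pairs(n, dims["genotype"])
  colnames(geno) <- sprintf("snp_%04d", seq_len(ncol(geno)))

  # assemble twin-level rows: heavier twin value = pair mean + diff/2
  twin_rows <- function(pair_mean_mat, diff_mat) {
    hv <- pair_mean_mat + diff_mat / 2
    lv <- pair_mean_mat - diff_mat / 2
    list(hv = hv, lv = lv)
  }
  clin_fac <- twin_rows(matrix(rnorm(n * n_fac_clin), n, n_fac_clin),
                        diffs$clinical)
  cyto <- twin_rows(matrix(rnorm(n * dims["cytokine"]), n, dims["cytokine"]),
                    diffs$cytokine)
  meth <- twin_rows(matrix(0.5 + b * rep(meth_mean, each = n),
                           n, dims["methylation"]),
                    diffs$methylation)
  diet <- twin_rows(matrix(rnorm(n * dims["dietary"]), n, dims["dietary"]),
                    diffs$dietary)

  colnames(clin_fac$hv) <- colnames(clin_fac$lv) <- colnames(diffs$clinical)
  for (nm in c("cytokine", "methylation", "dietary")) {
    obj <- switch(nm, cytokine = cyto, methylation = meth, dietary = diet)
    colnames(obj$hv) <- colnames(obj$lv) <- colnames(diffs[[nm]])
    assign(nm, obj)
  }

  build_twin <- function(which_twin) {
    sm <- if (which_twin == "h") smoke_h else smoke_l
    sgn <- if (which_twin == "h") 1 else -1
    data.frame(
      bmi = bmi_mean + sgn * d_bmi / 2,
      smoking = sm, gender = gender, age = age, year = year,
      (if (which_twin == "h") clin_fac$hv else clin_fac$lv),
      (if (which_twin == "h") cyto$hv else cyto$lv),
      as.data.frame(geno),
      pmin(pmax(if (which_twin == "h") meth$hv else meth$lv, 0), 1),
      (if (which_twin == "h") diet$hv else diet$lv),
      check.names = FALSE)
  }
  heavier <- build_twin("h"); leaner <- build_twin("l")
  # randomize within-pair row order so nothing downstream can rely on it
  first_heavier <- runif(n) < 0.5
  values <- heavier
  values[!first_heavier, ] <- leaner[!first_heavier, ]
  second <- leaner
  second[!first_heavier, ] <- heavier[!first_heavier, ]
  values <- rbind(values, second)
  sample_id <- c(paste0(pair_ids, "_a"), paste0(pair_ids, "_b"))
  ord <- order(rep(pair_ids, 2), sample_id)
  values <- values[ord, , drop = FALSE]
  sample_id <- sample_id[ord]
  pair_id <- rep(pair_ids, 2)[ord]

  meta <- rbind(
    data.frame(name = c("bmi", "smoking", "gender", "age", "year"),
               view = "clinical",
               vtype = c("continuous", "categorical", "binary", "continuous",
                         "continuous"),
               pair_constant = c(FALSE, FALSE, TRUE, TRUE, TRUE),
               units = c("kg m-2", "", "0=male 1=female", "year", "")),
    data.frame(name = colnames(diffs$clinical), view = "clinical",
               vtype = "continuous", pair_constant = FALSE, units = ""),
    data.frame(name = colnames(diffs$cytokine), view = "cytokine",
               vtype = "continuous", pair_constant = FALSE, units = ""),
    data.frame(name = colnames(geno), view = "genotype", vtype = "dosage",
               pair_constant = TRUE, units = "risk alleles"),
    data.frame(name = colnames(diffs$methylation), view = "methylation",
               vtype = "continuous", pair_constant = FALSE, units = "beta"),
    data.frame(name = colnames(diffs$dietary), view = "dietary",
               vtype = "continuous", pair_constant = FALSE, units = "")
  )
  cohort <- twin_cohort(values, sample_id, pair_id, meta)

  # apply MCAR missingness at the twin level (never to bmi or the
  # pair-constant columns), then recompute the planted difference
  # matrices with their induced missing cells
  rates <- config$missing_rates
  prot <- c("bmi", "smoking", "gender", "age", "year", colnames(geno))
  for (vw in names(rates)) {
    if (rates[vw] <= 0) next
    vars <- setdiff(cohort$meta$name[cohort$meta$view == vw], prot)
    for (v in vars) {
      hit <- runif(nrow(cohort$values)) < rates[vw]
      cohort$values[[v]][hit] <- NA
    }
  }
  # expand the truth state to the full five-view layout: zero loadings for
  # the special clinical columns (BMI, smoking one-hots, pair constants)
  # and for the pair-identical genotype view, in planted column order
  K <- ncol(truth$H)
  pad_rows <- function(W, n_before) rbind(matrix(0, n_before, K), W)
  W5 <- list(clinical = pad_rows(truth$W[[1]], length(special_clin)),
             cytokine = truth$W[[2]],
             genotype = matrix(0, ncol(geno), K),
             methylation = truth$W[[3]],
             dietary = truth$W[[4]])
  H5 <- rbind(clinical = truth$H[1, ], cytokine = truth$H[2, ],
              genotype = rep(0L, K), methylation = truth$H[3, ],
              dietary = truth$H[4, ])
  alpha5 <- lapply(W5, function(w) matrix(1 / config$loading_scale^2,
                                          nrow(w), K))
  geno_var <- pmax(apply(geno, 2, stats::var), 1e-8)
  tau5 <- list(clinical = c(rep(1, length(special_clin)), truth$tau[[1]]),
               cytokine = truth$tau[[2]],
               genotype = 1 / geno_var,
               methylation = truth$tau[[3]],
               dietary = truth$tau[[4]])
  truth <- gfa_state(truth$Z, W5, H5, truth$pi, alpha5, tau5)

  planted <- c(list(clinical = cbind(bmi = d_bmi, smoke_diff,
                                     gender = gender, age = age, year = year,
                                     diffs$clinical)),
               diffs[c("cytokine")],
               list(genotype = geno),
               diffs[c("methylation", "dietary")])
  for (vw in names(planted)) {
    rownames(planted[[vw]]) <- pair_ids
    vars <- colnames(planted[[vw]])
    pc <- cohort$meta$pair_constant[match(vars, cohort$meta$name)]
    pc[is.na(pc)] <- FALSE   # one-hot smoking diff columns
    present <- vars %in% names(cohort$values)
    for (j in which(present & !pc)) {
      v <- cohort$values[[vars[j]]]
      na_pair <- tapply(is.na(v), cohort$pair_id, any)
      planted[[vw]][na_pair[pair_ids], j] <- NA
    }
  }
  list(cohort = cohort, views = planted, truth = truth)
}
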