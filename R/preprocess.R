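#' Order co-twins by BMI within each pair
#'
#' Designates, per pair, the twin with the larger BMI as the heavier twin.
#' The co-twin control convention used throughout: differences are always
#' heavier minus leaner, so the BMI difference column is strictly
#' positive. An exact BMI tie is a hard error unless an explicit
#' tie-break is configured, since the design presumes discordance.
#'
#' @param cohort a [twin_cohort()].
#' @param bmi_threshold within-pair BMI difference (kg/m^2) above which a
#'   pair is flagged discordant; study threshold 3.
#' @param tie_break `NULL` (error on ties) or a character vector of
#'   variable names compared in order to break exact BMI ties;
#'   `"sample_id"` may be used as a final deterministic fallback.
#' @return data frame with one row per pair (lexicographic `pair_id`
#'   order): `pair_id`, `heavier`, `leaner` (sample ids), `bmi_heavier`,
#'   `bmi_leaner`, `delta_bmi`, `discordant`.
#' @export
order_pairs_by_bmi <- function(cohort, bmi_threshold = 3, tie_break = NULL) {
  bmi <- cohort$values[[cohort$bmi_variable]]
  pairs <- sort(unique(cohort$pair_id))
  rows <- lapply(pairs, function(p) {
    idx <- which(cohort$pair_id == p)
    b <- bmi[idx]
    if (b[1] == b[2]) {
      pick <- NA_integer_
      for (tb in tie_break) {
        v <- if (tb == "sample_id") cohort$sample_id[idx] else
          cohort$values[[tb]][idx]
        if (!is.null(v) && !any(is.na(v)) && v[1] != v[2]) {
          pick <- if (v[1] > v[2]) 1L else 2L
          break
        }
      }
      if (is.na(pick))
        tgfa_stop("tgfa_bmi_tie", sprintf(
          paste("pair %s has an exact BMI tie; set tie_break (e.g.",
                "c(\"weight\", \"sample_id\")) to order it explicitly"), p))
      hv <- idx[pick]; lv <- idx[-pick][1]
    } else if (b[1] > b[2]) {
      hv <- idx[1]; lv <- idx[2]
    } else {
      hv <- idx[2]; lv <- idx[1]
    }
    data.frame(pair_id = p,
               heavier = cohort$sample_id[hv], leaner = cohort$sample_id[lv],
               bmi_heavier = bmi[match(cohort$sample_id[hv], cohort$sample_id)],
               bmi_leaner = bmi[match(cohort$sample_id[lv], cohort$sample_id)])
  })
  out <- do.call(rbind, rows)
  out$delta_bmi <- out$bmi_heavier - out$bmi_leaner
  out$discordant <- out$delta_bmi > bmi_threshold
  out
}

#' One-hot encode a three-level smoking variable
#'
#' Replaces a categorical smoking-status column (levels `never`, `former`,
#' `current`) by three twin-level 0/1 columns named
#' `<variable>.never/.former/.current`. Rows sum to 1 where observed;
#' after heavier-minus-leaner differencing the columns take values in
#' \{-1, 0, 1\}, and are all zero when both co-twins share a status.
#'
#' @param cohort a [twin_cohort()].
#' @param variable name of the categorical column (default `"smoking"`).
#' @return the cohort with the column replaced and metadata updated.
#' @export
encode_smoking_onehot <- function(cohort, variable = "smoking") {
  v <- as.character(cohort$values[[variable]])
  if (is.null(cohort$values[[variable]]))
    tgfa_stop("tgfa_missing_variable", sprintf("no column '%s'", variable))
  levels <- c("never", "former", "current")
  bad <- setdiff(unique(v[!is.na(v)]), levels)
  if (length(bad))
    tgfa_stop("tgfa_unknown_level", sprintf(
      "unknown smoking level(s): %s", paste(bad, collapse = ", ")))
  meta_row <- cohort$meta[cohort$meta$name == variable, ]
  onehot <- vapply(levels, function(l) as.numeric(v == l), numeric(length(v)))
  colnames(onehot) <- paste(variable, levels, sep = ".")
  pos <- match(variable, names(cohort$values))
  vals <- cbind(cohort$values[, seq_len(pos - 1), drop = FALSE],
                as.data.frame(onehot),
                cohort$values[, -seq_len(pos), drop = FALSE])
  new_meta <- do.call(rbind, lapply(colnames(onehot), function(nm) {
    r <- meta_row; r$name <- nm; r$vtype <- "binary"; r
  }))
  mpos <- which(cohort$meta$name == variable)
  meta <- rbind(cohort$meta[seq_len(mpos - 1), , drop = FALSE], new_meta,
                cohort$meta[-seq_len(mpos), , drop = FALSE])
  twin_cohort(vals, cohort$sample_id, cohort$pair_id, meta,
              bmi_variable = cohort$bmi_variable)
}

#' Build the per-view model input matrices from twin-level data
#'
#' For every non-pair-constant variable the matrix entry is the heavier
#' twin's value minus the leaner twin's value (missing if either is
#' missing); pair-constant variables (genotype dosages, age, gender,
#' study year, liver-fat discordance) carry the shared value, taken from
#' the heavier twin (missing if that twin's value is missing). Pairs are
#' rows in lexicographic `pair_id` order so results are independent of
#' input row order.
#'
#' @param cohort a [twin_cohort()] with categorical variables already
#'   encoded (see [encode_smoking_onehot()]).
#' @param pair_table output of [order_pairs_by_bmi()].
#' @param tol tolerance beyond which two twin values of a pair-constant
#'   variable are considered different (hard error naming the variable).
#' @return named list of \code{difference_view} objects, one per view,
#'   each with fields `values` (pairs x variables), `view`, `pair_ids`
#'   and `scaling` (`"none"` until [standardize_views()]).
#' @export
compute_pair_differences <- function(cohort, pair_table, tol = 1e-8) {
  not_num <- names(cohort$values)[!vapply(cohort$values, is.numeric, TRUE)]
  if (length(not_num))
    tgfa_stop("tgfa_unencoded_variable", sprintf(
      "non-numeric variables must be encoded first: %s",
      paste(not_num, collapse = ", ")))
  hv <- match(pair_table$heavier, cohort$sample_id)
  lv <- match(pair_table$leaner, cohort$sample_id)
  views <- unique(cohort$meta$view)
  out <- lapply(views, function(vw) {
    vars <- cohort$meta$name[cohort$meta$view == vw]
    pc <- cohort$meta$pair_constant[match(vars, cohort$meta$name)]
    vals <- vapply(seq_along(vars), function(j) {
      x <- cohort$values[[vars[j]]]
      if (pc[j]) {
        both <- !is.na(x[hv]) & !is.na(x[lv])
        if (any(abs(x[hv][both] - x[lv][both]) > tol))
          tgfa_stop("tgfa_pair_constant_violation", sprintf(
            "pair-constant variable '%s' differs within a pair", vars[j]))
        x[hv]
      } else {
        x[hv] - x[lv]
      }
    }, numeric(length(hv)))
    vals <- matrix(vals, nrow = length(hv),
                   dimnames = list(pair_table$pair_id, vars))
    structure(list(values = vals, view = vw, pair_ids = pair_table$pair_id,
                   scaling = "none"),
              class = "difference_view")
  })
  setNames(out, views)
}

#' @export
print.difference_view <- function(x, ...) {
  cat(sprintf("difference view '%s': %d pairs x %d variables (%.1f%% missing, scaling: %s)\n",
              x$view, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values)),
              if (identical(x$scaling, "none")) "none" else "unit variance"))
  invisible(x)
}

# shared column-dropping core used by the missingness filters
drop_columns <- function(view, drop, rule, statistic) {
  report <- data.frame(variable = colnames(view$values)[drop],
                       view = rep(view$view, sum(drop)),
                       rule = rep(rule, sum(drop)),
                       statistic = statistic[drop])
  view$values <- view$values[, !drop, drop = FALSE]
  if (!identical(view$scaling, "none")) {
    view$scaling$center <- view$scaling$center[!drop]
    view$scaling$scale <- view$scaling$scale[!drop]
  }
  if (ncol(view$values) == 0)
    tgfa_warn("tgfa_empty_view", sprintf("view '%s' has no variables left",
                                         view$view))
  list(view = view, report = report)
}

#' Drop variables with too many missing values
#'
#' Removes every column whose missing fraction is strictly greater than
#' the threshold: 50% is the model-input default for all views; the
#' cytokine panel uses 25% applied at the twin level upstream (see
#' [preprocess_cohort()]).
#'
#' @param view a \code{difference_view} (or plain matrix).
#' @param max_missing_frac threshold in \[0, 1\] (default 0.5).
#' @return list with the filtered `view` and a `report` data frame
#'   (variable, view, rule, statistic = missing fraction).
#' @export
filter_missing <- function(view, max_missing_frac = 0.5) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  plain <- !inherits(view, "difference_view")
  if (plain)
    view <- structure(list(values = as.matrix(view), view = "matrix",
                           pair_ids = rownames(view), scaling = "none"),
                      class = "difference_view")
  frac <- colMeans(is.na(view$values))
  res <- drop_columns(view, frac > max_missing_frac,
                      sprintf("missing_frac > %g", max_missing_frac), frac)
  if (plain) res$view <- res$view$values
  res
}

#' Remove rare- and ubiquitous-carrier SNPs
#'
#' A SNP column is removed when the number of pairs carrying a nonzero
#' risk-allele dosage is at most `min_carrier_pairs - 1` (too rare: 3 or
#' fewer carrier pairs under the default) or greater than
#' `max_carrier_pairs` (near-universal: more than 38 under the default) —
#' such SNPs cannot be linked to within-pair differences and would only
#' pull the model toward a different locally optimal solution.
#'
#' @param view the genotype \code{difference_view}; entries must be risk
#'   allele dosages 0/1/2 or missing.
#' @param min_carrier_pairs smallest carrier count kept (default 4).
#' @param max_carrier_pairs largest carrier count kept (default 38).
#' @return list with the filtered `view` and a `report` data frame.
#' @export
filter_snp_carriers <- function(view, min_carrier_pairs = 4,
                                max_carrier_pairs = 38) {
  v <- view$values
  ok <- is.na(v) | v == 0 | v == 1 | v == 2
  if (!all(ok))
    tgfa_stop("tgfa_bad_dosage",
              "genotype entries must be dosages 0, 1, 2 or missing")
  carriers <- colSums(v != 0, na.rm = TRUE)
  drop <- carriers <= (min_carrier_pairs - 1) | carriers > max_carrier_pairs
  drop_columns(view, drop,
               sprintf("carrier_pairs outside [%d, %d]", min_carrier_pairs,
                       max_carrier_pairs), carriers)
}

#' Scale views to unit variance
#'
#' Mean-centres each column and scales it to unit sample variance over its
#' observed entries — for every view except genotype, which enters the
#' model unscaled (and uncentred) so that dosage components can capture
#' near-universal risk alleles. Zero-variance columns cannot be scaled and
#' are dropped with a warning. The applied centre/scale is recorded in
#' each view's `scaling` field and can be undone exactly with
#' [invert_scaling()].
#'
#' @param views named list of \code{difference_view} objects.
#' @param skip_views view labels returned untouched (default
#'   `"genotype"`).
#' @param center mean-centre before scaling (default TRUE).
#' @return named list of views with scaling records.
#' @export
standardize_views <- function(views, skip_views = "genotype", center = TRUE) {
  lapply(views, function(v) {
    if (v$view %in% skip_views) return(v)
    ctr <- if (center) colMeans(v$values, na.rm = TRUE) else
      rep(0, ncol(v$values))
    sc <- sqrt(apply(v$values, 2, var, na.rm = TRUE))
    degenerate <- !is.finite(sc) | sc == 0
    if (any(degenerate)) {
      tgfa_warn("tgfa_zero_variance", sprintf(
        "dropping zero-variance variable(s) in view '%s': %s", v$view,
        paste(colnames(v$values)[degenerate], collapse = ", ")))
      v$values <- v$values[, !degenerate, drop = FALSE]
      ctr <- ctr[!degenerate]; sc <- sc[!degenerate]
    }
    v$values <- sweep(sweep(v$values, 2, ctr), 2, sc, "/")
    v$scaling <- list(center = ctr, scale = sc)
    v
  })
}

#' Undo the recorded standardization of a view
#'
#' @param view a \code{difference_view} with a scaling record.
#' @return the view on its original scale.
#' @export
invert_scaling <- function(view) {
  if (identical(view$scaling, "none")) return(view)
  view$values <- sweep(sweep(view$values, 2, view$scaling$scale, "*"),
                       2, view$scaling$center, "+")
  view$scaling <- "none"
  view
}

#' Full preprocessing pipeline: twin cohort to model-ready views
#'
#' Applies, in order: one-hot encoding of categorical smoking variables;
#' the twin-level 25% missingness rule for the cytokine panel; BMI
#' ordering of pairs; heavier-minus-leaner differencing (pair-constant
#' variables passed through); the 50% missingness rule per difference
#' view; the SNP carrier-band filter on the genotype view; and unit
#' variance scaling of all views except genotype. This order makes each
#' filter's threshold refer to the counts its rule is stated in
#' (twin-level for the cytokine panel, pair-level for the rest).
#'
#' @param cohort a [twin_cohort()].
#' @param bmi_threshold discordance threshold in kg/m^2 (default 3).
#' @param tie_break see [order_pairs_by_bmi()].
#' @param max_missing_frac pair-level missingness threshold (default 0.5).
#' @param cytokine_missing_frac twin-level threshold for the cytokine view
#'   (default 0.25).
#' @param min_carrier_pairs,max_carrier_pairs SNP carrier band (defaults
#'   4 and 38).
#' @param scale apply [standardize_views()] (default TRUE).
#' @param center mean-centre non-genotype views before scaling.
#' @return list with `views` (named list of \code{difference_view}),
#'   `pair_table`, and `removed` (combined filter report).
#' @export
preprocess_cohort <- function(cohort, bmi_threshold = 3, tie_break = NULL,
                              max_missing_frac = 0.5,
                              cytokine_missing_frac = 0.25,
                              min_carrier_pairs = 4, max_carrier_pairs = 38,
                              scale = TRUE, center = TRUE) {
  for (v in cohort$meta$name[cohort$meta$vtype == "categorical"])
    cohort <- encode_smoking_onehot(cohort, v)
  removed <- list()
  # cytokine missingness rule applied at the twin level, before differencing
  cyto <- cohort$meta$name[cohort$meta$view == "cytokine"]
  if (length(cyto)) {
    frac <- vapply(cyto, function(v) mean(is.na(cohort$values[[v]])), 0)
    drop <- names(frac)[frac > cytokine_missing_frac]
    if (length(drop)) {
      removed$cytokine_twin <- data.frame(
        variable = drop, view = "cytokine",
        rule = sprintf("twin-level missing_frac > %g", cytokine_missing_frac),
        statistic = frac[drop])
      cohort$values <- cohort$values[, setdiff(names(cohort$values), drop),
                                     drop = FALSE]
      cohort$meta <- cohort$meta[!cohort$meta$name %in% drop, , drop = FALSE]
    }
  }
  pair_table <- order_pairs_by_bmi(cohort, bmi_threshold, tie_break)
  views <- compute_pair_differences(cohort, pair_table)
  views <- lapply(views, function(v) {
    res <- filter_missing(v, max_missing_frac)
    removed[[paste0(v$view, "_missing")]] <<- res$report
    res$view
  })
  if ("genotype" %in% names(views)) {
    res <- filter_snp_carriers(views$genotype, min_carrier_pairs,
                               max_carrier_pairs)
    removed$genotype_carriers <- res$report
    views$genotype <- res$view
  }
  if (scale) views <- standardize_views(views, center = center)
  list(views = views, pair_table = pair_table,
       removed = do.call(rbind, c(removed, list(make.row.names = FALSE))))
}
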