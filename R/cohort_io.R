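#' Construct and validate a twin cohort table
#'
#' A cohort holds twin-level observations (one row per twin) for all views
#' in a single table, together with the pair map and per-variable
#' metadata. Invariants checked: every `pair_id` occurs exactly twice,
#' `sample_id`s are unique, the BMI variable is present and non-missing
#' for every twin, and every data column has exactly one metadata row.
#'
#' @param values data frame of twin-level observations (columns numeric,
#'   or character for categorical variables such as smoking status).
#' @param sample_id character vector of unique twin identifiers.
#' @param pair_id character vector of pair identifiers (each twice).
#' @param meta data frame with columns `name`, `view` (one of clinical,
#'   cytokine, genotype, methylation, dietary), `vtype` (continuous,
#'   binary, categorical, dosage), `pair_constant` (logical), `units`.
#' @param bmi_variable name of the column used for heavier/leaner ordering.
#' @return an object of class \code{twin_cohort}.
#' @export
twin_cohort <- function(values, sample_id, pair_id, meta,
                        bmi_variable = "bmi") {
  values <- as.data.frame(values, check.names = FALSE)
  sample_id <- as.character(sample_id)
  pair_id <- as.character(pair_id)
  stopifnot(nrow(values) == length(sample_id),
            length(sample_id) == length(pair_id))
  if (anyDuplicated(sample_id))
    tgfa_stop("tgfa_duplicate_sample", sprintf(
      "duplicate sample_id: %s",
      paste(unique(sample_id[duplicated(sample_id)]), collapse = ", ")))
  tab <- table(pair_id)
  bad <- names(tab)[tab != 2]
  if (length(bad))
    tgfa_stop("tgfa_unpaired_sample", sprintf(
      "pair_id not occurring exactly twice: %s", paste(bad, collapse = ", ")))
  req <- c("name", "view", "vtype", "pair_constant")
  if (!all(req %in% names(meta)))
    tgfa_stop("tgfa_bad_meta", sprintf(
      "metadata must have columns %s", paste(req, collapse = ", ")))
  if (!"units" %in% names(meta)) meta$units <- ""
  known_views <- c("clinical", "cytokine", "genotype", "methylation", "dietary")
  if (!all(meta$view %in% known_views))
    tgfa_stop("tgfa_bad_meta", "unknown view label in metadata")
  no_meta <- setdiff(names(values), meta$name)
  if (length(no_meta))
    tgfa_stop("tgfa_missing_meta", sprintf(
      "variables without metadata: %s", paste(no_meta, collapse = ", ")))
  if (anyDuplicated(meta$name))
    tgfa_stop("tgfa_bad_meta", "duplicate metadata rows")
  meta <- meta[meta$name %in% names(values), , drop = FALSE]
  if (any(meta$vtype == "dosage" & meta$view != "genotype"))
    tgfa_stop("tgfa_bad_meta", "dosage variables allowed only in the genotype view")
  if (!bmi_variable %in% names(values))
    tgfa_stop("tgfa_missing_bmi", sprintf(
      "BMI variable '%s' not found", bmi_variable))
  if (any(is.na(values[[bmi_variable]])))
    tgfa_stop("tgfa_missing_bmi", sprintf(
      "BMI variable '%s' has missing values", bmi_variable))
  structure(list(values = values, sample_id = sample_id, pair_id = pair_id,
                 meta = meta, bmi_variable = bmi_variable),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat(sprintf("twin cohort: %d twins in %d pairs, %d variables (%s)\n",
              length(x$sample_id), length(unique(x$pair_id)),
              ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$meta$view)),
                            as.integer(table(x$meta$view))), collapse = " ")))
  invisible(x)
}

#' Read a twin cohort from delimited text files
#'
#' Reads one matrix file per view (CSV, first column `sample_id`, header
#' row of variable names, empty string or `NA` as missing), a pair map
#' (`sample_id,pair_id`) and a variable metadata table, validates them and
#' assembles a [twin_cohort()]. Samples are aligned across views by
#' `sample_id`; missing cells are preserved, never imputed.
#'
#' @param matrix_files named character vector of per-view file paths
#'   (names are view labels; they must match the metadata `view` column).
#' @param pair_map_file CSV with columns `sample_id`, `pair_id`.
#' @param meta_file CSV with the [twin_cohort()] metadata columns.
#' @param bmi_variable name of the BMI column (default `"bmi"`).
#' @return a \code{twin_cohort}.
#' @export
read_cohort <- function(matrix_files, pair_map_file, meta_file,
                        bmi_variable = "bmi") {
  for (f in c(matrix_files, pair_map_file, meta_file))
    if (!file.exists(f))
      tgfa_stop("tgfa_missing_file", sprintf("file not found: %s", f))
  pm <- read.csv(pair_map_file, colClasses = "character")
  if (!all(c("sample_id", "pair_id") %in% names(pm)))
    tgfa_stop("tgfa_bad_pair_map", "pair map needs sample_id and pair_id columns")
  meta <- read.csv(meta_file, check.names = FALSE)
  meta$pair_constant <- as.logical(meta$pair_constant)
  mats <- lapply(matrix_files, function(f) {
    d <- read.csv(f, check.names = FALSE, na.strings = c("NA", ""))
    names(d)[1] <- "sample_id"
    d$sample_id <- as.character(d$sample_id)
    if (anyDuplicated(d$sample_id))
      tgfa_stop("tgfa_duplicate_sample", sprintf(
        "duplicate sample_id in %s", f))
    d
  })
  ids <- mats[[1]]$sample_id
  for (d in mats) {
    if (!setequal(d$sample_id, ids))
      tgfa_stop("tgfa_sample_mismatch",
                "views do not share an identical sample set")
  }
  absent <- setdiff(pm$sample_id, ids)
  if (length(absent))
    tgfa_stop("tgfa_unknown_sample", sprintf(
      "pair map lists samples absent from the matrices: %s",
      paste(absent, collapse = ", ")))
  extra <- setdiff(ids, pm$sample_id)
  if (length(extra))
    tgfa_stop("tgfa_unpaired_sample", sprintf(
      "samples missing from the pair map: %s", paste(extra, collapse = ", ")))
  values <- do.call(cbind, lapply(seq_along(mats), function(i) {
    d <- mats[[i]]
    d <- d[match(ids, d$sample_id), setdiff(names(d), "sample_id"),
           drop = FALSE]
    d
  }))
  pair_id <- pm$pair_id[match(ids, pm$sample_id)]
  twin_cohort(values, ids, pair_id, meta, bmi_variable = bmi_variable)
}

fmt10 <- function(x) {
  # 10 significant digits, plain notation where possible
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

write_num_csv <- function(mat, path, row_label) {
  df <- data.frame(rownames(mat) %||% seq_len(nrow(mat)),
                   apply(mat, 2, fmt10), check.names = FALSE)
  names(df) <- c(row_label, colnames(mat))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_num_csv <- function(path, row_label) {
  d <- read.csv(path, check.names = FALSE)
  rn <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- rn
  m
}

#' Write posterior result tables
#'
#' Writes, as comma-separated text at 10 significant digits: one loading
#' matrix per view (variables x components, posterior means), the score
#' matrix (pairs x components), the activity matrix (views x components,
#' posterior inclusion probabilities), a per-component `pi` summary,
#' per-variable residual variances, and a JSON run manifest recording the
#' configuration, seed and package version. [read_results()] reproduces
#' the written values bit-exactly at the printed precision.
#'
#' @param posterior a \code{gfa_posterior} from [run_chain()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the character vector of files written.
#' @export
write_results <- function(posterior, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outdir, 2) != 0)
    tgfa_stop("tgfa_unwritable", sprintf("cannot write to %s", outdir))
  files <- character(0)
  K <- ncol(posterior$activity)
  comp <- sprintf("comp%02d", seq_len(K))
  for (m in seq_along(posterior$Wmean)) {
    W <- posterior$Wmean[[m]]
    colnames(W) <- comp
    f <- file.path(outdir, sprintf("loadings_%s.csv", posterior$view_names[m]))
    write_num_csv(W, f, "variable")
    files <- c(files, f)
  }
  Z <- posterior$Zmean
  rownames(Z) <- posterior$pair_ids
  colnames(Z) <- comp
  f <- file.path(outdir, "scores.csv"); write_num_csv(Z, f, "pair_id")
  files <- c(files, f)
  A <- posterior$activity
  rownames(A) <- posterior$view_names; colnames(A) <- comp
  f <- file.path(outdir, "activity.csv"); write_num_csv(A, f, "view")
  files <- c(files, f)
  pi_sum <- cbind(mean = colMeans(posterior$pi_draws),
                  sd = apply(posterior$pi_draws, 2, sd),
                  q025 = apply(posterior$pi_draws, 2, quantile, 0.025),
                  q975 = apply(posterior$pi_draws, 2, quantile, 0.975))
  rownames(pi_sum) <- comp
  f <- file.path(outdir, "pi_summary.csv"); write_num_csv(pi_sum, f, "component")
  files <- c(files, f)
  rv <- do.call(rbind, lapply(seq_along(posterior$sigma2_mean), function(m)
    data.frame(variable = posterior$var_names[[m]],
               view = posterior$view_names[m],
               residual_variance = fmt10(posterior$sigma2_mean[[m]]))))
  f <- file.path(outdir, "residual_variance.csv")
  write.csv(rv, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  manifest <- list(
    package = "twingfa",
    version = as.character(packageVersion("twingfa")),
    gamma_convention = "shape-rate",
    seed = posterior$config$chain$seed,
    K = posterior$config$hyper$K,
    n_iter = posterior$config$chain$n_iter,
    burnin_frac = posterior$config$chain$burnin_frac,
    thinning = posterior$config$chain$thinning,
    n_retained = posterior$n_retained,
    noise_target = posterior$config$hyper$noise_target,
    hyper = posterior$config$hyper[c("a_pi", "b_pi", "a_alpha", "b_alpha",
                                     "a_tau")],
    views = as.list(setNames(vapply(posterior$var_names, length, 0L),
                             posterior$view_names))
  )
  f <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, f)
  invisible(files)
}

#' Read back result tables written by [write_results()]
#'
#' @param outdir directory written by [write_results()].
#' @return list with `loadings` (per view), `scores`, `activity`,
#'   `pi_summary`, `residual_variance` and the parsed `manifest`.
#' @export
read_results <- function(outdir) {
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                                  simplifyVector = TRUE)
  views <- names(manifest$views)
  loadings <- setNames(lapply(views, function(v)
    read_num_csv(file.path(outdir, sprintf("loadings_%s.csv", v)),
                 "variable")), views)
  list(loadings = loadings,
       scores = read_num_csv(file.path(outdir, "scores.csv"), "pair_id"),
       activity = read_num_csv(file.path(outdir, "activity.csv"), "view"),
       pi_summary = read_num_csv(file.path(outdir, "pi_summary.csv"),
                                 "component"),
       residual_variance = read.csv(file.path(outdir,
                                              "residual_variance.csv")),
       manifest = manifest)
}
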