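# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

# A 4-twin / 2-pair cohort with three clinical variables and a smoking
# status column. Pair p1: BMI 30 vs 27 (discordant at the 3 kg/m^2
# threshold is FALSE: delta = 3 exactly is not > 3); pair p2: 32 vs 24.
tiny_cohort <- function(smoking = c("current", "never", "current", "current"),
                        bmi = c(30, 27, 32, 24)) {
  values <- data.frame(
    bmi = bmi,
    weight = c(88, 80.5, 95, 70),
    gender = c(1, 1, 0, 0),
    smoking = smoking,
    stringsAsFactors = FALSE)
  meta <- data.frame(
    name = c("bmi", "weight", "gender", "smoking"),
    view = "clinical",
    vtype = c("continuous", "continuous", "binary", "categorical"),
    pair_constant = c(FALSE, FALSE, TRUE, FALSE),
    units = c("kg m-2", "kg", "", ""))
  twin_cohort(values, sample_id = c("t1a", "t1b", "t2a", "t2b"),
              pair_id = c("p1", "p1", "p2", "p2"), meta = meta)
}

# Write a cohort in the cohort_io CSV conventions; returns the file paths.
write_cohort_files <- function(cohort, dir) {
  views <- unique(cohort$meta$view)
  mats <- setNames(file.path(dir, paste0(views, ".csv")), views)
  for (vw in views) {
    vars <- cohort$meta$name[cohort$meta$view == vw]
    df <- cbind(sample_id = cohort$sample_id,
                cohort$values[, vars, drop = FALSE])
    write.csv(df, mats[[vw]], row.names = FALSE, quote = FALSE, na = "")
  }
  pm <- file.path(dir, "pair_map.csv")
  write.csv(data.frame(sample_id = cohort$sample_id,
                       pair_id = cohort$pair_id),
            pm, row.names = FALSE, quote = FALSE)
  mf <- file.path(dir, "variable_meta.csv")
  write.csv(cohort$meta, mf, row.names = FALSE, quote = FALSE)
  list(matrices = mats, pair_map = pm, meta = mf)
}

# Small two-view dataset drawn from the model with one shared and one
# view-specific component; returns views plus generating truth.
tiny_sim <- function(n = 30, d = c(a = 6, b = 8), seed = 1) {
  set.seed(seed)
  mask <- rbind(c(1, 1), c(1, 0))
  simulate_difference_views(n, d, mask)
}

# Minimal hand-built posterior object for the pure summary functions.
fake_posterior <- function(activity, Zmean = NULL, Wmean = NULL,
                           sigma2 = NULL, var_names = NULL) {
  M <- nrow(activity); K <- ncol(activity)
  vn <- rownames(activity) %||% sprintf("view%d", seq_len(M))
  structure(list(
    activity = activity,
    Zmean = Zmean %||% matrix(rnorm(10 * K), 10, K),
    Wmean = Wmean,
    sigma2_mean = sigma2,
    view_names = vn,
    var_names = var_names,
    pair_ids = sprintf("pair%02d", 1:10),
    n_retained = 1L), class = "gfa_posterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# batch-means standard error for autocorrelated chains
batch_se <- function(x, n_batches = 100) {
  n <- n_batches * floor(length(x) / n_batches)
  b <- colMeans(matrix(x[seq_len(n)], ncol = n_batches))
  sd(b) / sqrt(n_batches)
}
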