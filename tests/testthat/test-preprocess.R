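test_that("pairs are ordered by BMI deterministically, independent of row order", {
  cohort <- tiny_cohort()
  pt <- order_pairs_by_bmi(cohort)
  expect_equal(pt$heavier, c("t1a", "t2a"))
  expect_equal(pt$delta_bmi, c(3, 8))
  # delta = 3 is not > 3; 8 is
  expect_equal(pt$discordant, c(FALSE, TRUE))

  # swapping the two input rows of a pair changes nothing
  swapped <- tiny_cohort(bmi = c(27, 30, 32, 24),
                         smoking = c("never", "current", "current", "current"))
  swapped$values$weight <- c(80.5, 88, 95, 70)
  sw_ids <- c("t1b", "t1a", "t2a", "t2b")
  cohort2 <- twin_cohort(swapped$values, sw_ids, cohort$pair_id, cohort$meta)
  pt2 <- order_pairs_by_bmi(cohort2)
  expect_equal(pt2$heavier, pt$heavier)
  expect_equal(pt2$delta_bmi, pt$delta_bmi)
})

test_that("exact BMI ties error unless an explicit tie-break is configured", {
  cohort <- tiny_cohort(bmi = c(30, 30, 32, 24))
  expect_error(order_pairs_by_bmi(cohort), "tie_break",
               class = "tgfa_bmi_tie")
  pt <- order_pairs_by_bmi(cohort, tie_break = c("weight", "sample_id"))
  expect_equal(pt$heavier[1], "t1a")  # weight 88 > 80.5
})

test_that("smoking one-hot encoding follows the never/former/current convention", {
  cohort <- tiny_cohort(smoking = c("current", "never", "current", "current"))
  enc <- encode_smoking_onehot(cohort)
  oh <- enc$values[, c("smoking.never", "smoking.former", "smoking.current")]
  expect_equal(unname(unlist(oh[1, ])), c(0, 0, 1))   # "current" -> (0,0,1)
  expect_true(all(rowSums(oh) == 1))

  pt <- order_pairs_by_bmi(enc)
  views <- compute_pair_differences(enc, pt)
  d <- views$clinical$values
  # heavier current, leaner never -> +1 / -1; both current -> all zero
  expect_equal(unname(d["p1", c("smoking.current", "smoking.never",
                                "smoking.former")]), c(1, -1, 0))
  expect_equal(unname(d["p2", c("smoking.current", "smoking.never",
                                "smoking.former")]), c(0, 0, 0))

  bad <- tiny_cohort(smoking = c("pipe", "never", "current", "current"))
  expect_error(encode_smoking_onehot(bad), "pipe",
               class = "tgfa_unknown_level")
})

test_that("differences are heavier minus leaner; pair-constant columns pass through", {
  cohort <- encode_smoking_onehot(tiny_cohort())
  pt <- order_pairs_by_bmi(cohort)
  views <- compute_pair_differences(cohort, pt)
  d <- views$clinical$values
  expect_equal(unname(d[, "weight"]), c(7.5, 25))   # 88-80.5, 95-70
  expect_true(all(d[, "bmi"] > 0))                  # strictly positive by design
  expect_equal(unname(d[, "gender"]), c(1, 0))      # shared value, female = 1

  # antisymmetry: relabelling heavier <-> leaner flips every
  # non-pair-constant column and leaves pair-constant columns unchanged
  pt_flip <- pt
  pt_flip$heavier <- pt$leaner; pt_flip$leaner <- pt$heavier
  d2 <- compute_pair_differences(cohort, pt_flip)$clinical$values
  pc <- cohort$meta$pair_constant[match(colnames(d), cohort$meta$name)]
  expect_equal(d2[, !pc], -d[, !pc])
  expect_equal(d2[, pc], d[, pc])
})

test_that("missing twin values propagate and differing pair-constants error", {
  cohort <- encode_smoking_onehot(tiny_cohort())
  cohort$values$weight[1] <- NA
  pt <- order_pairs_by_bmi(cohort)
  d <- compute_pair_differences(cohort, pt)$clinical$values
  expect_true(is.na(d["p1", "weight"]))
  expect_false(anyNA(d["p2", ]))

  bad <- encode_smoking_onehot(tiny_cohort())
  bad$values$gender <- c(1, 0, 0, 0)   # pair-constant violated in p1
  expect_error(compute_pair_differences(bad, pt), "gender",
               class = "tgfa_pair_constant_violation")
})

test_that("the missingness filter drops columns strictly above the threshold", {
  # 43 pairs as in the study: 22/43 = 0.512 dropped, 21/43 = 0.488 kept
  m <- matrix(rnorm(43 * 3), 43, 3,
              dimnames = list(NULL, c("dropme", "keepme", "full")))
  m[1:22, "dropme"] <- NA
  m[1:21, "keepme"] <- NA
  res <- filter_missing(m, 0.5)
  expect_equal(colnames(res$view), c("keepme", "full"))
  expect_equal(res$report$variable, "dropme")
  expect_equal(res$report$statistic, 22 / 43)

  # threshold 0 keeps a fully observed column
  res0 <- filter_missing(m[, "full", drop = FALSE], 0)
  expect_equal(ncol(res0$view), 1)

  # idempotence
  res2 <- filter_missing(res$view, 0.5)
  expect_equal(res2$view, res$view)
  expect_equal(nrow(res2$report), 0)
})

test_that("the SNP carrier band removes rare and near-universal SNPs", {
  n <- 43
  v <- structure(list(
    values = cbind(rare = c(rep(1, 3), rep(0, n - 3)),
                   common = c(rep(1, 39), rep(0, n - 39)),
                   ok = c(rep(2, 10), rep(0, n - 10))),
    view = "genotype", pair_ids = sprintf("p%02d", 1:n), scaling = "none"),
    class = "difference_view")
  res <- filter_snp_carriers(v)
  expect_equal(colnames(res$view$values), "ok")    # 3 and 39 carriers removed
  expect_setequal(res$report$variable, c("rare", "common"))

  # idempotence
  res2 <- filter_snp_carriers(res$view)
  expect_equal(res2$view$values, res$view$values)

  v$values[1, 1] <- 0.5
  expect_error(filter_snp_carriers(v), class = "tgfa_bad_dosage")
})

test_that("standardization gives unit variance, skips genotype, inverts exactly", {
  mk <- function(vals, label) structure(
    list(values = vals, view = label, pair_ids = rownames(vals),
         scaling = "none"), class = "difference_view")
  clin <- mk(cbind(a = c(2, 4, 6), b = c(1, 1.5, 5)), "clinical")
  geno <- mk(cbind(s1 = c(0, 1, 2)), "genotype")
  out <- standardize_views(list(clinical = clin, genotype = geno))
  expect_equal(unname(apply(out$clinical$values, 2, var)), c(1, 1))
  expect_identical(out$genotype$values, geno$values)   # bit-identical
  expect_identical(out$genotype$scaling, "none")

  back <- invert_scaling(out$clinical)
  expect_equal(back$values, clin$values, tolerance = 1e-12)

  # zero-variance columns cannot be scaled and are dropped with a warning
  degen <- mk(cbind(flat = c(1, 1, 1), ok = c(0, 1, 3)), "dietary")
  expect_warning(res <- standardize_views(list(dietary = degen)),
                 class = "tgfa_zero_variance")
  expect_equal(colnames(res$dietary$values), "ok")
})

test_that("the full preprocessing pipeline is deterministic and applies the cytokine rule at twin level", {
  sim <- simulate_twin_cohort(sim_config(seed = 11))
  # force one cytokine variable above the 25% twin-level rule
  cohort <- sim$cohort
  cy <- cohort$meta$name[cohort$meta$view == "cytokine"][1]
  n <- nrow(cohort$values)
  cohort$values[[cy]][seq_len(ceiling(0.3 * n))] <- NA
  p1 <- preprocess_cohort(cohort)
  p2 <- preprocess_cohort(cohort)
  expect_false(cy %in% colnames(p1$views$cytokine$values))
  expect_true(any(grepl("twin-level", p1$removed$rule)))
  expect_identical(p1$views, p2$views)   # bit-identical pipeline
})
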