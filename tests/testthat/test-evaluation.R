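test_that("between-biospecimen correlations hit the algebraic extremes", {
  a <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("m", 1:4), paste0("s", 1:10)))
  st_same <- paired_study(a, a, factor(rep(c("g1", "g2"), 5)),
                          log_scale = TRUE)
  expect_equal(between_biospecimen_correlations(st_same)$r, rep(1, 4),
               ignore_attr = TRUE)
  b <- -(a - rowMeans(a)) + 3
  st_neg <- paired_study(a, b, factor(rep(c("g1", "g2"), 5)),
                         log_scale = TRUE)
  expect_equal(between_biospecimen_correlations(st_neg)$r, rep(-1, 4),
               ignore_attr = TRUE)
  # zero-variance rows are flagged undefined, not errors
  a2 <- a; a2[2, ] <- 7
  st_flat <- paired_study(a2, a, factor(rep(c("g1", "g2"), 5)),
                          log_scale = TRUE)
  r <- between_biospecimen_correlations(st_flat)$r
  expect_true(is.na(r[2]) && !anyNA(r[-2]))
})

test_that("sample correlations are unbiased for the generating value", {
  # narrow profile pinned near 0.5; mean sample r over many replicate
  # studies converges to it at N = 79
  pr <- correlation_profile("custom", r_min = 0.49, r_max = 0.51,
                            r_mode = 0.5, concentration = 50)
  rs <- sapply(1:500, function(s) {
    st <- generate_paired_study(group_design(48, 31, 0, 0), pr, 2, seed = s)
    between_biospecimen_correlations(log_transform_study(st))$r
  })
  expect_equal(mean(rs), 0.5, tolerance = 0.02)
})

test_that("Hotelling MANOVA matches its contracts and invariances", {
  g <- factor(rep(c("a", "b"), each = 6))
  # identical data in both groups: T2 = 0, p = 1
  v <- c(1, 5, 2, 8, 3, 9)
  r0 <- manova_two_group(c(v, v), c(rev(v), rev(v)), factor(rep(c("a", "b"),
                                                               each = 6)))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  set.seed(3)
  a <- rnorm(12) + (g == "a")
  b <- rnorm(12) + 0.5 * (g == "a")
  r <- manova_two_group(a, b, g)
  # invariant to subject reordering and to swapping the two biospecimens
  perm <- sample(12)
  expect_equal(manova_two_group(a[perm], b[perm], g[perm])$p_value,
               r$p_value, tolerance = 1e-12)
  expect_equal(manova_two_group(b, a, g)$p_value, r$p_value,
               tolerance = 1e-12)
  expect_error(manova_two_group(a, b, factor(rep("a", 12))), "two levels")
  expect_error(manova_two_group(a[1:5], b[1:5],
                                factor(c("a", "a", "a", "b", "b"))),
               "at least 3")
})

test_that("Hotelling p-values equal classical MANOVA on random instances", {
  for (s in 1:5) {
    set.seed(s)
    g <- factor(rep(c("a", "b"), c(7, 9)))
    a <- rnorm(16) + 0.7 * (g == "a")
    b <- rnorm(16)
    ours <- manova_two_group(a, b, g)$p_value
    fit <- summary(stats::manova(cbind(a, b) ~ g), test = "Pillai")
    expect_equal(ours, fit$stats[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("singular pooled covariance yields a flagged non-call", {
  g <- factor(rep(c("a", "b"), each = 4))
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_warning(r <- manova_two_group(a, a, g), "singular")
  expect_false(r$call)
  expect_true(r$singular && is.na(r$p_value))
})

test_that("validity metrics follow their definitions", {
  truth <- c(rep(TRUE, 4), rep(FALSE, 6))
  imputed <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
               TRUE)
  vm <- validity_metrics(truth, imputed)
  expect_identical(c(vm$TP, vm$FN, vm$TN, vm$FP), c(3L, 1L, 5L, 1L))
  expect_equal(vm$sensitivity, 0.75)
  expect_equal(vm$specificity, 5 / 6)
  expect_equal(vm$accuracy, 0.8)
  expect_identical(vm$TP + vm$FP + vm$TN + vm$FN, length(truth))
  # perfect agreement
  vm1 <- validity_metrics(truth, truth)
  expect_equal(c(vm1$sensitivity, vm1$specificity, vm1$accuracy),
               c(1, 1, 1))
  # all-negative imputed calls
  vm0 <- validity_metrics(truth, rep(FALSE, 10))
  expect_equal(vm0$sensitivity, 0)
  expect_equal(vm0$specificity, 1)
  # undefined rates on zero denominators
  expect_true(is.na(validity_metrics(rep(FALSE, 5),
                                     rep(FALSE, 5))$sensitivity))
})

test_that("bias summaries aggregate and exclude undefined records", {
  rec <- data.frame(metabolite = c("a", "b", "c"),
                    r_true = c(0.5, 0.5, 0.2),
                    r_imputed = c(0.4, 0.6, NA),
                    bias = c(-0.1, 0.1, NA))
  s <- bias_summary(rec)
  expect_equal(s$mean_bias, 0)
  expect_equal(s$mean_abs_bias, 0.1)
  expect_identical(s$n, 2L)
  expect_identical(s$n_undefined, 1L)
  rec$method <- c("HM", "HM", "RF")
  g <- bias_summary(rec, by = "method")
  expect_identical(nrow(g), 2L)
  expect_identical(g$n[g$method == "RF"], 0L)
})

test_that("bias is exactly zero without missingness", {
  st <- log_transform_study(small_study(n_metabolites = 20))
  rec <- correlation_records(st, st)
  expect_true(all(rec$bias == 0))
  expect_true(all(rec$n_missing_A == 0L))
})

test_that("attenuation grows with missingness for every method", {
  # the central qualitative effect: more missingness pulls imputed
  # between-biospecimen correlations toward zero
  reps <- 6
  mab <- array(NA_real_, c(reps, 2, 5),
               dimnames = list(NULL, c("p5", "p60"), imputation_methods()))
  for (r in seq_len(reps)) {
    st <- small_study(n_metabolites = 40, n1 = 12, n2 = 12, seed = 300 + r)
    logc <- log_transform_study(st)
    for (pi in 1:2) {
      p <- c(5, 60)[pi]
      ma <- induce_missingness(st$A, p, seed = 400 + r)
      mb <- induce_missingness(st$B, p, seed = 500 + r)
      masked <- log_transform_study(mask_study(st, ma, mb))
      for (me in imputation_methods()) {
        imp <- suppressWarnings(
          impute_study(masked, me, "separate", fast_settings(seed = r)))
        rec <- correlation_records(logc, imp, ma, mb)
        mab[r, pi, me] <- mean(abs(rec$r_imputed), na.rm = TRUE)
      }
    }
  }
  for (me in imputation_methods()) {
    expect_lt(mean(mab[, "p60", me]), mean(mab[, "p5", me]))
  }
})
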