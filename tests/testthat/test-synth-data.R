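test_that("generated studies have the requested structure", {
  st <- generate_paired_study(group_design(48, 31, 0.23, 1),
                              correlation_profile("high"), 176, seed = 1)
  expect_identical(dim(st$A), c(176L, 79L))
  expect_identical(dim(st$B), c(176L, 79L))
  expect_identical(rownames(st$A), rownames(st$B))
  expect_equal(as.vector(table(st$groups)), c(48L, 31L),
               ignore_attr = TRUE)
  expect_true(all(st$A > 0) && all(st$B > 0))
  expect_false(st$log_scale)
  expect_true(all(st$true_r >= -0.2 & st$true_r <= 0.98))
})

test_that("differential truth counts are exact and deterministic", {
  for (case in list(c(176, 0.23), c(327, 0.21), c(40, 0), c(10, 1))) {
    m <- case[1]; d <- case[2]
    st <- generate_paired_study(group_design(10, 10, d, 1),
                                correlation_profile("low"), m, seed = 5)
    expect_identical(sum(st$true_de), as.integer(round(d * m)))
  }
})

test_that("identical seeds give bit-identical studies", {
  a <- generate_paired_study(group_design(6, 6, 0.5, 1),
                             correlation_profile("high"), 25, seed = 9)
  b <- generate_paired_study(group_design(6, 6, 0.5, 1),
                             correlation_profile("high"), 25, seed = 9)
  expect_identical(a, b)
  c <- generate_paired_study(group_design(6, 6, 0.5, 1),
                             correlation_profile("high"), 25, seed = 10)
  expect_false(identical(a$A, c$A))
})

test_that("log transform of a study is invertible", {
  st <- small_study()
  lg <- log_transform_study(st)
  expect_true(lg$log_scale)
  expect_equal(exp(lg$A), st$A, tolerance = 1e-12)
  expect_error(log_transform_study(lg), "already")
})

test_that("correlation sampler respects bounds and its analytic mean", {
  for (nm in c("high", "low")) {
    pr <- correlation_profile(nm)
    draws <- sample_correlations(pr, 10000, seed = 3)
    expect_true(all(draws >= pr$r_min & draws <= pr$r_max))
    # analytic mean of the rescaled beta distribution
    expect_equal(mean(draws), pr$mean, tolerance = 0.02)
  }
  expect_equal(correlation_profile("low")$mean, 0) # symmetric case
  expect_error(correlation_profile("custom", r_min = 0.5, r_max = 0.2,
                                   r_mode = 0.3), "r_min")
})

test_that("sample correlations converge to the generating correlation", {
  # large N: every metabolite's sample log-scale correlation sits close to
  # its generating value, and a metabolite with r near 0.8 is within 0.02
  st <- generate_paired_study(group_design(2500, 2500, 0, 0),
                              correlation_profile("high"), 50, seed = 21)
  lg <- log_transform_study(st)
  r_hat <- between_biospecimen_correlations(lg)$r
  expect_true(all(abs(r_hat - st$true_r) < 0.06))
  i <- which.min(abs(st$true_r - 0.8))
  expect_lt(abs(st$true_r[i] - 0.8), 0.1) # the profile covers 0.8
  expect_lt(abs(r_hat[i] - st$true_r[i]), 0.02)
})

test_that("null studies produce nominal MANOVA rejection rates", {
  st <- generate_paired_study(group_design(20, 20, 0, 0),
                              correlation_profile("high"), 2000, seed = 31)
  calls <- manova_calls(log_transform_study(st))
  expect_gt(mean(calls$call), 0.035)
  expect_lt(mean(calls$call), 0.065)
})

test_that("design and profile validation rejects bad inputs", {
  expect_error(group_design(2, 10), "at least 3")
  expect_error(group_design(5, 5, de_fraction = 1.2), "de_fraction")
  expect_error(group_design(5, 5, 0.1, -1), "effect_size")
  expect_error(generate_paired_study(group_design(5, 5),
                                     correlation_profile("low"), 1,
                                     seed = 1), "at least 2")
})

test_that("studies round-trip through TSV files", {
  st <- small_study(n_metabolites = 12, n1 = 4, n2 = 3)
  dir <- withr::local_tempdir()
  write_paired_study(st, dir, prefix = "fx")
  back <- read_paired_study(file.path(dir, "fx_biospecimenA.tsv"),
                            file.path(dir, "fx_biospecimenB.tsv"),
                            file.path(dir, "fx_subjects.tsv"))
  expect_equal(back$A, st$A, tolerance = 1e-6)
  expect_identical(as.character(back$groups), as.character(st$groups))
})
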