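test_that("the default corruption-impact grid enumerates 21 x 2 configurations", {
  g <- experiment_grid()
  cfgs <- enumerate_grid(g)
  expect_equal(nrow(cfgs), 42)
  expect_equal(length(unique(cfgs$fraction)), 21)
  expect_setequal(unique(cfgs$mode), c("systematic_lateral", "random"))
  expect_error(experiment_grid(fractions = c(0, 1.2)), "fractions")
  expect_error(experiment_grid(curation_rates = c(0, 0.95)), "rates")
})

test_that("truth sets corrupt only the apparent arm", {
  coh <- generate_cohort(10, tiny_params(), 41,
                         proportions = c(train = 4, val = 3, test_true = 3))
  val_before <- lapply(cases_list <- coh$cases[coh$splits == "val"],
                       function(cc) cc$mask$voxels)
  true_before <- lapply(coh$cases[coh$splits == "test_true"],
                        function(cc) cc$mask$voxels)

  sp0 <- corruption_spec("systematic_lateral", magnitude = 3, fraction = 0,
                         seed = 2)
  ts0 <- build_truth_sets(coh, sp0, seed = 5)
  expect_identical(lapply(ts0$apparent, function(cc) cc$mask$voxels), val_before)

  sp1 <- corruption_spec("systematic_lateral", magnitude = 3, fraction = 1,
                         seed = 2)
  ts1 <- build_truth_sets(coh, sp1, seed = 5)
  expect_length(ts1$apparent_corrupted_ids, 3)
  expect_true(all(vapply(ts1$apparent, `[[`, NA, "corrupted")))
  expect_identical(lapply(ts1$true, function(cc) cc$mask$voxels), true_before)

  ext <- build_truth_sets(coh, sp1, seed = 5,
                          external_params = tiny_params(side = "left"),
                          n_external = 2)
  expect_length(ext$external, 2)
})

test_that("full corruption hurts clean-test performance in both modes", {
  # standard grid and the default 10-voxel magnitude: corruption severe
  # enough that even the noise-averaging linear backend degrades
  coh <- generate_cohort(16, phantom_params(), 43,
                         proportions = c(train = 12, val = 1, test_true = 3))
  g <- experiment_grid(fractions = c(0, 1))
  res <- run_corruption_grid(coh, g, segmenter_config(epochs = 20), seed = 3,
                             magnitude = 10L)
  expect_equal(nrow(res), 8)   # 2 modes x 2 fractions x 2 splits
  for (mode in unique(res$mode)) {
    true0 <- res$median_dsc[res$mode == mode & res$fraction == 0 &
                              res$split == "test_true"]
    true1 <- res$median_dsc[res$mode == mode & res$fraction == 1 &
                              res$split == "test_true"]
    expect_lt(true1, true0)
  }
  # bias is learned and reproduced: systematic corruption leaves
  # training-distribution DSC high while true performance collapses
  sys1 <- res[res$mode == "systematic_lateral" & res$fraction == 1, ]
  expect_gt(sys1$median_dsc[sys1$split == "train"],
            sys1$median_dsc[sys1$split == "test_true"])
})

test_that("the curation matrix runs its seven conditions", {
  coh <- generate_cohort(14, tiny_params(), 47,
                         proportions = c(train = 10, val = 2, test_true = 2))
  res <- run_curation_matrix(coh, tiny_config(), seed = 9, folds = 1,
                             magnitude = 4)
  expect_equal(res$condition, 1:7)
  expect_true(all(is.na(res$sensitivity[c(1, 2, 4, 6)])))
  expect_false(anyNA(res$sensitivity[c(5, 7)]))   # ground truth available
  expect_true(all(res$median_dsc >= 0 & res$median_dsc <= 1))
})

test_that("rate sweep arms coincide at rate zero and share series lengths", {
  coh <- generate_cohort(12, tiny_params(), 53,
                         proportions = c(train = 8, val = 2, test_true = 2))
  sp <- corruption_spec("systematic_lateral", magnitude = 4, fraction = 0.25,
                        seed = 3)
  ts <- build_truth_sets(coh, sp, seed = 7)
  train_cases <- corrupt_cohort(coh$cases[coh$splits == "train"], sp)$cases
  sw <- run_rate_sweep(train_cases, ts, rates = c(0, 0.25), tiny_config(),
                       seed = 11)
  r <- sw$results
  at0 <- r[r$rate == 0, ]
  expect_equal(at0$median_dsc[at0$arm == "curation"],
               at0$median_dsc[at0$arm == "random"])
  expect_equal(sum(r$arm == "curation"), sum(r$arm == "random"))
  expect_true(sw$best_rate %in% c(0, 0.25))
})

test_that("RRSS summarizes medians and IQR across differing sub-cohorts", {
  coh <- generate_cohort(12, tiny_params(), 59,
                         proportions = c(train = 8, val = 2, test_true = 2))
  sp <- corruption_spec("systematic_lateral", magnitude = 4, fraction = 0.25,
                        seed = 5)
  ts <- build_truth_sets(coh, sp, seed = 13)
  rr <- run_rrss(coh$cases[coh$splits == "train"], ts, subsample_n = 5,
                 repeats = 2, rates = c(0, 0.2), tiny_config(), seed = 17)
  expect_true(all(c("median_dsc", "q1", "q3") %in% names(rr$summary)))
  expect_equal(sort(unique(rr$runs$repeat_id)), 1:2)
  expect_error(run_rrss(coh$cases[coh$splits == "train"], ts, 50, 2,
                        c(0), tiny_config()), "larger than pool")
})

test_that("repeated curation with one fold collapses to the single model", {
  coh <- generate_cohort(9, tiny_params(), 61,
                         proportions = c(train = 6, val = 1, test_true = 2))
  train_cases <- coh$cases[coh$splits == "train"]
  eval_cases <- coh$cases[coh$splits == "test_true"]
  rep1 <- run_repeated_curation(train_cases, eval_cases, R_best = 0.34,
                                folds = 1, tiny_config(), seed = 19)
  # with one fold the per-case median is the single run, and the one-model
  # ensemble equals that model
  expect_equal(rep1$median_per_case$curated, rep1$ensemble_dsc$curated)
  expect_equal(rep1$median_per_case$baseline, rep1$ensemble_dsc$baseline)
  expect_equal(rep1$test$alpha_adjusted, 0.05)
})

test_that("cross-validation scores every case once with balanced quartiles", {
  cases <- tiny_cohort(9, seed = 67)
  cv <- run_cross_validation(cases, 3, tiny_config(), seed = 23)
  expect_setequal(cv$case_id, vapply(cases, `[[`, "", "case_id"))
  expect_equal(nrow(cv), 9)
  qs <- table(cv$quartile)
  expect_lte(diff(range(qs)), 1)
  # Q1 holds the highest agreement
  expect_equal(max(cv$dsc), max(cv$dsc[cv$quartile == 1]))
  expect_error(run_cross_validation(cases, 100, tiny_config()), "k must be")
})
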