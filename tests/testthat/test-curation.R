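test_that("prompt training uses the ceiling of the prompt fraction", {
  cases <- tiny_cohort(2, seed = 18)
  p40 <- prompt_train(cases, segmenter_config(epochs = 40), 0.25, seed = 1)
  expect_equal(p40$provenance$epochs_trained, 10L)
  p5 <- prompt_train(cases, segmenter_config(epochs = 5), 0.25, seed = 1)
  expect_equal(p5$provenance$epochs_trained, 2L)   # ceil(1.25)
  expect_error(prompt_train(list(), segmenter_config(), 0.25), "empty")
})

test_that("ranking is ascending in DSC with id tie-breaks and order invariance", {
  cases <- tiny_cohort(8, seed = 19)
  sp <- corruption_spec("systematic_lateral", magnitude = 4, fraction = 0.25,
                        seed = 4)
  corr <- corrupt_cohort(cases, sp)
  pm <- prompt_train(corr$cases, tiny_config(), 0.25, seed = 2)
  rk <- rank_training_cases(pm, corr$cases)
  expect_true(!is.unsorted(rk$dsc))
  # the two corrupted cases score lowest under the consensus-trained model
  expect_setequal(rk$case_id[1:2], corr$corrupted_ids)
  # permuting the input order changes nothing
  rk2 <- rank_training_cases(pm, rev(corr$cases))
  expect_identical(rk, rk2)

  # equal scores sort by case id: three identical cases under one model
  trip <- lapply(c("m1", "a9", "z2"), function(id) {
    cc <- cases[[1]]; cc$case_id <- id; cc
  })
  rk3 <- rank_training_cases(pm, trip)
  expect_equal(rk3$case_id, sort(c("m1", "a9", "z2")))
})

test_that("curation removes floor(R*N) lowest cases and partitions ids", {
  cases <- tiny_cohort(8, seed = 23)
  sp <- corruption_spec("systematic_lateral", magnitude = 4, fraction = 0.25,
                        seed = 6)
  corr <- corrupt_cohort(cases, sp)
  res <- curate_and_retrain(corr$cases, tiny_config(), curation_config(0.25),
                            seed = 3, corrupted_ids = corr$corrupted_ids)
  ids <- vapply(cases, `[[`, "", "case_id")
  expect_length(res$removed_ids, 2)            # floor(0.25 * 8)
  expect_length(intersect(res$removed_ids, res$kept_ids), 0)
  expect_setequal(c(res$removed_ids, res$kept_ids), ids)
  expect_equal(res$removed_ids, res$ranking$case_id[1:2])
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  # final model trained on kept cases only, for the full budget
  expect_setequal(res$model$provenance$case_ids, res$kept_ids)
  expect_equal(res$model$provenance$epochs_trained, 8L)

  expect_warning(curate_and_retrain(corr$cases[1:4], tiny_config(),
                                    curation_config(0.1), seed = 1),
                 "no-op")
  expect_error(curation_config(1), "removal_fraction")
})

test_that("random removal keeps floor((1-R)*N) cases deterministically", {
  cases <- id_cases(sprintf("c%02d", 1:100))
  kept <- random_removal(cases, 0.30, seed = 5)
  expect_length(kept$kept, 70)
  expect_length(kept$removed_ids, 30)
  expect_identical(kept$removed_ids, random_removal(cases, 0.30, seed = 5)$removed_ids)
  expect_false(identical(kept$removed_ids, random_removal(cases, 0.30, seed = 6)$removed_ids))
  expect_identical(random_removal(cases, 0, seed = 1)$kept_ids,
                   vapply(cases, `[[`, "", "case_id"))
})

test_that("sensitivity and specificity follow their set definitions", {
  corrupted <- sprintf("k%02d", 1:30)
  removed <- c(corrupted[1:29], "x1")
  expect_equal(curation_sensitivity(removed, corrupted), 29 / 30)
  expect_equal(curation_sensitivity(corrupted, corrupted), 1)
  expect_equal(curation_sensitivity("none", corrupted), 0)
  expect_error(curation_sensitivity(removed, character(0)), "empty")

  poor <- sprintf("p%02d", 1:40)
  removed50 <- c(poor, sprintf("ok%02d", 1:10))
  expect_equal(curation_specificity(removed50, poor), 0.8)
  expect_equal(curation_specificity(poor, poor), 1)
  expect_equal(curation_specificity(removed50, "absent"), 0)
  expect_error(curation_specificity(character(0), poor), "empty")
})

test_that("curation agreement averages pairwise overlap over k", {
  s <- list(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_equal(curation_agreement(s), 1)
  expect_equal(curation_agreement(list(c("a", "b"), c("c", "d"))), 0)
  expect_equal(curation_agreement(list(c("a", "b"), c("b", "c"))), 0.5)
  expect_error(curation_agreement(list(c("a", "b"))), ">= 2")
  expect_error(curation_agreement(list(c("a", "b"), "c")), "unequal")
})

test_that("deterministic curation agrees with itself across repeats", {
  cases <- tiny_cohort(6, seed = 29)
  runs <- lapply(1:2, function(i)
    curate_and_retrain(cases, tiny_config(), curation_config(0.34),
                       seed = 77)$removed_ids)
  expect_equal(curation_agreement(runs), 1)
})

test_that("ensembling averages pre-sigmoid scores", {
  d <- c(4, 4, 4)
  v <- seg_volume(array(0, d))
  m <- constant_model(2, d)
  expect_identical(ensemble_predict(list(m), v)$voxels,
                   predict_mask(m, v)$voxels)
  expect_identical(ensemble_predict(list(m, m, m), v)$voxels,
                   predict_mask(m, v)$voxels)

  trio <- list(constant_model(2, d), constant_model(-1, d), constant_model(1, d))
  lg <- ensemble_logits(trio, v)
  expect_equal(lg[1, 1, 1], 2 / 3, tolerance = 1e-12)
  expect_true(all(ensemble_predict(trio, v)$voxels == 1L))
  expect_error(ensemble_predict(list(), v), "empty")
  expect_error(ensemble_logits(list(m, constant_model(1, c(5, 5, 5))), v),
               "mismatch")
})
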