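test_that("directional dilation matches its voxelwise definition", {
  m <- seg_mask(array(0L, c(12, 12, 12)))
  m$voxels[5, 5, 5] <- 1L
  d <- directional_dilate(m, c(1, 1), 2)
  fg <- which(d$voxels == 1L, arr.ind = TRUE)
  expect_equal(fg[order(fg[, 1]), , drop = FALSE],
               cbind(row = 5:7, col = 5, 5), ignore_attr = TRUE)

  expect_identical(directional_dilate(m, c(2, -1), 0)$voxels, m$voxels)

  for (i in 1:8) {
    rm <- random_mask(c(16, 16, 16), p = 0.2, seed = 40 + i)
    dir <- list(c(1, 1), c(2, -1), c(3, 1), c(1, -1))[[1 + i %% 4]]
    expect_identical(directional_dilate(rm, dir, 3, clip = TRUE)$voxels,
                     bf_dilate(rm, dir, 3)$voxels)
  }
})

test_that("directional erosion matches its definition and the dual identity", {
  bar <- seg_mask(array(0L, c(14, 6, 6)))
  bar$voxels[3:12, 3, 3] <- 1L
  e <- directional_erode(bar, c(1, 1), 2)
  expect_equal(sum(e$voxels), 8)
  expect_equal(range(which(e$voxels == 1L, arr.ind = TRUE)[, 1]), c(3, 10))
  expect_identical(directional_erode(bar, c(1, 1), 0)$voxels, bar$voxels)

  for (i in 1:8) {
    rm <- random_mask(c(16, 16, 16), p = 0.4, seed = 60 + i)
    dir <- list(c(1, 1), c(2, 1), c(3, -1), c(1, -1))[[1 + i %% 4]]
    m <- 1 + i %% 3
    expect_identical(directional_erode(rm, dir, m)$voxels,
                     bf_erode(rm, dir, m)$voxels)
    # erode(M) = complement(dilate(complement(M), -d)), with the
    # complement's exterior foreground (background ring embedding)
    expect_identical(directional_erode(rm, dir, m)$voxels,
                     duality_dual_erode(rm, dir, m))
  }
})

test_that("dilation refuses to push foreground across the grid boundary", {
  m <- seg_mask(array(0L, c(8, 8, 8)))
  m$voxels[6, 4, 4] <- 1L
  expect_error(directional_dilate(m, c(1, 1), 3), "boundary")
  expect_no_error(directional_dilate(m, c(1, 1), 2))
  expect_no_error(directional_dilate(m, c(1, 1), 3, clip = TRUE))
})

test_that("systematic corruption is lateral, recorded, and DSC-monotone", {
  cc <- generate_case(tiny_params(), 21)
  c0 <- corrupt_systematic(cc, 0)
  expect_equal(c0$corruption$agreement, 1)

  c3 <- corrupt_systematic(cc, 3)
  c5 <- corrupt_systematic(cc, 5)
  expect_true(c5$corrupted)
  expect_equal(c5$corruption$direction, c(1L, 1L))  # right-sided phantom
  expect_lt(c5$corruption$agreement, c3$corruption$agreement)
  expect_lt(c3$corruption$agreement, 1)

  left <- corrupt_systematic(generate_case(tiny_params(side = "left"), 21), 3)
  expect_equal(left$corruption$direction, c(1L, -1L))

  # agreement non-increasing over a magnitude sweep
  agr <- vapply(0:6, function(m) corrupt_systematic(cc, m)$corruption$agreement,
                numeric(1))
  expect_true(all(diff(agr) <= 0))
})

test_that("random corruption is seeded, records ops, and scales erosion", {
  cc <- generate_case(tiny_params(), 22)
  a <- corrupt_random(cc, m = 4, seed = 7)
  b <- corrupt_random(cc, m = 4, seed = 7)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_identical(a$corruption, b$corruption)

  # identity when both magnitudes collapse to zero
  z <- corrupt_random(cc, m = 0, erosion_factor = 1, seed = 3)
  expect_identical(z$mask$voxels, cc$mask$voxels)
  expect_equal(z$corruption$agreement, 1)

  # applied erosion magnitude is round(0.8 * m)
  for (s in 1:30) {
    r <- corrupt_random(cc, m = 4, erosion_factor = 0.8, seed = 100 + s)
    expect_equal(r$corruption$magnitude,
                 if (r$corruption$op == "erode") 3L else 4L)
    expect_true(list(as.numeric(r$corruption$direction)) %in%
                  lapply(segcurate:::CARDINAL_DIRECTIONS, as.numeric))
  }
})

test_that("cohort corruption selects round(i*N) cases and touches nothing else", {
  cases <- tiny_cohort(20, seed = 3)
  sp <- corruption_spec("systematic_lateral", magnitude = 3, fraction = 0.3,
                        seed = 5)
  res <- corrupt_cohort(cases, sp)
  expect_length(res$corrupted_ids, 6)   # round(0.3 * 20)
  expect_length(res$cases, 20)
  ids <- vapply(res$cases, `[[`, "", "case_id")
  for (i in seq_along(cases)) {
    if (ids[i] %in% res$corrupted_ids) {
      expect_true(res$cases[[i]]$corrupted)
      expect_false(identical(res$cases[[i]]$mask$voxels, cases[[i]]$mask$voxels))
    } else {
      expect_identical(res$cases[[i]], cases[[i]])
    }
  }

  none <- corrupt_cohort(cases, corruption_spec("random", fraction = 0, seed = 1))
  expect_length(none$corrupted_ids, 0)
  expect_identical(none$cases, cases)

  all_c <- corrupt_cohort(cases, corruption_spec("systematic_lateral",
                                                 magnitude = 2, fraction = 1,
                                                 seed = 1))
  expect_length(all_c$corrupted_ids, 20)
  expect_true(all(vapply(all_c$cases, `[[`, NA, "corrupted")))
})

test_that("magnitude calibration finds the best integer magnitude", {
  cases <- tiny_cohort(12, seed = 9)
  cal0 <- calibrate_magnitude(cases, 1.0, search_range = 0:5)
  expect_equal(cal0$magnitude, 0L)

  cal <- calibrate_magnitude(cases, 0.8, search_range = 0:6)
  # exhaustive-search oracle over the returned profile
  err <- abs(cal$profile$median_dsc - 0.8)
  expect_equal(cal$magnitude, cal$profile$magnitude[which.min(err)])
  step <- max(abs(diff(cal$profile$median_dsc)))
  expect_lte(abs(cal$median_dsc - 0.8), step)

  expect_warning(calibrate_magnitude(cases, 0.05, search_range = 0:3),
                 "max magnitude")
})

test_that("the synthetic quality rubric maps flags to scores", {
  mk <- function(agr, op = "dilate") segcurate:::new_corruption_record(
    op, c(1, 1), 3L, agr)
  expect_equal(quality_from_record(NULL)$score, 5L)
  expect_equal(quality_from_record(mk(1))$score, 5L)
  expect_equal(quality_from_record(mk(0.96))$score, 4L)
  q3 <- quality_from_record(mk(0.9))
  expect_equal(q3$score, 3L)
  expect_equal(q3$flags, "e")       # dilation sweeps bone/skin/air
  expect_equal(quality_from_record(mk(0.75))$score, 2L)
  expect_equal(quality_from_record(mk(0.5))$score, 1L)
  expect_length(quality_from_record(mk(0.5))$flags, 3)
  expect_equal(quality_from_record(mk(0.9, "erode"))$flags, "a")
})
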