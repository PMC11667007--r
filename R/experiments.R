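#' Experiment grid
#'
#' The corruption-impact grid crosses corruption fractions (default 0 to 1
#' in steps of 0.05, i.e. 21 values) with the two corruption modes, giving
#' 42 model configurations by default; curation-rate sweeps default to 0 to
#' 0.9 in steps of 0.05.
#'
#' @param fractions corruption fractions in `[0, 1]`.
#' @param modes corruption modes.
#' @param folds repeat count for seeded repetitions.
#' @param curation_rates removal rates in `[0, 0.9]`.
#' @param rrss_n,rrss_repeats repeated-random-sub-sampling size and repeats.
#' @return list of class `experiment_grid`.
#' @export
experiment_grid <- function(fractions = seq(0, 1, by = 0.05),
                            modes = c("systematic_lateral", "random"),
                            folds = 5,
                            curation_rates = seq(0, 0.9, by = 0.05),
                            rrss_n = 100, rrss_repeats = 10) {
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0, 1]")
  if (any(curation_rates < 0 | curation_rates > 0.9))
    stop("curation rates must be in [0, 0.9]")
  structure(list(fractions = fractions, modes = modes, folds = folds,
                 curation_rates = curation_rates, rrss_n = rrss_n,
                 rrss_repeats = rrss_repeats),
            class = "experiment_grid")
}

#' Enumerate the corruption-impact configurations of a grid
#'
#' @param grid an [experiment_grid()].
#' @return data.frame with one row per (mode, fraction) configuration.
#' @export
enumerate_grid <- function(grid) {
  expand.grid(fraction = grid$fractions, mode = grid$modes,
              stringsAsFactors = FALSE)
}

cases_in_split <- function(cohort, split) {
  cohort$cases[cohort$splits == split]
}

train_on <- function(cases, config, seed) {
  seg <- init_segmenter(config, seed = seed)
  train_segmenter(seg, cases, epochs = config$epochs, seed = seed)
}

median_dsc <- function(model, cases) {
  stats::median(vapply(cases, function(cc)
    dsc(predict_mask(model, cc$volume), cc$mask), numeric(1)))
}

case_dscs <- function(model, cases) {
  stats::setNames(vapply(cases, function(cc)
    dsc(predict_mask(model, cc$volume), cc$mask), numeric(1)),
    vapply(cases, `[[`, "", "case_id"))
}

#' Build true/apparent/external evaluation sets
#'
#' True-performance cases keep their clean labels untouched; the
#' apparent-performance set corrupts the validation labels with the training
#' corruption distribution under an independent derived seed; the external
#' set (optional) is generated from a shifted phantom parameter
#' distribution.
#'
#' @param cohort a [generate_cohort()] result with `test_true` and `val`
#'   splits.
#' @param spec the training [corruption_spec()].
#' @param seed master seed.
#' @param external_params optional shifted [phantom_params()] for the
#'   out-of-distribution set.
#' @param n_external number of external cases to generate.
#' @return list of class `truth_sets`: `true`, `apparent`,
#'   `apparent_corrupted_ids`, `external`.
#' @export
build_truth_sets <- function(cohort, spec, seed, external_params = NULL,
                             n_external = 0) {
  true_cases <- cases_in_split(cohort, "test_true")
  val_cases <- cases_in_split(cohort, "val")
  if (length(true_cases) == 0 || length(val_cases) == 0)
    stop("cohort must have test_true and val splits")
  app_spec <- corruption_spec(spec$mode, spec$magnitude, spec$erosion_factor,
                              spec$fraction, seed = derive_seed(seed, "apparent"))
  app <- corrupt_cohort(val_cases, app_spec)
  ext <- NULL
  if (!is.null(external_params) && n_external > 0) {
    ext <- lapply(seq_len(n_external), function(i)
      generate_case(external_params, derive_seed(seed, paste0("ext", i)),
                    case_id = sprintf("ext%04d", i)))
  }
  structure(list(true = true_cases, apparent = app$cases,
                 apparent_corrupted_ids = app$corrupted_ids, external = ext),
            class = "truth_sets")
}

#' Corruption-impact experiment
#'
#' For every (mode, fraction) configuration: corrupt that fraction of the
#' training labels, train the backend, and report clean-test ("true") and
#' training-distribution DSC, reusing the same train/val/test allocation
#' throughout.
#'
#' @param cohort a [generate_cohort()] result.
#' @param grid an [experiment_grid()].
#' @param config a [segmenter_config()].
#' @param seed master seed.
#' @param magnitude corruption magnitude in voxels.
#' @return long data.frame (`mode`, `fraction`, `split`, `median_dsc`).
#' @export
run_corruption_grid <- function(cohort, grid, config, seed = 1L,
                                magnitude = 10L) {
  cfgs <- enumerate_grid(grid)
  train_cases <- cases_in_split(cohort, "train")
  test_cases <- cases_in_split(cohort, "test_true")
  rows <- lapply(seq_len(nrow(cfgs)), function(i) {
    mode <- cfgs$mode[i]; frac <- cfgs$fraction[i]
    sp <- corruption_spec(mode, magnitude = magnitude, fraction = frac,
                          seed = derive_seed(seed, paste0("grid/", mode, "/", frac)))
    corr <- suppressWarnings(corrupt_cohort(train_cases, sp))
    model <- train_on(corr$cases, config,
                      derive_seed(seed, paste0("train/", mode, "/", frac)))
    data.frame(mode = mode, fraction = frac,
               split = c("test_true", "train"),
               median_dsc = c(median_dsc(model, test_cases),
                              median_dsc(model, corr$cases)))
  })
  do.call(rbind, rows)
}

#' Seven-condition curation matrix
#'
#' Conditions: (1) clean baseline, (2) clean + random removal, (3) clean +
#' auto-curation, (4, 6) 30% systematic/random corruption without curation,
#' (5, 7) the same with auto-curation; each repeated over `folds` seeds and
#' evaluated on the clean test split.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [segmenter_config()].
#' @param seed master seed.
#' @param folds number of seeded repeats per condition.
#' @param fraction corruption fraction for conditions 4-7.
#' @param R removal fraction for conditions 2, 3, 5, 7.
#' @param magnitude corruption magnitude in voxels.
#' @return data.frame (`condition`, `fold`, `median_dsc`, `sensitivity`).
#' @export
run_curation_matrix <- function(cohort, config, seed = 1L, folds = 5,
                                fraction = 0.3, R = 0.3, magnitude = 10L) {
  train_cases <- cases_in_split(cohort, "train")
  test_cases <- cases_in_split(cohort, "test_true")
  cur <- curation_config(removal_fraction = R)
  one <- function(condition, fold) {
    fseed <- derive_seed(seed, paste0("cond", condition, "/fold", fold))
    corrupted_ids <- NULL
    cases <- train_cases
    if (condition %in% 4:7) {
      mode <- if (condition %in% 4:5) "systematic_lateral" else "random"
      sp <- corruption_spec(mode, magnitude = magnitude, fraction = fraction,
                            seed = derive_seed(seed, paste0("corr", condition,
                                                            "/", fold)))
      cc <- corrupt_cohort(cases, sp)
      cases <- cc$cases; corrupted_ids <- cc$corrupted_ids
    }
    sens <- NA_real_
    if (condition %in% c(3, 5, 7)) {
      res <- curate_and_retrain(cases, config, cur, seed = fseed,
                                corrupted_ids = corrupted_ids)
      model <- res$model; sens <- res$sensitivity
    } else if (condition == 2) {
      kept <- random_removal(cases, R, seed = fseed)$kept
      model <- train_on(kept, config, fseed)
    } else {
      model <- train_on(cases, config, fseed)
    }
    data.frame(condition = condition, fold = fold,
               median_dsc = median_dsc(model, test_cases), sensitivity = sens)
  }
  do.call(rbind, lapply(1:7, function(cond)
    do.call(rbind, lapply(seq_len(folds), function(f) one(cond, f)))))
}

#' Curation-rate sweep with a random-removal baseline
#'
#' For each rate: train a curated model and a random-removal model on the
#' (possibly noisy) training cases and evaluate both on the supplied truth
#' sets. The best rate maximizes external-set curation efficacy (curated
#' minus baseline median DSC), ties to the smaller rate; with no external
#' set the true set is used.
#'
#' @param train_cases training `seg_case` list (labels as-is, possibly
#'   corrupted).
#' @param truth_sets a [build_truth_sets()] result.
#' @param rates removal rates.
#' @param config a [segmenter_config()].
#' @param seed master seed.
#' @param with_distances also report MSD/HD medians.
#' @return list with `results` (long data.frame: `rate`, `arm`, `split`,
#'   `median_dsc`, optionally `median_msd`, `median_hd`) and `best_rate`.
#' @export
run_rate_sweep <- function(train_cases, truth_sets, rates, config, seed = 1L,
                           with_distances = FALSE) {
  splits <- list(true = truth_sets$true, apparent = truth_sets$apparent)
  if (!is.null(truth_sets$external)) splits$external <- truth_sets$external
  eval_model <- function(model, rate, arm) {
    do.call(rbind, lapply(names(splits), function(snm) {
      rep <- evaluate_cohort(model, splits[[snm]], with_distances = with_distances)
      row <- data.frame(rate = rate, arm = arm, split = snm,
                        median_dsc = stats::median(rep$dsc))
      if (with_distances) {
        row$median_msd <- stats::median(rep$msd_mm, na.rm = TRUE)
        row$median_hd <- stats::median(rep$hd_mm, na.rm = TRUE)
      }
      row
    }))
  }
  rows <- lapply(rates, function(R) {
    rseed <- derive_seed(seed, paste0("rate", R))
    if (R == 0) {
      base <- train_on(train_cases, config, rseed)
      rbind(eval_model(base, R, "curation"), eval_model(base, R, "random"))
    } else {
      curated <- curate_and_retrain(train_cases, config,
                                    curation_config(removal_fraction = R),
                                    seed = rseed)
      rnd <- train_on(random_removal(train_cases, R, seed = rseed)$kept,
                      config, rseed)
      rbind(eval_model(curated$model, R, "curation"),
            eval_model(rnd, R, "random"))
    }
  })
  results <- do.call(rbind, rows)
  ref_split <- if (!is.null(truth_sets$external)) "external" else "true"
  cur <- results[results$arm == "curation" & results$split == ref_split, ]
  base_dsc <- cur$median_dsc[cur$rate == min(cur$rate)][1]
  eff <- cur$median_dsc - base_dsc
  best_rate <- cur$rate[which.max(eff)]  # which.max takes first (smaller) tie
  list(results = results, best_rate = best_rate)
}

#' Repeated random sub-sampling of the rate sweep
#'
#' Runs the rate sweep on `repeats` random training subsets of size
#' `subsample_n` and reports the median (and IQR for the curation arm) of
#' the per-rate median DSC across repeats.
#'
#' @param train_cases training pool.
#' @param truth_sets a [build_truth_sets()] result.
#' @param subsample_n subset size (<= pool size).
#' @param repeats number of repetitions.
#' @param rates removal rates.
#' @param config a [segmenter_config()].
#' @param seed master seed.
#' @return list with `summary` (rate, arm, split, median over repeats, IQR
#'   bounds) and `runs` (per-repeat results).
#' @export
run_rrss <- function(train_cases, truth_sets, subsample_n, repeats, rates,
                     config, seed = 1L) {
  if (subsample_n > length(train_cases)) stop("subsample larger than pool")
  runs <- lapply(seq_len(repeats), function(r) {
    idx <- with_seed(derive_seed(seed, paste0("rrss", r)),
                     sample.int(length(train_cases), subsample_n))
    out <- run_rate_sweep(train_cases[idx], truth_sets, rates, config,
                          seed = derive_seed(seed, paste0("rrss-run", r)))$results
    out$repeat_id <- r
    out
  })
  all <- do.call(rbind, runs)
  key <- interaction(all$rate, all$arm, all$split, drop = TRUE)
  summ <- do.call(rbind, lapply(split(all, key), function(g) {
    q <- stats::quantile(g$median_dsc, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(rate = g$rate[1], arm = g$arm[1], split = g$split[1],
               median_dsc = q[2], q1 = q[1], q3 = q[3])
  }))
  rownames(summ) <- NULL
  list(summary = summ, runs = all)
}

#' Repeated curation at the best rate, with ensembling
#'
#' Repeats (no-curation, curation at `R_best`) over `folds` seeds; collapses
#' per-case DSC to per-case medians across folds, forms mean-logit ensembles
#' per arm, and tests curated vs non-curated per-case medians with the
#' Wilcoxon signed-rank test at a Bonferroni-adjusted threshold.
#'
#' @param train_cases training cases (labels as-is).
#' @param eval_cases evaluation cases with clean labels.
#' @param R_best removal rate.
#' @param folds repeats.
#' @param config a [segmenter_config()].
#' @param seed master seed.
#' @param n_comparisons number of planned comparisons for the Bonferroni
#'   adjustment (defaults to 1: the curated-vs-baseline test below).
#' @return list with `median_per_case` (arm -> named vector),
#'   `ensemble_dsc` (arm -> named vector), `test` (Wilcoxon result +
#'   adjusted threshold + stars).
#' @export
run_repeated_curation <- function(train_cases, eval_cases, R_best, folds,
                                  config, seed = 1L, n_comparisons = 1) {
  arms <- list(baseline = list(), curated = list())
  models <- list(baseline = list(), curated = list())
  for (f in seq_len(folds)) {
    fseed <- derive_seed(seed, paste0("rep", f))
    base <- train_on(train_cases, config, fseed)
    curd <- if (R_best > 0)
      curate_and_retrain(train_cases, config,
                         curation_config(removal_fraction = R_best),
                         seed = fseed)$model else base
    arms$baseline[[f]] <- case_dscs(base, eval_cases)
    arms$curated[[f]] <- case_dscs(curd, eval_cases)
    models$baseline[[f]] <- base
    models$curated[[f]] <- curd
  }
  med <- lapply(arms, aggregate_repeats)
  ens <- lapply(models, function(ms)
    stats::setNames(vapply(eval_cases, function(cc)
      dsc(ensemble_predict(ms, cc$volume), cc$mask), numeric(1)),
      vapply(eval_cases, `[[`, "", "case_id")))
  thr <- bonferroni_threshold(0.05, n_comparisons)
  test <- tryCatch({
    wt <- wilcoxon_signed_rank(med$curated, med$baseline)
    c(wt, list(alpha_adjusted = thr$threshold,
               significant = wt$p < thr$threshold,
               stars = significance_stars(wt$p)))
  }, error = function(e) list(error = conditionMessage(e),
                              alpha_adjusted = thr$threshold))
  list(median_per_case = med, ensemble_dsc = ens, test = test)
}

#' k-fold cross-validation with DSC quartile assignment
#'
#' Every training case is scored exactly once out-of-fold; cases are ranked
#' by out-of-fold DSC into quartiles Q1 (highest agreement) to Q4 (lowest),
#' ties broken by case id.
#'
#' @param cases training `seg_case` list.
#' @param k number of folds (2 <= k <= N).
#' @param config a [segmenter_config()].
#' @param seed master seed (fold assignment + training).
#' @return data.frame (`case_id`, `fold`, `dsc`, `quartile`).
#' @export
run_cross_validation <- function(cases, k, config, seed = 1L) {
  N <- length(cases)
  if (k < 2 || k > N) stop("k must be in [2, N]")
  fold_of <- with_seed(derive_seed(seed, "folds"),
                       sample(rep(seq_len(k), length.out = N)))
  rows <- lapply(seq_len(k), function(f) {
    model <- train_on(cases[fold_of != f], config,
                      derive_seed(seed, paste0("cv", f)))
    held <- cases[fold_of == f]
    data.frame(case_id = vapply(held, `[[`, "", "case_id"), fold = f,
               dsc = unname(case_dscs(model, held)))
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$dsc, out$case_id)   # Q1 = highest agreement
  qsizes <- split_counts(N, rep(1, 4))
  out$quartile <- NA_integer_
  out$quartile[ord] <- rep(1:4, qsizes)
  out
}

#' Scaled-down curation-sensitivity study
#'
#' The package's standard desk-scale experiment: per master seed, generate a
#' phantom cohort, corrupt a fraction of the training labels with systematic
#' lateral dilation at a magnitude calibrated so the median agreement DSC of
#' fully perturbed data matches `target_dsc`, prompt-train the backend for
#' the prompt fraction of epochs, remove the lowest-DSC fraction `R`, and
#' score the removal against the known corrupted ids; optionally retrain and
#' compare the curated model with the non-curated model on the clean test
#' split.
#'
#' @param seeds integer vector of master seeds (one study repetition each).
#' @param n_train,n_test cohort sizes.
#' @param fraction corrupted fraction of the training labels.
#' @param R removal fraction.
#' @param target_dsc calibration target for the median agreement DSC of
#'   fully corrupted labels.
#' @param config a [segmenter_config()].
#' @param params a [phantom_params()].
#' @param retrain if `TRUE`, also fully train curated and non-curated models
#'   and evaluate clean-test DSC.
#' @return data.frame with one row per seed: `seed`, `magnitude`,
#'   `median_agreement`, `sensitivity`, and (with `retrain`) `curated_dsc`,
#'   `noncurated_dsc`.
#' @export
scaled_curation_study <- function(seeds, n_train = 60, n_test = 20,
                                  fraction = 0.3, R = 0.3,
                                  target_dsc = 0.778,
                                  config = segmenter_config(),
                                  params = phantom_params(),
                                  retrain = TRUE) {
  rows <- lapply(seeds, function(s) {
    coh <- generate_cohort(n_train + n_test, params, s,
                           proportions = c(train = n_train, test_true = n_test))
    train_cases <- cases_in_split(coh, "train")
    test_cases <- cases_in_split(coh, "test_true")
    cal <- calibrate_magnitude(train_cases, target_dsc,
                               mode = "systematic_lateral",
                               seed = derive_seed(s, "cal"))
    sp <- corruption_spec("systematic_lateral", magnitude = cal$magnitude,
                          fraction = fraction, seed = derive_seed(s, "corrupt"))
    corr <- corrupt_cohort(train_cases, sp)
    agr <- stats::median(vapply(corr$cases[match(corr$corrupted_ids,
                                                 vapply(corr$cases, `[[`, "", "case_id"))],
                                function(cc) cc$corruption$agreement, numeric(1)))
    if (retrain) {
      res <- curate_and_retrain(corr$cases, config,
                                curation_config(removal_fraction = R),
                                seed = s, corrupted_ids = corr$corrupted_ids)
      base <- train_on(corr$cases, config, derive_seed(s, "baseline"))
      data.frame(seed = s, magnitude = cal$magnitude, median_agreement = agr,
                 sensitivity = res$sensitivity,
                 curated_dsc = median_dsc(res$model, test_cases),
                 noncurated_dsc = median_dsc(base, test_cases))
    } else {
      prompt <- prompt_train(corr$cases, config, seed = s)
      ranking <- rank_training_cases(prompt, corr$cases)
      removed <- ranking$case_id[seq_len(floor(R * length(corr$cases)))]
      data.frame(seed = s, magnitude = cal$magnitude, median_agreement = agr,
                 sensitivity = curation_sensitivity(removed, corr$corrupted_ids))
    }
  })
  do.call(rbind, rows)
}
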