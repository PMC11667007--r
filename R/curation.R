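#' Curation configuration
#'
#' @param removal_fraction R, the fraction of training cases removed, in
#'   `[0, 1)`; `floor(R * N)` cases are removed.
#' @param prompt_fraction fraction of the full epoch budget used for the
#'   prompt (ranking) phase; default 0.25, i.e. 25% of epochs.
#' @return list of class `curation_config`.
#' @export
curation_config <- function(removal_fraction = 0.3, prompt_fraction = 0.25) {
  if (removal_fraction < 0 || removal_fraction >= 1)
    stop("removal_fraction must be in [0, 1)")
  if (prompt_fraction <= 0 || prompt_fraction >= 1)
    stop("prompt_fraction must be in (0, 1)")
  structure(list(removal_fraction = removal_fraction,
                 prompt_fraction = prompt_fraction),
            class = "curation_config")
}

#' Prompt-train a segmenter for a fraction of the full epoch budget
#'
#' Trains for exactly `ceiling(prompt_fraction * epochs)` epochs; used only
#' to rank training cases before curation.
#'
#' @param cases nonempty list of training `seg_case` objects.
#' @param config a [segmenter_config()].
#' @param prompt_fraction see [curation_config()].
#' @param seed integer seed (weight initialization).
#' @return a trained `seg_segmenter` with the prompt epoch count in its
#'   provenance.
#' @export
prompt_train <- function(cases, config, prompt_fraction = 0.25, seed = 1L) {
  if (length(cases) == 0) stop("empty training split")
  e <- as.integer(ceiling(prompt_fraction * config$epochs))
  seg <- init_segmenter(config, seed = derive_seed(seed, "prompt-init"))
  train_segmenter(seg, cases, epochs = e, seed = seed)
}

#' Rank training cases by prompt-model DSC, ascending
#'
#' DSC is computed between the prompt model's prediction and each case's own
#' (possibly corrupted) reference label -- the same labels the model trained
#' on, which is what makes low agreement a corruption signal. Ties are broken
#' by case id, so the ranking is a pure function of its inputs.
#'
#' @param prompt_model a trained `seg_segmenter`.
#' @param cases the training cases the model was prompt-trained on.
#' @return data.frame (`case_id`, `dsc`) sorted ascending by DSC.
#' @export
rank_training_cases <- function(prompt_model, cases) {
  ids <- vapply(cases, `[[`, "", "case_id")
  scores <- vapply(cases, function(cc)
    dsc(predict_mask(prompt_model, cc$volume), cc$mask), numeric(1))
  ord <- order(scores, ids)
  data.frame(case_id = ids[ord], dsc = scores[ord], stringsAsFactors = FALSE)
}

#' Curate a training cohort and retrain from scratch
#'
#' Prompt-trains, ranks all training cases by DSC, removes the
#' `floor(R * N)` lowest, reinitializes the weights with a fresh derived
#' seed, and trains the full epoch budget on the kept cases only. Validation
#' and test cases are never candidates for removal (only the supplied
#' training cases are).
#'
#' @param cases training `seg_case` list.
#' @param config a [segmenter_config()].
#' @param curation a [curation_config()].
#' @param seed master seed.
#' @param corrupted_ids optional ground-truth corrupted id set; when given,
#'   curation sensitivity/specificity are filled in.
#' @return list of class `curation_result`: `removed_ids`, `kept_ids`,
#'   `ranking` (per-case prompt DSC), `model` (the final trained segmenter),
#'   `sensitivity`, `specificity`, `prompt_epochs`.
#' @export
curate_and_retrain <- function(cases, config, curation = curation_config(),
                               seed = 1L, corrupted_ids = NULL) {
  N <- length(cases)
  n_rm <- floor(curation$removal_fraction * N)
  if (n_rm >= N) stop("removal would empty the training set")
  if (n_rm == 0L && curation$removal_fraction > 0)
    warning("removal_fraction * N rounds down to 0; curation is a no-op")

  prompt <- prompt_train(cases, config, curation$prompt_fraction, seed = seed)
  ranking <- rank_training_cases(prompt, cases)
  removed <- ranking$case_id[seq_len(n_rm)]
  ids <- vapply(cases, `[[`, "", "case_id")
  kept_cases <- cases[!ids %in% removed]

  final <- init_segmenter(config, seed = derive_seed(seed, "retrain"))
  final <- train_segmenter(final, kept_cases, epochs = config$epochs,
                           seed = derive_seed(seed, "retrain"))
  sens <- if (!is.null(corrupted_ids) && length(corrupted_ids))
    curation_sensitivity(removed, corrupted_ids) else NA_real_
  spec <- if (!is.null(corrupted_ids) && length(removed))
    curation_specificity(removed, corrupted_ids) else NA_real_
  structure(list(removed_ids = removed,
                 kept_ids = setdiff(ids, removed),
                 ranking = ranking, model = final,
                 sensitivity = sens, specificity = spec,
                 prompt_epochs = prompt$provenance$epochs_trained,
                 config = list(curation = curation, seed = seed)),
            class = "curation_result")
}

#' Random-removal baseline
#'
#' Uniform without-replacement removal of `floor(R * N)` training cases.
#'
#' @param cases training `seg_case` list.
#' @param R removal fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `kept` (cases), `kept_ids`, `removed_ids`.
#' @export
random_removal <- function(cases, R, seed = 1L) {
  N <- length(cases)
  n_rm <- floor(R * N)
  if (n_rm >= N) stop("removal would empty the training set")
  ids <- vapply(cases, `[[`, "", "case_id")
  rm_idx <- if (n_rm > 0) with_seed(seed, sample.int(N, n_rm)) else integer(0)
  list(kept = cases[setdiff(seq_len(N), rm_idx)],
       kept_ids = ids[setdiff(seq_len(N), rm_idx)],
       removed_ids = ids[rm_idx])
}

#' Curation sensitivity
#'
#' Fraction of truly corrupted (quality < 4) cases that were removed:
#' `|removed n corrupted| / |corrupted|`.
#'
#' @param removed_ids,corrupted_ids character id vectors; `corrupted_ids`
#'   nonempty.
#' @return sensitivity in `[0, 1]`.
#' @export
curation_sensitivity <- function(removed_ids, corrupted_ids) {
  if (length(corrupted_ids) == 0) stop("corrupted set is empty")
  length(intersect(removed_ids, corrupted_ids)) / length(corrupted_ids)
}

#' Curation specificity
#'
#' Fraction of removed cases that genuinely warranted removal:
#' `|removed n poor| / |removed|`.
#'
#' @param removed_ids character vector, nonempty.
#' @param poor_quality_ids ids of cases with quality below the acceptance
#'   threshold.
#' @return specificity in `[0, 1]`.
#' @export
curation_specificity <- function(removed_ids, poor_quality_ids) {
  if (length(removed_ids) == 0) stop("removed set is empty")
  length(intersect(removed_ids, poor_quality_ids)) / length(removed_ids)
}

#' Curation agreement across repeated runs
#'
#' Mean over all unordered pairs of iterations of `|A_i n A_j| / k`, where
#' each iteration removed exactly `k` cases from the same pool. Under
#' uniform random removal its expectation equals the curation rate `k / N`;
#' identical sets give 1, pairwise disjoint sets give 0.
#'
#' @param removed_sets list (length >= 2) of character id vectors, all of
#'   equal length `k`.
#' @return agreement in `[0, 1]`.
#' @export
curation_agreement <- function(removed_sets) {
  if (length(removed_sets) < 2) stop("need >= 2 iterations")
  k <- unique(lengths(removed_sets))
  if (length(k) != 1) stop("unequal removal counts across iterations")
  if (k == 0) stop("empty removal sets")
  pairs <- utils::combn(length(removed_sets), 2)
  mean(apply(pairs, 2, function(ij)
    length(intersect(removed_sets[[ij[1]]], removed_sets[[ij[2]]])) / k))
}

#' Ensemble prediction by mean pre-sigmoid score
#'
#' Averages the per-voxel pre-sigmoid scores across models and thresholds
#' the mean at 0 (for a single binary output this equals thresholding the
#' sigmoid of the mean logit at 0.5).
#'
#' @param models nonempty list of trained `seg_segmenter` objects sharing a
#'   grid.
#' @param volume a [seg_volume()].
#' @return a [seg_mask()].
#' @export
ensemble_predict <- function(models, volume) {
  if (length(models) == 0) stop("empty ensemble")
  lg <- ensemble_logits(models, volume)
  seg_mask(array(as.integer(lg > 0), dim = dim(lg)), volume$spacing)
}

#' Mean pre-sigmoid score across an ensemble
#'
#' @inheritParams ensemble_predict
#' @return numeric array of mean logits.
#' @export
ensemble_logits <- function(models, volume) {
  if (length(models) == 0) stop("empty ensemble")
  acc <- predict_logits(models[[1]], volume)
  if (length(models) > 1) {
    for (m in models[-1]) {
      nxt <- predict_logits(m, volume)
      if (!identical(dim(nxt), dim(acc))) stop("grid mismatch across models")
      acc <- acc + nxt
    }
  }
  acc / length(models)
}
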