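# Small, fast phantom settings used throughout the unit tests: a 32^3 grid
# with a radius-4 organ tolerating corruption magnitudes up to 6.
tiny_params <- function(max_corruption = 6, ...) {
  phantom_params(grid_shape = c(32, 32, 32), radius_range = c(3.5, 4.5),
                 center_offset = 2, max_corruption = max_corruption, ...)
}

tiny_config <- function(epochs = 8, ...) segmenter_config(epochs = epochs, ...)

tiny_cohort <- function(n, seed = 1, params = tiny_params()) {
  lapply(seq_len(n), function(i)
    generate_case(params, seed * 1000 + i, sprintf("c%03d", i)))
}

# lightweight id-only cases for bookkeeping tests (no volumes needed)
id_cases <- function(ids) {
  lapply(ids, function(id)
    structure(list(case_id = id), class = "seg_case"))
}

# a "trained" scorer whose logit is constant everywhere: bias-only weights
constant_model <- function(logit, d = c(4, 4, 4)) {
  s <- init_segmenter(segmenter_config(), seed = 1)
  s$weights[] <- 0
  s$weights[1] <- logit
  s$norm <- list(center = 0, scale = 1)
  s$atlas <- array(0, dim = d)
  s$trained <- TRUE
  s
}
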