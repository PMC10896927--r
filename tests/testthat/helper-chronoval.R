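# Deterministic generator settings: no noise anywhere, so every RT equals the
# sum of the applicable effects exactly.
det_params <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(subject_sd = 0, item_sd = 0,
                   residual_shape = list(sdlog = 0, shift = 200),
                   error_base = 0, error_mismatch_increment = 0,
                   practice_slope = 0, seed = seed)
  do.call(rt_gen_params, utils::modifyList(defaults, args))
}

null_params <- function(seed, ...) {
  rt_gen_params(match_effect = 0, congruency_effect = 0, domain_effect = 0,
                practice_slope = 0, seed = seed, ...)
}

small_design <- function(n_subjects = 4, items_per_category = 2) {
  design_exp2(n_subjects = n_subjects, items_per_category = items_per_category)
}

# Brute-force HAL oracle: enumerate all token pairs at distance <= window
# within each document, counting both directions.
hal_brute_force <- function(corpus, window) {
  toks <- strsplit(tolower(unclass(corpus)), "[[:space:]]+")
  vocab <- sort(unique(unlist(toks)))
  m <- matrix(0, length(vocab), length(vocab), dimnames = list(vocab, vocab))
  for (tok in toks) {
    n <- length(tok)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):min(n, i + window)) {
        m[tok[i], tok[j]] <- m[tok[i], tok[j]] + 1
        m[tok[j], tok[i]] <- m[tok[j], tok[i]] + 1
      }
    }
  }
  m
}

as_corpus <- function(docs) structure(docs, class = "chronoval_corpus")
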