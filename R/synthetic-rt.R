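#' Specify a factorial Match x Congruency x Domain block design
#'
#' Describes the block structure of a speeded word-categorisation experiment
#' in which four word categories (past, future, negative, positive) are mapped
#' onto two response alternatives. A block is *match* when past and negative
#' share one response (and future and positive the other), *mismatch* under
#' the crossed assignment. Within a block the stimulus-response mapping of
#' each domain can additionally be *congruent* or *incongruent* with the
#' left-to-right mental time line / valence-space association.
#'
#' @param n_subjects number of subjects (>= 2). For a between-subject match
#'   factor, subjects alternate between the match and mismatch groups.
#' @param items_per_category number of words in each of the past, future,
#'   negative and positive lists.
#' @param match_factor `"between"` (each subject sees only one match
#'   condition, as with manual left/right responses) or `"within"` (each
#'   subject sees all blocks, as with vocal responses).
#' @param blocks data frame with columns `match`
#'   (`"match"`/`"mismatch"`) and `congruency`, one row per block in base
#'   presentation order. `congruency` is a block label:
#'   `"congruent"`/`"incongruent"` apply to every trial,
#'   `"time_congruent"`/`"valence_congruent"` give congruent trials for one
#'   domain and incongruent for the other (the mixed blocks of a mismatch
#'   condition), `"not_applicable"` marks designs without a spatial mapping.
#' @param trials_per_block trials per block; when it equals
#'   `4 * items_per_category` every word is shown exactly once per block.
#' @param response_modality `"manual"` or `"vocal"` (metadata only).
#'
#' @return an object of class `"design_spec"`.
#' @seealso [design_exp1()], [design_exp2()], [design_exp3()] for the three
#'   canonical designs; [generate_rt_experiment()] to simulate trials.
#' @export
design_spec <- function(n_subjects, items_per_category, match_factor,
                        blocks, trials_per_block = 4L * items_per_category,
                        response_modality = c("manual", "vocal")) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  items_per_category <- check_count(items_per_category, "items_per_category")
  match_factor <- match_enum(match_factor, c("between", "within"), "match_factor")
  response_modality <- match.arg(response_modality)
  trials_per_block <- check_count(trials_per_block, "trials_per_block")
  if (!is.data.frame(blocks) || nrow(blocks) == 0L ||
      !all(c("match", "congruency") %in% names(blocks))) {
    stop_config("`blocks` must be a non-empty data frame with columns match, congruency")
  }
  if (!all(blocks$match %in% c("match", "mismatch"))) {
    stop_config("block match condition must be 'match' or 'mismatch'")
  }
  cong_levels <- c("congruent", "incongruent", "time_congruent",
                   "valence_congruent", "not_applicable")
  if (!all(blocks$congruency %in% cong_levels)) {
    stop_config("block congruency label must be one of: ",
                paste(cong_levels, collapse = ", "))
  }
  if (match_factor == "between" &&
      length(unique(blocks$match)) < 2L) {
    stop_config("a between-subject design needs blocks for both match conditions")
  }
  structure(list(n_subjects = n_subjects,
                 items_per_category = items_per_category,
                 match_factor = match_factor,
                 blocks = data.frame(match = as.character(blocks$match),
                                     congruency = as.character(blocks$congruency),
                                     stringsAsFactors = FALSE),
                 trials_per_block = trials_per_block,
                 response_modality = response_modality),
            class = "design_spec")
}

#' Canonical designs of the three reaction-time experiments
#'
#' `design_exp1()` is the manual-response design: Match is between-subject
#' (default 40 subjects per group) and each subject runs a fully congruent and
#' a fully incongruent block (match group) or the two mixed blocks (mismatch
#' group). `design_exp2()` and `design_exp3()` are the vocal-response designs:
#' Match is within-subject with four alternating blocks and no spatial
#' congruency manipulation.
#'
#' @param n_subjects total number of subjects.
#' @param items_per_category words per category list.
#' @return a [design_spec()] object.
#' @export
design_exp1 <- function(n_subjects = 80, items_per_category = 15) {
  design_spec(
    n_subjects, items_per_category, match_factor = "between",
    blocks = data.frame(
      match = c("match", "match", "mismatch", "mismatch"),
      congruency = c("congruent", "incongruent",
                     "time_congruent", "valence_congruent")),
    response_modality = "manual")
}

#' @rdname design_exp1
#' @export
design_exp2 <- function(n_subjects = 40, items_per_category = 15) {
  design_spec(
    n_subjects, items_per_category, match_factor = "within",
    blocks = data.frame(
      match = c("match", "mismatch", "match", "mismatch"),
      congruency = rep("not_applicable", 4)),
    response_modality = "vocal")
}

#' @rdname design_exp1
#' @export
design_exp3 <- design_exp2

#' Parameters of the reaction-time generator
#'
#' Condition effects are additive on the millisecond scale; the trial residual
#' is a shifted lognormal (right-skewed, strictly positive) whose mean is
#' calibrated so that the expected RT of a trial equals the sum of the
#' applicable effects. Errors are generated independently of RT by
#' per-condition Bernoulli rates.
#'
#' @param base_rt expected RT (ms) of a correct match/congruent/valence-word
#'   trial in the first block.
#' @param match_effect ms added on mismatch trials.
#' @param congruency_effect ms added on incongruent trials.
#' @param domain_effect ms added on time-word trials.
#' @param practice_slope ms added per block position beyond the first
#'   (negative values model practice speed-up).
#' @param subject_sd,item_sd SDs (ms) of normal subject and item intercepts.
#' @param residual_shape list with `sdlog` (sigma of the lognormal residual on
#'   the log scale; 0 gives a degenerate residual) and `shift` (ms, lower
#'   bound of the RT distribution).
#' @param error_base error probability on match trials.
#' @param error_mismatch_increment extra error probability on mismatch trials.
#' @param seed integer RNG seed (mandatory).
#' @return an object of class `"rt_gen_params"`.
#' @export
rt_gen_params <- function(base_rt = 680, match_effect = 170,
                          congruency_effect = 48, domain_effect = 158,
                          practice_slope = -10, subject_sd = 100,
                          item_sd = 40,
                          residual_shape = list(sdlog = 0.3, shift = 200),
                          error_base = 0.04,
                          error_mismatch_increment = 0.04,
                          seed) {
  if (missing(seed)) stop_config("`seed` is mandatory")
  if (!is.numeric(base_rt) || base_rt <= 0) stop_config("`base_rt` must be > 0")
  p <- list(base_rt = as.numeric(base_rt),
            match_effect = as.numeric(match_effect),
            congruency_effect = as.numeric(congruency_effect),
            domain_effect = as.numeric(domain_effect),
            practice_slope = as.numeric(practice_slope),
            subject_sd = check_nonneg(subject_sd, "subject_sd"),
            item_sd = check_nonneg(item_sd, "item_sd"),
            residual_shape = list(
              sdlog = check_nonneg(residual_shape$sdlog, "residual_shape$sdlog"),
              shift = check_nonneg(residual_shape$shift, "residual_shape$shift")),
            error_base = check_prob(error_base, "error_base"),
            error_mismatch_increment =
              check_prob(error_mismatch_increment, "error_mismatch_increment"),
            seed = as.integer(seed))
  if (p$error_base + p$error_mismatch_increment > 1) {
    stop_config("error_base + error_mismatch_increment must not exceed 1")
  }
  structure(p, class = "rt_gen_params")
}

item_pool <- function(items_per_category) {
  cats <- c("past", "future", "negative", "positive")
  prefix <- c(past = "PAST", future = "FUT", negative = "NEG", positive = "POS")
  data.frame(
    item_id = unlist(lapply(cats, function(cc)
      sprintf("%s%02d", prefix[[cc]], seq_len(items_per_category)))),
    category = rep(cats, each = items_per_category),
    domain = rep(c("time", "time", "valence", "valence"), each = items_per_category),
    stringsAsFactors = FALSE)
}

trial_congruency <- function(block_label, domain) {
  switch(block_label,
         congruent = rep("congruent", length(domain)),
         incongruent = rep("incongruent", length(domain)),
         time_congruent = ifelse(domain == "time", "congruent", "incongruent"),
         valence_congruent = ifelse(domain == "valence", "congruent", "incongruent"),
         not_applicable = rep("not_applicable", length(domain)))
}

#' Generate a trial-level reaction-time experiment
#'
#' Simulates every subject running every block of the design. Expected RT per
#' trial is `base_rt` plus the applicable match, congruency, domain and
#' practice effects plus the subject's and item's intercepts; the residual is
#' shifted-lognormal so that the per-trial expectation equals that sum
#' exactly. Block order is counterbalanced by reversing the base order for
#' even-numbered subjects; within a block, items are cycled to
#' `trials_per_block` and shuffled uniformly. The experiment half
#' (`"first"`/`"second"`) is derived from the block's position in the
#' subject's own presentation order.
#'
#' @param design a [design_spec()].
#' @param params an [rt_gen_params()].
#' @return a data frame of class `"chronoval_trials"` with columns
#'   `subject_id`, `item_id`, `domain`, `category`, `match`, `congruency`,
#'   `block_index`, `half`, `rt_ms`, `correct`.
#' @examples
#' trials <- generate_rt_experiment(design_exp1(n_subjects = 8),
#'                                  rt_gen_params(seed = 1))
#' aggregate(rt_ms ~ match, trials[trials$correct, ], mean)
#' @export
generate_rt_experiment <- function(design, params) {
  if (!inherits(design, "design_spec")) stop_config("`design` must be a design_spec")
  if (!inherits(params, "rt_gen_params")) stop_config("`params` must be rt_gen_params")
  pool <- item_pool(design$items_per_category)
  with_seed(params$seed, {
    subj_off <- stats::rnorm(design$n_subjects, 0, params$subject_sd)
    item_off <- stats::rnorm(nrow(pool), 0, params$item_sd)
    names(item_off) <- pool$item_id

    per_subject <- lapply(seq_len(design$n_subjects), function(s) {
      blocks <- design$blocks
      if (design$match_factor == "between") {
        grp <- if (s %% 2L == 1L) "match" else "mismatch"
        blocks <- blocks[blocks$match == grp, , drop = FALSE]
      }
      # counterbalance presentation order across the subject index
      if ((s + 1L) %/% 2L %% 2L == 0L) blocks <- blocks[rev(seq_len(nrow(blocks))), ]
      nb <- nrow(blocks)
      half <- ifelse(seq_len(nb) <= nb / 2, "first", "second")
      do.call(rbind, lapply(seq_len(nb), function(b) {
        idx <- rep_len(seq_len(nrow(pool)), design$trials_per_block)
        idx <- sample(idx)
        data.frame(subject_id = sprintf("S%03d", s),
                   item_id = pool$item_id[idx],
                   domain = pool$domain[idx],
                   category = pool$category[idx],
                   match = blocks$match[b],
                   congruency = trial_congruency(blocks$congruency[b],
                                                 pool$domain[idx]),
                   block_index = b,
                   half = half[b],
                   stringsAsFactors = FALSE)
      }))
    })
    trials <- do.call(rbind, per_subject)
    rownames(trials) <- NULL

    mu <- params$base_rt +
      params$match_effect * (trials$match == "mismatch") +
      params$congruency_effect * (trials$congruency == "incongruent") +
      params$domain_effect * (trials$domain == "time") +
      params$practice_slope * (trials$block_index - 1L) +
      subj_off[as.integer(sub("S", "", trials$subject_id))] +
      item_off[trials$item_id]
    shift <- params$residual_shape$shift
    sdlog <- params$residual_shape$sdlog
    # extreme subject/item offsets could push the latent mean below the
    # distribution's lower bound; floor it 1 ms above the shift (RTs stay
    # positive, expectation bias is confined to the deep tail)
    mu <- pmax(mu, shift + 1)
    trials$rt_ms <- shift +
      stats::rlnorm(nrow(trials), meanlog = log(mu - shift) - sdlog^2 / 2,
                    sdlog = sdlog)
    p_err <- params$error_base +
      params$error_mismatch_increment * (trials$match == "mismatch")
    trials$correct <- stats::runif(nrow(trials)) >= p_err
    class(trials) <- c("chronoval_trials", "data.frame")
    trials
  })
}

#' Read or write a trial table
#'
#' The on-disk format is a headered CSV with columns `subject_id`, `item_id`,
#' `domain`, `category`, `match`, `congruency`, `block_index`, `half`,
#' `rt_ms`, `correct`.
#'
#' @param trials a trial data frame.
#' @param path file path.
#' @export
write_trials <- function(trials, path) write_table_csv(trials, path)

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "item_id", "domain", "category", "match",
              "congruency", "block_index", "half", "rt_ms", "correct")
  if (!all(needed %in% names(trials))) {
    stop_data("trial CSV is missing columns: ",
              paste(setdiff(needed, names(trials)), collapse = ", "))
  }
  trials$correct <- as.logical(trials$correct)
  class(trials) <- c("chronoval_trials", "data.frame")
  trials
}
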