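#' Parameters of the valence-rating generator
#'
#' Emulates a two-age-group survey in which every participant rates each
#' past-related and future-related word on a 1-7 Likert scale (1 = terrible,
#' 7 = excellent). A participant's rating of a word is a normal draw around
#' the word category's mean plus the participant's intercept, rounded to the
#' integer scale and clamped to [1, 7].
#'
#' @param n_young,n_old group sizes (each >= 1).
#' @param past_mean,future_mean latent category means on the rating scale.
#' @param between_subject_sd SD of the participant intercepts.
#' @param within_noise_sd SD of the per-rating noise.
#' @param age_interaction added to the future-word mean for the older group
#'   (0 means both groups share the same time effect).
#' @param n_items words per time category (each participant rates all of
#'   them).
#' @param seed integer RNG seed (mandatory).
#' @return an object of class `"rating_gen_params"`.
#' @seealso [calibrate_rating_params()] to pick means for a target
#'   standardised time effect.
#' @export
rating_gen_params <- function(n_young = 826, n_old = 221,
                              past_mean = 3.88, future_mean = 4.12,
                              between_subject_sd = 0.8,
                              within_noise_sd = 1.2,
                              age_interaction = 0,
                              n_items = 15, seed) {
  if (missing(seed)) stop_config("`seed` is mandatory")
  p <- list(n_young = check_count(n_young, "n_young"),
            n_old = check_count(n_old, "n_old"),
            past_mean = as.numeric(past_mean),
            future_mean = as.numeric(future_mean),
            between_subject_sd = check_nonneg(between_subject_sd, "between_subject_sd"),
            within_noise_sd = check_nonneg(within_noise_sd, "within_noise_sd"),
            age_interaction = as.numeric(age_interaction),
            n_items = check_count(n_items, "n_items"),
            seed = as.integer(seed))
  if (p$past_mean < 1 || p$past_mean > 7 || p$future_mean < 1 || p$future_mean > 7) {
    stop_config("category means must lie within the 1-7 scale")
  }
  structure(p, class = "rating_gen_params")
}

#' Choose rating-generator means for a target standardised time effect
#'
#' Returns [rating_gen_params()] whose latent past/future means are placed
#' symmetrically about `center` so that the standardised within-subject time
#' effect d = mean(future - past) / SD(future - past), computed on
#' per-participant means over `n_items` ratings, equals `d`. The per-rating
#' variance used in the calibration is `within_noise_sd^2 + 1/12`, the
#' Sheppard-corrected variance accounting for rounding to the integer scale.
#'
#' @param d target standardised difference.
#' @param center scale value about which the two means are placed.
#' @inheritParams rating_gen_params
#' @param ... further arguments passed to [rating_gen_params()].
#' @return a `"rating_gen_params"` object.
#' @export
calibrate_rating_params <- function(d, seed, center = 4,
                                    within_noise_sd = 1.2, n_items = 15, ...) {
  sd_diff <- sqrt(2 * (within_noise_sd^2 + 1 / 12) / n_items)
  delta <- d * sd_diff
  rating_gen_params(past_mean = center - delta / 2,
                    future_mean = center + delta / 2,
                    within_noise_sd = within_noise_sd,
                    n_items = n_items, seed = seed, ...)
}

#' Generate a two-age-group valence-rating survey
#'
#' @param params a [rating_gen_params()].
#' @return a data frame of class `"chronoval_ratings"` with columns
#'   `participant_id`, `age_group` (`"younger"`/`"older"`), `word`,
#'   `time_category` (`"past"`/`"future"`), `rating` (integer 1-7).
#' @examples
#' r <- generate_ratings(rating_gen_params(n_young = 20, n_old = 5, seed = 1))
#' aggregate(rating ~ time_category, r, mean)
#' @export
generate_ratings <- function(params) {
  if (!inherits(params, "rating_gen_params")) {
    stop_config("`params` must be rating_gen_params")
  }
  n <- params$n_young + params$n_old
  words <- c(sprintf("PAST%02d", seq_len(params$n_items)),
             sprintf("FUT%02d", seq_len(params$n_items)))
  time_category <- rep(c("past", "future"), each = params$n_items)
  with_seed(params$seed, {
    age_group <- rep(c("younger", "older"), c(params$n_young, params$n_old))
    intercept <- stats::rnorm(n, 0, params$between_subject_sd)
    out <- data.frame(
      participant_id = rep(sprintf("P%04d", seq_len(n)), each = 2L * params$n_items),
      age_group = rep(age_group, each = 2L * params$n_items),
      word = rep(words, n),
      time_category = rep(time_category, n),
      stringsAsFactors = FALSE)
    mu <- ifelse(out$time_category == "past", params$past_mean,
                 params$future_mean) +
      params$age_interaction *
        (out$age_group == "older" & out$time_category == "future") +
      rep(intercept, each = 2L * params$n_items)
    raw <- mu + stats::rnorm(nrow(out), 0, params$within_noise_sd)
    out$rating <- pmin(pmax(round(raw), 1L), 7L)
    class(out) <- c("chronoval_ratings", "data.frame")
    out
  })
}

#' Read or write a rating table
#'
#' CSV columns: `participant_id`, `age_group`, `word`, `time_category`,
#' `rating`.
#'
#' @param ratings a rating data frame.
#' @param path file path.
#' @export
write_ratings <- function(ratings, path) write_table_csv(ratings, path)

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  ratings <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "age_group", "word", "time_category", "rating")
  if (!all(needed %in% names(ratings))) {
    stop_data("rating CSV is missing columns: ",
              paste(setdiff(needed, names(ratings)), collapse = ", "))
  }
  class(ratings) <- c("chronoval_ratings", "data.frame")
  ratings
}
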