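#' Per-participant mean ratings by time category
#'
#' @param ratings a rating data frame (see [generate_ratings()]).
#' @return a data frame with columns `participant_id`, `age_group`,
#'   `mean_past`, `mean_future`, one row per participant.
#' @export
participant_means <- function(ratings) {
  key <- interaction(ratings$participant_id, ratings$time_category, drop = FALSE)
  by_part <- split(ratings, ratings$participant_id)
  missing <- names(by_part)[!vapply(by_part, function(d)
    all(c("past", "future") %in% d$time_category), logical(1))]
  if (length(missing)) {
    stop_data("participant(s) missing a time category: ",
              paste(utils::head(missing, 5L), collapse = ", "))
  }
  ids <- names(by_part)
  m <- tapply(ratings$rating,
              list(factor(ratings$participant_id, ids),
                   factor(ratings$time_category, c("past", "future"))),
              mean)
  data.frame(participant_id = ids,
             age_group = vapply(by_part, function(d) d$age_group[1L], ""),
             mean_past = m[, "past"],
             mean_future = m[, "future"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mixed-design ANOVA of past/future valence ratings
#'
#' Classical 2 (age group, between-subject) x 2 (time category,
#' within-subject) ANOVA computed from sums of squares: the between-subject
#' stratum is built on participant averages, the within-subject stratum on
#' each participant's future-minus-past difference. Degrees of freedom derive
#' from the design: (1, N - 2) for all three effects, with N the number of
#' participants. The standardised time effect is the within-subject
#' d = mean(future - past) / SD(future - past), pooled across all
#' participants.
#'
#' When the within-subject error is exactly zero (e.g. a constant difference
#' with no noise), the Time F is reported as `Inf` with p = 0 and the report
#' carries a `degenerate` flag.
#'
#' @param means output of [participant_means()].
#' @return an object of class `"rating_anova"`: a list with `table` (rows
#'   `adult`, `time`, `adult_time`; columns `F`, `df1`, `df2`, `p`),
#'   `d_time`, `n` (per-group sizes) and `degenerate`.
#' @examples
#' r <- generate_ratings(rating_gen_params(n_young = 30, n_old = 10, seed = 2))
#' mixed_anova(participant_means(r))
#' @export
mixed_anova <- function(means) {
  groups <- sort(unique(means$age_group))
  if (length(groups) != 2L) stop_data("need exactly two age groups")
  n_g <- table(factor(means$age_group, groups))
  if (any(n_g < 2L)) {
    stop_data("each age group needs at least 2 participants")
  }
  N <- nrow(means)
  A <- (means$mean_past + means$mean_future) / 2
  D <- means$mean_future - means$mean_past
  g <- factor(means$age_group, groups)

  # between-subject stratum (participant averages, 2 measurements each)
  grand <- mean(A)
  gm <- tapply(A, g, mean)
  ss_adult <- 2 * sum(as.numeric(n_g) * (gm - grand)^2)
  ss_subj <- 2 * sum((A - gm[g])^2)
  df_err <- N - 2L

  # within-subject stratum (difference scores)
  sumD <- sum(D)
  sumD_g <- tapply(D, g, sum)
  ss_time <- sumD^2 / (2 * N)
  ss_int <- sum(sumD_g^2 / (2 * as.numeric(n_g))) - ss_time
  ss_werr <- sum(D^2) / 2 - sum(sumD_g^2 / (2 * as.numeric(n_g)))

  ms_subj <- ss_subj / df_err
  ms_werr <- ss_werr / df_err
  f_of <- function(ss, ms_err) if (ms_err > 0) ss / ms_err else
    if (ss > 0) Inf else 0
  Fs <- c(adult = f_of(ss_adult, ms_subj),
          time = f_of(ss_time, ms_werr),
          adult_time = f_of(ss_int, ms_werr))
  ps <- ifelse(is.infinite(Fs), 0, stats::pf(Fs, 1, df_err, lower.tail = FALSE))
  sd_D <- stats::sd(D)
  structure(list(
    table = data.frame(effect = c("adult", "time", "adult_time"),
                       F = as.numeric(Fs), df1 = 1L, df2 = df_err,
                       p = as.numeric(ps), stringsAsFactors = FALSE),
    d_time = if (sd_D > 0) mean(D) / sd_D else
      if (mean(D) == 0) 0 else Inf * sign(mean(D)),
    n = as.integer(n_g),
    degenerate = ms_werr == 0 || ms_subj == 0),
    class = "rating_anova")
}

#' @export
print.rating_anova <- function(x, ...) {
  cat(sprintf("Mixed 2 x 2 ANOVA on ratings (n = %d + %d participants)\n",
              x$n[1L], x$n[2L]))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-10s F(%d, %d) = %.2f, p = %.3g\n",
                tab$effect[i], tab$df1[i], tab$df2[i], tab$F[i], tab$p[i]))
  }
  cat(sprintf("  time effect d = %.3f (within-subject difference scores)\n",
              x$d_time))
  if (x$degenerate) cat("  note: degenerate (zero) error variance in one stratum\n")
  invisible(x)
}
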