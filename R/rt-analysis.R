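#' Filter reaction-time outliers
#'
#' Discards trials with RTs strictly below `low` or strictly above `high`
#' (boundary values are retained, matching removal of RTs "shorter than" /
#' "larger than" the cutoffs). The filter runs on the full trial table,
#' before any accuracy partitioning, and is idempotent.
#'
#' @param trials a trial data frame (see [generate_rt_experiment()]).
#' @param low,high cutoffs in ms; default 250 and 2000.
#' @return an object of class `"filter_report"`: a list with `n_input`,
#'   `n_below_low`, `n_above_high`, `fraction_below`, `fraction_above` and
#'   the retained `trials`.
#' @examples
#' tr <- data.frame(rt_ms = c(200, 250, 1500, 2000, 2500))
#' filter_outliers(tr)$n_below_low
#' @export
filter_outliers <- function(trials, low = 250, high = 2000) {
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    stop_config("`low` must be smaller than `high`")
  }
  n <- nrow(trials)
  below <- trials$rt_ms < low
  above <- trials$rt_ms > high
  structure(list(
    n_input = n,
    n_below_low = sum(below),
    n_above_high = sum(above),
    fraction_below = if (n) sum(below) / n else 0,
    fraction_above = if (n) sum(above) / n else 0,
    low = low, high = high,
    trials = trials[!(below | above), , drop = FALSE]),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Outlier filter [%g, %g] ms: %d trials in, %d below (%.2f%%), %d above (%.2f%%), %d retained\n",
    x$low, x$high, x$n_input, x$n_below_low, 100 * x$fraction_below,
    x$n_above_high, 100 * x$fraction_above, nrow(x$trials)))
  invisible(x)
}

rt_factors <- c("match", "congruency", "domain", "category", "half")

#' Condition means of RT and percentage correct
#'
#' Cell means over the crossing of the requested factors. RT means use
#' correct trials only; percentage correct uses all retained trials. Cells of
#' the factor crossing without any trials are kept in the table and flagged
#' via `n_trials = 0`.
#'
#' @param trials filtered trials.
#' @param factors character vector of factor names among `match`,
#'   `congruency`, `domain`, `category`, `half`.
#' @return a data frame with one row per cell: the factor columns,
#'   `mean_rt` (ms, correct trials), `pc` (percent correct), `n_trials`,
#'   `n_correct`.
#' @export
condition_summary <- function(trials, factors = c("match", "congruency", "domain")) {
  bad <- setdiff(factors, rt_factors)
  if (length(bad)) stop_config("unknown factor name(s): ", paste(bad, collapse = ", "))
  levels <- lapply(factors, function(f) sort(unique(trials[[f]])))
  names(levels) <- factors
  grid <- expand.grid(levels, stringsAsFactors = FALSE)
  key <- do.call(paste, c(trials[factors], sep = "\r"))
  gkey <- do.call(paste, c(grid, sep = "\r"))
  grid$n_trials <- as.integer(table(factor(key, levels = gkey)))
  corr <- trials$correct
  grid$n_correct <- as.integer(table(factor(key[corr], levels = gkey)))
  rt_sum <- tapply(trials$rt_ms[corr], factor(key[corr], levels = gkey), sum)
  grid$mean_rt <- as.numeric(rt_sum) / grid$n_correct
  grid$pc <- 100 * grid$n_correct / grid$n_trials
  grid$mean_rt[grid$n_correct == 0L] <- NA_real_
  grid$pc[grid$n_trials == 0L] <- NA_real_
  grid[c(factors, "mean_rt", "pc", "n_trials", "n_correct")]
}

effect_levels <- list(
  match = c("match", "mismatch"),
  congruency = c("congruent", "incongruent"),
  domain = c("valence", "time"))

# Subject-level means, aggregated item -> subject: per subject x level, each
# item's trials are averaged first, then the item means are averaged.
subject_level_means <- function(trials, effect_name, measure = "rt") {
  levs <- effect_levels[[effect_name]]
  use <- trials[trials[[effect_name]] %in% levs, , drop = FALSE]
  if (measure == "rt") {
    use <- use[use$correct, , drop = FALSE]
    value <- use$rt_ms
  } else {
    value <- 100 * as.numeric(use$correct)
  }
  if (nrow(use) == 0L) {
    return(data.frame(subject_id = character(), level = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  ikey <- interaction(use$subject_id, use[[effect_name]], use$item_id, drop = TRUE)
  item_means <- tapply(value, ikey, mean)
  parts <- strsplit(names(item_means), ".", fixed = TRUE)
  sub <- vapply(parts, `[`, "", 1L)
  lev <- vapply(parts, `[`, "", 2L)
  skey <- paste(sub, lev, sep = "\r")
  sm <- tapply(as.numeric(item_means), skey, mean)
  parts <- strsplit(names(sm), "\r", fixed = TRUE)
  data.frame(subject_id = vapply(parts, `[`, "", 1L),
             level = vapply(parts, `[`, "", 2L),
             value = as.numeric(sm), stringsAsFactors = FALSE)
}

#' Estimate a condition effect with subject-level permutation inference
#'
#' The estimand is the difference of the two level means, computed on
#' subject-level means (each subject contributes one mean per level it saw,
#' items averaged first). The sign convention is second minus first level of
#' `match/mismatch`, `congruent/incongruent`, `valence/time`, so the canonical
#' slowing effects are positive. The permutation null flips each subject's
#' level labels (within-subject factor) or reassigns subjects to groups
#' (between-subject factor); `p = (1 + #\{|perm| >= |obs|\}) / (1 + B)`.
#'
#' @param trials filtered trials.
#' @param effect_name `"match"`, `"congruency"` or `"domain"`.
#' @param n_permutations number of permutations.
#' @param seed RNG seed (mandatory).
#' @param measure `"rt"` (ms, correct trials only) or `"pc"` (percentage
#'   points, all trials).
#' @return an object of class `"effect_report"`: `effect_name`, `estimate`,
#'   `level_means`, `permutation_p`, `n_permutations`, `type`
#'   (`"within"`/`"between"`), `n_subjects`, `seed`, `measure`.
#' @export
estimate_effect <- function(trials, effect_name, n_permutations = 5000, seed,
                            measure = c("rt", "pc")) {
  if (missing(seed)) stop_config("`seed` is mandatory")
  measure <- match.arg(measure)
  effect_name <- match_enum(effect_name, names(effect_levels), "effect_name")
  n_permutations <- check_count(n_permutations, "n_permutations")
  levs <- effect_levels[[effect_name]]
  sm <- subject_level_means(trials, effect_name, measure)
  if (!all(levs %in% sm$level)) {
    stop_data("level(s) missing for all subjects: ",
              paste(setdiff(levs, sm$level), collapse = ", "))
  }
  per_subject <- split(sm, sm$subject_id)
  both <- vapply(per_subject, function(d) all(levs %in% d$level), logical(1))
  within <- all(both)
  level_means <- vapply(levs, function(l) mean(sm$value[sm$level == l]), numeric(1))
  with_seed(seed, {
    if (within) {
      d <- vapply(per_subject, function(s) {
        s$value[s$level == levs[2L]] - s$value[s$level == levs[1L]]
      }, numeric(1))
      obs <- mean(d)
      signs <- matrix(sample(c(-1, 1), n_permutations * length(d), replace = TRUE),
                      n_permutations, length(d))
      perm <- drop(signs %*% d) / length(d)
    } else {
      if (any(both)) {
        stop_data("mixed within/between structure for factor ", effect_name)
      }
      v <- vapply(per_subject, function(s) s$value[1L], numeric(1))
      g <- vapply(per_subject, function(s) s$level[1L], character(1))
      n2 <- sum(g == levs[2L])
      obs <- mean(v[g == levs[2L]]) - mean(v[g == levs[1L]])
      perm <- vapply(seq_len(n_permutations), function(b) {
        idx <- sample.int(length(v), n2)
        mean(v[idx]) - mean(v[-idx])
      }, numeric(1))
    }
    p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_permutations)
  })
  structure(list(effect_name = effect_name, estimate = obs,
                 level_means = level_means, permutation_p = p,
                 n_permutations = n_permutations,
                 type = if (within) "within" else "between",
                 n_subjects = length(per_subject),
                 seed = as.integer(seed), measure = measure),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  unit <- if (x$measure == "rt") "ms" else "pp"
  cat(sprintf("%s effect (%s, %s-subject): %s = %.1f %s [%s]\n",
              x$effect_name, x$measure, x$type,
              paste(rev(names(x$level_means)), collapse = " - "),
              x$estimate, unit,
              paste(sprintf("%s %.1f", names(x$level_means), x$level_means),
                    collapse = ", ")))
  cat(sprintf("  permutation p = %.4g (%d permutations, seed %d)\n",
              x$permutation_p, x$n_permutations, x$seed))
  invisible(x)
}

#' First- versus second-half practice analysis of the match effect
#'
#' Splits the retained trials by experiment half and reports, per half, the
#' match and mismatch mean RT (correct trials) and percentage correct, and
#' the match effects as mismatch minus match for both measures (so the PC
#' effect is negative when the match condition is the more accurate one). The
#' Half x Match interaction is tested by permutation at the subject level:
#' for a within-subject match factor each subject's half labels are flipped
#' (sign-flipping the subject's first-minus-second match-effect difference);
#' for a between-subject match factor subjects' practice effects are
#' reassigned across the two groups.
#'
#' @param trials filtered trials carrying `half` labels.
#' @param n_permutations permutations for the interaction test.
#' @param seed RNG seed (mandatory).
#' @return an object of class `"half_split_report"`: `cells` (a data frame
#'   with one row per half), `interaction_p_rt`, `interaction_p_pc`.
#' @export
half_split <- function(trials, n_permutations = 5000, seed) {
  if (missing(seed)) stop_config("`seed` is mandatory")
  halves <- c("first", "second")
  if (!all(halves %in% trials$half)) {
    stop_data("half with no trials: ",
              paste(setdiff(halves, unique(trials$half)), collapse = ", "))
  }
  cs <- condition_summary(trials, c("half", "match"))
  cells <- do.call(rbind, lapply(halves, function(h) {
    m <- cs[cs$half == h & cs$match == "match", ]
    mm <- cs[cs$half == h & cs$match == "mismatch", ]
    data.frame(half = h,
               match_rt = m$mean_rt, mismatch_rt = mm$mean_rt,
               rt_effect = mm$mean_rt - m$mean_rt,
               match_pc = m$pc, mismatch_pc = mm$pc,
               pc_effect = mm$pc - m$pc,
               stringsAsFactors = FALSE)
  }))
  p <- lapply(c(rt = "rt", pc = "pc"), function(measure)
    half_interaction_p(trials, measure, n_permutations, seed))
  structure(list(cells = cells,
                 interaction_p_rt = p$rt, interaction_p_pc = p$pc,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "half_split_report")
}

# Subject-level Half x Match interaction permutation test.
half_interaction_p <- function(trials, measure, n_permutations, seed) {
  cell_means <- function(sub) {
    out <- matrix(NA_real_, 2, 2, dimnames = list(c("first", "second"),
                                                  c("match", "mismatch")))
    use <- if (measure == "rt") sub[sub$correct, , drop = FALSE] else sub
    value <- if (measure == "rt") use$rt_ms else 100 * as.numeric(use$correct)
    m <- tapply(value, list(factor(use$half, rownames(out)),
                            factor(use$match, colnames(out))), mean)
    out[] <- m
    out
  }
  per_subject <- lapply(split(trials, trials$subject_id), cell_means)
  has_both_match <- vapply(per_subject, function(m) all(!is.na(m)), logical(1))
  with_seed(seed, {
    if (all(has_both_match)) {
      # within-subject match: d = (mm - m)_first - (mm - m)_second per subject
      d <- vapply(per_subject, function(m) {
        (m["first", "mismatch"] - m["first", "match"]) -
          (m["second", "mismatch"] - m["second", "match"])
      }, numeric(1))
      d <- d[is.finite(d)]
      if (length(d) < 2L) stop_data("too few subjects with complete cells")
      obs <- mean(d)
      signs <- matrix(sample(c(-1, 1), n_permutations * length(d), replace = TRUE),
                      n_permutations, length(d))
      perm <- drop(signs %*% d) / length(d)
    } else {
      # between-subject match: practice effect (first - second) per subject,
      # interaction = group difference of practice effects
      pe <- vapply(per_subject, function(m) {
        col <- colnames(m)[colSums(!is.na(m)) == 2L][1L]
        m["first", col] - m["second", col]
      }, numeric(1))
      grp <- vapply(split(trials$match, trials$subject_id), `[`, "", 1L)
      keep <- is.finite(pe)
      pe <- pe[keep]; grp <- grp[names(pe)]
      n_mm <- sum(grp == "mismatch")
      obs <- mean(pe[grp == "mismatch"]) - mean(pe[grp == "match"])
      perm <- vapply(seq_len(n_permutations), function(b) {
        idx <- sample.int(length(pe), n_mm)
        mean(pe[idx]) - mean(pe[-idx])
      }, numeric(1))
    }
    (1 + sum(abs(perm) >= abs(obs))) / (1 + n_permutations)
  })
}

#' @export
print.half_split_report <- function(x, ...) {
  cat("Match effect by experiment half (mismatch - match):\n")
  for (i in seq_len(nrow(x$cells))) {
    r <- x$cells[i, ]
    cat(sprintf("  %s half: RT %.0f - %.0f = %.0f ms; PC %.1f - %.1f = %.1f%%\n",
                r$half, r$mismatch_rt, r$match_rt, r$rt_effect,
                r$mismatch_pc, r$match_pc, r$pc_effect))
  }
  cat(sprintf("  Half x Match interaction: p(RT) = %.3f, p(PC) = %.3f\n",
              x$interaction_p_rt, x$interaction_p_pc))
  invisible(x)
}

#' Check that an RT effect is not a speed-accuracy trade-off
#'
#' For each requested effect, tests whether the level that is faster in mean
#' RT is also weakly more accurate (ties count as consistent). Returns `TRUE`
#' overall only if every examined effect is consistent.
#'
#' @param trials filtered trials.
#' @param effects effect names to examine.
#' @return an object of class `"speed_accuracy_report"` with `consistent`
#'   (overall logical) and a per-effect `table`.
#' @export
speed_accuracy_check <- function(trials, effects = c("match", "congruency", "domain")) {
  rows <- lapply(effects, function(e) {
    levs <- effect_levels[[e]]
    if (!all(levs %in% trials[[e]])) return(NULL)
    sm_rt <- subject_level_means(trials, e, "rt")
    sm_pc <- subject_level_means(trials, e, "pc")
    rt <- vapply(levs, function(l) mean(sm_rt$value[sm_rt$level == l]), numeric(1))
    pc <- vapply(levs, function(l) mean(sm_pc$value[sm_pc$level == l]), numeric(1))
    faster <- levs[which.min(rt)]
    data.frame(effect = e, faster_level = faster,
               rt_diff = rt[levs[2L]] - rt[levs[1L]],
               pc_diff = pc[levs[2L]] - pc[levs[1L]],
               consistent = pc[faster] >= pc[setdiff(levs, faster)],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(consistent = all(tab$consistent), table = tab),
            class = "speed_accuracy_report")
}

#' Cross-check a condition effect with a mixed-effects model
#'
#' Convenience plumbing around `lme4::lmer()` (suggested dependency): fits
#' RT on the requested factor with random intercepts for subjects and items
#' and returns the fixed-effect estimate for comparison with
#' [estimate_effect()]. This is a cross-check utility, not the package's
#' inference path.
#'
#' @param trials filtered trials.
#' @param effect_name `"match"`, `"congruency"` or `"domain"`.
#' @return the fixed-effect estimate (ms) of the factor's second level, or
#'   `NA` with a message when `lme4` is not installed.
#' @export
mixed_model_check <- function(trials, effect_name = "match") {
  effect_name <- match_enum(effect_name, names(effect_levels), "effect_name")
  if (!requireNamespace("lme4", quietly = TRUE)) {
    message("lme4 not installed; skipping mixed-model cross-check")
    return(NA_real_)
  }
  levs <- effect_levels[[effect_name]]
  use <- trials[trials$correct & trials[[effect_name]] %in% levs, , drop = FALSE]
  use$x <- factor(use[[effect_name]], levs)
  fit <- lme4::lmer(rt_ms ~ x + (1 | subject_id) + (1 | item_id), data = use)
  unname(lme4::fixef(fit)[2L])
}

#' @export
print.speed_accuracy_report <- function(x, ...) {
  cat("Speed-accuracy consistency:",
      if (x$consistent) "no trade-off detected" else "trade-off pattern present", "\n")
  print.data.frame(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
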