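make_ratings <- function(tbl) {
  # tbl: list of participant -> list(age, past = c(...), future = c(...))
  do.call(rbind, lapply(names(tbl), function(id) {
    p <- tbl[[id]]
    data.frame(participant_id = id, age_group = p$age,
               word = c(sprintf("PAST%02d", seq_along(p$past)),
                        sprintf("FUT%02d", seq_along(p$future))),
               time_category = rep(c("past", "future"),
                                   c(length(p$past), length(p$future))),
               rating = c(p$past, p$future), stringsAsFactors = FALSE)
  }))
}

test_that("participant means are plain arithmetic means per category", {
  r <- make_ratings(list(P1 = list(age = "younger", past = c(3, 5), future = c(6, 6))))
  pm <- participant_means(r)
  expect_equal(pm$mean_past, 4)
  expect_equal(pm$mean_future, 6)
  r7 <- make_ratings(list(P1 = list(age = "younger", past = c(7, 7), future = c(7, 7)),
                          P2 = list(age = "older", past = 7, future = 7)))
  pm7 <- participant_means(r7)
  expect_true(all(pm7$mean_past == 7) && all(pm7$mean_future == 7))
  incomplete <- r[r$time_category == "past", ]
  expect_error(participant_means(incomplete), "P1")
})

test_that("participant means agree with an independent group-by oracle", {
  r <- generate_ratings(rating_gen_params(n_young = 15, n_old = 8, seed = 6))
  pm <- participant_means(r)
  oracle <- aggregate(rating ~ participant_id + time_category, r, mean)
  for (i in seq_len(nrow(pm))) {
    expect_equal(pm$mean_past[i],
                 oracle$rating[oracle$participant_id == pm$participant_id[i] &
                                 oracle$time_category == "past"])
    expect_equal(pm$mean_future[i],
                 oracle$rating[oracle$participant_id == pm$participant_id[i] &
                                 oracle$time_category == "future"])
  }
})

test_that("mixed ANOVA matches the aov() oracle on small balanced tables", {
  r <- generate_ratings(rating_gen_params(n_young = 8, n_old = 8, seed = 9))
  pm <- participant_means(r)
  long <- reshape(pm, direction = "long",
                  varying = c("mean_past", "mean_future"), v.names = "y",
                  timevar = "time", times = c("past", "future"),
                  idvar = "participant_id")
  fit <- summary(aov(y ~ age_group * time + Error(factor(participant_id)),
                     data = long))
  between <- fit[["Error: factor(participant_id)"]][[1]]
  within <- fit[["Error: Within"]][[1]]
  an <- mixed_anova(pm)$table
  expect_equal(an$F[an$effect == "adult"], between["age_group", "F value"])
  expect_equal(an$F[an$effect == "time"], within["time", "F value"])
  expect_equal(an$F[an$effect == "adult_time"],
               within["age_group:time", "F value"])
  expect_equal(unique(an$df2), 14)
})

test_that("mixed ANOVA matches aov() with unbalanced groups", {
  r <- generate_ratings(rating_gen_params(n_young = 21, n_old = 6, seed = 10))
  pm <- participant_means(r)
  long <- reshape(pm, direction = "long",
                  varying = c("mean_past", "mean_future"), v.names = "y",
                  timevar = "time", times = c("past", "future"),
                  idvar = "participant_id")
  fit <- summary(aov(y ~ age_group * time + Error(factor(participant_id)),
                     data = long))
  an <- mixed_anova(pm)$table
  expect_equal(an$F[an$effect == "time"],
               fit[["Error: Within"]][[1]]["time", "F value"])
  expect_equal(an$F[an$effect == "adult_time"],
               fit[["Error: Within"]][[1]]["age_group:time", "F value"])
})

test_that("degenerate zero-variance designs are flagged, not crashed", {
  tbl <- list(P1 = list(age = "younger", past = 3, future = 4),
              P2 = list(age = "younger", past = 4, future = 5),
              P3 = list(age = "older", past = 2, future = 3),
              P4 = list(age = "older", past = 5, future = 6))
  an <- mixed_anova(participant_means(make_ratings(tbl)))
  expect_true(is.infinite(an$table$F[an$table$effect == "time"]))
  expect_equal(an$table$p[an$table$effect == "time"], 0)
  expect_equal(an$table$F[an$table$effect == "adult_time"], 0)
  expect_true(an$degenerate)
})

test_that("F and d are invariant to adding a constant to all ratings", {
  r <- generate_ratings(rating_gen_params(n_young = 10, n_old = 5,
                                          between_subject_sd = 0.3,
                                          within_noise_sd = 0.5, seed = 11))
  pm <- participant_means(r)
  an1 <- mixed_anova(pm)
  pm2 <- pm
  pm2$mean_past <- pm2$mean_past + 10
  pm2$mean_future <- pm2$mean_future + 10
  an2 <- mixed_anova(pm2)
  expect_equal(an1$table$F, an2$table$F)
  expect_equal(an1$d_time, an2$d_time)
})

test_that("swapping past and future negates d and preserves F", {
  r <- generate_ratings(rating_gen_params(n_young = 10, n_old = 5, seed = 12))
  pm <- participant_means(r)
  an1 <- mixed_anova(pm)
  pm2 <- pm
  names(pm2)[match(c("mean_past", "mean_future"), names(pm2))] <-
    c("mean_future", "mean_past")
  an2 <- mixed_anova(pm2)
  expect_equal(an2$d_time, -an1$d_time)
  expect_equal(an2$table$F, an1$table$F)
})

test_that("group-size preconditions are enforced", {
  tbl <- list(P1 = list(age = "younger", past = 3, future = 4),
              P2 = list(age = "younger", past = 4, future = 5),
              P3 = list(age = "older", past = 2, future = 3))
  expect_error(mixed_anova(participant_means(make_ratings(tbl))), "at least 2")
  one_group <- make_ratings(list(P1 = list(age = "younger", past = 3, future = 4),
                                 P2 = list(age = "younger", past = 4, future = 5)))
  expect_error(mixed_anova(participant_means(one_group)), "two age groups")
})
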