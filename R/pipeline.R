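#' Run a seeded end-to-end generate-analyze-report pipeline
#'
#' Executes one study component from a configuration, writing all
#' intermediate tables as headered CSV plus a JSON manifest with the config
#' echo, package version and per-file MD5 checksums. Components:
#' \describe{
#'   \item{`exp_rt`}{generate a trial table, filter outliers, condition
#'     summary, permutation effect estimates, half-split practice analysis,
#'     speed-accuracy check.}
#'   \item{`exp_rating`}{generate ratings, participant means, mixed ANOVA.}
#'   \item{`exp_dsm`}{generate a corpus, build LSA and HAL spaces, cosine
#'     tables and category ANOVAs.}
#'   \item{`ia_predictions`}{match-effect predictions for both network
#'     variants and their comparison.}
#' }
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Required fields: `component` and `seed`; per-component generator and
#'   analysis parameters are passed in nested lists `design`, `params` and
#'   `analysis` (see the examples in the package vignette).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly, as a list of class `"run_manifest"`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("`config` must be a list or a YAML file path")
  if (is.null(config$seed)) stop_config("`seed` is mandatory in the run config")
  component <- match_enum(config$component %||% "",
                          c("exp_rt", "exp_rating", "exp_dsm", "ia_predictions"),
                          "component")
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- switch(component,
                  exp_rt = run_exp_rt(config, seed, out_dir),
                  exp_rating = run_exp_rating(config, seed, out_dir),
                  exp_dsm = run_exp_dsm(config, seed, out_dir),
                  ia_predictions = run_ia_predictions(config, out_dir))
  manifest <- list(config = config,
                   component = component,
                   package_version = as.character(utils::packageVersion("chronoval")),
                   files = as.list(tools::md5sum(files)),
                   generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}

apply_args <- function(fun, args, fixed = list()) {
  do.call(fun, c(as.list(args), fixed))
}

run_exp_rt <- function(config, seed, out_dir) {
  design <- apply_args(
    switch(config$design$template %||% "exp1",
           exp1 = design_exp1, exp2 = design_exp2, exp3 = design_exp3),
    config$design[setdiff(names(config$design), "template")])
  params <- apply_args(rt_gen_params, config$params, list(seed = seed))
  trials <- generate_rt_experiment(design, params)
  flt <- filter_outliers(trials,
                         low = config$analysis$low %||% 250,
                         high = config$analysis$high %||% 2000)
  nperm <- config$analysis$n_permutations %||% 5000
  effects <- c("match", if (any(flt$trials$congruency %in%
                                c("congruent", "incongruent"))) "congruency",
               "domain")
  est <- lapply(effects, function(e)
    estimate_effect(flt$trials, e, n_permutations = nperm, seed = seed))
  hs <- half_split(flt$trials, n_permutations = nperm, seed = seed)
  sac <- speed_accuracy_check(flt$trials, effects)
  paths <- file.path(out_dir, c("trials.csv", "condition_summary.csv",
                                "effects.csv", "half_split.csv",
                                "speed_accuracy.csv"))
  write_trials(trials, paths[1L])
  write_table_csv(condition_summary(flt$trials,
                                    intersect(c("match", "congruency", "domain"),
                                              effects)), paths[2L])
  write_table_csv(do.call(rbind, lapply(est, function(e)
    data.frame(effect = e$effect_name, estimate = e$estimate,
               level_1 = e$level_means[1L], level_2 = e$level_means[2L],
               permutation_p = e$permutation_p, type = e$type))), paths[3L])
  write_table_csv(cbind(hs$cells,
                        interaction_p_rt = hs$interaction_p_rt,
                        interaction_p_pc = hs$interaction_p_pc), paths[4L])
  write_table_csv(sac$table, paths[5L])
  paths
}

run_exp_rating <- function(config, seed, out_dir) {
  params <- apply_args(rating_gen_params, config$params, list(seed = seed))
  ratings <- generate_ratings(params)
  pm <- participant_means(ratings)
  an <- mixed_anova(pm)
  paths <- file.path(out_dir, c("ratings.csv", "participant_means.csv",
                                "anova.csv"))
  write_ratings(ratings, paths[1L])
  write_table_csv(pm, paths[2L])
  write_table_csv(cbind(an$table, d_time = an$d_time), paths[3L])
  paths
}

run_exp_dsm <- function(config, seed, out_dir) {
  spec <- apply_args(corpus_spec, config$params, list(seed = seed))
  corpus <- generate_corpus(spec)
  paths <- file.path(out_dir, c("corpus.txt", "cosines_lsa.csv",
                                "cosines_hal.csv", "dsm_anova.csv"))
  write_corpus(corpus, paths[1L])
  lsa <- build_lsa(corpus,
                   n_dimensions = min(config$analysis$n_dimensions %||% 50,
                                      length(corpus),
                                      length(unlist(spec$vocabulary))))
  hal <- build_hal(corpus, window = config$analysis$window %||% 5)
  tabs <- list(lsa = cosine_table(lsa, spec$vocabulary),
               hal = cosine_table(hal, spec$vocabulary))
  write_table_csv(as.data.frame(tabs$lsa), paths[2L])
  write_table_csv(as.data.frame(tabs$hal), paths[3L])
  an <- do.call(rbind, lapply(names(tabs), function(r) {
    a <- category_anova(tabs[[r]])
    cbind(recipe = r, a$table,
          direction_time = a$direction[["time"]],
          direction_valence = a$direction[["valence"]])
  }))
  write_table_csv(an, paths[4L])
  paths
}

run_ia_predictions <- function(config, out_dir) {
  nets <- list(model1 = apply_args(ia_network, config$params,
                                   list(variant = "model1")),
               model2 = apply_args(ia_network, config$params,
                                   list(variant = "model2")))
  preds <- lapply(nets, predict)
  paths <- file.path(out_dir, c("ia_predictions.csv", "ia_comparison.csv"))
  write_table_csv(do.call(rbind, lapply(names(preds), function(v)
    cbind(variant = v, as.data.frame(preds[[v]])))), paths[1L])
  comp <- data.frame(
    variant = names(preds),
    effect_past_negative = vapply(preds, function(p)
      p$effect_steps[p$category == "past/negative"], numeric(1)),
    effect_future_positive = vapply(preds, function(p)
      p$effect_steps[p$category == "future/positive"], numeric(1)))
  write_table_csv(comp, paths[2L])
  trace_dir <- file.path(out_dir, "traces")
  dir.create(trace_dir, showWarnings = FALSE)
  for (v in names(nets)) {
    for (stim in c("past", "future")) {
      for (cond in c("match", "mismatch")) {
        tr <- simulate(nets[[v]], stimulus = stim, condition = cond)
        write_trace(tr, file.path(trace_dir,
                                  sprintf("%s_%s_%s.csv", v, stim, cond)))
      }
    }
  }
  paths
}

table2_cells <- list(
  exp1 = list(match_factor = "between",
              rt = c(first_mismatch = 957, first_match = 786,
                     second_mismatch = 936, second_match = 776),
              pc = c(first_mismatch = 91.2, first_match = 95.8,
                     second_mismatch = 92.7, second_match = 96.0)),
  exp2 = list(match_factor = "within",
              rt = c(first_mismatch = 1014, first_match = 804,
                     second_mismatch = 972, second_match = 789),
              pc = c(first_mismatch = 87.8, first_match = 92.4,
                     second_mismatch = 88.2, second_match = 90.2)),
  exp3 = list(match_factor = "within",
              rt = c(first_mismatch = 934, first_match = 785,
                     second_mismatch = 930, second_match = 724),
              pc = c(first_mismatch = 80.5, first_match = 94.0,
                     second_mismatch = 89.0, second_match = 95.2)))

# A trial table whose half x match cell means and accuracies are fixed
# exactly at the requested values: every trial in a cell carries the cell's
# mean RT, and the number of correct trials per cell is pc * trials_per_cell
# (which must come out integer).
engineered_trials <- function(cells, match_factor, trials_per_cell = 1000L,
                              n_subjects = 20L) {
  stopifnot(trials_per_cell %% n_subjects == 0L ||
              match_factor == "between")
  grid <- expand.grid(half = c("first", "second"),
                      match = c("match", "mismatch"),
                      stringsAsFactors = FALSE)
  if (match_factor == "between") {
    subj <- list(match = sprintf("S%03d", seq_len(n_subjects / 2L)),
                 mismatch = sprintf("S%03d", n_subjects / 2L + seq_len(n_subjects / 2L)))
  } else {
    subj <- list(match = sprintf("S%03d", seq_len(n_subjects)),
                 mismatch = sprintf("S%03d", seq_len(n_subjects)))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    h <- grid$half[i]; m <- grid$match[i]
    key <- paste(h, m, sep = "_")
    n_correct <- round(cells$pc[[key]] / 100 * trials_per_cell)
    stopifnot(abs(n_correct - cells$pc[[key]] / 100 * trials_per_cell) < 1e-9)
    ids <- rep_len(subj[[m]], trials_per_cell)
    item <- rep_len(c("PAST01", "NEG01"), trials_per_cell)
    data.frame(subject_id = ids,
               item_id = item,
               domain = ifelse(item == "PAST01", "time", "valence"),
               category = ifelse(item == "PAST01", "past", "negative"),
               match = m,
               congruency = "not_applicable",
               block_index = if (h == "first") 1L else 2L,
               half = h,
               rt_ms = cells$rt[[key]],
               correct = seq_len(trials_per_cell) <= n_correct,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("chronoval_trials", "data.frame")
  out
}

#' Write small deterministic fixture inputs
#'
#' Generates the small input files used by the test suite and by worked
#' examples:
#' \describe{
#'   \item{`tiny_trials`}{an 8-subject manual-response trial table.}
#'   \item{`tiny_ratings`}{a 12 + 6 participant rating survey.}
#'   \item{`tiny_corpus`}{10 short documents with a strong built-in
#'     past-negative / future-positive association.}
#'   \item{`table2_cells`}{three engineered trial tables (one per RT
#'     experiment) whose half x match cell mean RTs and accuracies equal the
#'     experiments' reported first/second-half values, so the half-split
#'     analysis reproduces the reported match effects exactly.}
#' }
#'
#' @param kind fixture kind.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return character vector of file paths written.
#' @export
make_fixtures <- function(kind = c("tiny_trials", "tiny_ratings",
                                   "tiny_corpus", "table2_cells"),
                          seed, dir) {
  kind <- match.arg(kind)
  if (missing(seed)) stop_config("`seed` is mandatory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(kind,
    tiny_trials = {
      trials <- generate_rt_experiment(
        design_exp1(n_subjects = 8, items_per_category = 3),
        rt_gen_params(seed = seed))
      write_trials(trials, file.path(dir, "tiny_trials.csv"))
    },
    tiny_ratings = {
      r <- generate_ratings(rating_gen_params(n_young = 12, n_old = 6,
                                              n_items = 4, seed = seed))
      write_ratings(r, file.path(dir, "tiny_ratings.csv"))
    },
    tiny_corpus = {
      corp <- generate_corpus(corpus_spec(
        n_documents = 10, doc_length = 12,
        vocabulary = default_vocabulary(n_category = 3, n_filler = 6),
        association_strength = 0.8, direction = "both", seed = seed))
      write_corpus(corp, file.path(dir, "tiny_corpus.txt"))
    },
    table2_cells = {
      vapply(names(table2_cells), function(e) {
        cells <- table2_cells[[e]]
        write_trials(engineered_trials(cells, cells$match_factor),
                     file.path(dir, sprintf("table2_%s.csv", e)))
      }, character(1))
    })
}
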