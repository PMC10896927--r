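#' Specify a toy corpus with designed time-valence co-occurrence
#'
#' Describes a corpus of token documents over four labelled word lists (past,
#' future, negative, positive) plus filler tokens. The designed association
#' has two components, both governed by `association_strength`:
#' \itemize{
#'   \item \emph{Shared contexts}: with probability `association_strength` a
#'     document is themed around one of the covered category pairs
#'     (past-negative and/or future-positive, per `direction`); in a themed
#'     document the two theme categories are sampled at `theme_boost` times
#'     their baseline rate, so partner words occur in the same documents and
#'     the same local windows.
#'   \item \emph{Adjacency}: in any document, each drawn time word covered by
#'     `direction` is followed by a uniformly chosen word of its partner
#'     valence category with probability `association_strength`.
#' }
#' With `direction = "none"` neither mechanism operates: documents are plain
#' uniform draws and the four cross-category co-occurrence rates are
#' exchangeable.
#'
#' @param n_documents number of documents.
#' @param doc_length primary token draws per document (inserted associates
#'   come on top, so realised document length is between `doc_length` and
#'   `2 * doc_length`).
#' @param vocabulary named list with character elements `past`, `future`,
#'   `negative`, `positive`, `filler`; the lists must be disjoint. The default
#'   uses abstract tokens (`past01` ..., `fill01` ...).
#' @param association_strength probability in [0, 1] controlling both the
#'   theming rate of documents and the adjacency coupling of covered time
#'   words to their partner category.
#' @param direction which associations are built in:
#'   `"past-with-negative"`, `"future-with-positive"`, `"both"` or `"none"`.
#' @param theme_boost sampling-rate multiplier of the theme categories inside
#'   a themed document (>= 1).
#' @param seed integer RNG seed (mandatory).
#' @return an object of class `"corpus_spec"`.
#' @export
corpus_spec <- function(n_documents = 200, doc_length = 50,
                        vocabulary = default_vocabulary(),
                        association_strength = 0.5,
                        direction = c("both", "past-with-negative",
                                      "future-with-positive", "none"),
                        theme_boost = 4,
                        seed) {
  if (missing(seed)) stop_config("`seed` is mandatory")
  direction <- match.arg(direction)
  n_documents <- check_count(n_documents, "n_documents")
  doc_length <- check_count(doc_length, "doc_length")
  association_strength <- check_prob(association_strength, "association_strength")
  needed <- c("past", "future", "negative", "positive", "filler")
  if (!is.list(vocabulary) || !all(needed %in% names(vocabulary))) {
    stop_config("`vocabulary` must be a named list with elements ",
                paste(needed, collapse = ", "))
  }
  vocabulary <- lapply(vocabulary[needed], tolower)
  all_words <- unlist(vocabulary, use.names = FALSE)
  if (anyDuplicated(all_words)) {
    stop_config("vocabulary word lists must be disjoint")
  }
  if (any(lengths(vocabulary[c("past", "future", "negative", "positive")]) == 0L)) {
    stop_config("each category word list must be non-empty")
  }
  if (!is.numeric(theme_boost) || length(theme_boost) != 1L || theme_boost < 1) {
    stop_config("`theme_boost` must be a single number >= 1")
  }
  structure(list(n_documents = n_documents, doc_length = doc_length,
                 vocabulary = vocabulary,
                 association_strength = association_strength,
                 direction = direction, theme_boost = as.numeric(theme_boost),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' @rdname corpus_spec
#' @param n_category words per category list.
#' @param n_filler filler tokens.
#' @export
default_vocabulary <- function(n_category = 8, n_filler = 24) {
  list(past = sprintf("past%02d", seq_len(n_category)),
       future = sprintf("futr%02d", seq_len(n_category)),
       negative = sprintf("negv%02d", seq_len(n_category)),
       positive = sprintf("posv%02d", seq_len(n_category)),
       filler = sprintf("fill%02d", seq_len(n_filler)))
}

#' Generate a corpus with designed time-valence co-occurrence structure
#'
#' @param spec a [corpus_spec()].
#' @return a character vector of class `"chronoval_corpus"`, one document per
#'   element, tokens separated by single spaces.
#' @examples
#' corp <- generate_corpus(corpus_spec(n_documents = 5, doc_length = 10,
#'                                     association_strength = 1, seed = 1))
#' strsplit(corp[1], " ")[[1]]
#' @export
generate_corpus <- function(spec) {
  if (!inherits(spec, "corpus_spec")) stop_config("`spec` must be a corpus_spec")
  v <- spec$vocabulary
  all_words <- unlist(v, use.names = FALSE)
  couple_past <- spec$direction %in% c("both", "past-with-negative")
  couple_future <- spec$direction %in% c("both", "future-with-positive")
  themes <- c(if (couple_past) "past_negative", if (couple_future) "future_positive")
  theme_weights <- function(theme) {
    w <- rep(1, length(all_words))
    boosted <- if (theme == "past_negative") c(v$past, v$negative) else
      c(v$future, v$positive)
    w[all_words %in% boosted] <- spec$theme_boost
    w / sum(w)
  }
  with_seed(spec$seed, {
    docs <- vapply(seq_len(spec$n_documents), function(d) {
      themed <- length(themes) > 0L &&
        stats::runif(1) < spec$association_strength
      if (themed) {
        theme <- if (length(themes) == 1L) themes else sample(themes, 1L)
        primary <- sample(all_words, spec$doc_length, replace = TRUE,
                          prob = theme_weights(theme))
      } else {
        primary <- sample(all_words, spec$doc_length, replace = TRUE)
      }
      insert <- rep(NA_character_, spec$doc_length)
      trigger <- stats::runif(spec$doc_length) < spec$association_strength
      is_past <- primary %in% v$past
      is_future <- primary %in% v$future
      sel <- which(is_past & trigger & couple_past)
      if (length(sel)) {
        insert[sel] <- sample(v$negative, length(sel), replace = TRUE)
      }
      sel <- which(is_future & trigger & couple_future)
      if (length(sel)) {
        insert[sel] <- sample(v$positive, length(sel), replace = TRUE)
      }
      tokens <- as.vector(rbind(primary, insert))
      paste(tokens[!is.na(tokens)], collapse = " ")
    }, character(1))
    structure(docs, class = "chronoval_corpus")
  })
}

#' Read or write a corpus
#'
#' UTF-8 text, one document per line, space-separated tokens.
#'
#' @param corpus a `"chronoval_corpus"` (or plain character vector).
#' @param path file path.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(unclass(corpus), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  docs <- readLines(path, encoding = "UTF-8")
  if (length(docs) == 0L) stop_data("corpus file is empty")
  structure(tolower(docs), class = "chronoval_corpus")
}

corpus_tokens <- function(corpus) {
  strsplit(tolower(unclass(corpus)), "[[:space:]]+")
}

#' Count time-valence word pairs within a window
#'
#' Tabulates, for every occurrence of a time word, the valence words within
#' `window` positions (either side, within the same document), as a 2 x 2
#' table of time category by valence category. Used to check the designed
#' association of a generated corpus.
#'
#' @param corpus a corpus.
#' @param vocabulary the named word lists the corpus was built over.
#' @param window co-occurrence window in token positions.
#' @return a 2 x 2 integer matrix (rows past/future, columns
#'   negative/positive).
#' @export
pair_count_table <- function(corpus, vocabulary, window = 1L) {
  window <- check_count(window, "window")
  counts <- matrix(0L, 2, 2,
                   dimnames = list(c("past", "future"), c("negative", "positive")))
  time_cat <- c(stats::setNames(rep("past", length(vocabulary$past)), vocabulary$past),
                stats::setNames(rep("future", length(vocabulary$future)), vocabulary$future))
  val_cat <- c(stats::setNames(rep("negative", length(vocabulary$negative)), vocabulary$negative),
               stats::setNames(rep("positive", length(vocabulary$positive)), vocabulary$positive))
  for (tok in corpus_tokens(corpus)) {
    n <- length(tok)
    t_idx <- which(tok %in% names(time_cat))
    for (i in t_idx) {
      lo <- max(1L, i - window); hi <- min(n, i + window)
      ctx <- tok[setdiff(lo:hi, i)]
      ctx <- ctx[ctx %in% names(val_cat)]
      for (w in ctx) {
        counts[time_cat[[tok[i]]], val_cat[[w]]] <-
          counts[time_cat[[tok[i]]], val_cat[[w]]] + 1L
      }
    }
  }
  counts
}
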