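#' Word-by-document count matrix
#'
#' @param corpus a corpus (character vector, one document per element).
#' @return integer matrix, words in rows (sorted vocabulary), documents in
#'   columns.
#' @export
term_document_matrix <- function(corpus) {
  toks <- corpus_tokens(corpus)
  if (sum(lengths(toks)) == 0L) stop_data("corpus contains no tokens")
  vocab <- sort(unique(unlist(toks)))
  m <- vapply(toks, function(tok)
    tabulate(match(tok, vocab), nbins = length(vocab)), integer(length(vocab)))
  m <- matrix(m, nrow = length(vocab),
              dimnames = list(vocab, sprintf("doc%d", seq_along(toks))))
  m
}

#' Build an LSA distributional space
#'
#' Constructs the word-by-document count matrix, optionally applies
#' log-entropy weighting, and reduces it by truncated singular value
#' decomposition. Word vectors are the left singular vectors scaled by the
#' singular values, so that in the full-rank case pairwise cosines equal
#' those of the raw (weighted) count rows.
#'
#' @param corpus a corpus.
#' @param n_dimensions retained dimensions; must be positive and not exceed
#'   the rank of the count matrix.
#' @param weighting `FALSE` (raw counts, default) or `TRUE` for log-entropy:
#'   `log(1 + count)` scaled per word by one minus its normalised
#'   distribution entropy over documents.
#' @return an object of class `"dsm_space"`: list with `vocabulary`,
#'   `vectors` (word x dimension matrix), `recipe = "lsa"`, `params`, and
#'   `singular_values`.
#' @export
build_lsa <- function(corpus, n_dimensions = 300, weighting = FALSE) {
  m <- term_document_matrix(corpus)
  if (!is.numeric(n_dimensions) || length(n_dimensions) != 1L ||
      n_dimensions <= 0 || n_dimensions != floor(n_dimensions)) {
    stop_config("`n_dimensions` must be a positive integer")
  }
  if (n_dimensions > min(dim(m))) {
    stop_config("`n_dimensions` exceeds min(vocabulary size, number of documents)")
  }
  x <- m
  if (isTRUE(weighting)) {
    p <- m / pmax(rowSums(m), 1)
    ent <- -rowSums(ifelse(p > 0, p * log(p), 0)) / log(max(ncol(m), 2))
    x <- (1 - ent) * log1p(m)
  }
  s <- svd(x)
  tol <- max(dim(x)) * max(s$d) * .Machine$double.eps
  rank <- sum(s$d > tol)
  if (n_dimensions > rank) {
    stop_config("`n_dimensions` (", n_dimensions, ") exceeds matrix rank (", rank, ")")
  }
  k <- seq_len(n_dimensions)
  vectors <- s$u[, k, drop = FALSE] %*% diag(s$d[k], nrow = length(k))
  rownames(vectors) <- rownames(m)
  structure(list(vocabulary = rownames(m), vectors = vectors, recipe = "lsa",
                 params = list(n_dimensions = n_dimensions, weighting = weighting),
                 singular_values = s$d),
            class = "dsm_space")
}

#' Build a HAL distributional space
#'
#' For each target word, counts the occurrences of every context word within
#' `window` token positions, summed over the left and right contexts within
#' each document. Contexts are unweighted by default; `distance_weighting`
#' applies the linear ramp `window - distance + 1`.
#'
#' @param corpus a corpus.
#' @param window window size in token positions (>= 1).
#' @param distance_weighting logical.
#' @return an object of class `"dsm_space"` with a word x word count matrix
#'   as `vectors`.
#' @export
build_hal <- function(corpus, window = 5, distance_weighting = FALSE) {
  window <- check_count(window, "window")
  toks <- corpus_tokens(corpus)
  if (sum(lengths(toks)) == 0L) stop_data("corpus contains no tokens")
  vocab <- sort(unique(unlist(toks)))
  V <- length(vocab)
  acc <- numeric(V * V)
  for (tok in toks) {
    idx <- match(tok, vocab)
    n <- length(idx)
    if (n < 2L) next
    for (d in seq_len(min(window, n - 1L))) {
      a <- idx[seq_len(n - d)]
      b <- idx[seq_len(n - d) + d]
      w <- if (distance_weighting) window - d + 1 else 1
      # symmetric: b is in a's right context, a in b's left context
      cells <- c((b - 1L) * V + a, (a - 1L) * V + b)
      t1 <- tabulate(cells, nbins = V * V)
      acc <- acc + w * t1
    }
  }
  vectors <- matrix(acc, V, V, dimnames = list(vocab, vocab))
  structure(list(vocabulary = vocab, vectors = vectors, recipe = "hal",
                 params = list(window = window,
                               distance_weighting = distance_weighting)),
            class = "dsm_space")
}

#' @export
print.dsm_space <- function(x, ...) {
  cat(sprintf("%s space: %d words x %d dimensions\n", toupper(x$recipe),
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' Dot product over the product of Euclidean norms. A zero vector has no
#' direction, so its similarity is undefined and raises an error rather than
#' silently returning 0.
#'
#' @param v1,v2 numeric vectors of equal length.
#' @return cosine similarity in [-1, 1].
#' @examples
#' cosine_sim(c(1, 1), c(1, 0))  # sqrt(2)/2
#' @export
cosine_sim <- function(v1, v2) {
  if (length(v1) != length(v2)) stop_config("vectors must have equal length")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    stop_data("cosine similarity is undefined for a zero vector")
  }
  sum(v1 * v2) / (n1 * n2)
}

#' Cosine table for all time-word x valence-word pairs
#'
#' @param space a `"dsm_space"`.
#' @param vocabulary named list with `past`, `future`, `negative`, `positive`
#'   word lists; words absent from the space are dropped with a warning.
#' @return a data frame of class `"cosine_table"` with columns `time_word`,
#'   `valence_word`, `time_category`, `valence_category`, `cosine`, one row
#'   per cross-domain pair.
#' @export
cosine_table <- function(space, vocabulary) {
  pick <- function(words, what) {
    words <- tolower(words)
    miss <- setdiff(words, space$vocabulary)
    if (length(miss)) {
      warning(sprintf("%d %s word(s) absent from the space, dropped", length(miss), what))
    }
    intersect(words, space$vocabulary)
  }
  tw <- list(past = pick(vocabulary$past, "past"),
             future = pick(vocabulary$future, "future"))
  vw <- list(negative = pick(vocabulary$negative, "negative"),
             positive = pick(vocabulary$positive, "positive"))
  if (any(lengths(tw) == 0L) || any(lengths(vw) == 0L)) {
    stop_data("every category needs at least one word present in the space")
  }
  grid <- expand.grid(time_word = unlist(tw, use.names = FALSE),
                      valence_word = unlist(vw, use.names = FALSE),
                      stringsAsFactors = FALSE)
  grid$time_category <- ifelse(grid$time_word %in% tw$past, "past", "future")
  grid$valence_category <- ifelse(grid$valence_word %in% vw$negative,
                                  "negative", "positive")
  grid$cosine <- vapply(seq_len(nrow(grid)), function(i)
    cosine_sim(space$vectors[grid$time_word[i], ],
               space$vectors[grid$valence_word[i], ]), numeric(1))
  structure(grid, recipe = space$recipe,
            class = c("cosine_table", "data.frame"))
}

#' Two-way ANOVA on time-valence cosine similarities
#'
#' Crossed fixed-effects ANOVA of pair-level cosines on time category
#' (past/future) and valence category (negative/positive), reporting F,
#' degrees of freedom and p per effect together with the direction of each
#' main effect.
#'
#' @param table a [cosine_table()].
#' @return an object of class `"dsm_anova"`: `table` (effects x F/df/p),
#'   `cell_means` (2 x 2), `direction` (which level of each factor has the
#'   higher mean cosine).
#' @export
category_anova <- function(table) {
  cells <- table(factor(table$time_category, c("past", "future")),
                 factor(table$valence_category, c("negative", "positive")))
  if (any(cells == 0L)) {
    stop_data("empty design cell(s): all four category combinations are required")
  }
  dat <- data.frame(cosine = table$cosine,
                    time = factor(table$time_category, c("past", "future")),
                    valence = factor(table$valence_category,
                                     c("negative", "positive")))
  df2 <- nrow(dat) - 4L
  if (stats::var(dat$cosine) == 0) {  # constant response: no effect, by definition
    tab <- data.frame(effect = c("time", "valence", "time_valence"),
                      F = 0, df1 = 1L, df2 = df2, p = 1,
                      stringsAsFactors = FALSE)
  } else {
    if (df2 < 1L) stop_data("no residual degrees of freedom for the 2 x 2 ANOVA")
    fit <- stats::aov(cosine ~ time * valence, data = dat)
    an <- summary(fit)[[1L]]
    tab <- data.frame(effect = c("time", "valence", "time_valence"),
                      F = an[1:3, "F value"], df1 = an[1:3, "Df"],
                      df2 = an["Residuals", "Df"], p = an[1:3, "Pr(>F)"],
                      stringsAsFactors = FALSE)
  }
  cm <- tapply(dat$cosine, list(dat$time, dat$valence), mean)
  structure(list(
    table = tab, cell_means = cm,
    direction = c(
      time = if (mean(cm["past", ]) >= mean(cm["future", ])) "past" else "future",
      valence = if (mean(cm[, "negative"]) >= mean(cm[, "positive"]))
        "negative" else "positive"),
    recipe = attr(table, "recipe")),
    class = "dsm_anova")
}

#' @export
print.dsm_anova <- function(x, ...) {
  cat(sprintf("Cosine-similarity 2 x 2 ANOVA (%s space):\n",
              toupper(x$recipe %||% "?")))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-12s F(%d, %d) = %.2f, p = %.3g\n",
                tab$effect[i], tab$df1[i], tab$df2[i], tab$F[i], tab$p[i]))
  }
  cat(sprintf("  higher mean cosine: time -> %s, valence -> %s\n",
              x$direction[["time"]], x$direction[["valence"]]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a distributional space or cosine table as CSV
#'
#' @param space a `"dsm_space"`.
#' @param path file path.
#' @export
write_space <- function(space, path) {
  out <- data.frame(word = rownames(space$vectors), space$vectors,
                    check.names = FALSE)
  names(out)[-1L] <- sprintf("dim_%d", seq_len(ncol(space$vectors)))
  write_table_csv(out, path)
}
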