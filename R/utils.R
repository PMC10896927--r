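#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so that a seeded call is
# reproducible regardless of surrounding code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) {
  stop(structure(class = c("chronoval_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("chronoval_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_config("`", name, "` must be a single integer >= ", min)
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_config("`", name, "` must be a probability in [0, 1]")
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_config("`", name, "` must be a single non-negative number")
  }
  as.numeric(x)
}

match_enum <- function(x, choices, name) {
  if (!is.character(x) || length(x) != 1L || !x %in% choices) {
    stop_config("`", name, "` must be one of: ", paste(choices, collapse = ", "))
  }
  x
}

write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
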