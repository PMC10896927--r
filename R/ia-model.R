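#' Interactive-activation network of the time-valence match effect
#'
#' Builds the four-node interactive-activation network in which nodes
#' represent past time (1), future time (2), negative valence (3) and
#' positive valence (4). Within each domain the two nodes inhibit each other
#' (past-future, negative-positive); across domains the agonist pairs excite
#' each other. Under `variant = "model1"` both agonist pairs (past-negative
#' and future-positive) carry excitatory links of weight `gamma`; under
#' `variant = "model2"` the past-negative links are removed and only
#' future-positive excitation remains. A stimulus injects constant input into
#' its node; the supra-rest outputs of all four nodes drive two response
#' accumulators whose wiring depends on the match condition (see
#' [accumulate_response()]).
#'
#' Node activations follow a discrete Euler update with bounded growth:
#' for net input `n_i = sum_j w[i,j] O_j + I_i` with output
#' `O_j = max(a_j - rest, 0)`, the step is
#' `da_i = step * (n_i (max - a_i) - decay (a_i - rest))` when `n_i >= 0` and
#' `da_i = step * (n_i (a_i - min) - decay (a_i - rest))` otherwise,
#' with activations clipped to `[min, max]`.
#'
#' @param variant `"model1"` (symmetric agonist links) or `"model2"`
#'   (future-positive excitation only).
#' @param gamma excitatory cross-domain weight (> 0).
#' @param beta magnitude of the within-domain inhibitory weight (> 0).
#' @param input stimulus input strength injected into the stimulated node.
#' @param rest,min,max resting, floor and ceiling activation.
#' @param decay per-step decay rate towards rest, in [0, 1].
#' @param step Euler step size.
#' @param gain scaling of output-to-response accumulation.
#' @param threshold response activation at which a response is emitted
#'   (must exceed `rest`).
#' @param max_steps maximum number of simulation steps.
#' @param weights optional 4 x 4 weight matrix overriding the one implied by
#'   `gamma`/`beta`; it must satisfy the variant's sign pattern.
#' @return an object of class `"ia_network"`.
#' @examples
#' net <- ia_network("model1")
#' net
#' predict(net)
#' @export
ia_network <- function(variant = c("model1", "model2"),
                       gamma = 0.10, beta = 0.10, input = 0.40,
                       rest = 0, min = -0.2, max = 1.0, decay = 0.10,
                       step = 0.1, gain = 1.0, threshold = 0.5,
                       max_steps = 2000, weights = NULL) {
  variant <- match.arg(variant)
  for (nm in c("gamma", "beta", "input", "rest", "min", "max", "decay",
               "step", "gain", "threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_config("`", nm, "` must be a single finite number")
    }
  }
  if (!(min <= rest && rest <= max)) stop_config("need min <= rest <= max")
  if (decay < 0 || decay > 1) stop_config("`decay` must lie in [0, 1]")
  if (threshold <= rest) stop_config("`threshold` must exceed `rest`")
  if (step <= 0) stop_config("`step` must be positive")
  max_steps <- check_count(max_steps, "max_steps")
  if (is.null(weights)) {
    g13 <- if (variant == "model1") gamma else 0
    weights <- matrix(0, 4, 4)
    weights[1, 2] <- weights[2, 1] <- -beta
    weights[3, 4] <- weights[4, 3] <- -beta
    weights[1, 3] <- weights[3, 1] <- g13
    weights[2, 4] <- weights[4, 2] <- gamma
  } else {
    if (!is.matrix(weights) || !all(dim(weights) == c(4, 4)) ||
        !all(is.finite(weights))) {
      stop_config("`weights` must be a finite 4 x 4 matrix")
    }
  }
  check_sign_pattern(weights, variant)
  nodes <- c("past", "future", "negative", "positive")
  dimnames(weights) <- list(nodes, nodes)
  structure(list(variant = variant, weights = weights, gamma = gamma,
                 beta = beta, input = input, rest = rest, min = min,
                 max = max, decay = decay, step = step, gain = gain,
                 threshold = threshold, max_steps = max_steps),
            class = "ia_network")
}

check_sign_pattern <- function(w, variant) {
  inhib <- rbind(c(1, 2), c(2, 1), c(3, 4), c(4, 3))
  if (any(w[inhib] >= 0)) {
    stop_config("within-domain weights (past-future, negative-positive) must be negative")
  }
  fp <- rbind(c(2, 4), c(4, 2))
  if (any(w[fp] <= 0)) {
    stop_config("future-positive weights must be positive")
  }
  pn <- rbind(c(1, 3), c(3, 1))
  if (variant == "model1") {
    if (any(w[pn] <= 0)) stop_config("model1 requires positive past-negative weights")
  } else {
    if (any(w[pn] != 0)) stop_config("model2 requires zero past-negative weights")
  }
  invisible(TRUE)
}

#' @export
print.ia_network <- function(x, ...) {
  cat("Interactive-activation network (", x$variant, ")\n", sep = "")
  cat("  nodes: 1 past, 2 future, 3 negative, 4 positive\n")
  cat("  weights:\n")
  print(round(x$weights, 3))
  cat(sprintf("  input %.2f, rest %.2f, range [%.2f, %.2f], decay %.2f\n",
              x$input, x$rest, x$min, x$max, x$decay))
  cat(sprintf("  step %.3f, gain %.2f, threshold %.2f, max_steps %d\n",
              x$step, x$gain, x$threshold, x$max_steps))
  invisible(x)
}

#' @export
coef.ia_network <- function(object, ...) {
  c(gamma = object$gamma, beta = object$beta, input = object$input,
    rest = object$rest, min = object$min, max = object$max,
    decay = object$decay, step = object$step, gain = object$gain,
    threshold = object$threshold)
}

response_wiring <- function(condition) {
  # match: A <- O1 + O3, B <- O2 + O4; mismatch: A <- O1 + O4, B <- O2 + O3
  switch(condition,
         match = list(A = c(1L, 3L), B = c(2L, 4L)),
         mismatch = list(A = c(1L, 4L), B = c(2L, 3L)),
         stop_config("`condition` must be 'match' or 'mismatch'"))
}

ia_run <- function(net, stimulus, condition, max_steps = net$max_steps) {
  nodes <- c("past", "future", "negative", "positive")
  stim_idx <- match(stimulus, nodes)
  if (is.na(stim_idx)) {
    stop_config("`stimulus` must be one of: ", paste(nodes, collapse = ", "))
  }
  wiring <- response_wiring(condition)
  I <- numeric(4); I[stim_idx] <- net$input
  a <- rep(net$rest, 4)
  O_prev <- numeric(4)
  respA <- 0; respB <- 0
  out <- matrix(NA_real_, max_steps, 11L)
  crossing <- NA_integer_
  for (t in seq_len(max_steps)) {
    net_in <- drop(net$weights %*% O_prev) + I
    da <- ifelse(net_in >= 0,
                 net$step * (net_in * (net$max - a) - net$decay * (a - net$rest)),
                 net$step * (net_in * (a - net$min) - net$decay * (a - net$rest)))
    a <- pmin(pmax(a + da, net$min), net$max)
    if (any(!is.finite(a))) {
      stop_data("non-finite activation at step ", t)
    }
    respA <- respA + net$step * net$gain * sum(O_prev[wiring$A])
    respB <- respB + net$step * net$gain * sum(O_prev[wiring$B])
    O <- pmax(a - net$rest, 0)
    out[t, ] <- c(t, a, O, respA, respB)
    if (is.na(crossing) && (respA >= net$threshold || respB >= net$threshold)) {
      crossing <- t
      out <- out[seq_len(t), , drop = FALSE]
      break
    }
    O_prev <- O
  }
  trace <- as.data.frame(out)
  names(trace) <- c("step", paste0("a", 1:4), paste0("O", 1:4), "respA", "respB")
  structure(trace,
            stimulus = stimulus, condition = condition,
            crossing_step = crossing,
            crossing_time = crossing_time(trace, crossing, net$threshold, net$step),
            crossing_response = if (is.na(crossing)) NA_character_ else
              if (trace$respA[nrow(trace)] >= trace$respB[nrow(trace)]) "A" else "B",
            step_size = net$step,
            class = c("ia_trace", "data.frame"))
}

# Continuous threshold-crossing time: the discrete crossing step minus the
# linearly interpolated fraction of the last step that overshot the
# threshold, in model time units (steps * step). Removes the one-step
# quantisation of the discrete crossing so that crossing times converge
# smoothly under step-size refinement.
crossing_time <- function(trace, crossing, threshold, step) {
  if (is.na(crossing)) return(NA_real_)
  winner <- if (trace$respA[crossing] >= trace$respB[crossing]) "respA" else "respB"
  r1 <- trace[[winner]][crossing]
  r0 <- if (crossing > 1L) trace[[winner]][crossing - 1L] else 0
  frac <- if (r1 > r0) (r1 - threshold) / (r1 - r0) else 0
  step * (crossing - frac)
}

#' Simulate activation and response trajectories
#'
#' Runs the network's deterministic dynamics for one stimulus category under
#' one match condition and returns the full trace of node activations, node
#' outputs and response accumulators, stopping early once a response
#' accumulator reaches the threshold. The model is deterministic, so `nsim`
#' and `seed` are accepted for compatibility with the [stats::simulate()]
#' generic but ignored.
#'
#' @param object an [ia_network()].
#' @param nsim,seed ignored (deterministic model).
#' @param stimulus stimulated category: `"past"`, `"future"`, `"negative"` or
#'   `"positive"`.
#' @param condition `"match"` or `"mismatch"` response wiring.
#' @param ... unused.
#' @return a data frame of class `"ia_trace"` with columns `step`,
#'   `a1`..`a4`, `O1`..`O4`, `respA`, `respB`, and attributes
#'   `crossing_step` (NA when no response reached threshold within
#'   `max_steps`) and `crossing_response`.
#' @examples
#' tr <- simulate(ia_network("model1"), stimulus = "past", condition = "match")
#' attr(tr, "crossing_step")
#' @export
simulate.ia_network <- function(object, nsim = 1, seed = NULL,
                                stimulus = "past", condition = "match", ...) {
  ia_run(object, stimulus, condition)
}

#' Re-derive response accumulators from a node-output trace
#'
#' Applies the match or mismatch response wiring to the recorded node outputs
#' of a trace: `resp(t+1) = resp(t) + step * gain * (sum of wired outputs at
#' t)`, starting from 0 with all outputs 0 before the first step. Useful to
#' re-score a simulated trace under the other wiring.
#'
#' @param trace an `"ia_trace"`.
#' @param condition `"match"` or `"mismatch"`.
#' @param gain,threshold accumulator gain and response threshold.
#' @return the trace with replaced `respA`/`respB` columns and updated
#'   `crossing_step`/`crossing_response` attributes.
#' @export
accumulate_response <- function(trace, condition, gain = 1.0, threshold = 0.5) {
  if (!inherits(trace, "ia_trace")) stop_config("`trace` must be an ia_trace")
  wiring <- response_wiring(condition)
  step <- attr(trace, "step_size")
  O <- as.matrix(trace[paste0("O", 1:4)])
  lagged <- function(idx) {
    drive <- rowSums(O[, idx, drop = FALSE])
    step * gain * cumsum(c(0, drive[-length(drive)]))
  }
  trace$respA <- lagged(wiring$A)
  trace$respB <- lagged(wiring$B)
  crossed <- which(trace$respA >= threshold | trace$respB >= threshold)
  crossing <- if (length(crossed)) crossed[1L] else NA_integer_
  attr(trace, "condition") <- condition
  attr(trace, "crossing_step") <- crossing
  attr(trace, "crossing_response") <-
    if (is.na(crossing)) NA_character_ else
      if (trace$respA[crossing] >= trace$respB[crossing]) "A" else "B"
  trace
}

#' Predict the match effect from the network
#'
#' Simulates each response category (past/negative and future/positive,
#' stimulated via their time-word representative) under both match
#' conditions, reports the threshold-crossing times and the per-category
#' match effects (mismatch minus match). Crossing times are reported in
#' simulation steps (`*_steps`, discrete) and in model time (`*_time`,
#' linearly interpolated at the threshold so refinement of the step size
#' converges smoothly); [steps_to_ms()] maps them onto a display millisecond
#' scale.
#'
#' @param object an [ia_network()].
#' @param ... unused.
#' @return an object of class `"ia_match_prediction"`: a data frame with one
#'   row per response category and columns `match_steps`, `mismatch_steps`,
#'   `match_time`, `mismatch_time`, `effect_steps`, `effect_time`,
#'   `terminated`.
#' @examples
#' predict(ia_network("model2"))
#' @export
predict.ia_network <- function(object, ...) {
  cats <- c("past/negative" = "past", "future/positive" = "future")
  rows <- lapply(names(cats), function(lab) {
    runs <- lapply(c(match = "match", mismatch = "mismatch"), function(cond)
      ia_run(object, cats[[lab]], cond))
    steps <- vapply(runs, function(r) as.numeric(attr(r, "crossing_step")), numeric(1))
    times <- vapply(runs, function(r) as.numeric(attr(r, "crossing_time")), numeric(1))
    data.frame(category = lab,
               match_steps = steps[["match"]],
               mismatch_steps = steps[["mismatch"]],
               match_time = times[["match"]],
               mismatch_time = times[["mismatch"]],
               effect_steps = steps[["mismatch"]] - steps[["match"]],
               effect_time = times[["mismatch"]] - times[["match"]],
               terminated = all(is.finite(steps)),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), variant = object$variant,
            class = c("ia_match_prediction", "data.frame"))
}

#' @export
print.ia_match_prediction <- function(x, ...) {
  cat("Predicted match effects (", attr(x, "variant"),
      "), crossing times in steps:\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Map simulation steps onto a display millisecond scale
#'
#' Affine mapping `ms = intercept + ms_per_step * steps`, provided for
#' display only: the model predicts ordinal structure and differences of
#' crossing times, not absolute RTs.
#'
#' @param steps crossing times in simulation steps.
#' @param intercept ms at 0 steps (residual sensory/motor time).
#' @param ms_per_step ms per simulation step.
#' @export
steps_to_ms <- function(steps, intercept = 300, ms_per_step = 5) {
  intercept + ms_per_step * steps
}

#' Plot response-activation trajectories
#'
#' One panel per response category (past/negative, future/positive), showing
#' the winning response accumulator under the match and mismatch wiring, with
#' the response threshold as a horizontal line.
#'
#' @param x an [ia_network()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ia_network <- function(x, ...) {
  cats <- c("past/negative" = "past", "future/positive" = "future")
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (lab in names(cats)) {
    tr_m <- ia_run(x, cats[[lab]], "match")
    tr_mm <- ia_run(x, cats[[lab]], "mismatch")
    n <- max(nrow(tr_m), nrow(tr_mm))
    y <- cbind(c(pmax(tr_m$respA, tr_m$respB), rep(NA, n - nrow(tr_m))),
               c(pmax(tr_mm$respA, tr_mm$respB), rep(NA, n - nrow(tr_mm))))
    graphics::matplot(seq_len(n), y, type = "l", lty = c(1, 2), col = c(1, 2),
                      xlab = "step", ylab = "response activation",
                      main = paste0(lab, " (", x$variant, ")"), ...)
    graphics::abline(h = x$threshold, col = "grey")
    graphics::legend("bottomright", legend = c("match", "mismatch"),
                     lty = c(1, 2), col = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Export a trace as CSV
#'
#' @param trace an `"ia_trace"`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) write_table_csv(as.data.frame(trace), path)
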