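#' Posterior probability (positive predictive value) by Bayes' theorem
#'
#' Computes `P(H | E)` for a binary hypothesis H (e.g. fire, disease) and
#' binary evidence E (alarm, positive test):
#'
#' \deqn{P(H|E) = \frac{P(E|H)\,P(H)}{P(E|H)\,P(H) + P(E|\neg H)\,(1 - P(H))}}
#'
#' In diagnostic terms this is the positive predictive value computed from
#' the base rate, the sensitivity (true-positive rate) and the false-alarm
#' (false-positive) rate.
#'
#' @param base_rate Prior probability `P(H)` in `[0, 1]`.
#' @param tpr True-positive rate `P(E | H)`.
#' @param far False-alarm rate `P(E | not H)`.
#' @return The posterior probability, in `[0, 1]`.
#' @export
#' @examples
#' posterior(0.01, 0.80, 0.096)  # the classic mammography task, ~0.078
#' posterior(0.1, 0.5, 0.27)     # fire-and-alarm with cohort medians, ~0.17
posterior <- function(base_rate, tpr, far) {
  check_probability(base_rate, "base_rate")
  check_probability(tpr, "tpr")
  check_probability(far, "far")
  denom <- tpr * base_rate + far * (1 - base_rate)
  if (denom <= 0) {
    stop("degenerate task: no positive-evidence mass ",
         "(tpr*base_rate + far*(1-base_rate) == 0)", call. = FALSE)
  }
  tpr * base_rate / denom
}

#' Sequential posterior after repeated binary draws
#'
#' Conjugate Bayesian updating of a prior over two hypotheses from a
#' sequence of binary outcomes drawn i.i.d. with replacement -- the
#' bookbag-and-poker-chips paradigm. A "success" is an outcome of the type
#' that hypothesis H makes more likely (a red chip from the predominantly
#' red bag).
#'
#' Because draws are exchangeable, the posterior depends only on the counts
#' of successes and failures, not on their order.
#'
#' @param prior Prior probability of H, in `(0, 1)`.
#' @param p_success_H Probability of a success under H, in `(0, 1)`.
#' @param p_success_notH Probability of a success under not-H, in `(0, 1)`.
#' @param draws Logical or 0/1 vector of outcomes (`TRUE`/1 = success).
#'   May be empty, in which case the prior is returned.
#' @return Posterior probability of H.
#' @export
#' @examples
#' # two bags of chips, 70/30 vs 30/70; six red and four blue observed
#' sequential_posterior(0.5, 0.7, 0.3, rep(c(TRUE, FALSE), c(6, 4)))
sequential_posterior <- function(prior, p_success_H, p_success_notH, draws) {
  check_probability(prior, "prior")
  check_probability(p_success_H, "p_success_H")
  check_probability(p_success_notH, "p_success_notH")
  if (prior %in% c(0, 1) || p_success_H %in% c(0, 1) ||
      p_success_notH %in% c(0, 1)) {
    stop("prior and likelihood parameters must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (length(draws) == 0L) return(prior)
  draws <- as.logical(draws)
  if (anyNA(draws)) stop("`draws` must be a binary vector", call. = FALSE)
  k <- sum(draws)
  n <- length(draws)
  # work in log odds for numerical stability at long sequences
  log_odds <- log(prior) - log1p(-prior) +
    k * (log(p_success_H) - log(p_success_notH)) +
    (n - k) * (log1p(-p_success_H) - log1p(-p_success_notH))
  stats::plogis(log_odds)
}

# ---- problem trees ---------------------------------------------------------

new_problem_tree <- function(base_rate, tpr, far, format, population, nodes) {
  structure(
    list(base_rate = base_rate, tpr = tpr, far = far,
         format = format, population = population, nodes = nodes),
    class = "problem_tree"
  )
}

#' @export
print.problem_tree <- function(x, ...) {
  unit <- if (x$format == "frequency") "events" else "%"
  cat(sprintf("<problem_tree> %s format, population %s\n",
              x$format, format(x$population)))
  cat(sprintf("  triple: base %.4g, tpr %.4g, far %.4g (true PPV %.4g)\n",
              x$base_rate, x$tpr, x$far, true_posterior(x)))
  cat("  nodes (", unit, "): ", sep = "")
  cat(paste(names(x$nodes), x$nodes, sep = "="), sep = ", ")
  cat("\n")
  invisible(x)
}

#' Build a natural-frequency task tree
#'
#' Scales a (base rate, true-positive rate, false-alarm rate) triple to a
#' two-level tree of integer event counts over a fixed total population, as
#' a natural-sampling presentation does: each node holds the events left
#' over from the preceding splits. A reported base rate of 1/5 over a
#' population of 1000 gives 200 events with the hypothesis; a
#' true-positive rate of 9/10 then gives 180 hypothesis-and-evidence events
#' out of those 200.
#'
#' At each split the first child is rounded half-up to the nearest integer
#' and the complement receives the residual, so children always sum exactly
#' to their parent.
#'
#' @inheritParams posterior
#' @param population Total number of events at the root (default 1000).
#' @return A `problem_tree` with integer node counts
#'   `T, F, nF, FA, FnA, nFA, nFnA`.
#' @export
#' @examples
#' build_frequency_tree(1 / 5, 9 / 10, 0.1)
build_frequency_tree <- function(base_rate, tpr, far, population = 1000L) {
  check_probability(base_rate, "base_rate")
  check_probability(tpr, "tpr")
  check_probability(far, "far")
  population <- check_count(population, "population", min = 1L)
  f    <- round_half_up(base_rate * population)
  nf   <- population - f
  fa   <- round_half_up(tpr * f)
  fna  <- f - fa
  nfa  <- round_half_up(far * nf)
  nfna <- nf - nfa
  nodes <- c(T = population, F = f, nF = nf,
             FA = fa, FnA = fna, nFA = nfa, nFnA = nfna)
  new_problem_tree(base_rate, tpr, far, "frequency", population, nodes)
}

#' Build a percentage task tree
#'
#' The percentage presentation renormalises at every branch: each node
#' displays a percentage of its parent, so the two branch values at every
#' split sum to 100.
#'
#' @inheritParams posterior
#' @return A `problem_tree` with percentage node values (population 100).
#' @export
build_probability_tree <- function(base_rate, tpr, far) {
  check_probability(base_rate, "base_rate")
  check_probability(tpr, "tpr")
  check_probability(far, "far")
  nodes <- c(T = 100, F = 100 * base_rate, nF = 100 * (1 - base_rate),
             FA = 100 * tpr, FnA = 100 * (1 - tpr),
             nFA = 100 * far, nFnA = 100 * (1 - far))
  new_problem_tree(base_rate, tpr, far, "probability", 100, nodes)
}

#' True posterior of a task tree
#'
#' @param tree A `problem_tree`.
#' @param from_nodes For a frequency tree, compute from the displayed
#'   integer node counts `FA / (FA + nFA)` (what a participant reading the
#'   graph could compute) rather than from the underlying triple.
#' @return Probability `P(H | E)` for the task.
#' @export
true_posterior <- function(tree, from_nodes = FALSE) {
  stopifnot(inherits(tree, "problem_tree"))
  if (from_nodes && tree$format == "frequency") {
    pos <- tree$nodes[["FA"]] + tree$nodes[["nFA"]]
    if (pos == 0) stop("degenerate task: no positive-evidence events",
                       call. = FALSE)
    return(tree$nodes[["FA"]] / pos)
  }
  posterior(tree$base_rate, tree$tpr, tree$far)
}

# ---- answers ---------------------------------------------------------------

#' Construct a participant answer
#'
#' Frequency-format answers are proportions "`numerator` out of
#' `denominator`" events; percentage-format answers are percentages, stored
#' with denominator 100. The task interface enforced
#' `numerator <= denominator`, and so does this constructor.
#'
#' @param numerator Non-negative number.
#' @param denominator Positive number; 100 for percentage answers.
#' @return An `answer` object with an `as_probability()` accessor.
#' @export
#' @examples
#' as_probability(answer(80, 1000))
answer <- function(numerator, denominator) {
  if (!is.finite(numerator) || !is.finite(denominator)) {
    stop("invalid answer: numerator and denominator must be finite",
         call. = FALSE)
  }
  if (denominator <= 0) stop("invalid answer: denominator must be positive",
                             call. = FALSE)
  if (numerator < 0) stop("invalid answer: numerator must be non-negative",
                          call. = FALSE)
  if (numerator > denominator) {
    stop("invalid answer: numerator cannot exceed denominator",
         call. = FALSE)
  }
  structure(list(numerator = numerator, denominator = denominator),
            class = "answer")
}

#' @rdname answer
#' @param x An `answer`.
#' @export
as_probability <- function(x) {
  stopifnot(inherits(x, "answer"))
  x$numerator / x$denominator
}

# ---- performance metrics ---------------------------------------------------

#' Strict-rounding correctness
#'
#' An answer counts as correct only if, expressed in percent, it matches
#' the true posterior rounded either up or down to the next full percentage
#' point: the acceptance band is `[floor(t), ceil(t)]` percent, inclusive,
#' where `t` is the true posterior in percent. This is the strict
#' criterion conventional in the Bayesian-reasoning literature.
#'
#' @param ans An [answer()].
#' @param tree A `problem_tree`.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' tr <- build_probability_tree(0.1, 0.5, 0.27)  # true PPV 17.06%
#' correctness(answer(17, 100), tr)
#' correctness(answer(18, 100), tr)
#' correctness(answer(50, 100), tr)
correctness <- function(ans, tree) {
  stopifnot(inherits(tree, "problem_tree"))
  pe <- 100 * as_probability(ans)
  t_pct <- 100 * true_posterior(tree)
  eps <- 1e-9
  pe >= floor(t_pct) - eps && pe <= ceiling(t_pct) + eps
}

#' Log-relative-error of an estimate
#'
#' `log10(Pe / Pt)`: the log-transformed ratio of the estimated posterior
#' `Pe` to the true posterior `Pt`. Positive values are overestimates,
#' negative underestimates, zero an exact match.
#'
#' A zero estimate makes the log undefined; it is floored at
#' `1 / (10 * population)` (a tenth of one displayable event) and the
#' result is flagged with attribute `floored = TRUE` so downstream
#' summaries can mark the record as degenerate.
#'
#' @param pe Estimated posterior in `[0, 1]`.
#' @param pt True posterior in `(0, 1]`.
#' @param population Tree population used for the zero floor (default 1000).
#' @return `log10(pe / pt)`, with attribute `floored` if the floor was used.
#' @export
log_relative_error <- function(pe, pt, population = 1000L) {
  check_probability(pe, "pe")
  check_probability(pt, "pt")
  if (pt <= 0) stop("`pt` must be positive", call. = FALSE)
  floored <- FALSE
  if (pe <= 0) {
    pe <- 1 / (10 * population)
    floored <- TRUE
  }
  out <- log10(pe / pt)
  if (floored) attr(out, "floored") <- TRUE
  out
}

#' Log-experience-deviation of a subjective posterior
#'
#' `log10(Ps / Pt)` where `Ps` is the subjective posterior -- the PPV
#' implied by the participant's own reported (base rate, true-positive,
#' false-alarm) triple -- and `Pt` is the true posterior of the task
#' actually displayed. It measures how far lived experience sits from the
#' presented data; when the task is built from the participant's own
#' triple, it is identically zero.
#'
#' @param ps Subjective posterior in `[0, 1]`.
#' @inheritParams log_relative_error
#' @return `log10(ps / pt)`, zero-floored as in [log_relative_error()].
#' @export
log_experience_deviation <- function(ps, pt, population = 1000L) {
  log_relative_error(ps, pt, population = population)
}

# ---- strategy classification -----------------------------------------------

#' Classify the strategy behind an answer
#'
#' Assigns each answer to one of four mutually exclusive labels, checked in
#' fixed priority order:
#'
#' * `correct_ppv` -- strict-rounding correct (see [correctness()]);
#' * `sensitivity_confusion` -- the answer reproduces the true-positive
#'   rate instead of the PPV (the classic confusion of `P(E|H)` with
#'   `P(H|E)`), within `tol`;
#' * `total_denominator` -- frequency format only: the stated denominator
#'   is the whole population rather than the positive-evidence subset;
#' * `other` -- anything else.
#'
#' @param ans An [answer()].
#' @param tree A `problem_tree`.
#' @param tol Matching tolerance on the probability scale for the
#'   sensitivity check; default 0.005 (half a percentage point, the
#'   granularity of the strict-rounding criterion).
#' @return A `strategy_label` list with fields `label` and `tolerance`.
#' @export
#' @examples
#' tr <- build_frequency_tree(0.1, 0.5, 0.27)
#' classify_strategy(answer(500, 1000), tr)$label   # gave the sensitivity
#' classify_strategy(answer(50, 1000), tr)$label    # total as denominator
classify_strategy <- function(ans, tree, tol = 0.005) {
  stopifnot(inherits(tree, "problem_tree"), tol >= 0)
  label <-
    if (correctness(ans, tree)) {
      "correct_ppv"
    } else if (abs(as_probability(ans) - tree$tpr) <= tol) {
      "sensitivity_confusion"
    } else if (tree$format == "frequency" &&
               ans$denominator == tree$population) {
      "total_denominator"
    } else {
      "other"
    }
  structure(list(label = label, tolerance = tol), class = "strategy_label")
}

#' Strategy label levels
#'
#' @return Character vector of the four strategy labels in priority order.
#' @export
strategy_levels <- function() {
  c("correct_ppv", "sensitivity_confusion", "total_denominator", "other")
}
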