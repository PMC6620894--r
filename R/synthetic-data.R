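#' Stationary distribution of a hover Markov chain
#'
#' @param matrix Row-stochastic 8x8 matrix over [aoi_codes()] with zero
#'   diagonal.
#' @return Named stationary probability vector.
#' @export
markov_stationary <- function(matrix) {
  check_markov_matrix(matrix)
  e <- eigen(t(matrix))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), aoi_codes())
}

#' Theoretical bigram distribution of a hover Markov chain
#'
#' The long-run frequency of ordered pair `i -> j` in a first-order chain
#' is `pi_i * P_ij` with `pi` the stationary distribution. This is the
#' distribution the empirical transition table of a long sequence
#' converges to, and the scale on which planted between-condition effects
#' are calibrated.
#'
#' @inheritParams markov_stationary
#' @return Named probability vector over the 56 [transition_keys()].
#' @export
markov_pair_distribution <- function(matrix) {
  pi_ <- markov_stationary(matrix)
  pair <- outer(pi_, rep(1, 8)) * matrix
  keys <- transition_keys()
  a <- aoi_codes()
  from <- sub("-.*", "", keys)
  to <- sub(".*-", "", keys)
  stats::setNames(pair[cbind(match(from, a), match(to, a))], keys)
}

# internal: validate an 8x8 zero-diagonal row-stochastic matrix
check_markov_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !all(dim(matrix) == c(8L, 8L))) {
    stop("Markov matrix must be 8x8 over the AOI codes", call. = FALSE)
  }
  if (any(diag(matrix) != 0)) {
    stop("Markov matrix must have a zero diagonal (no self-transitions)",
         call. = FALSE)
  }
  if (any(matrix < 0) || any(abs(rowSums(matrix) - 1) > 1e-8)) {
    stop("Markov matrix rows must be non-negative and sum to 1",
         call. = FALSE)
  }
  invisible(matrix)
}

# internal: baseline chain -- uniform over the other seven AOIs, with the
# question button twice as attractive (participants re-check the question)
baseline_markov_matrix <- function() {
  a <- aoi_codes()
  w <- stats::setNames(rep(1, 8), a)
  w["Q"] <- 2
  m <- matrix(rep(w, each = 8), 8, 8, dimnames = list(a, a))
  diag(m) <- 0
  m / rowSums(m)
}

# internal: multiply selected "from-to" entries by exp(lambda), renormalize
tilt_markov_matrix <- function(matrix, transitions, lambda) {
  a <- aoi_codes()
  for (k in transitions) {
    from <- sub("-.*", "", k)
    to <- sub(".*-", "", k)
    matrix[from, to] <- matrix[from, to] * exp(lambda)
  }
  m <- matrix / rowSums(matrix)
  dimnames(m) <- list(a, a)
  m
}

#' Condition-specific hover chains with a calibrated format effect
#'
#' Builds the pair of first-order Markov chains used to simulate hover
#' behaviour under the two information formats. Starting from a common
#' baseline, the frequency-format chain up-weights the "reversion to
#' total" transitions typical of natural-frequency reasoners
#' (`F-T`, `nF-T`, `FnA-F`, `nFA-nF`) and the percentage-format chain
#' up-weights the question-checking transitions typical of percentage
#' reasoners (`Q-T`, `FnA-nF`, `nF-Q`). The common tilt strength is solved
#' numerically so that the Hellinger distance between the two chains'
#' theoretical bigram distributions equals `effect_hd`.
#'
#' `effect_hd = 0` returns two identical (baseline) chains -- the null
#' configuration.
#'
#' @param effect_hd Target Hellinger distance between the two conditions'
#'   theoretical bigram distributions (default 0.12, the magnitude of the
#'   between-format effect the analysis is powered for).
#' @return List with row-stochastic matrices `frequency` and `probability`.
#' @export
format_markov_matrices <- function(effect_hd = 0.12) {
  stopifnot(is.numeric(effect_hd), length(effect_hd) == 1L,
            effect_hd >= 0, effect_hd < 0.9)
  base <- baseline_markov_matrix()
  freq_up <- c("F-T", "nF-T", "FnA-F", "nFA-nF")
  prob_up <- c("Q-T", "FnA-nF", "nF-Q")
  if (effect_hd == 0) return(list(frequency = base, probability = base))
  hd_at <- function(lambda) {
    mf <- tilt_markov_matrix(base, freq_up, lambda)
    mp <- tilt_markov_matrix(base, prob_up, lambda)
    hellinger(markov_pair_distribution(mf), markov_pair_distribution(mp))
  }
  lambda <- stats::uniroot(function(l) hd_at(l) - effect_hd,
                           lower = 0, upper = 5, tol = 1e-8)$root
  list(frequency = tilt_markov_matrix(base, freq_up, lambda),
       probability = tilt_markov_matrix(base, prob_up, lambda))
}

#' Simulate one hover sequence from a first-order Markov chain
#'
#' Draws a visit sequence of geometric length (at least 2 visits; expected
#' length `1/stop_param + 1`) from a zero-diagonal row-stochastic chain,
#' then attaches per-visit dwell durations drawn from a per-AOI log-normal
#' model and lays the hovers back to back from time 0.
#'
#' @param matrix 8x8 row-stochastic matrix over [aoi_codes()], zero
#'   diagonal.
#' @param start_dist Distribution of the first visit; default the chain's
#'   stationary distribution.
#' @param stop_param Per-step stopping probability in `(0, 1)`.
#' @param dwell_model List with named vectors `meanlog` (per AOI) and a
#'   scalar `sdlog`, parameters of the log-normal dwell in ms.
#' @param participant_id Identifier for the resulting sequence.
#' @param seed Optional integer seed.
#' @param n_visits Optional fixed number of visits (at least 2), overriding
#'   the geometric draw; useful for convergence checks on long sequences.
#' @return A `hover_sequence`.
#' @export
markov_sequence <- function(matrix, start_dist = NULL, stop_param = 0.05,
                            dwell_model = default_dwell_model(),
                            participant_id = "sim", seed = NULL,
                            n_visits = NULL) {
  check_markov_matrix(matrix)
  stopifnot(stop_param > 0, stop_param < 1)
  if (is.null(start_dist)) start_dist <- markov_stationary(matrix)
  stopifnot(length(start_dist) == 8L, all(start_dist >= 0),
            abs(sum(start_dist) - 1) < 1e-8)
  maybe_seed(seed)
  n <- if (is.null(n_visits)) 2L + stats::rgeom(1L, stop_param) else
    check_count(n_visits, "n_visits", min = 2L)
  states <- integer(n)
  states[1L] <- sample.int(8L, 1L, prob = start_dist)
  for (i in seq_len(n - 1L)) {
    states[i + 1L] <- sample.int(8L, 1L, prob = matrix[states[i], ])
  }
  visits <- aoi_codes()[states]
  dwell <- stats::rlnorm(n, meanlog = dwell_model$meanlog[visits],
                         sdlog = dwell_model$sdlog)
  hover_sequence(participant_id, visits, dwell_ms = dwell)
}

#' Default per-AOI dwell model
#'
#' Log-normal dwell durations in milliseconds. The question button gets a
#' longer typical dwell (reading text) than the data nodes (reading one
#' number), which reproduces the field observation that roughly 40% of
#' total hover time is spent on the question.
#'
#' @return List with `meanlog` (named over [aoi_codes()]) and `sdlog`.
#' @export
default_dwell_model <- function() {
  meanlog <- stats::setNames(rep(log(800), 8), aoi_codes())
  meanlog["Q"] <- log(3500)
  list(meanlog = meanlog, sdlog = 0.6)
}

# ---- cohort configuration --------------------------------------------------

#' Configure a synthetic cohort
#'
#' Describes the data-generating world of one simulated study arm pair:
#' sample size per condition, data-generating mode, the distributions of
#' reported (base rate, true-positive, false-alarm) triples, the mixture
#' of answer strategies in each format, and the hover Markov chains.
#'
#' Defaults state the world the analysis assumes: 150 participants per
#' cell; reported triples Beta-distributed around the believed values seen
#' in this paradigm (base ~ Beta(2, 18), mean 0.10; tpr ~ Beta(5, 5),
#' mean 0.50; far ~ Beta(2.7, 7.3), mean 0.27); the fixed-values task
#' triple (0.1, 0.5, 0.27); strategy mixtures reflecting the dominant
#' error in each format (total-population denominators under frequencies,
#' sensitivity confusion under percentages); and condition chains with a
#' format effect of Hellinger magnitude 0.12.
#'
#' @param n_per_cell Participants per format condition.
#' @param study `"experience_matched"` (task built from each participant's
#'   reported triple) or `"fixed_values"` (task built from `fixed_triple`).
#' @param fixed_triple Numeric `(base, tpr, far)` for fixed-values mode.
#' @param triple_priors List of `c(shape1, shape2)` Beta parameters named
#'   `base`, `tpr`, `far`.
#' @param strategy_mixture List of named probability vectors `frequency`
#'   and `probability` over [strategy_levels()]; each must sum to 1, and
#'   `total_denominator` is only meaningful under the frequency format.
#' @param markov_matrices List of matrices `frequency` and `probability`;
#'   default [format_markov_matrices()] at `effect_hd`.
#' @param effect_hd Planted between-format effect used when
#'   `markov_matrices` is not supplied.
#' @param dwell_model See [default_dwell_model()].
#' @param stop_param Geometric stopping probability of the hover chains.
#' @param adblocker_rate Probability a participant keeps an active
#'   ad-blocker (and is later excluded); default 0.
#' @param force_question_visit Prepend a `Q` visit when the chain never
#'   reaches the question, so participants pass the validity filter unless
#'   exclusion behaviour is being exercised deliberately.
#' @param seed Integer master seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_per_cell = 150L,
                          study = c("experience_matched", "fixed_values"),
                          fixed_triple = c(0.1, 0.5, 0.27),
                          triple_priors = list(base = c(2, 18),
                                               tpr = c(5, 5),
                                               far = c(2.7, 7.3)),
                          strategy_mixture = NULL,
                          markov_matrices = NULL,
                          effect_hd = 0.12,
                          dwell_model = default_dwell_model(),
                          stop_param = 0.05,
                          adblocker_rate = 0,
                          force_question_visit = TRUE,
                          seed = 1L) {
  study <- match.arg(study)
  n_per_cell <- check_count(n_per_cell, "n_per_cell", min = 1L)
  stopifnot(length(fixed_triple) == 3L, all(fixed_triple >= 0),
            all(fixed_triple <= 1))
  if (is.null(strategy_mixture)) {
    strategy_mixture <- if (study == "experience_matched") {
      list(frequency = c(correct_ppv = 0.39, total_denominator = 0.45,
                         other = 0.16),
           probability = c(correct_ppv = 0.14, sensitivity_confusion = 0.60,
                           other = 0.26))
    } else {
      list(frequency = c(correct_ppv = 0.09, total_denominator = 0.57,
                         other = 0.34),
           probability = c(correct_ppv = 0.02, sensitivity_confusion = 0.52,
                           other = 0.46))
    }
  }
  for (fmt in c("frequency", "probability")) {
    mix <- strategy_mixture[[fmt]]
    if (is.null(mix) || abs(sum(mix) - 1) > 1e-8 || any(mix < 0) ||
        !all(names(mix) %in% strategy_levels())) {
      stop(sprintf("invalid strategy mixture for the %s format", fmt),
           call. = FALSE)
    }
    if (fmt == "probability" &&
        isTRUE(mix["total_denominator"] > 0)) {
      stop("total_denominator strategy is undefined under the probability ",
           "format (the displayed denominator is always 100)",
           call. = FALSE)
    }
  }
  if (is.null(markov_matrices)) {
    markov_matrices <- format_markov_matrices(effect_hd)
  }
  check_markov_matrix(markov_matrices$frequency)
  check_markov_matrix(markov_matrices$probability)
  stopifnot(adblocker_rate >= 0, adblocker_rate <= 1)
  structure(list(n_per_cell = n_per_cell, study = study,
                 fixed_triple = fixed_triple, triple_priors = triple_priors,
                 strategy_mixture = strategy_mixture,
                 markov_matrices = markov_matrices,
                 dwell_model = dwell_model, stop_param = stop_param,
                 adblocker_rate = adblocker_rate,
                 force_question_visit = force_question_visit,
                 seed = check_count(seed, "seed")),
            class = "cohort_config")
}

# internal: one reported triple, clamped away from the degenerate edges
draw_triple <- function(priors) {
  draw <- function(p) stats::rbeta(1L, p[1], p[2])
  pmin(pmax(c(base = draw(priors$base), tpr = draw(priors$tpr),
              far = draw(priors$far)), 0.001), 0.999)
}

# internal: answer implied by a strategy label on a given tree; "other"
# answers are quoted out of 100 so they cannot collide with the
# total-population-denominator signature
strategy_answer <- function(label, tree) {
  den <- if (tree$format == "frequency") 1000 else 100
  switch(label,
    correct_ppv = answer(true_posterior(tree) * den, den),
    sensitivity_confusion = answer(tree$tpr * den, den),
    total_denominator = answer(tree$nodes[["FA"]], tree$population),
    other = answer(stats::runif(1L) * 100, 100)
  )
}

#' Generate a synthetic cohort
#'
#' Simulates a two-condition (frequency vs. percentage format) cohort with
#' the structure the analysis pipeline consumes: a participant table with
#' condition labels, reported probability triples, numeracy scores and
#' answers drawn from per-condition strategy mixtures, and a hover-event
#' log drawn from per-condition first-order Markov chains. Fully
#' reproducible from `config$seed`.
#'
#' In experience-matched mode each participant's task tree is built from
#' their own reported triple (so their log-experience-deviation is zero);
#' in fixed-values mode all trees use `config$fixed_triple`.
#'
#' @param config A [cohort_config()].
#' @return List with `participants` (data frame, one row per participant),
#'   `events` (hover-event log data frame: `participant_id`, `aoi`,
#'   `enter_ms`, `exit_ms`) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_total <- 2L * config$n_per_cell
  seeds <- derive_seeds(config$seed, n_total + 1L)
  formats <- rep(c("frequency", "probability"), each = config$n_per_cell)
  study_no <- if (config$study == "experience_matched") 1L else 2L

  participants <- vector("list", n_total)
  events <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(seeds[i])
    fmt <- formats[i]
    id <- sprintf("s%d_%s_%03d", study_no, substr(fmt, 1, 4), i)
    triple <- draw_triple(config$triple_priors)
    # reported values are quantized the way participants state them:
    # "x out of 1000" under frequencies, tenth-of-a-percent otherwise
    if (fmt == "frequency") {
      den <- 1000
      nums <- pmax(1, round_half_up(triple * den))
    } else {
      den <- 100
      nums <- pmax(0.1, round(triple * den, 1))
    }
    triple <- nums / den
    task_triple <- if (config$study == "experience_matched") triple else
      config$fixed_triple
    tree <- if (fmt == "frequency") {
      build_frequency_tree(task_triple[1], task_triple[2], task_triple[3])
    } else {
      build_probability_tree(task_triple[1], task_triple[2], task_triple[3])
    }
    mix <- config$strategy_mixture[[fmt]]
    label <- sample(names(mix), 1L, prob = mix)
    ans <- strategy_answer(label, tree)
    numeracy <- min(6, max(1, stats::rnorm(1L, 3.9, 0.7)))
    adblocker <- stats::runif(1L) < config$adblocker_rate

    seq_ <- markov_sequence(config$markov_matrices[[fmt]],
                            stop_param = config$stop_param,
                            dwell_model = config$dwell_model,
                            participant_id = id)
    if (config$force_question_visit && !"Q" %in% seq_$visits) {
      dw <- stats::rlnorm(1L, config$dwell_model$meanlog[["Q"]],
                          config$dwell_model$sdlog)
      seq_ <- hover_sequence(id, c("Q", seq_$visits),
                             c(dw, seq_$events$dwell_ms))
    }
    participants[[i]] <- data.frame(
      participant_id = id, study = study_no, dgm = config$study,
      format = fmt,
      base_num = nums[1], base_den = den,
      tpr_num = nums[2], tpr_den = den,
      far_num = nums[3], far_den = den,
      answer_num = ans$numerator, answer_den = ans$denominator,
      numeracy = numeracy, adblocker_active = adblocker,
      strategy_true = label,
      stringsAsFactors = FALSE
    )
    ev <- seq_$events
    events[[i]] <- data.frame(participant_id = id, aoi = ev$aoi,
                              enter_ms = ev$enter_ms, exit_ms = ev$exit_ms,
                              stringsAsFactors = FALSE)
  }
  list(participants = do.call(rbind, participants),
       events = do.call(rbind, events),
       config = config)
}
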