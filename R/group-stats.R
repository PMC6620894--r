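#' Hellinger distance between two discrete distributions
#'
#' \deqn{Hd(p, q) = \frac{1}{\sqrt 2}\sqrt{\sum_i (\sqrt{p_i} - \sqrt{q_i})^2}}
#'
#' A bounded distance in `[0, 1]`: 0 for identical distributions, 1 for
#' distributions with disjoint support. Used here to compare group-level
#' transition frequency distributions over the 56 AOI pairs, but accepts
#' any pair of aligned discrete distributions.
#'
#' @param p,q Non-negative numeric vectors of equal length, each summing
#'   to 1 (within `1e-8`). `transition_table` objects are accepted and
#'   their `normalized` component used.
#' @return The Hellinger distance.
#' @export
#' @examples
#' hellinger(c(0.5, 0.5, 0), c(1, 0, 0))  # sqrt(1 - sqrt(0.5)) = 0.5412
hellinger <- function(p, q) {
  if (inherits(p, "transition_table")) p <- p$normalized
  if (inherits(q, "transition_table")) q <- q$normalized
  if (length(p) != length(q)) {
    stop("`p` and `q` must have the same length", call. = FALSE)
  }
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8) {
    stop("`p` and `q` must be normalized distributions (non-negative, sum 1)",
         call. = FALSE)
  }
  min(1, sqrt(sum((sqrt(p) - sqrt(q))^2)) / sqrt(2))
}

#' Permutation / resampling test on the group Hellinger distance
#'
#' Tests whether the Hellinger distance between the pooled transition
#' distributions of two participant groups is larger than expected by
#' chance. The observed statistic is `hellinger(pool_group(A),
#' pool_group(B))`. The null distribution is built by repeatedly forming
#' two pseudo-groups of the original sizes from the combined participants
#' and recomputing the distance:
#'
#' * `"with_replacement"` (default): each pseudo-group is drawn from the
#'   combined pool with replacement -- groups created at random from the
#'   population of participants;
#' * `"label_permutation"`: group labels are shuffled without replacement
#'   (a classical permutation of the partition).
#'
#' The p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`, which cannot be zero at
#' finite `n_perm`. Replicates in which a pseudo-group has zero transitions
#' are redrawn (and counted in `n_redrawn`).
#'
#' @param group_a,group_b Lists of participant-scope `transition_table`s.
#' @param n_perm Number of resamples (default 10000).
#' @param seed Integer seed; the test is reproducible given the seed.
#' @param mode `"with_replacement"` or `"label_permutation"`.
#' @return A `comparison_result` list: `hd_observed`, `p_value`, `n_perm`,
#'   `resample_mode`, `seed`, `group_sizes`, `null_distances`, `n_redrawn`.
#' @export
permutation_test <- function(group_a, group_b, n_perm = 10000L, seed = 1L,
                             mode = c("with_replacement",
                                      "label_permutation")) {
  mode <- match.arg(mode)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  hd_obs <- hellinger(pool_group(group_a), pool_group(group_b))

  # participants' count vectors as columns of one matrix
  m <- vapply(c(group_a, group_b), `[[`, numeric(56), "counts")
  n_a <- length(group_a)
  n_b <- length(group_b)
  n_all <- n_a + n_b

  maybe_seed(seed)
  null_d <- numeric(n_perm)
  n_redrawn <- 0L
  remaining <- seq_len(n_perm)
  # vectorized resampling: participant-selection count matrices multiplied
  # against the 56 x n matrix of per-participant counts, in chunks to
  # bound memory; replicates with an empty pseudo-group are redrawn
  while (length(remaining) > 0L) {
    k <- min(length(remaining), 2000L)
    idx <- remaining[seq_len(k)]
    if (mode == "with_replacement") {
      draw <- function(size) {
        s <- sample.int(n_all, size * k, replace = TRUE)
        counts <- tabulate(s + rep(seq_len(k) - 1L, each = size) * n_all,
                           nbins = n_all * k)
        matrix(counts, n_all, k)
      }
      s_a <- draw(n_a)
      s_b <- draw(n_b)
    } else {
      s_a <- matrix(0, n_all, k)
      s_b <- matrix(0, n_all, k)
      for (j in seq_len(k)) {
        perm <- sample.int(n_all, n_all)
        s_a[perm[seq_len(n_a)], j] <- 1
        s_b[perm[-seq_len(n_a)], j] <- 1
      }
    }
    ca <- m %*% s_a
    cb <- m %*% s_b
    ta <- colSums(ca)
    tb <- colSums(cb)
    ok <- ta > 0 & tb > 0
    d <- suppressWarnings(pmin(1, sqrt(colSums(
      (sqrt(sweep(ca, 2, ta, "/")) - sqrt(sweep(cb, 2, tb, "/")))^2
    )) / sqrt(2)))
    null_d[idx[ok]] <- d[ok]
    n_redrawn <- n_redrawn + sum(!ok)
    remaining <- c(remaining[-seq_len(k)], idx[!ok])
  }
  p <- (1 + sum(null_d >= hd_obs)) / (n_perm + 1)
  structure(list(hd_observed = hd_obs, p_value = p, n_perm = n_perm,
                 resample_mode = mode, seed = seed,
                 group_sizes = c(n_a, n_b),
                 null_distances = null_d, n_redrawn = n_redrawn),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> Hd = %.4f, p = %.4g (%d resamples, %s, groups %d/%d)\n",
    x$hd_observed, x$p_value, x$n_perm, x$resample_mode,
    x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

#' Odds ratio for one transition between two groups
#'
#' For a transition with relative frequency `p` in group A and `q` in
#' group B, `OR = (p / (1 - p)) / (q / (1 - q))`, computed on the 2x2
#' table `{count, total - count}` for the two groups. The 95% confidence
#' interval is Wald on the log scale with
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`; when any cell is zero the
#' Haldane--Anscombe correction (+0.5 on all four cells) is applied to
#' both the estimate and the interval.
#'
#' @param count_a,total_a Transition count and total transition count in
#'   group A.
#' @param count_b,total_b Same for group B.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, `max_frequency`
#'   (`max(count_a, count_b)`), and `haldane` (whether the correction was
#'   applied).
#' @export
#' @examples
#' transition_odds_ratio(20, 100, 10, 100)$odds_ratio  # 2.25
transition_odds_ratio <- function(count_a, total_a, count_b, total_b,
                                  conf_level = 0.95) {
  stopifnot(total_a > 0, total_b > 0,
            count_a >= 0, count_b >= 0,
            count_a <= total_a, count_b <= total_b)
  cells <- c(a = count_a, b = total_a - count_a,
             c = count_b, d = total_b - count_b)
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  or <- (cells[["a"]] / cells[["b"]]) / (cells[["c"]] / cells[["d"]])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(odds_ratio = or,
       ci_low = or * exp(-z * se),
       ci_high = or * exp(z * se),
       max_frequency = max(count_a, count_b),
       haldane = haldane)
}

#' Screen for discriminative transitions between two groups
#'
#' Computes the odds ratio with 95% CI for each of the 56 transitions
#' between two group-scope transition tables. A transition is flagged
#' discriminative when its CI excludes 1 *and* its maximum frequency
#' `F = max(x_i, y_i)` (the larger of the two groups' raw counts) reaches
#' `min_frequency` -- transitions that occur only a few times are not
#' representative of group behaviour however extreme their odds ratio.
#'
#' @param table_a,table_b Group-scope `transition_table`s.
#' @param min_frequency Minimum `F` for the discriminative flag
#'   (default 30).
#' @param conf_level Confidence level for the CIs.
#' @return Data frame with one row per transition, sorted by `|log OR|`
#'   descending: `transition`, `count_a`, `count_b`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `max_frequency`, `discriminative`.
#' @export
screen_discriminative <- function(table_a, table_b, min_frequency = 30L,
                                  conf_level = 0.95) {
  stopifnot(inherits(table_a, "transition_table"),
            inherits(table_b, "transition_table"))
  keys <- transition_keys()
  rows <- lapply(keys, function(k) {
    res <- transition_odds_ratio(table_a$counts[[k]], table_a$total,
                                 table_b$counts[[k]], table_b$total,
                                 conf_level = conf_level)
    data.frame(transition = k,
               count_a = table_a$counts[[k]],
               count_b = table_b$counts[[k]],
               odds_ratio = res$odds_ratio,
               ci_low = res$ci_low, ci_high = res$ci_high,
               max_frequency = res$max_frequency,
               discriminative = (res$ci_low > 1 || res$ci_high < 1) &&
                 res$max_frequency >= min_frequency,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(log(out$odds_ratio))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chi-squared test of association with Cramér's V
#'
#' Pearson chi-squared test of independence on a contingency table,
#' without continuity correction, with an optional Bonferroni adjustment
#' for a family of `n_comparisons` tests. Effect size is Cramér's
#' `V = sqrt(chi2 / (N * min(r - 1, c - 1)))`.
#'
#' @param table Matrix of non-negative integer counts (at least 2x2).
#' @param n_comparisons Size of the Bonferroni family (default 1 = no
#'   correction).
#' @return An `association_result` list: `chi_squared`, `df`, `p_raw`,
#'   `p_adjusted`, `cramers_v`, `n`, `correction`.
#' @export
chi_squared_association <- function(table, n_comparisons = 1L) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), nrow(table) >= 2L, ncol(table) >= 2L)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: zero row or column marginal", call. = FALSE)
  }
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  chi2 <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  p_raw <- stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi_squared = chi2, df = df, p_raw = p_raw,
                 p_adjusted = min(1, p_raw * n_comparisons),
                 cramers_v = sqrt(chi2 / (n * min(nrow(table) - 1L,
                                                  ncol(table) - 1L))),
                 n = n,
                 correction = if (n_comparisons > 1L) "bonferroni" else "none"),
            class = "association_result")
}

# ---- reporting regressions -------------------------------------------------

# internal: Wald 95% CIs from a fitted model, on the link scale
wald_ci <- function(fit, conf_level = 0.95) {
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = names(est), estimate = est,
             ci_low = est - z * se, ci_high = est + z * se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Logistic model of strict-rounding correctness
#'
#' Fits `correct ~ format + dgm + numeracy` by maximum-likelihood logistic
#' regression and reports coefficients as odds ratios with 95% Wald CIs.
#' Reference classes: `format = "frequency"`, `dgm = "experience_matched"`,
#' so the format odds ratio is the odds of answering correctly under the
#' percentage format relative to the natural-frequency format, and the DGM
#' odds ratio is experience-mismatched relative to experience-matched.
#'
#' Perfect separation (or a constant response) is flagged and the CIs
#' reported as unavailable.
#'
#' @param records Data frame with columns `correct` (logical), `format`
#'   (`"frequency"`/`"probability"`), `dgm`
#'   (`"experience_matched"`/`"fixed_values"`), `numeracy` (numeric).
#' @return A `regression_result` list: `model`, `scale`, `coefficients`
#'   (term / estimate / ci_low / ci_high), `separation` flag.
#' @export
fit_correctness_model <- function(records) {
  stopifnot(all(c("correct", "format", "dgm", "numeracy") %in%
                  names(records)))
  records$format <- factor(records$format,
                           levels = c("frequency", "probability"))
  records$dgm <- factor(records$dgm,
                        levels = c("experience_matched", "fixed_values"))
  y <- as.logical(records$correct)
  if (length(unique(y)) < 2L) {
    stop("constant response: correctness does not vary", call. = FALSE)
  }
  drop_const <- vapply(c(format = "format", dgm = "dgm"),
                       function(v) length(unique(records[[v]])) < 2L,
                       logical(1))
  terms <- c(if (!drop_const[["format"]]) "format",
             if (!drop_const[["dgm"]]) "dgm", "numeracy")
  fml <- stats::reformulate(terms, response = "correct")
  fit <- suppressWarnings(
    stats::glm(fml, data = transform(records, correct = y),
               family = stats::binomial())
  )
  co <- wald_ci(fit)
  separation <- !fit$converged || any(abs(co$estimate[-1L]) > 15)
  co$estimate <- exp(co$estimate)
  co$ci_low <- exp(co$ci_low)
  co$ci_high <- exp(co$ci_high)
  if (separation) co$ci_low <- co$ci_high <- NA_real_
  structure(list(model = "logistic_correctness", scale = "odds_ratio",
                 coefficients = co, separation = separation),
            class = "regression_result")
}

#' Linear model of log-relative-error
#'
#' Fits `log_relative_error ~ format + log_experience_deviation` by least
#' squares and reports model-scale coefficients with 95% CIs. Intended for
#' the fixed-values data-generating mode, where the deviation of lived
#' experience from the presented data varies across participants.
#'
#' @param records Data frame with columns `log_relative_error`, `format`,
#'   `log_experience_deviation`.
#' @return A `regression_result` list (scale `"model_scale"`).
#' @export
fit_error_model <- function(records) {
  stopifnot(all(c("log_relative_error", "format",
                  "log_experience_deviation") %in% names(records)))
  records$format <- factor(records$format,
                           levels = c("frequency", "probability"))
  if (stats::var(records$log_relative_error) == 0) {
    stop("constant response: log-relative-error does not vary",
         call. = FALSE)
  }
  fit <- stats::lm(log_relative_error ~ format + log_experience_deviation,
                   data = records)
  structure(list(model = "linear_log_error", scale = "model_scale",
                 coefficients = wald_ci(fit), separation = FALSE),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s (%s scale)%s\n", x$model, x$scale,
              if (x$separation) " [separation flagged]" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}
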