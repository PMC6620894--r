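# simulate -> filter -> metrics -> transitions -> inference -> report
# orchestration; all file formats are plain delimited text or JSON

#' Read / write the delimited participant table and event log
#'
#' Tab-separated text with a header row; columns as produced by
#' [generate_cohort()]. Reading then re-writing is lossless for all
#' included fields.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_*` return data frames; `write_*` return `path` invisibly.
#' @export
write_participants <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_participants
#' @export
write_events <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Load a cohort configuration from a JSON file
#'
#' Accepts the fields of [cohort_config()]; `markov_matrices`, if present,
#' are read as row-major 8x8 matrices. Unknown fields are rejected.
#'
#' @param path Path to a JSON configuration.
#' @return A validated `cohort_config`.
#' @export
load_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("n_per_cell", "study", "fixed_triple", "triple_priors",
             "strategy_mixture", "effect_hd", "stop_param",
             "adblocker_rate", "force_question_visit", "seed",
             "markov_matrices")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$markov_matrices)) {
    raw$markov_matrices <- lapply(raw$markov_matrices, function(m) {
      m <- matrix(unlist(m), 8L, 8L, byrow = TRUE,
                  dimnames = list(aoi_codes(), aoi_codes()))
      m
    })
  }
  if (!is.null(raw$strategy_mixture)) {
    raw$strategy_mixture <- lapply(raw$strategy_mixture, unlist)
  }
  if (!is.null(raw$triple_priors)) {
    raw$triple_priors <- lapply(raw$triple_priors, unlist)
  }
  do.call(cohort_config, raw)
}

# internal: run manifest helper
write_manifest <- function(path, manifest) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic cohort and writes `participants.tsv`,
#' `events.tsv` and `manifest.json` (config hash, seed, row counts,
#' output list, package version) into `out_dir`. The manifest is written
#' before the data files it describes are considered final, and identical
#' configs and seeds produce byte-identical outputs.
#'
#' @param config A [cohort_config()], or a path to a JSON config for
#'   [load_cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config's seed.
#' @return Invisible character vector of the files written.
#' @export
pipeline_simulate <- function(config, out_dir, seed = NULL) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- load_cohort_config(config)
  }
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) config$seed <- check_count(seed, "seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  files <- file.path(out_dir, c("participants.tsv", "events.tsv"))
  manifest <- list(
    stage = "simulate",
    config_hash = if (is.null(config_path)) NA else
      unname(tools::md5sum(config_path)),
    seed = config$seed,
    study = config$study,
    n_participants = nrow(cohort$participants),
    n_events = nrow(cohort$events),
    outputs = basename(files),
    package_version = as.character(utils::packageVersion("hoverbayes"))
  )
  write_manifest(file.path(out_dir, "manifest.json"), manifest)
  write_participants(cohort$participants, files[1])
  write_events(cohort$events, files[2])
  invisible(c(file.path(out_dir, "manifest.json"), files))
}

#' Per-participant performance metrics
#'
#' Joins the participant table to the task model: rebuilds each
#' participant's task tree (from their reported triple in
#' experience-matched mode, from `fixed_triple` otherwise), and computes
#' the true posterior `Pt`, estimated posterior `Pe`, subjective posterior
#' `Ps` (the PPV implied by the reported triple), strict-rounding
#' correctness, log-relative-error, log-experience-deviation and the
#' strategy classification.
#'
#' @param participants Participant table (see [generate_cohort()]).
#' @param fixed_triple `(base, tpr, far)` used for rows whose `dgm` is
#'   `"fixed_values"`.
#' @return The participant table with columns `pt`, `pe`, `ps`, `correct`,
#'   `log_relative_error`, `log_experience_deviation`, `lre_floored`,
#'   `strategy` appended.
#' @export
compute_metrics <- function(participants, fixed_triple = c(0.1, 0.5, 0.27)) {
  n <- nrow(participants)
  out <- participants
  out$pt <- out$pe <- out$ps <- NA_real_
  out$correct <- NA
  out$log_relative_error <- out$log_experience_deviation <- NA_real_
  out$lre_floored <- FALSE
  out$strategy <- NA_character_
  for (i in seq_len(n)) {
    row <- participants[i, ]
    reported <- c(row$base_num / row$base_den,
                  row$tpr_num / row$tpr_den,
                  row$far_num / row$far_den)
    task <- if (row$dgm == "experience_matched") reported else fixed_triple
    tree <- if (row$format == "frequency") {
      build_frequency_tree(task[1], task[2], task[3])
    } else {
      build_probability_tree(task[1], task[2], task[3])
    }
    ans <- answer(row$answer_num, row$answer_den)
    pt <- true_posterior(tree)
    pe <- as_probability(ans)
    ps <- posterior(reported[1], reported[2], reported[3])
    lre <- log_relative_error(pe, pt)
    out$pt[i] <- pt
    out$pe[i] <- pe
    out$ps[i] <- ps
    out$correct[i] <- correctness(ans, tree)
    out$log_relative_error[i] <- as.numeric(lre)
    out$lre_floored[i] <- isTRUE(attr(lre, "floored"))
    out$log_experience_deviation[i] <-
      as.numeric(log_experience_deviation(ps, pt))
    out$strategy[i] <- classify_strategy(ans, tree)$label
  }
  out
}

#' Group dwell-time summary
#'
#' Per-participant dwell percentages summarised as mean and SD across
#' participants, by group -- the conventional dwell-time table shape.
#'
#' @param sequences Named list of `hover_sequence`s.
#' @param groups Named character vector mapping participant id to group
#'   label.
#' @return Data frame: `group`, `aoi`, `mean_pct`, `sd_pct`, `n`.
#' @export
dwell_summary <- function(sequences, groups) {
  pct <- t(vapply(sequences, dwell_percentages, numeric(8)))
  grp <- groups[rownames(pct)]
  rows <- lapply(unique(grp), function(g) {
    sub <- pct[grp == g, , drop = FALSE]
    data.frame(group = g, aoi = aoi_codes(),
               mean_pct = apply(sub, 2, mean),
               sd_pct = apply(sub, 2, stats::sd),
               n = nrow(sub), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Analyze a cohort from disk
#'
#' Runs the full analysis on a participant table and hover-event log:
#' validity filtering, per-participant performance metrics, group dwell
#' summaries, pooled transition distributions, the between-format
#' Hellinger permutation test, the discriminative-transition odds-ratio
#' screen, the format-by-correctness association test, and the reporting
#' regressions (the error regression only when the cohort is in
#' fixed-values mode; the correctness logistic model needs both formats
#' and drops constant predictors automatically).
#'
#' Outputs written to `out_dir`: `manifest.json`, `metrics.tsv`,
#' `dwell_summary.tsv`, `transitions_frequency.json`,
#' `transitions_probability.json`, `comparison.json`, `or_screen.tsv`,
#' `association.json`, `regressions.json`.
#'
#' @param participants_path,events_path Paths to the delimited inputs.
#' @param out_dir Output directory.
#' @param n_perm Resamples for the permutation test.
#' @param seed Seed for the permutation test.
#' @param resample_mode `"with_replacement"` or `"label_permutation"`.
#' @param min_frequency Discriminative-screen frequency threshold.
#' @param fixed_triple Task triple for fixed-values rows.
#' @return Invisible list of the in-memory results.
#' @export
pipeline_analyze <- function(participants_path, events_path, out_dir,
                             n_perm = 10000L, seed = 1L,
                             resample_mode = "with_replacement",
                             min_frequency = 30L,
                             fixed_triple = c(0.1, 0.5, 0.27)) {
  participants <- read_participants(participants_path)
  events <- read_events(events_path)
  need <- c("participant_id", "study", "dgm", "format", "base_num",
            "base_den", "tpr_num", "tpr_den", "far_num", "far_den",
            "answer_num", "answer_den")
  missing_cols <- setdiff(need, names(participants))
  if (length(missing_cols) > 0L) {
    stop("participant table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sequences <- parse_event_log(events)
  # participants with no events at all fail the filter by construction
  reports <- lapply(seq_len(nrow(participants)), function(i) {
    id <- participants$participant_id[i]
    ad <- isTRUE(participants$adblocker_active[i])
    if (id %in% names(sequences)) {
      validity_filter(sequences[[id]], adblocker_active = ad)
    } else {
      structure(list(participant_id = id, included = FALSE,
                     reasons = c(if (ad) "adblocker_active",
                                 "question_never_viewed",
                                 "fewer_than_two_info_views")),
                class = "validity_report")
    }
  })
  included <- vapply(reports, `[[`, logical(1), "included")
  reason_counts <- table(unlist(lapply(reports, `[[`, "reasons")))
  if (!any(included)) {
    stop("degenerate analysis: all participants excluded", call. = FALSE)
  }

  manifest <- list(
    stage = "analyze",
    inputs = c(participants = unname(tools::md5sum(participants_path)),
               events = unname(tools::md5sum(events_path))),
    seed = seed, n_perm = n_perm, resample_mode = resample_mode,
    min_frequency = min_frequency,
    n_read = nrow(participants),
    n_included = sum(included),
    n_excluded = sum(!included),
    exclusion_reasons = as.list(reason_counts),
    excluded_ids = lapply(reports[!included], function(r)
      list(participant_id = r$participant_id, reasons = r$reasons)),
    outputs = c("metrics.tsv", "dwell_summary.tsv",
                "transitions_frequency.json", "transitions_probability.json",
                "comparison.json", "or_screen.tsv", "association.json",
                "regressions.json"),
    package_version = as.character(utils::packageVersion("hoverbayes"))
  )
  write_manifest(file.path(out_dir, "manifest.json"), manifest)

  keep <- participants[included, , drop = FALSE]
  metrics <- compute_metrics(keep, fixed_triple = fixed_triple)
  utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  seqs <- sequences[keep$participant_id]
  groups <- stats::setNames(keep$format, keep$participant_id)
  dw <- dwell_summary(seqs, groups)
  utils::write.table(dw, file.path(out_dir, "dwell_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tables <- lapply(seqs, bigram_transitions)
  by_fmt <- split(tables, keep$format)
  pooled <- lapply(by_fmt, pool_group)
  for (fmt in names(pooled)) {
    transition_table_json(pooled[[fmt]],
                          file.path(out_dir,
                                    sprintf("transitions_%s.json", fmt)))
  }

  comparison <- or_screen <- NULL
  if (all(c("frequency", "probability") %in% names(by_fmt))) {
    comparison <- permutation_test(by_fmt$frequency, by_fmt$probability,
                                   n_perm = n_perm, seed = seed,
                                   mode = resample_mode)
    jsonlite::write_json(
      list(hd_observed = comparison$hd_observed,
           p_value = comparison$p_value, n_perm = comparison$n_perm,
           resample_mode = comparison$resample_mode, seed = comparison$seed,
           group_sizes = comparison$group_sizes,
           n_redrawn = comparison$n_redrawn),
      file.path(out_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    or_screen <- screen_discriminative(pooled$frequency, pooled$probability,
                                       min_frequency = min_frequency)
    utils::write.table(or_screen, file.path(out_dir, "or_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  association <- NULL
  if (length(unique(metrics$format)) == 2L &&
      length(unique(metrics$correct)) == 2L) {
    tab <- table(metrics$format, metrics$correct)
    association <- chi_squared_association(tab, n_comparisons = 1L)
    jsonlite::write_json(unclass(association),
                         file.path(out_dir, "association.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  regressions <- list()
  if (length(unique(metrics$correct)) == 2L) {
    regressions$correctness <- tryCatch(fit_correctness_model(metrics),
                                        error = function(e) NULL)
  }
  if (all(metrics$dgm == "fixed_values")) {
    regressions$error <- tryCatch(fit_error_model(metrics),
                                  error = function(e) NULL)
  }
  jsonlite::write_json(
    lapply(Filter(Negate(is.null), regressions), function(r)
      list(model = r$model, scale = r$scale, separation = r$separation,
           coefficients = r$coefficients)),
    file.path(out_dir, "regressions.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")

  invisible(list(manifest = manifest, metrics = metrics, dwell = dw,
                 pooled = pooled, comparison = comparison,
                 or_screen = or_screen, association = association,
                 regressions = regressions))
}

#' Render a human-readable summary of an analysis directory
#'
#' Formats the result files written by [pipeline_analyze()] as text
#' tables (cohort summary, dwell table, discriminative transitions,
#' permutation test). Performs no recomputation: every number shown is
#' read from a result file.
#'
#' @param results_dir Directory written by [pipeline_analyze()].
#' @param file Connection or path passed to [base::cat()]; default stdout.
#' @return The report lines, invisibly.
#' @export
pipeline_report <- function(results_dir, file = "") {
  manifest_path <- file.path(results_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("missing manifest.json in ", results_dir, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  lines <- c(
    "== hoverbayes analysis report ==",
    sprintf("participants read %d | included %d | excluded %d",
            man$n_read, man$n_included, man$n_excluded))
  if (length(man$exclusion_reasons) > 0L) {
    lines <- c(lines, paste0("  exclusions: ",
                             paste(names(man$exclusion_reasons),
                                   unlist(man$exclusion_reasons),
                                   sep = "=", collapse = ", ")))
  }
  metrics_path <- file.path(results_dir, "metrics.tsv")
  if (file.exists(metrics_path)) {
    m <- utils::read.delim(metrics_path)
    agg <- stats::aggregate(correct ~ format, data = m, FUN = mean)
    lines <- c(lines, "", "correctness by format:",
               sprintf("  %-12s %5.1f%% (n=%d)", agg$format,
                       100 * agg$correct,
                       as.vector(table(m$format)[agg$format])))
    st <- table(m$format, m$strategy)
    lines <- c(lines, "strategy shares by format:",
               utils::capture.output(print(round(
                 prop.table(st, 1), 3))))
  }
  dwell_path <- file.path(results_dir, "dwell_summary.tsv")
  if (file.exists(dwell_path)) {
    dw <- utils::read.delim(dwell_path)
    lines <- c(lines, "", "dwell-time percentages (mean (sd)):")
    for (g in unique(dw$group)) {
      sub <- dw[dw$group == g, ]
      lines <- c(lines, sprintf("  %-12s %s", g,
                                paste(sprintf("%s=%.0f(%.0f)", sub$aoi,
                                              sub$mean_pct, sub$sd_pct),
                                      collapse = " ")))
    }
  }
  comparison_path <- file.path(results_dir, "comparison.json")
  if (file.exists(comparison_path)) {
    cmp <- jsonlite::read_json(comparison_path, simplifyVector = TRUE)
    lines <- c(lines, "",
               sprintf("between-format transition test: Hd = %.3f, p = %.4g (%d resamples, %s)",
                       cmp$hd_observed, cmp$p_value, cmp$n_perm,
                       cmp$resample_mode))
  }
  screen_path <- file.path(results_dir, "or_screen.tsv")
  if (file.exists(screen_path)) {
    sc <- utils::read.delim(screen_path)
    disc <- sc[sc$discriminative, , drop = FALSE]
    if (nrow(disc) == 0L) {
      lines <- c(lines, "discriminative transitions: none")
    } else {
      lines <- c(lines, "discriminative transitions:",
                 sprintf("  %-9s OR %5.2f  95%% CI %.2f-%.2f  F %d",
                         disc$transition, disc$odds_ratio, disc$ci_low,
                         disc$ci_high, disc$max_frequency))
    }
  }
  cat(lines, sep = "\n", file = file)
  invisible(lines)
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `analyze` and `report` subcommands; see
#' `inst/cli/hoverbayes.R` for the installed executable wrapper
#' (`Rscript $(Rscript -e 'cat(system.file("cli/hoverbayes.R",
#' package="hoverbayes"))') <command> ...`).
#'
#' Exit codes (returned, for the wrapper to pass to [base::quit()]):
#' 0 success, 2 validation error, 3 degenerate analysis.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
hoverbayes_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hoverbayes <command> [options]",
    "commands:",
    "  simulate --config <json> --out <dir> [--seed <int>]",
    "  analyze  --participants <tsv> --events <tsv> --out <dir>",
    "           [--seed <int>] [--n-perm <int>]",
    "           [--resample-mode replacement|permutation]",
    "           [--min-frequency <int>]",
    "  report   --results <dir>",
    sep = "\n")
  if (length(args) == 0L) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 0L) return(default)
    rest[i[1L] + 1L]
  }
  code <- tryCatch({
    switch(cmd,
      simulate = {
        out <- opt("--out")
        cfg <- opt("--config")
        if (is.null(out) || is.null(cfg)) stop(usage, call. = FALSE)
        seed <- opt("--seed")
        pipeline_simulate(cfg, out,
                          seed = if (is.null(seed)) NULL else
                            as.integer(seed))
        0L
      },
      analyze = {
        out <- opt("--out")
        pp <- opt("--participants")
        ee <- opt("--events")
        if (is.null(out) || is.null(pp) || is.null(ee)) {
          stop(usage, call. = FALSE)
        }
        mode <- switch(opt("--resample-mode", "replacement"),
                       replacement = "with_replacement",
                       permutation = "label_permutation",
                       stop("--resample-mode must be 'replacement' or ",
                            "'permutation'", call. = FALSE))
        pipeline_analyze(pp, ee, out,
                         n_perm = as.integer(opt("--n-perm", "10000")),
                         seed = as.integer(opt("--seed", "1")),
                         resample_mode = mode,
                         min_frequency =
                           as.integer(opt("--min-frequency", "30")))
        0L
      },
      report = {
        res <- opt("--results")
        if (is.null(res)) stop(usage, call. = FALSE)
        pipeline_report(res)
        0L
      },
      {
        message("unknown command: ", cmd, "\n", usage)
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("degenerate", conditionMessage(e))) 3L else 2L
  })
  invisible(code)
}
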