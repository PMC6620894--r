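#' Parse a hover-event log into per-participant AOI sequences
#'
#' The event log records one hover per row: the participant, the AOI
#' (button) hovered, and the enter/exit timestamps in milliseconds since
#' task start (half-open intervals `[enter, exit)`). Events are sorted by
#' enter time within participant; consecutive hovers on the same AOI are
#' collapsed into a single visit (their dwell times are summed), so the
#' derived visit sequence never repeats an AOI immediately and bigram
#' transitions live on the 56-pair space.
#'
#' @param records Data frame with columns `participant_id`, `aoi`,
#'   `enter_ms`, `exit_ms`.
#' @param min_duration_ms Hovers shorter than this many milliseconds are
#'   dropped before collapsing. Default 0 (no debouncing).
#' @return Named list of `hover_sequence` objects, one per participant, each
#'   with fields `participant_id`, `events` (the sorted, collapsed visit
#'   table with per-visit dwell), and `visits` (AOI codes in order).
#' @export
parse_event_log <- function(records, min_duration_ms = 0) {
  need <- c("participant_id", "aoi", "enter_ms", "exit_ms")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("event log is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_aoi(records$aoi)
  if (any(!is.finite(records$enter_ms)) || any(!is.finite(records$exit_ms)) ||
      any(records$exit_ms <= records$enter_ms) || any(records$enter_ms < 0)) {
    stop("malformed event log: need 0 <= enter_ms < exit_ms for every hover",
         call. = FALSE)
  }
  records <- records[records$exit_ms - records$enter_ms >= min_duration_ms, ,
                     drop = FALSE]
  ids <- unique(as.character(records$participant_id))
  out <- lapply(ids, function(id) {
    ev <- records[as.character(records$participant_id) == id, , drop = FALSE]
    ev <- ev[order(ev$enter_ms), , drop = FALSE]
    if (nrow(ev) > 1L &&
        any(ev$enter_ms[-1L] < ev$exit_ms[-nrow(ev)])) {
      stop(sprintf("malformed event log: overlapping hovers for participant %s",
                   id), call. = FALSE)
    }
    new_hover_sequence(id, as.character(ev$aoi),
                       ev$enter_ms, ev$exit_ms)
  })
  names(out) <- ids
  out
}

# internal constructor: collapses immediate repeats, keeps per-visit dwell
new_hover_sequence <- function(participant_id, aoi, enter_ms, exit_ms) {
  dur <- exit_ms - enter_ms
  if (length(aoi) > 0L) {
    run <- cumsum(c(TRUE, aoi[-1L] != aoi[-length(aoi)]))
    events <- data.frame(
      aoi = aoi[!duplicated(run)],
      enter_ms = enter_ms[!duplicated(run)],
      exit_ms = rev(rev(exit_ms)[!duplicated(rev(run))]),
      dwell_ms = as.vector(tapply(dur, run, sum)),
      stringsAsFactors = FALSE
    )
  } else {
    events <- data.frame(aoi = character(), enter_ms = numeric(),
                         exit_ms = numeric(), dwell_ms = numeric(),
                         stringsAsFactors = FALSE)
  }
  structure(list(participant_id = participant_id, events = events,
                 visits = events$aoi),
            class = "hover_sequence")
}

#' Construct a hover sequence from a visit vector
#'
#' Convenience constructor used by simulations and tests: builds a
#' `hover_sequence` from AOI codes and optional per-visit dwell times.
#' Immediate repeats are collapsed as in [parse_event_log()].
#'
#' @param participant_id Identifier.
#' @param visits Character vector of AOI codes.
#' @param dwell_ms Optional per-visit dwell durations (default 1000 ms
#'   each); visits are laid out back to back from time 0.
#' @return A `hover_sequence`.
#' @export
hover_sequence <- function(participant_id, visits, dwell_ms = NULL) {
  check_aoi(visits)
  n <- length(visits)
  if (is.null(dwell_ms)) dwell_ms <- rep(1000, n)
  stopifnot(length(dwell_ms) == n, all(dwell_ms > 0))
  exit <- cumsum(dwell_ms)
  enter <- if (n > 0L) c(0, exit[-n]) else numeric(0)
  new_hover_sequence(as.character(participant_id), as.character(visits),
                     enter, exit)
}

#' @export
print.hover_sequence <- function(x, ...) {
  cat(sprintf("<hover_sequence> participant %s: %d visits\n",
              x$participant_id, length(x$visits)))
  if (length(x$visits) > 0L) {
    cat("  ", paste(utils::head(x$visits, 20L), collapse = " > "),
        if (length(x$visits) > 20L) " ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Participant validity filter
#'
#' Applies the study's exclusion rules: a participant is excluded if
#' (a) an active ad-blocker was detected (it can corrupt event capture),
#' (b) the question button `Q` was never hovered, or (c) fewer than two
#' distinct information AOIs (excluding `Q`) were hovered -- answering
#' requires at least two pieces of information from the graph.
#'
#' @param seq A `hover_sequence`.
#' @param adblocker_active Logical flag from the participant record.
#' @return A `validity_report` list: `participant_id`, `included`, `reasons`
#'   (character vector drawn from `adblocker_active`,
#'   `question_never_viewed`, `fewer_than_two_info_views`).
#' @export
validity_filter <- function(seq, adblocker_active = FALSE) {
  stopifnot(inherits(seq, "hover_sequence"))
  reasons <- character()
  if (isTRUE(adblocker_active)) reasons <- c(reasons, "adblocker_active")
  if (!"Q" %in% seq$visits) reasons <- c(reasons, "question_never_viewed")
  if (length(setdiff(unique(seq$visits), "Q")) < 2L) {
    reasons <- c(reasons, "fewer_than_two_info_views")
  }
  structure(list(participant_id = seq$participant_id,
                 included = length(reasons) == 0L,
                 reasons = reasons),
            class = "validity_report")
}

#' Dwell-time percentages over the eight AOIs
#'
#' Hover time on each AOI as a percentage of the participant's total hover
#' time over all AOIs. Returned for all 8 AOIs (zeros for unvisited ones);
#' values sum to 100.
#'
#' @param seq A `hover_sequence` with positive total hover time.
#' @return Named numeric vector over [aoi_codes()].
#' @export
dwell_percentages <- function(seq) {
  stopifnot(inherits(seq, "hover_sequence"))
  total <- sum(seq$events$dwell_ms)
  if (!isTRUE(total > 0)) {
    stop("undefined dwell: total hover time is zero", call. = FALSE)
  }
  by_aoi <- vapply(aoi_codes(), function(a) {
    sum(seq$events$dwell_ms[seq$events$aoi == a])
  }, numeric(1))
  100 * by_aoi / total
}

# ---- transition tables -----------------------------------------------------

new_transition_table <- function(counts, scope) {
  total <- sum(counts)
  structure(list(scope = scope, counts = counts, total = total,
                 normalized = if (total > 0) counts / total else counts * 0),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("<transition_table> %s scope, %d transitions\n",
              x$scope, x$total))
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  if (length(top) > 0L) {
    cat("  top: ", paste(names(utils::head(top, 6L)),
                         utils::head(top, 6L), sep = "="), "\n")
  }
  invisible(x)
}

#' Bigram transition counts for one participant
#'
#' Counts consecutive ordered AOI pairs in the collapsed visit sequence.
#' Because immediate repeats are collapsed at parse time, self-pairs cannot
#' occur, and the counts live on the 56-key space of [transition_keys()].
#' An empty or singleton sequence yields an all-zero table.
#'
#' @param seq A `hover_sequence`.
#' @return A participant-scope `transition_table` with fields `counts`
#'   (named integer vector over the 56 keys), `total`, and `normalized`.
#' @export
bigram_transitions <- function(seq) {
  stopifnot(inherits(seq, "hover_sequence"))
  keys <- transition_keys()
  counts <- stats::setNames(integer(length(keys)), keys)
  v <- seq$visits
  if (length(v) >= 2L) {
    pairs <- paste(v[-length(v)], v[-1L], sep = "-")
    tab <- table(pairs)
    counts[names(tab)] <- as.integer(tab)
  }
  new_transition_table(counts, "participant")
}

#' Pool participant transition tables into a group table
#'
#' Sums counts element-wise across participants and renormalises by the
#' group's total transition count, producing the group-level frequency
#' distribution over the 56 transitions.
#'
#' @param tables List of participant-scope `transition_table`s.
#' @return A group-scope `transition_table`.
#' @export
pool_group <- function(tables) {
  if (length(tables) == 0L) stop("empty group", call. = FALSE)
  stopifnot(all(vapply(tables, inherits, logical(1), "transition_table")))
  counts <- Reduce(`+`, lapply(tables, `[[`, "counts"))
  new_transition_table(counts, "group")
}

#' Serialize a transition table to JSON
#'
#' Fixed 56-key ordering (origin slowest, both in [aoi_codes()] order) so
#' exports are byte-stable and diffable.
#'
#' @param table A `transition_table`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
transition_table_json <- function(table, path = NULL) {
  stopifnot(inherits(table, "transition_table"))
  obj <- list(scope = table$scope,
              total = table$total,
              counts = as.list(table$counts[transition_keys()]),
              normalized = as.list(table$normalized[transition_keys()]))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
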