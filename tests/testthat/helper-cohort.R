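# shared fixture builders -- everything is generated in code at test time

# transition tables for n participants simulated from one hover chain
sim_tables <- function(mat, n, stop_param = 0.05) {
  lapply(seq_len(n), function(i) {
    bigram_transitions(markov_sequence(mat, stop_param = stop_param,
                                       participant_id = sprintf("p%03d", i)))
  })
}

# a tiny hand-written event log with two participants
tiny_event_log <- function() {
  data.frame(
    participant_id = c("a", "a", "a", "a", "b", "b"),
    aoi = c("Q", "F", "FA", "nFA", "F", "T"),
    enter_ms = c(0, 1200, 2500, 4000, 0, 900),
    exit_ms = c(1000, 2200, 3500, 5000, 800, 1500),
    stringsAsFactors = FALSE
  )
}

# normalized distribution on the 56-key space concentrated on given keys
dist_on <- function(weights) {
  keys <- transition_keys()
  p <- stats::setNames(numeric(56), keys)
  p[names(weights)] <- weights
  p / sum(p)
}
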