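# internal helpers shared across modules

# round half away from zero; base round() is banker's rounding, which would
# make tree node counts depend on parity of the scaled value
round_half_up <- function(x) floor(x + 0.5)

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

# set.seed only when a seed is supplied; callers restore nothing on purpose
# (all stochastic entry points take an explicit seed)
maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    seed <- check_count(seed, "seed")
    set.seed(seed)
  }
  invisible(seed)
}

# derive a stream of child seeds from one master seed, kept below 2^31
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
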