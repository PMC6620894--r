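#' Areas of interest on the task tree
#'
#' The task diagram exposes eight hideable buttons: the seven data nodes of
#' the two-level tree -- total (`T`), the two first-level branches (`F`,
#' `nF`), the four leaves (`FA`, `FnA`, `nFA`, `nFnA`) -- and the question
#' text (`Q`). All hover analysis is carried out over this fixed sample
#' space.
#'
#' @return Character vector of the 8 AOI codes, in canonical order.
#' @export
#' @examples
#' aoi_codes()
aoi_codes <- function() {
  c("T", "F", "nF", "FA", "FnA", "nFA", "nFnA", "Q")
}

#' Ordered AOI transition pairs
#'
#' All ordered pairs of distinct AOIs (8 x 7 = 56), in canonical order
#' (origin varies slowest, both in the order of [aoi_codes()]). Keys are
#' written `"from-to"`, the notation used for transitions throughout.
#'
#' @return Character vector of 56 transition keys.
#' @export
#' @examples
#' length(transition_keys())
transition_keys <- function() {
  a <- aoi_codes()
  keys <- as.vector(t(outer(a, a, function(x, y) paste(x, y, sep = "-"))))
  keep <- as.vector(t(outer(a, a, "!=")))
  keys[keep]
}

# internal: validate a vector of AOI labels, error on unknown codes
check_aoi <- function(x) {
  bad <- setdiff(unique(as.character(x)), aoi_codes())
  if (length(bad) > 0L) {
    stop("unknown AOI code(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(aoi_codes(), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(as.character(x))
}
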