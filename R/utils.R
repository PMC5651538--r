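#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

#' Deterministic 31-bit stream seed from a base seed and a string label
#'
#' Used to give every drug (or stage) its own reproducible RNG substream so
#' that results do not depend on iteration order.
#' @noRd
substream_seed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(as.character(label))) {
    h <- (h * 131 + v) %% 2147483647
  }
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

#' Run code under a temporary seed, restoring RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Normalize gene symbols: trim whitespace and upper-case
#' @noRd
norm_symbol <- function(x) toupper(trimws(as.character(x)))

#' Organism codes recognized throughout the package
#' @noRd
ORGANISMS <- c("HS", "CE", "DM", "MM", "SC")

#' @noRd
check_organism <- function(organism, allow_hs = TRUE) {
  allowed <- if (allow_hs) ORGANISMS else setdiff(ORGANISMS, "HS")
  if (!is.character(organism) || length(organism) != 1L ||
      !organism %in% allowed) {
    abort(sprintf(
      "`organism` must be one of %s, got %s",
      paste(allowed, collapse = ", "),
      paste(utils::head(as.character(organism), 3), collapse = ", ")
    ))
  }
  invisible(organism)
}
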