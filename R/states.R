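#' Transplanting state vocabulary
#'
#' A transplanted seedling is in exactly one of three states: `normal`
#' (planted at proper depth, leaves fully exposed), `buried_seedling`
#' (planted too deep, leaves partly or fully covered by soil) or
#' `bare_root` (planted too shallow, root substrate exposed to air).
#' All counting and evaluation in this package is stratified by this
#' three-way vocabulary.
#'
#' @return Character vector of the three canonical state labels, in a
#'   fixed order (`normal`, `buried_seedling`, `bare_root`).
#' @export
#' @examples
#' transplant_states()
transplant_states <- function() {
  c("normal", "buried_seedling", "bare_root")
}

# Accepted spellings mapped to canonical labels. Matching is
# case-insensitive and tolerant of space/hyphen separators so that
# annotation files written by different hands parse identically.
.state_aliases <- c(
  normal          = "normal",
  buried_seedling = "buried_seedling",
  buried          = "buried_seedling",
  barried_seedling = "buried_seedling",
  bare_root       = "bare_root",
  bareroot        = "bare_root"
)

#' Canonicalize transplanting state labels
#'
#' Maps free-form class names (case-insensitive, with `-`, `space` or `_`
#' separators) onto the canonical lower-snake vocabulary of
#' [transplant_states()].
#'
#' @param x Character vector of state labels.
#' @return Character vector of canonical labels, same length as `x`.
#' @export
#' @examples
#' canonical_state(c("Normal", "Buried Seedling", "bare-root"))
canonical_state <- function(x) {
  key <- gsub("[ -]+", "_", tolower(trimws(as.character(x))))
  out <- unname(.state_aliases[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown transplanting state label(s): ",
         paste(sQuote(bad), collapse = ", "),
         "; expected one of ", paste(transplant_states(), collapse = ", "),
         call. = FALSE)
  }
  out
}
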