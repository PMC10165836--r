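#' Canonical SBS96 mutation-type labels
#'
#' The 96 single-base-substitution contexts in canonical catalog order:
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G, and within each class
#' the 5' flanking base A, C, G, T (slow) crossed with the 3' flanking base
#' A, C, G, T (fast).  Labels use the `"A[C>A]A"` notation.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs96_types())
sbs96_types <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  base <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    paste0(rep(base, each = 4), "[", s, "]", rep(base, times = 4))
  }))
}

# Order indices mapping a vector of mutation-type labels onto canonical order.
# Errors on labels outside the SBS96 set or duplicates.
sbs96_order <- function(types) {
  canon <- sbs96_types()
  unknown <- setdiff(types, canon)
  if (length(unknown) > 0) {
    stop("unrecognized mutation-type label(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (anyDuplicated(types)) {
    stop("duplicate mutation-type labels")
  }
  if (length(types) != 96) {
    stop("expected 96 mutation types, got ", length(types))
  }
  match(canon, types)
}
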