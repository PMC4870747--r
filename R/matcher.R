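# R surface of the element matchers.  Coordinates are 1-based inclusive
# throughout the user-facing API; an empty match at position s is the
# interval [s, s-1].

#' Search domain for one element
#'
#' Constrains where an element may match: the match must start inside
#' \code{start}, end inside \code{end}, and (when \code{cover} is given)
#' completely contain \code{cover}.  An empty interval (lo > hi) makes the
#' domain empty: no matches by definition.
#'
#' @param start,end length-2 numeric vectors \code{c(lo, hi)}.
#' @param cover optional length-2 numeric vector; \code{NULL} for none.
#' @return a \code{search_domain} object.
#' @export
search_domain <- function(start, end, cover = NULL) {
  stopifnot(length(start) == 2L, length(end) == 2L)
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 cover = if (!is.null(cover)) as.numeric(cover)),
            class = "search_domain")
}

# Whole-text domain (empty matches allowed at either edge).
full_domain <- function(n) search_domain(c(1, n + 1), c(0, n))

domain_empty <- function(d) d$start[1] > d$start[2] || d$end[1] > d$end[2]

dom_vec <- function(d) {
  cov <- if (is.null(d$cover)) c(-1L, -1L) else as.integer(d$cover)
  as.integer(c(d$start, d$end, cov))
}

#' Match a single-stranded element in a text window
#'
#' Exact dynamic programming over (text position, pattern position,
#' mismatches, insertions).  Returns every distinct interval that admits a
#' left-to-right alignment of the pattern within the distortion budgets and
#' the domain, each with the lexicographically minimal
#' (mismatches, insertions) over its alignments.  Wildcards match one
#' arbitrary nucleotide or the empty string; mismatches are chargeable only
#' at non-wildcard tokens; insertions consume one text base between two
#' consumed tokens.  An N in the text matches only the fully degenerate
#' class.
#'
#' @param spec an \code{ss_spec} (see \code{\link{parse_descriptor}}).
#' @param text a normalized A,C,G,T,N string, or an integer-encoded text.
#' @param domain a \code{\link{search_domain}}; default: the whole text.
#' @return integer matrix with columns start, end, mismatches, insertions,
#'   sorted by (start, end); zero rows when there is no match.
#' @export
match_single <- function(spec, text, domain = NULL) {
  stopifnot(inherits(spec, "ss_spec"))
  enc <- if (is.character(text)) encode_seq(text) else as.integer(text)
  if (is.null(domain)) domain <- full_domain(length(enc))
  if (domain_empty(domain))
    return(matrix(integer(0), 0, 4,
                  dimnames = list(NULL, c("start", "end", "mismatches",
                                          "insertions"))))
  dv <- dom_vec(domain)
  .dp_match_single(enc, spec$masks, spec$max_mismatch, spec$max_insert,
                   dv[1], dv[2], dv[3], dv[4], dv[5], dv[6])
}

#' Match a helical element in a text window
#'
#' Finds all (5' interval, 3' interval) pairs admitting a column alignment
#' of the two strand patterns with at most \code{max_mismatch} sequence
#' mismatches (summed over both strands), \code{max_mispair} aligned columns
#' whose base pair is not in the allowed set, and \code{max_insert}
#' single-base bulges on either strand, no two adjacent.  Both-wildcard
#' columns may be skipped (variable helix length).  Each distinct interval
#' pair carries the lexicographically minimal (mismatches, mispairs,
#' insertions).
#'
#' @param spec a \code{helix_spec}.
#' @param text normalized string or integer-encoded text.
#' @param domain5,domain3 \code{\link{search_domain}}s for the two strands;
#'   default: the whole text.
#' @param gap optional length-2 vector bounding the number of text bases
#'   strictly between the 5' and 3' strand intervals (used by the engine to
#'   enforce the length of the intervening motif elements); \code{NULL} for
#'   unbounded.
#' @return integer matrix with columns start5, end5, start3, end3,
#'   mismatches, mispairs, insertions, sorted by (start5, end5, start3,
#'   end3).
#' @export
match_helix <- function(spec, text, domain5 = NULL, domain3 = NULL,
                        gap = NULL) {
  stopifnot(inherits(spec, "helix_spec"))
  enc <- if (is.character(text)) encode_seq(text) else as.integer(text)
  n <- length(enc)
  if (is.null(domain5)) domain5 <- search_domain(c(1, n), c(1, n))
  if (is.null(domain3)) domain3 <- search_domain(c(1, n), c(1, n))
  empty <- matrix(integer(0), 0, 7,
                  dimnames = list(NULL, c("start5", "end5", "start3", "end3",
                                          "mismatches", "mispairs",
                                          "insertions")))
  if (domain_empty(domain5) || domain_empty(domain3)) return(empty)
  g <- if (is.null(gap)) c(-1L, -1L) else as.integer(gap)
  res <- .dp_match_helix(enc, spec$masks5, spec$masks3, spec$pairs,
                         spec$max_mismatch, spec$max_mispair, spec$max_insert,
                         dom_vec(domain5), dom_vec(domain3), g[1], g[2])
  if (nrow(res) > 1L)
    res <- res[order(res[, 1], res[, 2], res[, 3], res[, 4]), , drop = FALSE]
  res
}

#' Bit-parallel prefilter for single-stranded elements
#'
#' Returns a superset of the end positions of true matches inside the
#' domain; restricting \code{\link{match_single}} to these end positions
#' yields the same match set (equivalence contract).  Patterns without
#' wildcards or distortion budgets are filtered exactly by a shift-and
#' automaton over class bitmasks; for all other patterns every domain
#' position is returned (trivially a superset).
#'
#' @param spec an \code{ss_spec}.
#' @param text normalized string or integer-encoded text.
#' @param domain a \code{\link{search_domain}}.
#' @return sorted integer vector of candidate end positions.
#' @export
prefilter_positions <- function(spec, text, domain = NULL) {
  enc <- if (is.character(text)) encode_seq(text) else as.integer(text)
  n <- length(enc)
  if (is.null(domain)) domain <- full_domain(n)
  if (domain_empty(domain)) return(integer(0))
  e_rng <- max(domain$end[1], 0):min(domain$end[2], n)
  e_rng <- e_rng[e_rng >= 0]
  K <- length(spec$masks)
  exactish <- spec$max_mismatch == 0L && spec$max_insert == 0L &&
    all(spec$masks != 0L) && K <= 30L
  if (!exactish || K == 0L) return(as.integer(e_rng))
  # shift-and: state bit k-1 set iff pattern prefix of length k ends here
  accept <- lapply(0:4, function(b) {
    vapply(spec$masks, function(m) in_class_r(b, m), logical(1))
  })
  state <- rep(FALSE, K)
  hits <- logical(n)
  for (t in seq_len(n)) {
    acc <- accept[[enc[t] + 1L]]
    state <- c(TRUE, state[-K]) & acc
    hits[t] <- state[K]
  }
  pos <- e_rng[e_rng >= 1]
  as.integer(pos[hits[pos]])
}

# R-side mirror of the C++ class membership rule.
in_class_r <- function(b, mask) {
  if (mask == 0L) return(b < 4L)
  if (b == 4L) return(mask == 15L)
  bitwAnd(bitwShiftR(mask, b), 1L) > 0L
}
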