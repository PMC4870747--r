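# Windowed backtracking search.
#
# The sequence is cut into windows of size max(20 L, 3000) overlapping by L
# (the maximum occurrence length), so every occurrence lies completely
# inside at least one window.  Within a window, elements are matched one by
# one in a search order; each new element is restricted to a search domain
# derived from the nearest already-fixed occurrences on its left and right
# and the length flexibility of the elements between.  The element order
# changes the running time, never the result set.

#' Window size rule
#'
#' @param L maximum occurrence length of the descriptor.
#' @return \code{max(20 * L, 3000)}.
#' @export
window_size <- function(L) max(20 * L, 3000)

#' Partition a sequence into overlapping search windows
#'
#' Windows have length \code{W = max(20 L, 3000)} (override with
#' \code{width}), start at 1, advance by \code{W - L} and overlap by exactly
#' \code{L}; the last window is truncated at the sequence end.  Every
#' substring of length at most \code{L} is fully contained in at least one
#' window.
#'
#' @param seq_len sequence length (>= 1).
#' @param L maximum occurrence length (>= 1).
#' @param width optional window-size override; must exceed \code{L} unless a
#'   single window covers the sequence.
#' @return integer matrix with columns start, end (1-based inclusive).
#' @export
make_windows <- function(seq_len, L, width = NULL) {
  stopifnot(seq_len >= 1, L >= 1)
  W <- if (is.null(width)) window_size(L) else width
  if (W >= seq_len) return(cbind(start = 1L, end = as.integer(seq_len)))
  if (W <= L) stop("window size must exceed L = ", L)
  starts <- 1
  while (starts[length(starts)] + W - 1 < seq_len)
    starts <- c(starts, starts[length(starts)] + W - L)
  ends <- pmin(starts + W - 1, seq_len)
  # drop a final window fully contained in the previous one
  keep <- c(TRUE, ends[-1] > ends[-length(ends)])
  cbind(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

# Sums of per-occurrence min/max lengths over a range of map positions
# (empty range -> 0).
occ_len_sums <- function(desc, from, to) {
  if (from > to) return(c(min = 0, max = 0))
  c(min = sum(desc$occ$min_len[from:to]), max = sum(desc$occ$max_len[from:to]))
}

# Domain of one map occurrence given fixed occurrence intervals.
# `fixed_iv` is an n_occ x 2 matrix with NA rows for unfixed occurrences;
# `extra` optionally marks one more occurrence index as fixed with the given
# interval (used for the other strand of a helix target).
occ_domain <- function(desc, fixed_iv, q, window_len) {
  n_occ <- nrow(desc$occ)
  is_fixed <- !is.na(fixed_iv[, 1])

  left <- if (q > 1) { w <- which(is_fixed[1:(q - 1)]); if (length(w)) max(w) else 0L } else 0L
  right <- if (q < n_occ) { w <- which(is_fixed[(q + 1):n_occ]); if (length(w)) q + min(w) else 0L } else 0L

  if (left > 0L) {
    E <- fixed_iv[left, 2]
    sums <- occ_len_sums(desc, left + 1L, q - 1L)
    s_rng <- c(E + 1 + sums["min"], E + 1 + sums["max"])
  } else {
    sums <- occ_len_sums(desc, 1L, q - 1L)
    s_rng <- c(1 + sums["min"], Inf)
  }
  if (right > 0L) {
    S <- fixed_iv[right, 1]
    sums <- occ_len_sums(desc, q + 1L, right - 1L)
    e_rng <- c(S - 1 - sums["max"], S - 1 - sums["min"])
  } else {
    sums <- occ_len_sums(desc, q + 1L, n_occ)
    e_rng <- c(-Inf, window_len - sums["min"])
  }
  minl <- desc$occ$min_len[q]
  if (!is.finite(s_rng[2])) s_rng[2] <- e_rng[2] - minl + 1
  if (!is.finite(e_rng[1])) e_rng[1] <- s_rng[1] + minl - 1
  cover <- if (left > 0L && right > 0L && s_rng[2] <= e_rng[1])
    c(s_rng[2], e_rng[1])
  s_rng <- c(max(s_rng[1], 1), min(s_rng[2], window_len + 1))
  e_rng <- c(max(e_rng[1], 0), min(e_rng[2], window_len))
  search_domain(s_rng, e_rng, cover)
}

#' Search domain of an element given partially fixed matches
#'
#' For a single-stranded element, the returned domain is derived from the
#' nearest fixed occurrences on each side: the match must start right after
#' the left neighbour plus the min/max total length of the unfixed elements
#' between, and symmetrically for the end; with no fixed neighbour on a side
#' the window edge bounds it.  For a helix, a domain per strand is returned
#' together with a joint bound on the number of bases between the strands
#' (the total length of the map occurrences separating them) whenever no
#' fixed occurrence lies in between.  Domains are sound: they never exclude
#' a placement that extends to a full motif occurrence.
#'
#' @param desc a \code{motif_descriptor}.
#' @param fixed named list mapping fixed element tags to their match rows
#'   (length-2 vector \code{c(start, end)} for singles, length-4
#'   \code{c(start5, end5, start3, end3)} for helices).
#' @param target tag of the element to be placed next.
#' @param window_len window length.
#' @return for a single: a \code{\link{search_domain}}; for a helix: a list
#'   with components \code{domain5}, \code{domain3}, \code{gap}.
#' @export
compute_search_domain <- function(desc, fixed, target, window_len) {
  occ <- desc$occ
  n_occ <- nrow(occ)
  fixed_iv <- matrix(NA_real_, n_occ, 2)
  for (tg in names(fixed)) {
    m <- fixed[[tg]]
    w <- which(occ$elem == tg)
    if (length(m) == 2L) {
      fixed_iv[w, ] <- m
    } else {
      fixed_iv[w[1], ] <- m[1:2]
      fixed_iv[w[2], ] <- m[3:4]
    }
  }
  sp <- desc$specs[[target]]
  if (sp$kind == "single") {
    q <- which(occ$elem == target)
    return(occ_domain(desc, fixed_iv, q, window_len))
  }
  qs <- which(occ$elem == target)
  q5 <- qs[1]; q3 <- qs[2]
  # each strand's domain treats the other strand as unfixed; the joint gap
  # constraint ties them together when nothing in between is fixed
  d5 <- occ_domain(desc, fixed_iv, q5, window_len)
  d3 <- occ_domain(desc, fixed_iv, q3, window_len)
  gap <- NULL
  between <- if (q5 + 1L <= q3 - 1L) (q5 + 1L):(q3 - 1L) else integer(0)
  if (!length(between) || !any(!is.na(fixed_iv[between, 1]))) {
    sums <- occ_len_sums(desc, q5 + 1L, q3 - 1L)
    gap <- c(sums["min"], sums["max"])
  }
  list(domain5 = d5, domain3 = d3, gap = gap)
}

#' Backtracking search of one window
#'
#' Matches elements in the given order, computing a search domain for each
#' from the already fixed matches, and emits every complete assignment of
#' intervals to the map occurrences (distinct interval tuples).  The result
#' is independent of \code{order}.
#'
#' @param window_text the window's bases (normalized string) or an
#'   integer-encoded text.
#' @param desc a \code{motif_descriptor}.
#' @param order a permutation of the element tags; default: map order.
#' @return list of occurrences; each is an integer matrix with one row per
#'   map occurrence (rownames = occurrence tags) and columns start, end, in
#'   window-local coordinates.
#' @export
backtrack_window <- function(window_text, desc, order = NULL) {
  enc <- if (is.character(window_text)) encode_seq(window_text)
         else as.integer(window_text)
  n <- length(enc)
  if (is.null(order)) order <- desc$elements
  stopifnot(setequal(order, desc$elements),
            length(order) == length(desc$elements))
  occ <- desc$occ
  results <- list()

  emit <- function(fixed) {
    iv <- matrix(NA_integer_, nrow(occ), 2,
                 dimnames = list(occ$occurrence, c("start", "end")))
    for (tg in names(fixed)) {
      m <- fixed[[tg]]
      w <- which(occ$elem == tg)
      if (length(m) == 2L) iv[w, ] <- as.integer(m)
      else { iv[w[1], ] <- as.integer(m[1:2]); iv[w[2], ] <- as.integer(m[3:4]) }
    }
    results[[length(results) + 1L]] <<- iv
  }

  rec <- function(fixed, depth) {
    if (depth > length(order)) { emit(fixed); return(invisible()) }
    tg <- order[depth]
    sp <- desc$specs[[tg]]
    if (sp$kind == "single") {
      dom <- compute_search_domain(desc, fixed, tg, n)
      ms <- match_single(sp, enc, dom)
      for (k in seq_len(nrow(ms))) {
        fixed[[tg]] <- ms[k, 1:2]
        rec(fixed, depth + 1L)
      }
    } else {
      dm <- compute_search_domain(desc, fixed, tg, n)
      ms <- match_helix(sp, enc, dm$domain5, dm$domain3, dm$gap)
      for (k in seq_len(nrow(ms))) {
        fixed[[tg]] <- ms[k, 1:4]
        rec(fixed, depth + 1L)
      }
    }
    invisible()
  }
  rec(list(), 1L)
  results
}

occurrence_key <- function(iv) paste(t(iv), collapse = ",")

# span over non-empty intervals (an empty interval [s, s-1] has no extent)
occurrence_span <- function(iv) {
  nonempty <- iv[, 2] >= iv[, 1]
  if (!any(nonempty)) return(c(iv[1, 1], iv[1, 1] - 1L))
  c(min(iv[nonempty, 1]), max(iv[nonempty, 2]))
}
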