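# Exhaustive brute-force search oracle.
#
# Enumerates ALL assignments of contiguous intervals to the map occurrences
# in 5'->3' order and tests each element placement by plain recursive
# alignment enumeration — no dynamic programming tables, no search domains,
# no windows.  Deliberately independent of the engine: any disagreement is
# an engine (or oracle) bug.  Guarded against accidental blow-up.

# Does the pattern align to EXACTLY this substring within the budgets?
oracle_single_exact <- function(masks, text_enc, m, imax) {
  n <- length(text_enc)
  K <- length(masks)
  rec <- function(ti, pi, mm, ins, pending) {
    if (pi > K) return(!pending && ti == n + 1L)
    # insertion before the next token (internal: needs a consumed char
    # before and a consuming token after)
    if (pi > 1L && ti > 1L && ti <= n && ins < imax &&
        rec(ti + 1L, pi, mm, ins + 1L, TRUE)) return(TRUE)
    mask <- masks[pi]
    if (mask == 0L) {
      if (rec(ti, pi + 1L, mm, ins, pending)) return(TRUE)      # skip
      if (ti <= n && rec(ti + 1L, pi + 1L, mm, ins, FALSE)) return(TRUE)
    } else if (ti <= n) {
      miss <- if (in_class_r(text_enc[ti], mask)) 0L else 1L
      if (mm + miss <= m && rec(ti + 1L, pi + 1L, mm + miss, ins, FALSE))
        return(TRUE)
    }
    FALSE
  }
  rec(1L, 1L, 0L, 0L, FALSE)
}

# Do the two substrings form the helix exactly (all bases consumed)?
oracle_helix_exact <- function(spec, enc5, enc3) {
  K <- length(spec$masks5)
  n5 <- length(enc5); n3 <- length(enc3)
  mand <- helix_mandatory(spec)
  # i5: next 5' index from the left; i3: next 3' index from the RIGHT
  # (column 1 pairs the last base of the 3' substring)
  rec <- function(j, i5, i3, consumed, mm, mp, ins, bf) {
    if (j > K)
      return(!bf && consumed >= 1L && i5 == n5 + 1L && i3 == n3 + 1L)
    # bulges between consumed columns, never adjacent
    if (consumed >= 1L && !bf && ins < spec$max_insert) {
      if (i5 <= n5 && rec(j, i5 + 1L, i3, consumed, mm, mp, ins + 1L, TRUE))
        return(TRUE)
      if (i3 <= n3 && rec(j, i5, i3 + 1L, consumed, mm, mp, ins + 1L, TRUE))
        return(TRUE)
    }
    if (!mand[j] && rec(j + 1L, i5, i3, consumed, mm, mp, ins, bf))
      return(TRUE)
    if (i5 <= n5 && i3 <= n3) {
      x <- enc5[i5]
      y <- enc3[n3 + 1L - i3]
      madd <- (spec$masks5[j] != 0L && !in_class_r(x, spec$masks5[j])) +
              (spec$masks3[j] != 0L && !in_class_r(y, spec$masks3[j]))
      padd <- if (x < 4L && y < 4L && spec$pairs[x + 1L, y + 1L]) 0L else 1L
      if (mm + madd <= spec$max_mismatch && mp + padd <= spec$max_mispair &&
          rec(j + 1L, i5 + 1L, i3 + 1L, consumed + 1L, mm + madd, mp + padd,
              ins, FALSE))
        return(TRUE)
    }
    FALSE
  }
  rec(1L, 1L, 1L, 0L, 0L, 0L, 0L, FALSE)
}

#' Brute-force motif search (oracle)
#'
#' Enumerates every assignment of contiguous intervals to the motif map and
#' validates each element by exhaustive alignment enumeration.  Exponential:
#' refuses texts longer than \code{max_text} or descriptors with more than
#' \code{max_elems} elements.
#'
#' @param desc a \code{motif_descriptor}.
#' @param text a normalized sequence string.
#' @param max_text,max_elems instance-size guards.
#' @return list of occurrences in the same format as
#'   \code{\link{backtrack_window}} (interval matrices, sorted by tuple).
#' @export
brute_force_search <- function(desc, text, max_text = 250L, max_elems = 6L) {
  if (nchar(text) > max_text)
    stop("oracle refuses texts longer than ", max_text, " nt")
  if (length(desc$elements) > max_elems)
    stop("oracle refuses descriptors with more than ", max_elems, " elements")
  enc <- encode_seq(text)
  n <- length(enc)
  occ <- desc$occ
  n_occ <- nrow(occ)
  results <- list()

  rec <- function(q, pos, iv, helix_first) {
    if (q > n_occ) {
      m <- matrix(as.integer(t(iv)), n_occ, 2, byrow = TRUE,
                  dimnames = list(occ$occurrence, c("start", "end")))
      results[[length(results) + 1L]] <<- m
      return(invisible())
    }
    tg <- occ$elem[q]
    sp <- desc$specs[[tg]]
    for (len in occ$min_len[q]:occ$max_len[q]) {
      e <- pos + len - 1L
      if (e > n) break
      if (sp$kind == "single") {
        if (!oracle_single_exact(sp$masks, enc[seq_len(len) + pos - 1L],
                                 sp$max_mismatch, sp$max_insert)) next
      } else if (!occ$primed[q]) {
        # defer validation until the primed strand is placed
        helix_first[[tg]] <- c(pos, e)
      } else {
        f <- helix_first[[tg]]
        sub5 <- enc[f[1]:f[2]]
        sub3 <- if (len >= 1L) enc[pos:e] else integer(0)
        if (f[2] >= pos) next   # strands must not overlap
        if (!oracle_helix_exact(sp, sub5, sub3)) next
      }
      iv[q, ] <- c(pos, e)
      rec(q + 1L, e + 1L, iv, helix_first)
    }
    invisible()
  }

  iv0 <- matrix(NA_integer_, n_occ, 2)
  for (s0 in seq_len(n + 1L)) rec(1L, s0, iv0, list())

  # sort and deduplicate by interval tuple
  if (length(results)) {
    keys <- vapply(results, occurrence_key, "")
    results <- results[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
    spans <- t(vapply(results, occurrence_span, numeric(2)))
    results <- results[order(spans[, 1], spans[, 2], keys)]
  }
  results
}
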