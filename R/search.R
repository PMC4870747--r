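# Top-level motif search over full sequences and both strands.

#' Search sequences for a motif
#'
#' Scans each sequence (and optionally its reverse complement) in
#' overlapping windows with the backtracking search, deduplicates
#' occurrences found in more than one window, and returns one row per
#' occurrence.  Reverse-strand hits are found by scanning the reverse
#' complement and reported with strand \code{"-"} and forward-axis
#' coordinates.
#'
#' @param desc a \code{motif_descriptor}.
#' @param sequences named character vector of sequences (use
#'   \code{\link{read_fasta}} for files); unnamed sequences are named
#'   \code{seq1, seq2, ...}.
#' @param strand \code{"+"}, \code{"-"} or \code{"both"}.
#' @param order_mode \code{"auto"} (the descriptor's fixed order if present,
#'   else DDEO), \code{"user"}, \code{"heuristic"} (best-scoring tuple
#'   completed by information content, no timing) or \code{"ddeo"}.
#' @param order explicit search order (overrides everything else).
#' @param window_size optional window-size override (must exceed the
#'   descriptor's maximum occurrence length L).
#' @param collapse_spans report one occurrence per distinct span (the first
#'   interval tuple in sort order) instead of every interval tuple.
#' @param weights a \code{\link{heuristic_weights}}.
#' @param timer optional timing stub forwarded to \code{\link{ddeo_order}}.
#' @param seed optional integer seed for the DDEO candidate draws.
#' @return a data frame of class \code{motif_hits} with columns
#'   \code{seq_id}, \code{strand}, \code{span_start}, \code{span_end} and a
#'   list column \code{parts} holding, per hit, a data frame with one row
#'   per map occurrence (tag, start, end, seq).  The search order actually
#'   used is in \code{attr(x, "order")}.
#' @export
motif_search <- function(desc, sequences,
                         strand = c("+", "-", "both"),
                         order_mode = c("auto", "user", "heuristic", "ddeo"),
                         order = NULL, window_size = NULL,
                         collapse_spans = FALSE,
                         weights = heuristic_weights(), timer = NULL,
                         seed = NULL) {
  stopifnot(inherits(desc, "motif_descriptor"))
  strand <- match.arg(strand)
  order_mode <- match.arg(order_mode)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    names(sequences) <- paste0("seq", seq_along(sequences))
  keep <- nchar(sequences) > 0L
  if (!all(keep)) {
    warning("skipping ", sum(!keep), " empty sequence(s)")
    sequences <- sequences[keep]
  }
  sequences <- vapply(sequences, normalize_sequence, "", USE.NAMES = TRUE)

  strands <- switch(strand, "+" = "+", "-" = "-", both = c("+", "-"))

  # fixed search order, unless DDEO decides it online
  use_ddeo <- FALSE
  if (!is.null(order)) {
    fixed_order <- order
  } else if (order_mode == "user") {
    if (is.null(desc$user_order))
      stop("descriptor has no fixed search order")
    fixed_order <- desc$user_order
  } else if (order_mode == "heuristic") {
    fixed_order <- propose_candidates(desc, weights)[[1]]$order
  } else if (order_mode == "auto" && !is.null(desc$user_order)) {
    fixed_order <- desc$user_order
  } else {
    use_ddeo <- TRUE
    fixed_order <- NULL
    ddeo_st <- ddeo_state_new(desc, weights)
  }

  rows <- list()
  for (sid in names(sequences)) {
    fwd <- sequences[[sid]]
    n <- nchar(fwd)
    for (std in strands) {
      text <- if (std == "+") fwd else revcomp(fwd)
      wins <- make_windows(n, desc$L, window_size)
      seen <- new.env(parent = emptyenv())
      for (w in seq_len(nrow(wins))) {
        wtext <- substr(text, wins[w, 1], wins[w, 2])
        if (use_ddeo) {
          step <- ddeo_step(ddeo_st, wtext, timer)
          ddeo_st <- step$state
          occs <- step$occurrences
        } else {
          occs <- backtrack_window(wtext, desc, fixed_order)
        }
        off <- wins[w, 1] - 1L
        for (iv in occs) {
          iv[, ] <- iv + off
          key <- occurrence_key(iv)
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          rows[[length(rows) + 1L]] <-
            occurrence_row(desc, sid, std, iv, text, n)
        }
      }
    }
  }

  final_order <- if (use_ddeo) ddeo_current_order(ddeo_st) else fixed_order
  hits <- assemble_hits(rows, desc, collapse_spans)
  attr(hits, "order") <- final_order
  attr(hits, "descriptor") <- desc$name
  hits
}

# Build one result row from a window-absolute interval matrix (coordinates
# on the scanned strand axis; converted to forward axis for '-').
occurrence_row <- function(desc, sid, std, iv, scanned_text, n) {
  tags <- rownames(iv)
  seqs <- vapply(seq_len(nrow(iv)), function(r) {
    if (iv[r, 2] < iv[r, 1]) "" else substr(scanned_text, iv[r, 1], iv[r, 2])
  }, "")
  if (std == "-") {
    iv <- cbind(n - iv[, 2] + 1L, n - iv[, 1] + 1L)
  }
  sp <- occurrence_span(cbind(iv[, 1], iv[, 2]))
  list(seq_id = sid, strand = std, span_start = sp[1], span_end = sp[2],
       parts = data.frame(tag = tags, start = iv[, 1], end = iv[, 2],
                          seq = seqs, stringsAsFactors = FALSE))
}

assemble_hits <- function(rows, desc, collapse_spans) {
  if (!length(rows)) {
    out <- data.frame(seq_id = character(0), strand = character(0),
                      span_start = integer(0), span_end = integer(0))
    out$parts <- list()
    class(out) <- c("motif_hits", "data.frame")
    return(out)
  }
  out <- data.frame(
    seq_id = vapply(rows, `[[`, "", "seq_id"),
    strand = vapply(rows, `[[`, "", "strand"),
    span_start = vapply(rows, function(r) as.integer(r$span_start), integer(1)),
    span_end = vapply(rows, function(r) as.integer(r$span_end), integer(1)),
    stringsAsFactors = FALSE)
  out$parts <- lapply(rows, `[[`, "parts")
  tuple_key <- vapply(rows, function(r)
    paste(r$parts$start, r$parts$end, collapse = ","), "")
  ord <- order(out$seq_id, out$strand, out$span_start, out$span_end, tuple_key)
  out <- out[ord, , drop = FALSE]
  if (collapse_spans) {
    k <- paste(out$seq_id, out$strand, out$span_start, out$span_end)
    out <- out[!duplicated(k), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' @export
print.motif_hits <- function(x, ...) {
  cat("Motif hits: ", nrow(x), " occurrence(s)",
      if (!is.null(attr(x, "descriptor")))
        paste0(" of '", attr(x, "descriptor"), "'"), "\n", sep = "")
  if (!is.null(attr(x, "order")))
    cat("  search order: ", paste(attr(x, "order"), collapse = " "), "\n",
        sep = "")
  if (nrow(x)) {
    df <- x[, c("seq_id", "strand", "span_start", "span_end")]
    print.data.frame(utils::head(df, 20))
    if (nrow(x) > 20) cat("  ... and ", nrow(x) - 20, " more\n", sep = "")
  }
  invisible(x)
}
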