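# FASTA input and hit-table output.

#' Read sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased, U converted to T, and any other non-ACGTN
#' character replaced by N with a counted warning; records with empty
#' sequences are skipped with a warning.
#'
#' @param path path to a (possibly multi-record, wrapped) FASTA file.
#' @return named character vector of normalized sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, "", 1L)
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    warning("skipping ", sum(empty), " record(s) with empty sequence: ",
            paste(names(seqs)[empty], collapse = ", "))
    seqs <- seqs[!empty]
  }
  if (!length(seqs)) stop("no non-empty FASTA records in ", path)
  vapply(seqs, normalize_sequence, "", USE.NAMES = TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a hit table
#'
#' TSV with one row per occurrence: seq_id, strand, span_start, span_end,
#' then one column per map occurrence formatted \code{tag=start..end/SEQ}.
#' Header lines (\code{#}-prefixed) record the descriptor name, the search
#' order used, the seed and the package version, so identical inputs yield
#' byte-identical output.  \code{format = "text"} prints an aligned
#' per-occurrence block instead.
#'
#' @param hits a \code{motif_hits} data frame from
#'   \code{\link{motif_search}}.
#' @param path output file or \code{""} for stdout.
#' @param seed the seed used for the run (recorded in the header).
#' @param format \code{"tsv"} or \code{"text"}.
#' @export
write_hits <- function(hits, path = "", seed = NA, format = c("tsv", "text")) {
  format <- match.arg(format)
  con <- if (nzchar(path)) file(path, "w") else stdout()
  if (nzchar(path)) on.exit(close(con))
  ord <- attr(hits, "order")
  writeLines(c(
    paste0("# descriptor: ", attr(hits, "descriptor") %||% "motif"),
    paste0("# order: ", if (is.null(ord)) "-" else paste(ord, collapse = " ")),
    paste0("# seed: ", seed),
    paste0("# version: knotscan ",
           as.character(utils::packageVersion("knotscan")))), con)
  if (format == "tsv") {
    tags <- if (nrow(hits)) hits$parts[[1]]$tag else character(0)
    writeLines(paste(c("seq_id", "strand", "span_start", "span_end", tags),
                     collapse = "\t"), con)
    for (i in seq_len(nrow(hits))) {
      p <- hits$parts[[i]]
      cells <- paste0(p$tag, "=", p$start, "..", p$end, "/", p$seq)
      writeLines(paste(c(hits$seq_id[i], hits$strand[i], hits$span_start[i],
                         hits$span_end[i], cells), collapse = "\t"), con)
    }
  } else {
    for (i in seq_len(nrow(hits))) {
      p <- hits$parts[[i]]
      writeLines(c(
        paste0(">", hits$seq_id[i], " ", hits$strand[i], " ",
               hits$span_start[i], "..", hits$span_end[i]),
        paste(format(p$tag, width = 6), format(p$start, width = 8),
              format(p$end, width = 8), p$seq)), con)
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
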