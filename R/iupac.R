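# IUPAC nucleotide classes and sequence encoding shared by all modules.
# Internal base encoding: A=0, C=1, G=2, T=3, N=4 (ambiguous).
# A class is a bitmask over ACGT (A=1, C=2, G=4, T=8); mask 0 marks the
# wildcard token `*`, mask 15 the fully degenerate class N.

IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)

IUPAC_MASKS <- vapply(IUPAC_BASES, function(b) sum(.base_bit[b]), integer(1))

#' Base set of an IUPAC code
#'
#' @param code a single IUPAC nucleotide character (U is an alias for T).
#' @return character vector of unambiguous bases (subset of A,C,G,T).
#' @export
iupac_bases <- function(code) {
  b <- IUPAC_BASES[[toupper(code)]]
  if (is.null(b)) stop("not an IUPAC nucleotide code: '", code, "'")
  b
}

# Map a pattern token (IUPAC char or "*") to its bitmask; "*" -> 0L.
token_mask <- function(tok) {
  if (tok == "*") return(0L)
  m <- IUPAC_MASKS[toupper(tok)]
  if (is.na(m)) stop("invalid pattern character '", tok, "'")
  unname(m)
}

# Encode a base string to integers A=0 C=1 G=2 T=3 N=4 (input already
# normalized: uppercase, T not U, unknowns as N).
encode_seq <- function(s) {
  v <- utf8ToInt(s)
  out <- rep.int(4L, length(v))
  out[v == 65L] <- 0L  # A
  out[v == 67L] <- 1L  # C
  out[v == 71L] <- 2L  # G
  out[v == 84L] <- 3L  # T
  out
}

decode_seq <- function(x) {
  intToUtf8(c(65L, 67L, 71L, 84L, 78L)[x + 1L])
}

#' Normalize a nucleotide sequence
#'
#' Uppercases, converts U to T, and replaces any character outside
#' A,C,G,T,N by N.  Used on every sequence entering the search.
#'
#' @param s a character string.
#' @param warn emit a warning counting replaced characters.
#' @return normalized string over A,C,G,T,N.
#' @export
normalize_sequence <- function(s, warn = TRUE) {
  s <- chartr("u", "t", toupper(s))
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad)) {
    if (warn) warning(nchar(bad), " non-ACGTN character(s) replaced by N")
    s <- gsub("[^ACGTN]", "N", s)
  }
  s
}

#' Reverse complement
#'
#' N stays N; input must be a normalized A,C,G,T,N string.
#'
#' @param s a character string over A,C,G,T,N.
#' @return the reverse complement string.
#' @export
revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Parse a comma-separated base-pair list like "AT,TA,CG,GC,GT,TG" into a
# 4x4 logical matrix indexed [five_prime_base, three_prime_base].
parse_pairs <- function(txt) {
  toks <- strsplit(gsub("\\s", "", chartr("Uu", "Tt", toupper(txt))), ",")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("empty base-pair list")
  mat <- matrix(FALSE, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  for (p in toks) {
    if (nchar(p) != 2L || !all(strsplit(p, "")[[1]] %in% c("A","C","G","T")))
      stop("malformed base pair '", p, "'")
    mat[substr(p, 1, 1), substr(p, 2, 2)] <- TRUE
  }
  mat
}

# Watson-Crick pairs, the default for helical elements.
wc_pairs <- function() parse_pairs("AT,TA,CG,GC")

format_pairs <- function(mat) {
  idx <- which(mat, arr.ind = TRUE)
  paste(paste0(rownames(mat)[idx[, 1]], colnames(mat)[idx[, 2]]), collapse = ",")
}
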