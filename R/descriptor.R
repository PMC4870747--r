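# Motif descriptor language: parsing, validation, length bounds.
#
# A descriptor file has three parts (comments start with `#`):
#   1. the motif map: element occurrences 5'->3', e.g.  s1 h1 s2 h2 h1' s3 h2'
#      (each helix appears twice: h<k> for the 5' strand, h<k>' for the 3'
#      strand; the unprimed occurrence must come first; any interleaving is
#      allowed, so pseudoknots are expressible);
#   2. one specification line per element:
#        s1 m:i   PATTERN                 (single strand)
#        h1 m:r:i PAT5:PAT3 [PAIRLIST]    (helix)
#      where m = max mismatches, r = max mispairs, i = max single-base bulge
#      insertions; trailing distortion fields default to 0.  PAT3 is written
#      3'->5' so that column j of PAT5 pairs with column j of PAT3.  The
#      optional PAIRLIST (e.g. AT,TA,CG,GC,GT,TG) defaults to Watson-Crick.
#   3. optionally  `order: <tags>`  fixing the search order (helices listed
#      once, unprimed) and/or  `name: <text>`.

SINGLE_TAG_RE <- "^s[0-9]+$"
HELIX_TAG_RE  <- "^h[0-9]+$"

parse_tokens <- function(pat, where) {
  toks <- strsplit(pat, "", fixed = TRUE)[[1]]
  if (!length(toks)) stop(where, ": empty pattern")
  masks <- vapply(toks, function(ch) {
    if (ch == "*") 0L
    else if (toupper(ch) %in% names(IUPAC_MASKS)) unname(IUPAC_MASKS[toupper(ch)])
    else stop(where, ": invalid pattern character '", ch, "'")
  }, integer(1), USE.NAMES = FALSE)
  list(tokens = toupper(chartr("Uu", "Tt", toks)), masks = masks)
}

parse_distortions <- function(txt, n_fields, where) {
  parts <- strsplit(txt, ":", fixed = TRUE)[[1]]
  if (length(parts) > n_fields)
    stop(where, ": too many distortion fields in '", txt, "'")
  vals <- suppressWarnings(as.integer(parts))
  if (any(is.na(vals)) || any(vals < 0))
    stop(where, ": malformed distortion counts '", txt, "'")
  c(vals, rep.int(0L, n_fields - length(vals)))
}

new_single_spec <- function(tag, pattern, m = 0L, i = 0L) {
  tk <- parse_tokens(pattern, tag)
  structure(list(tag = tag, kind = "single",
                 tokens = tk$tokens, masks = tk$masks,
                 max_mismatch = as.integer(m), max_insert = as.integer(i)),
            class = "ss_spec")
}

new_helix_spec <- function(tag, pattern5, pattern3, pairs = wc_pairs(),
                           m = 0L, r = 0L, i = 0L) {
  t5 <- parse_tokens(pattern5, tag)
  t3 <- parse_tokens(pattern3, tag)
  if (length(t5$masks) != length(t3$masks))
    stop(tag, ": helix strand patterns differ in length (",
         length(t5$masks), " vs ", length(t3$masks), ")")
  structure(list(tag = tag, kind = "helix",
                 tokens5 = t5$tokens, masks5 = t5$masks,
                 tokens3 = t3$tokens, masks3 = t3$masks,
                 pairs = pairs,
                 max_mismatch = as.integer(m), max_mispair = as.integer(r),
                 max_insert = as.integer(i)),
            class = "helix_spec")
}

# Per-column valid pair counts P[j]; a wildcard side contributes all four
# bases.  Used both for validation and the information-content heuristic.
helix_pair_counts <- function(spec) {
  K <- length(spec$masks5)
  vapply(seq_len(K), function(j) {
    b5 <- if (spec$masks5[j] == 0L) 0:3 else which(bitwAnd(spec$masks5[j], c(1L,2L,4L,8L)) > 0L) - 1L
    b3 <- if (spec$masks3[j] == 0L) 0:3 else which(bitwAnd(spec$masks3[j], c(1L,2L,4L,8L)) > 0L) - 1L
    sum(spec$pairs[b5 + 1L, b3 + 1L, drop = FALSE])
  }, numeric(1))
}

# Columns where at least one side is a concrete class (must be consumed);
# both-wildcard columns may be skipped entirely.
helix_mandatory <- function(spec) !(spec$masks5 == 0L & spec$masks3 == 0L)

#' Minimum and maximum match length of an element
#'
#' For a single-stranded element the minimum is the number of non-wildcard
#' tokens and the maximum is the token count plus the insertion budget.  For
#' a helix the bounds are per strand: the minimum is the number of mandatory
#' (non both-wildcard) columns — at least one column must pair — and the
#' maximum is the column count plus the insertion budget (all bulges may
#' fall on one strand).
#'
#' @param spec an element specification (\code{ss_spec} or \code{helix_spec}).
#' @return named numeric vector \code{c(min, max)} (identical for both helix
#'   strands).
#' @export
length_bounds <- function(spec) {
  if (inherits(spec, "ss_spec")) {
    c(min = sum(spec$masks != 0L),
      max = length(spec$masks) + spec$max_insert)
  } else {
    c(min = max(1L, sum(helix_mandatory(spec))),
      max = length(spec$masks5) + spec$max_insert)
  }
}

#' Length flexibility of an element
#'
#' The difference between the maximum and minimum match length; for a helix,
#' per strand with the other strand considered fixed.
#'
#' @param spec an element specification.
#' @return a non-negative integer.
#' @export
flexibility <- function(spec) {
  b <- length_bounds(spec)
  unname(b["max"] - b["min"])
}

validate_helix <- function(spec) {
  P <- helix_pair_counts(spec)
  mand <- helix_mandatory(spec)
  if (spec$max_mispair == 0L && any(P == 0 & mand))
    stop(spec$tag, ": column ", which(P == 0 & mand)[1],
         " admits no allowed base pair and the mispair budget is 0 ",
         "(element is unmatchable)")
  invisible(spec)
}

build_descriptor <- function(map, specs, user_order = NULL, name = "motif") {
  tags <- vapply(specs, `[[`, "", "tag")
  names(specs) <- tags
  if (anyDuplicated(tags))
    stop("duplicate specification for tag '", tags[duplicated(tags)][1], "'")
  base_map <- sub("'$", "", map)
  primed <- grepl("'$", map)

  for (occ in seq_along(map)) {
    tg <- base_map[occ]
    if (!(tg %in% tags)) stop("map tag '", map[occ], "' has no specification")
  }
  for (tg in tags) {
    sp <- specs[[tg]]
    occs <- which(base_map == tg)
    if (inherits(sp, "ss_spec")) {
      if (!grepl(SINGLE_TAG_RE, tg))
        stop("single-strand tags must look like s1, s2, ...: '", tg, "'")
      if (length(occs) != 1L || primed[occs])
        stop("single-strand tag '", tg, "' must occur exactly once, unprimed")
    } else {
      if (!grepl(HELIX_TAG_RE, tg))
        stop("helix tags must look like h1, h2, ...: '", tg, "'")
      if (length(occs) != 2L || !identical(primed[occs], c(FALSE, TRUE)))
        stop("helix '", tg, "' must occur exactly twice: '", tg,
             "' (5' strand) before '", tg, "'' (3' strand)")
      validate_helix(sp)
    }
  }
  if (!is.null(user_order)) {
    if (!setequal(user_order, tags) || length(user_order) != length(tags))
      stop("search order must be a permutation of all element tags")
  }

  occ <- data.frame(occurrence = map, elem = base_map, primed = primed,
                    stringsAsFactors = FALSE)
  occ$kind <- vapply(occ$elem, function(t) specs[[t]]$kind, "")
  bounds <- lapply(occ$elem, function(t) length_bounds(specs[[t]]))
  occ$min_len <- vapply(bounds, `[[`, numeric(1), "min")
  occ$max_len <- vapply(bounds, `[[`, numeric(1), "max")
  occ$flex <- occ$max_len - occ$min_len

  structure(list(name = name, map = map, specs = specs,
                 user_order = user_order, elements = unname(tags),
                 occ = occ, L = sum(occ$max_len)),
            class = "motif_descriptor")
}

#' Parse a motif descriptor
#'
#' Parses the descriptor dialect described in the package vignette: a motif
#' map line, one specification line per element, and optional
#' \code{order:} / \code{name:} lines.  All invariants are validated
#' (helix strand alignment, primed-after-unprimed occurrence order,
#' matchability of every mandatory helix column, ...).
#'
#' @param text descriptor file content as a single string or a character
#'   vector of lines.
#' @return a \code{motif_descriptor} object with element specifications,
#'   per-element length bounds, and the maximum occurrence length \code{L}.
#' @seealso \code{\link{read_descriptor}}, \code{\link{serialize_descriptor}}
#' @examples
#' d <- parse_descriptor(c("s1 h1 s2 h1'",
#'                         "s1 0:0 GGA", "s2 0:0 ***", "h1 0:0:0 NNNN:NNNN"))
#' d$L  # 14
#' @export
parse_descriptor <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("descriptor is empty")

  map <- NULL; specs <- list(); user_order <- NULL; name <- "motif"
  for (ln in keep) {
    txt <- trimws(lines[ln])
    where <- paste0("line ", ln)
    if (grepl("^name:", txt)) {
      name <- trimws(sub("^name:", "", txt)); next
    }
    if (grepl("^order:", txt)) {
      user_order <- strsplit(trimws(sub("^order:", "", txt)), "[[:space:]]+")[[1]]
      next
    }
    fields <- strsplit(txt, "[[:space:]]+")[[1]]
    if (is.null(map)) {
      bad <- !grepl("^[sh][0-9]+'?$", fields)
      if (any(bad))
        stop(where, ": invalid map tag '", fields[bad][1], "'")
      map <- fields
      next
    }
    # specification line: tag distortions pattern [pairs]
    if (length(fields) < 3L)
      stop(where, ": expected 'tag distortions pattern', got '", txt, "'")
    tag <- fields[1]
    if (grepl(SINGLE_TAG_RE, tag)) {
      d <- parse_distortions(fields[2], 2L, where)
      if (length(fields) > 3L) stop(where, ": trailing fields after pattern")
      specs[[length(specs) + 1L]] <- new_single_spec(tag, fields[3], d[1], d[2])
    } else if (grepl(HELIX_TAG_RE, tag)) {
      d <- parse_distortions(fields[2], 3L, where)
      pat <- strsplit(fields[3], ":", fixed = TRUE)[[1]]
      if (length(pat) != 2L)
        stop(where, ": helix pattern must be PAT5:PAT3")
      pairs <- if (length(fields) >= 4L) parse_pairs(fields[4]) else wc_pairs()
      if (length(fields) > 4L) stop(where, ": trailing fields after pair list")
      specs[[length(specs) + 1L]] <-
        new_helix_spec(tag, pat[1], pat[2], pairs, d[1], d[2], d[3])
    } else {
      stop(where, ": unknown tag '", tag, "'")
    }
  }
  if (is.null(map)) stop("descriptor has no motif map line")
  if (!length(specs)) stop("descriptor has no element specifications")
  build_descriptor(map, specs, user_order, name)
}

#' Read a motif descriptor file
#'
#' @param path path to a descriptor file.
#' @return a \code{motif_descriptor}.
#' @export
read_descriptor <- function(path) {
  parse_descriptor(readLines(path, warn = FALSE))
}

#' Serialize a descriptor back to its file format
#'
#' \code{parse_descriptor(serialize_descriptor(d))} reconstructs an
#' identical descriptor.
#'
#' @param desc a \code{motif_descriptor}.
#' @return a character vector of lines.
#' @export
serialize_descriptor <- function(desc) {
  out <- c(paste0("name: ", desc$name), paste(desc$map, collapse = " "))
  for (sp in desc$specs) {
    if (inherits(sp, "ss_spec")) {
      out <- c(out, paste(sp$tag,
                          paste(sp$max_mismatch, sp$max_insert, sep = ":"),
                          paste(sp$tokens, collapse = "")))
    } else {
      out <- c(out, paste(sp$tag,
                          paste(sp$max_mismatch, sp$max_mispair, sp$max_insert,
                                sep = ":"),
                          paste0(paste(sp$tokens5, collapse = ""), ":",
                                 paste(sp$tokens3, collapse = "")),
                          format_pairs(sp$pairs)))
    }
  }
  if (!is.null(desc$user_order))
    out <- c(out, paste("order:", paste(desc$user_order, collapse = " ")))
  out
}

#' @export
print.motif_descriptor <- function(x, ...) {
  cat("Motif descriptor '", x$name, "'\n", sep = "")
  cat("  map: ", paste(x$map, collapse = " "), "\n", sep = "")
  cat("  elements: ", length(x$elements),
      " (", sum(x$occ$kind[!x$occ$primed] == "single"), " single-stranded, ",
      sum(x$occ$kind[!x$occ$primed] == "helix"), " helical)\n", sep = "")
  cat("  max occurrence length L = ", x$L, "\n", sep = "")
  if (!is.null(x$user_order))
    cat("  fixed search order: ", paste(x$user_order, collapse = " "), "\n",
        sep = "")
  invisible(x)
}
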