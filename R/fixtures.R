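# Synthetic data: concrete motif realizations, planted sequences with
# ground truth, and random descriptors for property-based testing.

sample_base_from_mask <- function(mask) {
  b <- which(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L)
  c("A", "C", "G", "T")[if (length(b) == 1L) b else sample(b, 1L)]
}

#' Sample a concrete occurrence of a descriptor
#'
#' Draws one string realizing the motif: class positions are sampled from
#' their base sets, wildcard lengths are sampled, helix columns are sampled
#' jointly from the allowed pairs intersected with the column's sequence
#' classes.  By default no distortions are used, so the realization is a
#' perfect match.
#'
#' @param desc a \code{motif_descriptor}.
#' @param wildcard_p probability that an optional (wildcard / both-wildcard)
#'   position is used.
#' @return \code{list(string, intervals)} where \code{intervals} is an
#'   integer matrix (one row per map occurrence, columns start/end, 1-based
#'   within the string; empty occurrences have end = start - 1).
#' @export
sample_occurrence <- function(desc, wildcard_p = 0.5) {
  occ <- desc$occ
  helix_mem <- list()
  pieces <- character(nrow(occ))

  for (q in seq_len(nrow(occ))) {
    tg <- occ$elem[q]
    sp <- desc$specs[[tg]]
    if (sp$kind == "single") {
      chars <- character(0)
      for (j in seq_along(sp$masks)) {
        if (sp$masks[j] == 0L) {
          if (stats::runif(1) < wildcard_p)
            chars <- c(chars, sample_base_from_mask(15L))
        } else chars <- c(chars, sample_base_from_mask(sp$masks[j]))
      }
      pieces[q] <- paste(chars, collapse = "")
    } else if (!occ$primed[q]) {
      mand <- helix_mandatory(sp)
      use <- mand | stats::runif(length(mand)) < wildcard_p
      if (!any(use)) use[sample.int(length(use), 1L)] <- TRUE
      c5 <- character(0); c3 <- character(0)
      for (j in which(use)) {
        b5 <- if (sp$masks5[j] == 0L) 0:3 else
          which(bitwAnd(sp$masks5[j], c(1L,2L,4L,8L)) > 0L) - 1L
        b3 <- if (sp$masks3[j] == 0L) 0:3 else
          which(bitwAnd(sp$masks3[j], c(1L,2L,4L,8L)) > 0L) - 1L
        valid <- which(sp$pairs[b5 + 1L, b3 + 1L, drop = FALSE], arr.ind = TRUE)
        if (!nrow(valid))
          stop(tg, ": column ", j, " has no allowed pair consistent with ",
               "its classes (cannot realize a perfect match)")
        pick <- valid[if (nrow(valid) == 1L) 1L else sample.int(nrow(valid), 1L), ]
        c5 <- c(c5, c("A", "C", "G", "T")[b5[pick[1]] + 1L])
        c3 <- c(c3, c("A", "C", "G", "T")[b3[pick[2]] + 1L])
      }
      pieces[q] <- paste(c5, collapse = "")
      # pattern3 is written 3'->5': reverse to lay the strand on the text
      helix_mem[[tg]] <- paste(rev(c3), collapse = "")
    } else {
      pieces[q] <- helix_mem[[tg]]
    }
  }
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  intervals <- cbind(start = as.integer(starts), end = as.integer(ends))
  rownames(intervals) <- occ$occurrence
  list(string = paste(pieces, collapse = ""), intervals = intervals)
}

#' Generate a background sequence with planted motif occurrences
#'
#' Draws an i.i.d. background (uniform base frequencies by default, GC
#' fraction configurable) and overwrites it with \code{n_plants}
#' non-overlapping sampled occurrences at uniformly chosen positions.
#'
#' @param desc a \code{motif_descriptor}.
#' @param length sequence length; must be at least \code{n_plants * L}.
#' @param n_plants number of occurrences to plant (may be 0).
#' @param gc background GC fraction.
#' @param max_tries placement retries before giving up.
#' @return \code{list(sequence, truth)}: \code{truth} is a data frame with
#'   one row per planted occurrence (columns plant, span_start, span_end,
#'   string) plus the per-occurrence intervals in
#'   \code{attr(truth, "intervals")} (a list of absolute interval matrices).
#' @export
generate_planted_sequence <- function(desc, length, n_plants, gc = 0.5,
                                      max_tries = 200L) {
  stopifnot(length >= 1)
  if (length < n_plants * desc$L)
    stop("sequence too short for ", n_plants, " plants of length up to ",
         desc$L)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bg <- sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p)

  plants <- lapply(seq_len(n_plants), function(i) sample_occurrence(desc))
  placed <- matrix(numeric(0), 0, 2)
  offsets <- integer(0)
  for (i in seq_len(n_plants)) {
    w <- nchar(plants[[i]]$string)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(length - w + 1L, 1L)
      if (!nrow(placed) || all(s > placed[, 2] | (s + w - 1L) < placed[, 1])) {
        placed <- rbind(placed, c(s, s + w - 1L))
        offsets[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place plant ", i, " without overlap after ",
                  max_tries, " tries")
  }
  for (i in seq_len(n_plants)) {
    s <- offsets[i]
    str <- strsplit(plants[[i]]$string, "")[[1]]
    bg[s:(s + length(str) - 1L)] <- str
  }
  truth <- data.frame(
    plant = seq_len(n_plants),
    span_start = if (n_plants) as.integer(offsets) else integer(0),
    span_end = if (n_plants)
      as.integer(offsets + vapply(plants, function(p) nchar(p$string),
                                  numeric(1)) - 1L) else integer(0),
    string = if (n_plants) vapply(plants, `[[`, "", "string") else character(0),
    stringsAsFactors = FALSE)
  attr(truth, "intervals") <- lapply(seq_len(n_plants), function(i) {
    iv <- plants[[i]]$intervals
    iv[, ] <- iv + (offsets[i] - 1L)
    iv
  })
  list(sequence = paste(bg, collapse = ""), truth = truth)
}

#' Write planted ground truth as TSV
#'
#' @param truth the truth component of
#'   \code{\link{generate_planted_sequence}}.
#' @param path output file.
#' @param seq_id sequence identifier written in the first column.
#' @export
write_truth_tsv <- function(truth, path, seq_id = "seq1") {
  df <- data.frame(seq_id = rep(seq_id, nrow(truth)), truth,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Random descriptor for property-based testing
#'
#' Draws a small random descriptor: single-stranded and helical elements
#' with random IUPAC classes, wildcards, pair sets (Watson-Crick, optionally
#' with GU/UG wobble) and small distortion budgets; helix occurrence slots
#' are shuffled freely, so pseudoknotted topologies arise naturally.
#'
#' @param n_single,n_helix element counts.
#' @param max_len maximum tokens per strand.
#' @param max_budget distortion budgets are drawn from 0..max_budget
#'   (biased towards 0).
#' @param wildcard_p per-token wildcard probability.
#' @return a \code{motif_descriptor}.
#' @export
random_descriptor <- function(n_single = 2, n_helix = 1, max_len = 6,
                              max_budget = 2, wildcard_p = 0.15) {
  stopifnot(n_single + n_helix >= 1)
  rbudget <- function() sample(0:max_budget, 1L,
                               prob = (c(6, 3, 2, 1)[seq_len(max_budget + 1)]))
  rclass <- function() {
    r <- stats::runif(1)
    if (r < 0.55) sample(c("A", "C", "G", "T"), 1L)
    else if (r < 0.80) sample(c("R", "Y", "S", "W", "K", "M"), 1L)
    else if (r < 0.90) sample(c("B", "D", "H", "V"), 1L)
    else "N"
  }
  specs <- list()
  for (i in seq_len(n_single)) {
    len <- sample(2:max_len, 1L)
    toks <- vapply(seq_len(len), function(j)
      if (stats::runif(1) < wildcard_p) "*" else rclass(), "")
    if (all(toks == "*")) toks[1] <- rclass()
    specs[[length(specs) + 1L]] <-
      new_single_spec(paste0("s", i), paste(toks, collapse = ""),
                      m = rbudget(), i = rbudget())
  }
  for (i in seq_len(n_helix)) {
    pairs <- if (stats::runif(1) < 0.3) parse_pairs("AT,TA,CG,GC,GT,TG")
             else wc_pairs()
    len <- sample(2:max_len, 1L)
    t5 <- character(len); t3 <- character(len)
    for (j in seq_len(len)) {
      if (stats::runif(1) < wildcard_p) { t5[j] <- "*"; t3[j] <- "*"; next }
      # draw a valid pair, then classes containing each base (keeps P[j] > 0)
      pr <- which(pairs, arr.ind = TRUE)
      pk <- pr[sample.int(nrow(pr), 1L), ]
      bases <- c("A", "C", "G", "T")
      cls_containing <- function(b) {
        cand <- names(IUPAC_MASKS)[vapply(names(IUPAC_MASKS), function(cd)
          b %in% IUPAC_BASES[[cd]], logical(1))]
        cand <- setdiff(cand, "U")
        sample(cand, 1L, prob = ifelse(nchar(cand) > 0 &
                                       cand %in% c("A","C","G","T"), 3, 1))
      }
      t5[j] <- cls_containing(bases[pk[1]])
      t3[j] <- cls_containing(bases[pk[2]])
    }
    specs[[length(specs) + 1L]] <-
      new_helix_spec(paste0("h", i), paste(t5, collapse = ""),
                     paste(t3, collapse = ""), pairs,
                     m = rbudget(), r = rbudget(), i = rbudget())
  }
  # shuffle occurrence slots; the earlier slot of each helix is unprimed
  slots <- c(if (n_single) paste0("s", seq_len(n_single)),
             if (n_helix) rep(paste0("h", seq_len(n_helix)), each = 2))
  slots <- sample(slots)
  seen <- character(0)
  map <- vapply(slots, function(tg) {
    if (grepl("^h", tg) && tg %in% seen) paste0(tg, "'")
    else { seen <<- c(seen, tg); tg }
  }, "", USE.NAMES = FALSE)
  build_descriptor(map, specs, name = "random")
}
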