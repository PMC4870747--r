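# Data-driven element ordering (DDEO).
#
# Candidate search orders are proposed by scoring ordered k-tuples of
# elements with a weighted combination of an information-content lower
# bound h1 (specific elements first: the fail-first rule) and a flexibility
# penalty h2 (elements whose placement is loosely constrained by the
# already-fixed ones are expensive).  Retained tuples are completed to full
# orders by decreasing h1 and then raced empirically: windows are searched
# with randomly drawn surviving candidates, per-window times are recorded,
# and pairwise one-sided Welch t-tests eliminate slower candidates online.

#' Heuristic weights and DDEO parameters
#'
#' Defaults: \code{c1_single = 3}, \code{c1_paired = 1} (single-strand
#' matching is considerably faster, so specific single strands are favoured
#' early), \code{c2 = -0.2} (flexibility penalty), tuple length
#' \code{k = 3}, score retention threshold \code{keep_fraction = 0.85} of
#' the maximum, at most \code{max_candidates = 50} candidate orders,
#' elimination level \code{alpha = 0.01}, and a fallback that discards the
#' higher sample mean once both members of a pair have
#' \code{max_samples = 75} timing samples.
#'
#' @param c1_single,c1_paired,c2,k,keep_fraction,max_candidates,alpha,max_samples
#'   override any default.
#' @return a \code{heuristic_weights} list.
#' @export
heuristic_weights <- function(c1_single = 3, c1_paired = 1, c2 = -0.2,
                              k = 3, keep_fraction = 0.85,
                              max_candidates = 50, alpha = 0.01,
                              max_samples = 75) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1, alpha > 0, alpha < 1,
            k >= 1, max_candidates >= 1, max_samples >= 2)
  structure(list(c1_single = c1_single, c1_paired = c1_paired, c2 = c2,
                 k = as.integer(k), keep_fraction = keep_fraction,
                 max_candidates = as.integer(max_candidates), alpha = alpha,
                 max_samples = as.integer(max_samples)),
            class = "heuristic_weights")
}

# exact count, via a polynomial DP in O(N*m), of ways to pick at most `mmax`
# distortion positions: product over positions of (good + bad*z), summed
# over coefficients up to z^mmax
distortion_poly_sum <- function(good, bad, mmax) {
  coef <- c(1, numeric(mmax))
  for (i in seq_along(good)) {
    new <- coef * good[i]
    if (mmax >= 1)
      new[-1] <- new[-1] + coef[-length(coef)] * bad[i]
    coef <- new
  }
  sum(coef)
}

# Insertion factors: over-counts of placements times free bases.  Each of
# the j used insertions contributes an arbitrary base at one of <= N+1
# positions; each unused budget unit leaves a free tail position beyond the
# match (two tails for a helix, one per strand), also arbitrary.  Ignoring
# the non-adjacency rule keeps these valid upper bounds.
insertion_factor_single <- function(N, imax) {
  4^imax * sum(choose(N + 1, 0:imax))
}

insertion_factor_helix <- function(N, imax) {
  4^(2 * imax) * sum(choose(2 * N + 2, 0:imax))
}

# maximal run lengths of wildcard positions
wildcard_blocks <- function(is_wild) {
  r <- rle(is_wild)
  r$lengths[r$values]
}

#' Information content of an element (bits)
#'
#' A lower bound on the information content \code{h1}: the background
#' entropy of a random sequence of the element's maximum occurrence length
#' (2 bits per base for single strands, 4 bits per aligned column pair for
#' helices) minus \code{log2} of an upper bound \code{X_U} on the number of
#' sequences matching the element.  \code{X_U} multiplies the product of
#' per-position class sizes (pair counts for helices) by factors for
#' wildcard blocks, mismatch/mispair budgets, and insertions; see the
#' vignette for the exact factors.  High h1 = specific element = good early
#' filter.
#'
#' @param spec an \code{ss_spec} or \code{helix_spec}.
#' @return h1 in bits (can be negative for very permissive elements, since
#'   \code{X_U} is an over-count).
#' @export
info_content <- function(spec) {
  if (inherits(spec, "ss_spec")) {
    N <- length(spec$masks) + spec$max_insert
    is_wild <- spec$masks == 0L
    C <- vapply(spec$masks[!is_wild], function(m) sum(bitwAnd(m, c(1L,2L,4L,8L)) > 0L), numeric(1))
    X <- distortion_poly_sum(C, 4 - C, spec$max_mismatch)
    for (k in wildcard_blocks(is_wild)) X <- X * 4^k * (k + 1)
    X <- X * insertion_factor_single(N, spec$max_insert)
    2 * N - log2(X)
  } else {
    N <- length(spec$masks5) + spec$max_insert
    mand <- helix_mandatory(spec)
    P <- helix_pair_counts(spec)[mand]
    X <- distortion_poly_sum(P, 16 - P, spec$max_mispair)
    # mismatch budget relaxes the same per-column constraints
    if (spec$max_mismatch > 0 && length(P) && prod(P) > 0)
      X <- X * distortion_poly_sum(P, 16 - P, spec$max_mismatch) /
        prod(P)
    for (k in wildcard_blocks(!mand)) X <- X * 16^k * (k + 1)
    X <- X * insertion_factor_helix(N, spec$max_insert)
    # an element needing more mispairs than budgeted has X_U = 0; floor it
    # so h1 stays finite (such elements are maximally specific anyway)
    4 * N - log2(max(X, 1))
  }
}

# X_U itself (exported for the upper-bound validation)
#' Upper bound on the number of matching sequences
#'
#' The over-count \code{X_U} underlying \code{\link{info_content}}:
#' \code{h1 = 2N - log2(X_U)} for single strands and \code{4N - log2(X_U)}
#' for helices.
#'
#' @param spec an element specification.
#' @return a positive number.
#' @export
match_count_bound <- function(spec) {
  N <- if (inherits(spec, "ss_spec")) length(spec$masks) + spec$max_insert
       else length(spec$masks5) + spec$max_insert
  h <- info_content(spec)
  if (inherits(spec, "ss_spec")) 2^(2 * N - h) else 2^(4 * N - h)
}

#' Flexibility heuristic h2
#'
#' Approximates the search-domain size of \code{target} given that the
#' elements in \code{fixed_prefix} are already matched: the flexibilities
#' (max minus min length) of all map occurrences strictly between
#' \code{target} and the nearest fixed occurrence are summed on each side;
#' the minimum of the two sides is returned when both have a fixed element,
#' the available side's sum when only one does, and 0 when
#' \code{fixed_prefix} is empty.  For a helix target the value is computed
#' per strand, treating the other strand as fixed, and the maximum of the
#' two is returned.
#'
#' @param desc a \code{motif_descriptor}.
#' @param fixed_prefix character vector of already-ordered element tags.
#' @param target an element tag not in \code{fixed_prefix}.
#' @return a non-negative number.
#' @export
h2_flex <- function(desc, fixed_prefix, target) {
  stopifnot(!(target %in% fixed_prefix))
  occ <- desc$occ
  side_sum <- function(q, fixed_occ) {
    left <- NA; right <- NA
    fl <- fixed_occ[fixed_occ < q]; fr <- fixed_occ[fixed_occ > q]
    if (length(fl)) {
      l <- max(fl)
      left <- if (l + 1 <= q - 1) sum(occ$flex[(l + 1):(q - 1)]) else 0
    }
    if (length(fr)) {
      r <- min(fr)
      right <- if (q + 1 <= r - 1) sum(occ$flex[(q + 1):(r - 1)]) else 0
    }
    if (is.na(left) && is.na(right)) return(0)
    min(left, right, na.rm = TRUE)
  }
  fixed_occ <- which(occ$elem %in% fixed_prefix)
  sp <- desc$specs[[target]]
  if (sp$kind == "single") {
    if (!length(fixed_prefix)) return(0)
    side_sum(which(occ$elem == target), fixed_occ)
  } else {
    qs <- which(occ$elem == target)
    v5 <- side_sum(qs[1], sort(c(fixed_occ, qs[2])))
    v3 <- side_sum(qs[2], sort(c(fixed_occ, qs[1])))
    max(v5, v3)
  }
}

#' Combine h1/h2 components into a tuple score
#'
#' The score of an ordered tuple e1..ek is
#' \code{sum_i 2^(k-i) * (c1(e_i) * h1(e_i) + c2 * h2(e_1..e_i))} with
#' exponentially decreasing weights (earlier elements search a larger part
#' of the window).
#'
#' @param h1,h2 numeric vectors of per-element component values.
#' @param kind character vector, \code{"single"} or \code{"helix"}.
#' @param weights a \code{\link{heuristic_weights}}.
#' @return the scalar score.
#' @export
score_from_components <- function(h1, h2, kind, weights = heuristic_weights()) {
  stopifnot(length(h1) == length(h2), length(kind) == length(h1))
  c1 <- ifelse(kind == "single", weights$c1_single, weights$c1_paired)
  w <- 2^(weights$k - seq_along(h1))
  sum(w * (c1 * h1 + weights$c2 * h2))
}

#' Score an ordered tuple of elements
#'
#' @param desc a \code{motif_descriptor}.
#' @param tuple character vector of distinct element tags (length at most
#'   \code{weights$k}).
#' @param weights a \code{\link{heuristic_weights}}.
#' @param fixed tags fixed before the tuple (during iterative refinement);
#'   they contribute to h2 but not to the score.
#' @return the scalar score.
#' @export
score_tuple <- function(desc, tuple, weights = heuristic_weights(),
                        fixed = character(0)) {
  stopifnot(!anyDuplicated(tuple), length(tuple) <= weights$k)
  h1 <- vapply(tuple, function(t) info_content(desc$specs[[t]]), numeric(1))
  h2 <- vapply(seq_along(tuple), function(i)
    h2_flex(desc, c(fixed, tuple[seq_len(i - 1L)]), tuple[i]), numeric(1))
  kind <- vapply(tuple, function(t) desc$specs[[t]]$kind, "")
  score_from_components(h1, h2, kind, weights)
}

# all ordered m-tuples of v (matrix, one tuple per row)
ordered_tuples <- function(v, m) {
  if (m == 0L) return(matrix(character(0), 1, 0))
  out <- matrix(v, ncol = 1)
  for (j in seq_len(m - 1L)) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(r) {
      rest <- setdiff(v, out[r, ])
      cbind(matrix(out[r, ], length(rest), j, byrow = TRUE), rest)
    }))
  }
  unname(out)
}

# complete a prefix to a full order: remaining elements by decreasing h1,
# ties broken lexicographically
complete_by_h1 <- function(desc, prefix) {
  rest <- setdiff(desc$elements, prefix)
  if (!length(rest)) return(prefix)
  h1 <- vapply(rest, function(t) info_content(desc$specs[[t]]), numeric(1))
  c(prefix, rest[order(-h1, rest)])
}

#' Propose candidate search orders
#'
#' Scores every ordered k-tuple of (remaining) elements, retains the tuples
#' scoring at least \code{keep_fraction} of the maximum (at most
#' \code{max_candidates}, best first), and completes each to a full order by
#' appending the remaining elements in decreasing information content.
#'
#' @param desc a \code{motif_descriptor}.
#' @param weights a \code{\link{heuristic_weights}}.
#' @param fixed tags already fixed (refinement); candidates share this
#'   prefix.
#' @return list of candidates, each \code{list(prefix, order, score)},
#'   sorted by decreasing score (ties: lexicographic tuple order).
#' @export
propose_candidates <- function(desc, weights = heuristic_weights(),
                               fixed = character(0)) {
  remaining <- setdiff(desc$elements, fixed)
  stopifnot(length(remaining) >= 1L)
  m <- min(weights$k, length(remaining))
  tup <- ordered_tuples(remaining, m)
  scores <- vapply(seq_len(nrow(tup)), function(r)
    score_tuple(desc, tup[r, ], weights, fixed), numeric(1))
  mx <- max(scores)
  thr <- if (mx > 0) weights$keep_fraction * mx
         else mx - (1 - weights$keep_fraction) * abs(mx)
  keep <- which(scores >= thr)
  key <- apply(tup, 1, paste, collapse = " ")
  keep <- keep[order(-scores[keep], key[keep])]
  keep <- keep[seq_len(min(length(keep), weights$max_candidates))]
  lapply(keep, function(r) {
    prefix <- c(fixed, tup[r, ])
    list(prefix = tup[r, ], order = complete_by_h1(desc, prefix),
         score = scores[r])
  })
}

#' One-sided Welch t-test
#'
#' Tests the null hypothesis \code{E[x] >= E[y]} against
#' \code{E[x] < E[y]} using the Welch statistic with Welch-Satterthwaite
#' degrees of freedom.  Degenerate inputs (fewer than two samples on either
#' side, or both variances zero) return the neutral p = 0.5 so that no
#' elimination happens.
#'
#' @param x,y numeric sample vectors.
#' @return the one-sided p-value.
#' @export
welch_one_sided <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) return(0.5)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx <= 0 && vy <= 0) return(0.5)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  stats::pt(t_stat, df)
}

# --------------------------------------------------------------------------
# DDEO controller: incremental state machine consumed window by window.

ddeo_state_new <- function(desc, weights = heuristic_weights(),
                           candidates = NULL) {
  if (length(desc$elements) == 1L) {
    return(list(done = TRUE, order = desc$elements, fixed = desc$elements,
                desc = desc, weights = weights, history = character(0)))
  }
  cand <- if (is.null(candidates)) propose_candidates(desc, weights)
          else candidates
  for (i in seq_along(cand)) cand[[i]]$samples <- numeric(0)
  st <- list(done = FALSE, desc = desc, weights = weights,
             fixed = character(0), cand = cand, order = NULL,
             history = character(0))
  ddeo_maybe_advance(st)
}

# fix prefixes while only one candidate remains; returns the state
ddeo_maybe_advance <- function(st) {
  while (!st$done && length(st$cand) == 1L) {
    st$fixed <- c(st$fixed, st$cand[[1]]$prefix)
    st$history <- c(st$history,
                    paste("fixed:", paste(st$fixed, collapse = " ")))
    if (length(st$fixed) >= length(st$desc$elements)) {
      st$done <- TRUE
      st$order <- st$fixed
    } else {
      st$cand <- propose_candidates(st$desc, st$weights, st$fixed)
      for (i in seq_along(st$cand)) st$cand[[i]]$samples <- numeric(0)
    }
  }
  st
}

# current working order: final if done, else the best surviving candidate
# (lowest mean; unsampled candidates by proposal rank)
ddeo_current_order <- function(st) {
  if (st$done) return(st$order)
  means <- vapply(st$cand, function(cc)
    if (length(cc$samples)) mean(cc$samples) else Inf, numeric(1))
  st$cand[[which.min(means)]]$order
}

# process one window: draw a surviving candidate uniformly at random, search
# with it, record the normalized time, run eliminations.  Returns
# list(state, occurrences, order_used).
ddeo_step <- function(st, window_text, timer = NULL) {
  if (st$done) {
    occ <- backtrack_window(window_text, st$desc, st$order)
    return(list(state = st, occurrences = occ, order = st$order))
  }
  x <- sample.int(length(st$cand), 1L)
  ord <- st$cand[[x]]$order
  wl <- if (is.character(window_text)) nchar(window_text)
        else length(window_text)
  t0 <- proc.time()
  occ <- backtrack_window(window_text, st$desc, ord)
  dt <- sum(proc.time()[c("user.self", "sys.self")] -
            t0[c("user.self", "sys.self")])
  raw <- if (is.null(timer)) dt else timer(ord, window_text)
  st$cand[[x]]$samples <- c(st$cand[[x]]$samples, raw / wl)

  # test x against every other survivor after its new sample
  alpha <- st$weights$alpha; mx_s <- st$weights$max_samples
  kill <- logical(length(st$cand))
  xs <- st$cand[[x]]$samples
  for (y in seq_along(st$cand)) {
    if (y == x || kill[y] || kill[x]) next
    ys <- st$cand[[y]]$samples
    if (welch_one_sided(xs, ys) < alpha) { kill[y] <- TRUE; next }
    if (welch_one_sided(ys, xs) < alpha) { kill[x] <- TRUE; next }
    if (length(xs) >= mx_s && length(ys) >= mx_s) {
      # fallback: both sampled many times, drop the higher sample mean
      # (ties: the later candidate in proposal order)
      if (mean(xs) >= mean(ys)) kill[x] <- TRUE else kill[y] <- TRUE
    }
  }
  if (any(kill)) st$cand <- st$cand[!kill]
  st <- ddeo_maybe_advance(st)
  list(state = st, occurrences = occ, order = ord)
}

#' Data-driven element ordering over a window stream
#'
#' Races the proposed candidate orders over the supplied windows: each
#' window is searched with a uniformly drawn surviving candidate and its
#' normalized time (process CPU time divided by window length, or the value
#' of an injectable \code{timer} stub) is recorded; candidates are
#' eliminated by pairwise one-sided Welch t-tests at level \code{alpha},
#' with the higher-sample-mean fallback once both members of a pair have
#' \code{max_samples} samples.  When one candidate survives, its leading
#' k-tuple is fixed and the next k-tuple is raced over the remaining
#' elements, until the order is fully fixed (or the windows run out, in
#' which case the current best candidate completes the order).  The
#' occurrence set is identical to a fixed-order run; only the time depends
#' on the order.
#'
#' @param desc a \code{motif_descriptor}.
#' @param windows list (or character vector) of window texts.
#' @param weights a \code{\link{heuristic_weights}}.
#' @param timer optional stub \code{function(order, window_text)} returning
#'   the raw time measurement; default: measure process CPU time.
#' @param candidates optional externally supplied candidate list (as from
#'   \code{\link{propose_candidates}}), mainly for testing.
#' @return \code{list(order, occurrences, windows_used, converged)} where
#'   \code{occurrences} is a list (per window) of occurrence lists from
#'   \code{\link{backtrack_window}}.
#' @export
ddeo_order <- function(desc, windows, weights = heuristic_weights(),
                       timer = NULL, candidates = NULL) {
  st <- ddeo_state_new(desc, weights, candidates)
  occs <- vector("list", length(windows))
  used <- 0L
  for (w in seq_along(windows)) {
    step <- ddeo_step(st, windows[[w]], timer)
    st <- step$state
    occs[[w]] <- step$occurrences
    used <- w
    if (st$done && w < length(windows)) {
      for (w2 in (w + 1L):length(windows))
        occs[[w2]] <- backtrack_window(windows[[w2]], desc, st$order)
      used <- length(windows)
      break
    }
  }
  list(order = ddeo_current_order(st), occurrences = occs,
       windows_used = used, converged = st$done)
}
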