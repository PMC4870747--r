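single <- function(p, m = 0, i = 0) knotscan:::new_single_spec("s1", p, m, i)
helix <- function(p5, p3, pairs = "AT,TA,CG,GC", m = 0, r = 0, i = 0) {
  knotscan:::new_helix_spec("h1", p5, p3, knotscan:::parse_pairs(pairs),
                            m, r, i)
}

test_that("single-strand matching handles classes, mismatches and wildcards", {
  m <- match_single(single("ACG"), "TACGT")
  expect_equal(unname(m[1, c("start", "end")]), c(2L, 4L))
  expect_equal(nrow(m), 1L)

  m <- match_single(single("A", m = 1), "TTTT")
  expect_equal(unname(m[, "start"]), 1:4)
  expect_equal(unname(m[, "mismatches"]), rep(1L, 4))

  m <- match_single(single("A*"), "AG")
  expect_equal(unname(m[, c("start", "end")]),
               matrix(c(1L, 1L, 1L, 2L), 2, byrow = TRUE))

  # empty match of an all-wildcard element
  m <- match_single(single("**"), "ACG")
  expect_true(any(m[, "end"] < m[, "start"]))
})

test_that("domains restrict starts, ends and force covers", {
  sp <- single("N")
  m <- match_single(sp, "ACGT", search_domain(c(2, 3), c(2, 3)))
  expect_equal(unname(m[, "start"]), 2:3)
  m <- match_single(single("NNN"), "ACGTA",
                    search_domain(c(1, 5), c(1, 5), cover = c(3, 3)))
  expect_true(all(m[, "start"] <= 3 & m[, "end"] >= 3))
  expect_equal(nrow(match_single(sp, "ACGT", search_domain(c(3, 2), c(1, 4)))),
               0L)
})

test_that("helix matching pairs columns and charges mispairs", {
  d5 <- search_domain(c(1, 2), c(1, 2)); d3 <- search_domain(c(3, 4), c(3, 4))
  m <- match_helix(helix("NN", "NN"), "ACGT", d5, d3)
  expect_equal(unname(m[1, 1:4]), c(1, 2, 3, 4))
  expect_equal(nrow(match_helix(helix("NN", "NN"), "ACCT", d5, d3)), 0L)
  m <- match_helix(helix("NN", "NN", r = 1), "ACCT", d5, d3)
  expect_equal(unname(m[1, "mispairs"]), 1L)
})

test_that("helix bulge insertions are single-base and never adjacent", {
  # one bulge on the 5' strand: A CG / CG -> pairs C-G, G-C around bulge A
  sp <- helix("CG", "GC", i = 1)
  m <- match_helix(sp, "CAGCG", search_domain(c(1, 1), c(1, 5)),
                   search_domain(c(1, 5), c(5, 5)))
  expect_true(any(m[, "insertions"] == 1 & m[, "end5"] == 3))
  # two bulges in the same gap would be adjacent: not allowed
  sp2 <- helix("CG", "GC", i = 2)
  m2 <- match_helix(sp2, "CAAGCG", search_domain(c(1, 1), c(1, 6)),
                    search_domain(c(1, 6), c(6, 6)))
  expect_false(any(m2[, "insertions"] == 2))
})

test_that("N in the text matches only fully degenerate classes", {
  expect_equal(nrow(match_single(single("A"), "N")), 0L)
  expect_equal(nrow(match_single(single("N"), "N")), 1L)
  # N never pairs
  d5 <- search_domain(c(1, 1), c(1, 1)); d3 <- search_domain(c(2, 2), c(2, 2))
  expect_equal(nrow(match_helix(helix("N", "N"), "NN", d5, d3)), 0L)
})

test_that("DP match sets equal exhaustive enumeration on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    d <- random_descriptor(n_single = 1, n_helix = 0, max_len = 6,
                           max_budget = 2)
    sp <- d$specs$s1
    txt <- random_dna(sample(10:30, 1))
    got <- match_single(sp, txt)
    # oracle: test every interval (including empty ones) by recursive
    # alignment enumeration
    n <- nchar(txt); enc <- knotscan:::encode_seq(txt)
    exp_rows <- list()
    for (s in 1:(n + 1)) for (e in (s - 1):n) {
      if (e >= s + length(sp$masks) + sp$max_insert) next
      sub <- if (e < s) integer(0) else enc[s:e]
      if (knotscan:::oracle_single_exact(sp$masks, sub, sp$max_mismatch,
                                         sp$max_insert))
        exp_rows[[length(exp_rows) + 1L]] <- c(s, e)
    }
    expect_equal(nrow(got), length(exp_rows))
    if (length(exp_rows))
      expect_equal(unname(got[, 1:2, drop = FALSE]),
                   matrix(unlist(exp_rows), ncol = 2, byrow = TRUE))
  }
})

test_that("helix DP equals exhaustive enumeration on random instances", {
  set.seed(202)
  for (rep in 1:25) {
    d <- random_descriptor(n_single = 0, n_helix = 1, max_len = 5,
                           max_budget = 2)
    sp <- d$specs$h1
    txt <- random_dna(sample(10:22, 1))
    n <- nchar(txt); enc <- knotscan:::encode_seq(txt)
    got <- match_helix(sp, txt)
    got_keys <- apply(got[, 1:4, drop = FALSE], 1, paste, collapse = ",")
    exp_keys <- character(0)
    mx <- length(sp$masks5) + sp$max_insert
    for (s5 in 1:n) for (e5 in s5:min(n, s5 + mx - 1))
      for (s3 in (e5 + 1):n) for (e3 in s3:min(n, s3 + mx - 1)) {
        if (s3 > n || s3 <= e5 || e3 < s3) next
        if (knotscan:::oracle_helix_exact(sp, enc[s5:e5], enc[s3:e3]))
          exp_keys <- c(exp_keys, paste(s5, e5, s3, e3, sep = ","))
      }
    expect_identical(sort(got_keys), sort(exp_keys))
  }
})

test_that("reported distortion counts are minimal over alignments", {
  # interval [1,3] of "AAA" vs pattern "A*A": achievable with 0 distortions
  # (wildcard consumes) even though an alignment with 1 insertion exists
  m <- match_single(single("A*A", i = 1), "AAA",
                    search_domain(c(1, 1), c(3, 3)))
  expect_equal(unname(m[, "mismatches"]), 0L)
  expect_equal(unname(m[, "insertions"]), 0L)
})

test_that("enlarging budgets or domains never removes matches", {
  set.seed(33)
  for (rep in 1:15) {
    d <- random_descriptor(n_single = 1, n_helix = 0, max_len = 5,
                           max_budget = 1)
    sp <- d$specs$s1
    txt <- random_dna(25)
    base <- match_single(sp, txt)
    sp2 <- sp; sp2$max_mismatch <- sp$max_mismatch + 1L
    sp3 <- sp; sp3$max_insert <- sp$max_insert + 1L
    k <- function(m) apply(m[, 1:2, drop = FALSE], 1, paste, collapse = ",")
    expect_true(all(k(base) %in% k(match_single(sp2, txt))))
    expect_true(all(k(base) %in% k(match_single(sp3, txt))))
    dom <- search_domain(c(5, 15), c(5, 15))
    sub <- match_single(sp, txt, dom)
    expect_true(all(k(sub) %in% k(base)))
  }
})

test_that("prefilter returns a superset of true end positions", {
  set.seed(44)
  for (rep in 1:20) {
    d <- random_descriptor(1, 0, max_len = 5, max_budget = 2)
    sp <- d$specs$s1
    txt <- random_dna(40)
    ends <- match_single(sp, txt)[, "end"]
    cand <- prefilter_positions(sp, txt)
    expect_true(all(ends[ends >= 1] %in% cand))
  }
  expect_identical(prefilter_positions(single("ACG"), "TACGT",
                                       search_domain(c(2, 1), c(2, 1))),
                   integer(0))
  # exact shift-and path: fully specified pattern
  expect_identical(prefilter_positions(single("ACG"), "TACGTACG"),
                   c(4L, 8L))
})
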