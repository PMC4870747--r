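# Shared helpers: canonical occurrence keys, toy descriptors, random
# instances for the oracle-equivalence suites.

# canonical sorted representation of an occurrence list
canon <- function(occs) {
  sort(vapply(occs, function(m) paste(t(m), collapse = ","), ""))
}

occurrence_key_of <- function(iv) paste(t(iv), collapse = ",")

toy_hairpin <- function() {
  parse_descriptor(c("h1 s1 h1'", "h1 0:0:0 N:N", "s1 0:0 AA"))
}

hdv_descriptor <- function() {
  read_descriptor(system.file("extdata", "hdv_like.dsc", package = "knotscan"))
}

aptamer_descriptor <- function() {
  read_descriptor(system.file("extdata", "aptamer_like.dsc", package = "knotscan"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# does the descriptor's map contain two crossing helices?
is_pseudoknotted <- function(desc) {
  occ <- desc$occ
  hel <- unique(occ$elem[occ$kind == "helix"])
  if (length(hel) < 2L) return(FALSE)
  pos <- lapply(hel, function(h) which(occ$elem == h))
  for (a in seq_along(hel))
    for (b in seq_along(hel))
      if (a != b &&
          pos[[a]][1] < pos[[b]][1] && pos[[b]][1] < pos[[a]][2] &&
          pos[[a]][2] < pos[[b]][2])
        return(TRUE)
  FALSE
}

# one random (descriptor, text) instance for the equivalence suites:
# 3-6 elements, strand lengths <= 6, budgets <= 2, text 100-200 nt,
# with a motif occurrence planted so instances are not trivially empty
random_instance <- function(plant = TRUE) {
  repeat {
    n_h <- sample(0:2, 1L)
    n_s <- sample(max(1L, 3L - 2L * n_h):(6L - n_h), 1L)
    if (n_s + n_h >= 3L && n_s + n_h <= 6L) break
  }
  d <- random_descriptor(n_s, n_h, max_len = 6, max_budget = 2)
  n <- sample(100:200, 1L)
  txt <- random_dna(n)
  if (plant && d$L < n) {
    occ <- sample_occurrence(d)
    s <- sample.int(n - nchar(occ$string) + 1L, 1L)
    substr(txt, s, s + nchar(occ$string) - 1L) <- occ$string
  }
  list(desc = d, text = txt)
}
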