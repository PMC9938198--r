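# Shared test oracles and fixture generators. These deliberately use naive
# algorithms, independent of the package's implementations.

# Brute-force exterior labels: a base is exterior iff it is unpaired and no
# pair strictly encloses it (checked against every pair).
brute_exterior <- function(s) {
  n <- s$n
  labels <- integer(n)
  p <- s$pairs
  for (k in seq_len(n)) {
    paired <- nrow(p) > 0 && any(p[, 1L] == k | p[, 2L] == k)
    enclosed <- nrow(p) > 0 && any(p[, 1L] < k & k < p[, 2L])
    labels[[k]] <- as.integer(!paired && !enclosed)
  }
  labels
}

# Random structure as a raw pair set: crossing pairs always possible and,
# when `allow_triples`, bases may appear in more than one pair.
random_raw_structure <- function(n = NULL, max_n = 120, allow_triples = FALSE) {
  if (is.null(n)) n <- sample(5:max_n, 1L)
  seq <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
  n_pairs <- sample(0:max(1L, n %/% 4L), 1L)
  pairs <- NULL
  if (n_pairs > 0) {
    taken <- logical(n)
    rows <- list()
    for (r in seq_len(n_pairs)) {
      cand <- if (allow_triples) seq_len(n) else which(!taken)
      if (length(cand) < 2L) break
      ij <- sample(cand, 2L)
      if (abs(ij[[1L]] - ij[[2L]]) < 2L) next
      rows[[length(rows) + 1L]] <- sort(ij)
      taken[ij] <- TRUE
    }
    if (length(rows)) pairs <- do.call(rbind, rows)
  }
  rna_structure(seq, pairs)
}

# Random single-partner structure (CT/BPSEQ-representable).
random_single_partner_structure <- function(n = NULL, max_n = 80) {
  random_raw_structure(n, max_n, allow_triples = FALSE)
}

# Exhaustive maximum nested pairing by recursive enumeration (no DP table):
# every structure is explored as "i unpaired" or "i paired to each allowed
# k"; the maximum pair count over all branches is returned.
brute_max_pairs <- function(sequence, min_loop = 3L,
                            allowed = c("AU", "UA", "GC", "CG", "GU", "UG")) {
  bases <- strsplit(sequence, "")[[1L]]
  ok <- function(a, b) paste0(bases[[a]], bases[[b]]) %in% allowed
  rec <- function(i, j) {
    if (i >= j || j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (!ok(i, k)) next
      inner <- if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L
      outer <- if (k + 1L <= j) rec(k + 1L, j) else 0L
      best <- max(best, inner + outer + 1L)
    }
    best
  }
  rec(1L, nchar(sequence))
}

random_rna_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# A tiny trained-free labeler for plumbing tests.
tiny_labeler <- function(L = 20L, seed = 1L) {
  build_labeler(model_config(K = 3L, C = 6L, U = 4L, N = 8L, L = L,
                             dropout = 0.1), seed = seed)
}

# Small synthetic corpus for pipeline tests.
tiny_corpus <- function(n = 10L, seed = 1L, ...) {
  generate_corpus(n, synth_params(...), seed = seed)
}
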