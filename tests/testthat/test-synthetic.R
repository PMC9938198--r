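test_that("generated labels agree exactly with label_exterior", {
  set.seed(12)
  for (rep in 1:80) {
    g <- generate_structure(synth_params(pseudoknot_prob = 0.3))
    expect_identical(g$labels, label_exterior(g$structure))
  }
})

test_that("fragment-count requests are honoured", {
  g <- generate_structure(synth_params(n_fragments = 0), seed = 1)
  expect_equal(nrow(g$fragments), 0L)
  expect_equal(g$labels, rep(1L, g$structure$n))
  expect_equal(nrow(g$structure$pairs), 0L)

  for (k in c(1L, 4L)) {
    g <- generate_structure(synth_params(n_fragments = k), seed = k)
    expect_equal(nrow(g$fragments), k)
  }

  counts <- vapply(1:30, function(s) {
    nrow(generate_structure(synth_params(n_fragments = c(2, 5)),
                            seed = s)$fragments)
  }, integer(1))
  expect_true(all(counts >= 2 & counts <= 5))
})

test_that("every generated structure is CT-representable and complementary", {
  set.seed(15)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  wobble <- list(c("G", "U"), c("U", "G"))
  for (rep in 1:30) {
    g <- generate_structure(synth_params(pseudoknot_prob = 0.5))
    s <- g$structure
    expect_true(rnafrag:::single_partner(s))
    if (nrow(s$pairs) > 0) {
      bases <- strsplit(s$sequence, "")[[1L]]
      for (r in seq_len(nrow(s$pairs))) {
        a <- bases[[s$pairs[r, 1L]]]
        b <- bases[[s$pairs[r, 2L]]]
        ok <- identical(comp[[a]], b) ||
          any(vapply(wobble, function(w) a == w[1] && b == w[2], logical(1)))
        expect_true(ok, info = paste(a, b))
      }
    }
  }
})

test_that("helix and loop geometry respect the configured minima", {
  set.seed(19)
  for (rep in 1:20) {
    g <- generate_structure(synth_params(pseudoknot_prob = 0))
    p <- g$structure$pairs
    if (nrow(p) == 0) next
    # nested grammar: hairpin loops at least 3 nt
    expect_true(all(p[, 2] - p[, 1] > 3))
  }
})

test_that("exterior linkers are GC-depleted when so parameterised", {
  corpus <- generate_corpus(50, synth_params(exterior_gc = 0.2,
                                             fragment_gc = 0.6), seed = 44)
  gc_of <- function(chars) mean(chars %in% c("G", "C"))
  gc_ext <- numeric(0); gc_int <- numeric(0)
  for (k in seq_len(nrow(corpus))) {
    bases <- strsplit(corpus$structure[[k]]$sequence, "")[[1L]]
    lab <- corpus$labels[[k]]
    if (any(lab == 1)) gc_ext <- c(gc_ext, gc_of(bases[lab == 1]))
    if (any(lab == 0)) gc_int <- c(gc_int, gc_of(bases[lab == 0]))
  }
  expect_lt(mean(gc_ext), 0.3)
  expect_gt(mean(gc_int), 0.45)
})

test_that("corpora are reproducible from their seed", {
  a <- generate_corpus(12, synth_params(), seed = 77)
  b <- generate_corpus(12, synth_params(), seed = 77)
  expect_equal(a$length, b$length)
  for (k in seq_len(nrow(a))) {
    expect_true(a$structure[[k]] == b$structure[[k]])
  }
  c1 <- generate_corpus(12, synth_params(), seed = 78)
  expect_false(all(a$length == c1$length))
})

test_that("generate_dataset splits RNAs disjointly and applies noise", {
  ds <- generate_dataset(40, synth_params(label_noise = 0.2),
                         L = 60, step = 60, seed = 8)
  expect_equal(sort(unique(ds$corpus$split)), c("test", "train", "val"))
  expect_equal(table(ds$corpus$split)[["train"]], 28)

  # accurate and coarse variants share inputs but differ in labels
  expect_equal(ds$accurate$train$x, ds$coarse$train$x)
  acc <- ds$accurate$train; coa <- ds$coarse$train
  flips <- (acc$y != coa$y)[acc$mask == 1]
  expect_equal(mean(flips), 0.2, tolerance = 0.03) # binomial tolerance
  # padding is never flipped
  expect_true(all(coa$y[acc$mask == 0] == 0))

  # with zero noise the variants coincide
  ds0 <- generate_dataset(20, synth_params(label_noise = 0),
                          L = 60, step = 60, seed = 8)
  expect_identical(ds0$accurate$train$y, ds0$coarse$train$y)

  # reproducibility
  ds2 <- generate_dataset(40, synth_params(label_noise = 0.2),
                          L = 60, step = 60, seed = 8)
  expect_identical(ds$coarse$train$y, ds2$coarse$train$y)
  expect_error(generate_dataset(3, synth_params(), seed = 1), "too small")
})

test_that("default corpus shape matches the intended architecture mix", {
  corpus <- generate_corpus(400, synth_params(), seed = 123)
  st <- fragment_stats(corpus)
  # most RNAs have 1-2 fragments; a modest minority more than two
  expect_gt(st$summary$frac_multi_fragment, 0.08)
  expect_lt(st$summary$frac_multi_fragment, 0.30)
  expect_true(all(corpus$length >= 10))
  # fragment count grows with RNA length across the corpus
  expect_gt(st$summary$cor_length_count, 0.2)
})
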