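test_that("make_windows follows the fixed-offset scheme with '-' padding", {
  ws <- make_windows(random_rna_sequence(200), L = 200, step = 200)
  expect_equal(ws$offsets, 1L)
  expect_false(grepl("-", ws$sequences[[1L]], fixed = TRUE))

  # 450 nt at step 200: windows at 1, 201, 401; last padded with 150 dashes
  ws <- make_windows(random_rna_sequence(450), L = 200, step = 200)
  expect_equal(ws$offsets, c(1L, 201L, 401L))
  expect_equal(nchar(gsub("[^-]", "", ws$sequences[[3L]])), 150L)

  # 300 nt at step 100: three windows, middle 100 covered twice
  ws <- make_windows(random_rna_sequence(300), L = 200, step = 100)
  expect_equal(ws$offsets, c(1L, 101L, 201L))
  masks <- window_masks(ws)
  expect_equal(sum(masks[3L, ]), 100L)

  # short sequences produce a single padded window
  ws <- make_windows("ACGUACGUAC", L = 200, step = 200)
  expect_equal(length(ws$offsets), 1L)
  expect_equal(sum(window_masks(ws)), 10L)

  expect_error(make_windows("", L = 10), "empty")
  expect_error(make_windows("ACGU", L = 10, step = 20), "step")
})

test_that("one-hot encoding is bit-exact to the channel codes", {
  x <- encode_onehot("A-UGC")
  # channel order (-, U, G, C, A): A = 00001, '-' = 10000
  expect_equal(as.vector(x[1, 1, ]), c(0, 0, 0, 0, 1))
  expect_equal(as.vector(x[1, 2, ]), c(1, 0, 0, 0, 0))
  expect_equal(as.vector(x[1, 3, ]), c(0, 1, 0, 0, 0))
  expect_equal(as.vector(x[1, 4, ]), c(0, 0, 1, 0, 0))
  expect_equal(as.vector(x[1, 5, ]), c(0, 0, 0, 1, 0))
  # exactly one hot per column
  ws <- make_windows(random_rna_sequence(333), L = 120, step = 60)
  enc <- encode_onehot(ws)
  expect_true(all(apply(enc, c(1, 2), sum) == 1))
  expect_error(encode_onehot("ACGN"), "unknown symbol")
})

test_that("encode/decode round trip is the identity", {
  ws <- make_windows(random_rna_sequence(450), L = 200, step = 200)
  expect_equal(decode_onehot(encode_onehot(ws)), ws$sequences)
})

test_that("build_labels slices exterior labels with zero-masked padding", {
  # all-unpaired 10-mer in one padded window
  s <- rna_structure(random_rna_sequence(10))
  ws <- make_windows(s$sequence, L = 16, step = 16)
  bl <- build_labels(s, ws)
  expect_equal(bl$labels[1, ], c(rep(1L, 10), rep(0L, 6)))
  expect_equal(bl$mask[1, ], c(rep(1L, 10), rep(0L, 6)))

  s <- rna_structure("ACGUACGUACGU", rbind(c(3, 8), c(4, 7)))
  ws <- make_windows(s$sequence, L = 12, step = 12)
  bl <- build_labels(s, ws)
  expect_equal(bl$labels[1, ], label_exterior(s))

  expect_error(build_labels(rna_structure("ACGU"), ws), "length")
})

test_that("unpadded label slices concatenate back to the full labels", {
  set.seed(88)
  for (rep in 1:20) {
    g <- generate_structure(synth_params())
    ws <- make_windows(g$structure$sequence, L = 50, step = 50)
    bl <- build_labels(g$structure, ws)
    flat <- as.vector(t(bl$labels))[as.vector(t(bl$mask)) == 1]
    expect_identical(as.integer(flat), label_exterior(g$structure))
  }
})

test_that("stitching averages overlapping windows and drops padding", {
  # no overlap: concatenation minus padding
  ws <- make_windows(random_rna_sequence(30), L = 20, step = 20)
  probs <- matrix(runif(2 * 20), 2, 20)
  st <- stitch_predictions(probs, ws)
  expect_equal(length(st), 30L)
  expect_equal(st[1:20], probs[1, ])
  expect_equal(st[21:30], probs[2, 1:10])

  # overlapped base gets the arithmetic mean (0.2, 0.6 -> 0.4)
  ws <- make_windows(random_rna_sequence(30), L = 20, step = 10)
  probs <- matrix(0.2, 3, 20)
  probs[2, ] <- 0.6
  st <- stitch_predictions(probs, ws)
  expect_equal(st[[15]], 0.4) # covered by windows 1 and 2
  expect_equal(st[[5]], 0.2)  # window 1 only

  # stitched values are bracketed by contributing windows
  set.seed(3)
  probs <- matrix(runif(3 * 20), 3, 20)
  st <- stitch_predictions(probs, ws)
  expect_true(all(st >= min(probs) & st <= max(probs)))

  # constant probability is a fixed point of averaging
  probs[] <- 0.37
  expect_equal(stitch_predictions(probs, ws), rep(0.37, 30))

  expect_error(stitch_predictions(probs[1:2, ], ws), "match")
})

test_that("window datasets bind and subset consistently", {
  g <- generate_structure(synth_params(), seed = 4)
  ws <- make_windows(g$structure$sequence, L = 40, step = 40)
  bl <- build_labels(g$structure, ws)
  ds <- window_dataset(encode_onehot(ws), bl$labels, bl$mask)
  both <- bind_window_datasets(ds, ds)
  expect_equal(dim(both$x)[[1L]], 2L * dim(ds$x)[[1L]])
  sub <- subset_window_dataset(both, seq_len(dim(ds$x)[[1L]]))
  expect_equal(sub$y, ds$y)
  expect_equal(sub$x, ds$x)
})
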