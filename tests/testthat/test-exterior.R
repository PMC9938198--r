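test_that("exterior labels match the definition on worked examples", {
  # fully unpaired: everything is exterior
  expect_equal(label_exterior(rna_structure("ACGUAC")), rep(1L, 6))

  # nested pairs (spec'd in 1-based coordinates: pairs (3,8), (4,7))
  s <- rna_structure("ACGUACGUACGU", rbind(c(3, 8), c(4, 7)))
  expect_equal(label_exterior(s), c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L,
                                    1L, 1L, 1L, 1L))

  # crossing pairs (1,6), (4,10): their interval union covers 2-9
  pk <- rna_structure("ACGUACGUACGU", rbind(c(1, 6), c(4, 10)))
  expect_equal(label_exterior(pk), c(rep(0L, 10), 1L, 1L))
})

test_that("label_exterior agrees exactly with the brute-force oracle", {
  set.seed(202)
  for (rep in 1:150) {
    s <- random_raw_structure(max_n = 120,
                              allow_triples = rep %% 3 == 0)
    expect_identical(label_exterior(s), brute_exterior(s))
  }
})

test_that("adding a pair never increases the number of exterior bases", {
  set.seed(33)
  for (rep in 1:50) {
    s <- random_raw_structure(max_n = 80)
    n_ext <- sum(label_exterior(s))
    ij <- sort(sample(s$n, 2L))
    if (ij[[2L]] - ij[[1L]] < 2L) next
    s2 <- rna_structure(s$sequence, rbind(s$pairs, ij))
    expect_lte(sum(label_exterior(s2)), n_ext)
  }
})

test_that("partition_ifragments returns maximal non-exterior runs", {
  seq10 <- strrep("A", 10)
  expect_equal(nrow(partition_ifragments(seq10, rep(1L, 10))), 0L)

  fr <- partition_ifragments(strrep("A", 12),
                             c(1, 1, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(fr$start, 3L)
  expect_equal(fr$end, 8L)

  fr <- partition_ifragments(seq10, c(0, 0, 1, 1, 0, 0, 0, 1, 0, 0))
  expect_equal(fr$start, c(1L, 5L, 9L))
  expect_equal(fr$end, c(2L, 7L, 10L))
  expect_equal(fr$length, c(2L, 3L, 2L))

  expect_error(partition_ifragments("ACGU", c(1, 0)), "length")
  expect_error(partition_ifragments("ACGU", c(1, 0, 2, 0)), "0/1")
})

test_that("extract_substructure shifts pairs into local coordinates", {
  s <- rna_structure("ACGUACGUACGU", rbind(c(3, 8), c(4, 7)))
  sub <- extract_substructure(s, 3, 8)
  expect_equal(sub$n, 6L)
  expect_equal(unname(sub$pairs), cbind(c(1L, 2L), c(6L, 5L)))
  # whole-sequence fragment is the identity
  whole <- extract_substructure(s, 1, s$n)
  expect_true(whole == s)
  # a straddling pair is an inconsistency, not silently dropped
  expect_error(extract_substructure(s, 4, 8), "straddles")
})

test_that("assemble inverts partition+extract on random structures", {
  set.seed(404)
  for (rep in 1:60) {
    g <- generate_structure(synth_params(pseudoknot_prob = 0.3))
    s <- g$structure
    labels <- label_exterior(s)
    fr <- partition_ifragments(s, labels)
    # every pair lands in exactly one fragment
    if (nrow(s$pairs) > 0) {
      hits <- vapply(seq_len(nrow(s$pairs)), function(r) {
        sum(fr$start <= s$pairs[r, 1L] & fr$end >= s$pairs[r, 2L])
      }, integer(1))
      expect_true(all(hits == 1L))
    }
    fr$substructure <- purrr::map2(fr$start, fr$end,
                                   function(a, b) extract_substructure(s, a, b))
    expect_true(assemble_structure(s$sequence, fr) == s)
  }
})

test_that("assemble validates geometry", {
  fr <- tibble::tibble(start = c(1L, 3L), end = c(4L, 6L),
                       substructure = list(rna_structure("ACGU"),
                                           rna_structure("ACGU")))
  expect_error(assemble_structure("ACGUACGU", fr), "overlap")
  fr2 <- tibble::tibble(start = 1L, end = 4L,
                        substructure = list(rna_structure("ACG")))
  expect_error(assemble_structure("ACGUACGU", fr2), "length")
  # zero fragments -> no pairs
  none <- assemble_structure("ACGU", tibble::tibble(start = integer(0),
                                                    end = integer(0),
                                                    substructure = list()))
  expect_equal(nrow(none$pairs), 0L)
})

test_that("fragment_stats matches hand computation on a toy corpus", {
  # rna1: fragments [3,8] -> one fragment of 6 nt, length 12
  s1 <- rna_structure("ACGUACGUACGU", rbind(c(3, 8), c(4, 7)))
  # rna2: fragments [1,5] and [8,12] -> two fragments of 5 nt, length 13
  s2 <- rna_structure("GGGAACCCGGAAC",
                      rbind(c(1, 5), c(2, 4), c(8, 12), c(9, 11)))
  st <- fragment_stats(list(s1, s2))
  expect_equal(st$per_rna$n_fragments, c(1L, 2L))
  expect_equal(st$summary$mean_fragment_count, 1.5)
  expect_equal(st$summary$mean_fragment_length, (6 + 5 + 5) / 3)
  expect_equal(st$summary$cor_length_count, 1) # two points, increasing
  expect_error(fragment_stats(list(s1)), "at least two")
})

test_that("degenerate variance yields undefined correlations, not NaN", {
  s <- rna_structure("ACGUACGUACGU", rbind(c(3, 8), c(4, 7)))
  st <- fragment_stats(list(s, s, s))
  expect_true(is.na(st$summary$cor_length_count))
  expect_false(is.nan(st$summary$cor_length_count))
})

test_that("recovered fragment counts match the generator's request", {
  corpus <- generate_corpus(40, synth_params(n_fragments = 3), seed = 9)
  st <- fragment_stats(corpus)
  expect_equal(st$summary$mean_fragment_count, 3)
})

test_that("context composition contrasts exterior vs fragment GC content", {
  corpus <- generate_corpus(60, synth_params(exterior_gc = 0.2,
                                             fragment_gc = 0.6), seed = 5)
  comp <- context_composition(corpus, window = 31, per_class = 300, seed = 2)
  expect_equal(sum(comp$freq_exterior), 1, tolerance = 1e-9)
  expect_equal(sum(comp$freq_non_exterior), 1, tolerance = 1e-9)
  gc_ext <- sum(comp$freq_exterior[comp$base %in% c("G", "C")])
  gc_non <- sum(comp$freq_non_exterior[comp$base %in% c("G", "C")])
  expect_lt(gc_ext, gc_non)
  # all-exterior corpus has no non-exterior centers to sample
  unpaired <- generate_corpus(10, synth_params(n_fragments = 0), seed = 1)
  expect_error(context_composition(unpaired, per_class = 10), "non-exterior")
})

test_that("labels serialize to TSV and BED", {
  dir <- withr::local_tempdir()
  s <- rna_structure("ACGUACGUACGU", rbind(c(3, 8), c(4, 7)))
  lab <- label_exterior(s)
  tsv <- file.path(dir, "lab.tsv")
  write_labels_tsv(s, lab, tsv, name = "rna1")
  df <- utils::read.delim(tsv)
  expect_equal(df$label, lab)
  expect_equal(df$position, 1:12)
  bed <- file.path(dir, "lab.bed")
  write_labels_bed(s, lab, bed, name = "rna1")
  bd <- utils::read.delim(bed, header = FALSE)
  expect_equal(bd$V2, c(0L, 8L)) # 0-based starts of exterior runs
  expect_equal(bd$V3, c(2L, 12L))
})
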