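test_that("dot-bracket parsing handles nesting, dots, and pseudoknot layers", {
  expect_equal(nrow(parse_dotbracket("AAAA\n....")$pairs), 0L)

  s <- parse_dotbracket("GGAAACC\n((...))")
  expect_equal(unname(s$pairs), cbind(c(1L, 2L), c(7L, 6L)))

  # crossing pairs across layers (stack per layer, hand-enumerated)
  s <- parse_dotbracket("ACGUACGUACGU\n((..[[..))]]")
  expect_equal(unname(s$pairs),
               rbind(c(1L, 10L), c(2L, 9L), c(5L, 12L), c(6L, 11L)))

  # FASTA-style header is honoured
  s <- parse_dotbracket(">my_rna\nGGAAACC\n((...))")
  expect_equal(s$name, "my_rna")
})

test_that("dot-bracket parsing raises structured errors with positions", {
  expect_error(parse_dotbracket("AAAA\n(..."), "unbalanced opening.*position 1")
  expect_error(parse_dotbracket("AAAA\n...)"), "unbalanced closing.*position 4")
  expect_error(parse_dotbracket("AAAA\n..."), "length")
  expect_error(parse_dotbracket("AXGU\n...."), "non-ACGU")
  expect_error(parse_dotbracket("AAAA\n..!."), "unknown structure symbol")
})

test_that("sequences are normalised: T to U, lowercase uppercased", {
  expect_equal(rna_structure("acgt")$sequence, "ACGU")
  expect_equal(parse_dotbracket("acgt\n....")$sequence, "ACGU")
})

test_that("CT parsing maps 1-based partners and validates symmetry", {
  ct4 <- paste(c("4 test", "1 A 0 2 0 1", "2 C 1 3 0 2",
                 "3 G 2 4 0 3", "4 U 3 0 0 4"), collapse = "\n")
  expect_equal(nrow(parse_ct(ct4)$pairs), 0L)

  ct7 <- paste(c("7 hp", "1 G 0 2 7 1", "2 G 1 3 6 2", "3 A 2 4 0 3",
                 "4 A 3 5 0 4", "5 A 4 6 0 5", "6 C 5 7 2 6",
                 "7 C 6 0 1 7"), collapse = "\n")
  expect_equal(unname(parse_ct(ct7)$pairs), cbind(c(1L, 2L), c(7L, 6L)))

  asym <- paste(c("3 bad", "1 G 0 2 3 1", "2 A 1 3 0 2",
                  "3 C 2 0 2 3"), collapse = "\n")
  expect_error(parse_ct(asym), "asymmetric")
  out_of_range <- paste(c("2 bad", "1 G 0 2 5 1", "2 A 1 0 0 2"),
                        collapse = "\n")
  expect_error(parse_ct(out_of_range), "out of range")
  expect_error(parse_ct("2 short\n1 A 0 2 0 1"), "base lines")
})

test_that("BPSEQ parsing and trivial records", {
  expect_equal(nrow(parse_bpseq("1 A 0\n2 C 0")$pairs), 0L)
  expect_equal(unname(parse_bpseq("1 G 3\n2 A 0\n3 C 1")$pairs),
               cbind(1L, 3L))
  expect_error(parse_bpseq("1 G 2\n2 A 1\n3 C 3"), "itself")
})

test_that("write_structure produces canonical output on worked cases", {
  s <- rna_structure("GGAAACC", cbind(c(1, 2), c(7, 6)))
  expect_equal(strsplit(write_structure(s, "dotbracket"), "\n")[[1L]][2L],
               "((...))")
  empty <- rna_structure("ACGU")
  expect_equal(strsplit(write_structure(empty, "dotbracket"), "\n")[[1L]][2L],
               "....")
  # crossing pairs get separate bracket layers (greedy coloring)
  pk <- rna_structure("ACGUACGUAC", cbind(c(1, 4), c(6, 10)))
  db <- strsplit(write_structure(pk, "dotbracket"), "\n")[[1L]][2L]
  expect_equal(db, "(..[.)...]")
})

test_that("base triples are serializable nowhere and rejected loudly", {
  triple <- rna_structure("GGGAAACCC", rbind(c(1, 9), c(1, 8)))
  expect_error(write_structure(triple, "ct"), "triple")
  expect_error(write_structure(triple, "bpseq"), "triple")
  expect_error(write_structure(triple, "dotbracket"), "triple")
  expect_error(structure_partners(triple), "triple")
})

test_that("parse(write(S)) is the identity for all three formats", {
  set.seed(71)
  for (rep in 1:40) {
    s <- random_single_partner_structure()
    expect_true(parse_ct(write_structure(s, "ct")) == s)
    expect_true(parse_bpseq(write_structure(s, "bpseq")) == s)
    expect_true(parse_dotbracket(write_structure(s, "dotbracket")) == s)
  }
})

test_that("structure files and FASTA round-trip through disk", {
  dir <- withr::local_tempdir()
  s <- parse_dotbracket(">x\nGGGAAACCC\n(((...)))")
  for (ext in c("db", "ct", "bpseq")) {
    path <- file.path(dir, paste0("s.", ext))
    write_structure_file(s, path)
    expect_true(read_structure_file(path) == s)
  }
  fa <- file.path(dir, "seqs.fa")
  write_rna_fasta(tibble::tibble(name = c("a", "b"),
                                 sequence = c("ACGU", "GGGCCC")), fa)
  back <- read_rna_fasta(fa)
  expect_equal(back$sequence, c("ACGU", "GGGCCC"))
  expect_equal(back$name, c("a", "b"))
})
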