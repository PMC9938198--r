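# Bracket layer alphabet, in precedence order. Layer 1 = "()", extra layers
# encode pseudoknots (crossing pairs).
BRACKET_OPEN  <- c("(", "[", "{", "<", "A", "B")
BRACKET_CLOSE <- c(")", "]", "}", ">", "a", "b")

#' Parse a dot-bracket record
#'
#' Reads a two-line record (sequence, then bracket string of equal length)
#' into an [rna_structure()]. Matched brackets of the same layer become base
#' pairs; the layer alphabet is `()`, `[]`, `{}`, `<>`, `Aa`, `Bb` in that
#' precedence, so crossing pairs (pseudoknots) are expressed across layers.
#' Dots (and `.`-like `-`,`:`,`,` commonly emitted by structure tools) mark
#' unpaired bases.
#'
#' @param text Character: either one string containing two newline-separated
#'   lines, or a character vector whose first two non-empty lines are the
#'   sequence and the bracket string. A leading FASTA-style `>name` header is
#'   honoured.
#' @return An [rna_structure()].
#' @examples
#' parse_dotbracket("GGGAAACCC\n(((...)))")
#' @export
parse_dotbracket <- function(text) {
  lines <- split_record_lines(text)
  name <- ""
  if (length(lines) && startsWith(lines[[1L]], ">")) {
    name <- sub("^>\\s*", "", lines[[1L]])
    lines <- lines[-1L]
  }
  if (length(lines) < 2L) {
    stop("dot-bracket record needs a sequence line and a bracket line",
         call. = FALSE)
  }
  sequence <- lines[[1L]]
  brackets <- lines[[2L]]
  if (nchar(brackets) != nchar(sequence)) {
    stop("bracket string length (", nchar(brackets),
         ") does not match sequence length (", nchar(sequence), ")",
         call. = FALSE)
  }
  sym <- strsplit(brackets, "", fixed = TRUE)[[1L]]
  stacks <- rep(list(integer(0)), length(BRACKET_OPEN))
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  for (k in seq_along(sym)) {
    s <- sym[[k]]
    if (s %in% c(".", "-", ":", ",")) next
    layer <- match(s, BRACKET_OPEN)
    if (!is.na(layer)) {
      stacks[[layer]] <- c(stacks[[layer]], k)
      next
    }
    layer <- match(s, BRACKET_CLOSE)
    if (is.na(layer)) {
      stop("unknown structure symbol '", s, "' at position ", k, call. = FALSE)
    }
    if (length(stacks[[layer]]) == 0L) {
      stop("unbalanced closing bracket '", s, "' at position ", k,
           call. = FALSE)
    }
    top <- length(stacks[[layer]])
    pairs_i <- c(pairs_i, stacks[[layer]][[top]])
    pairs_j <- c(pairs_j, k)
    stacks[[layer]] <- stacks[[layer]][-top]
  }
  open_left <- which(lengths(stacks) > 0L)
  if (length(open_left)) {
    pos <- stacks[[open_left[[1L]]]][[1L]]
    stop("unbalanced opening bracket '", BRACKET_OPEN[[open_left[[1L]]]],
         "' at position ", pos, call. = FALSE)
  }
  rna_structure(sequence, cbind(pairs_i, pairs_j), name = name)
}

split_record_lines <- function(text) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\r?\n"), use.names = FALSE)
  trimws(lines[nzchar(trimws(lines))])
}

#' Parse a CT-format secondary structure
#'
#' CT files carry a header line whose first token is the sequence length,
#' then one line per base: index, base, previous index, next index, partner
#' index (1-based; 0 marks an unpaired base), natural-numbering index.
#' Partner links must be symmetric; asymmetric or out-of-range partners are
#' validation errors, never silently dropped.
#'
#' @param text Character scalar or vector of lines.
#' @return An [rna_structure()].
#' @export
parse_ct <- function(text) {
  lines <- split_record_lines(text)
  if (length(lines) < 1L) stop("empty CT record", call. = FALSE)
  header <- strsplit(lines[[1L]], "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(header[[1L]]))
  if (is.na(n) || n < 0L) {
    stop("CT header must start with the sequence length", call. = FALSE)
  }
  name <- if (length(header) > 1L) paste(header[-1L], collapse = " ") else ""
  body <- lines[-1L]
  if (length(body) != n) {
    stop("CT record declares ", n, " bases but has ", length(body),
         " base lines", call. = FALSE)
  }
  parse_indexed_partner_lines(body, n, name, n_fields = 5L,
                              partner_field = 5L, format = "CT")
}

#' Parse a BPSEQ-format secondary structure
#'
#' BPSEQ lines are `index base partner` with 1-based indices and partner 0
#' for unpaired bases. `#`-prefixed comment lines are ignored.
#'
#' @inheritParams parse_ct
#' @return An [rna_structure()].
#' @export
parse_bpseq <- function(text) {
  lines <- split_record_lines(text)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1L) stop("empty BPSEQ record", call. = FALSE)
  parse_indexed_partner_lines(lines, length(lines), "", n_fields = 3L,
                              partner_field = 3L, format = "BPSEQ")
}

parse_indexed_partner_lines <- function(lines, n, name, n_fields,
                                        partner_field, format) {
  fields <- strsplit(lines, "\\s+")
  bases <- character(n)
  partner <- integer(n)
  for (k in seq_len(n)) {
    f <- fields[[k]]
    if (length(f) < partner_field) {
      stop(format, " line ", k, " has ", length(f), " fields; expected at least ",
           partner_field, call. = FALSE)
    }
    idx <- suppressWarnings(as.integer(f[[1L]]))
    if (is.na(idx) || idx != k) {
      stop(format, " line ", k, " has index '", f[[1L]],
           "'; indices must run 1..", n, call. = FALSE)
    }
    bases[[k]] <- f[[2L]]
    p <- suppressWarnings(as.integer(f[[partner_field]]))
    if (is.na(p) || p < 0L || p > n) {
      stop(format, " line ", k, " partner '", f[[partner_field]],
           "' out of range [0, ", n, "]", call. = FALSE)
    }
    if (p == k) stop(format, " line ", k, " pairs a base with itself",
                     call. = FALSE)
    partner[[k]] <- p
  }
  paired <- which(partner > 0L)
  bad <- paired[partner[partner[paired]] != paired]
  if (length(bad)) {
    k <- bad[[1L]]
    stop(format, ": asymmetric partner links (base ", k, " says ",
         partner[[k]], " but base ", partner[[k]], " says ",
         partner[[partner[[k]]]], ")", call. = FALSE)
  }
  keep <- paired[paired < partner[paired]]
  rna_structure(paste(bases, collapse = ""),
                cbind(keep, partner[keep]), name = name)
}

#' Serialize a secondary structure
#'
#' Writes an [rna_structure()] as canonical dot-bracket, CT, or BPSEQ text.
#' CT/BPSEQ use 1-based indices with partner 0 for unpaired bases and can
#' only represent structures where every base has at most one partner (base
#' triples raise an error). Dot-bracket assigns pairs to bracket layers by
#' greedy crossing-conflict coloring, so pseudoknots come out in `[]`, `{}`,
#' ... layers; structures needing more than six layers, or containing
#' triples, are rejected as unrepresentable.
#'
#' @param x An [rna_structure()].
#' @param format One of `"dotbracket"`, `"ct"`, `"bpseq"`.
#' @return A character scalar (lines joined with newlines).
#' @examples
#' s <- parse_dotbracket("GGGAAACCC\n(((...)))")
#' cat(write_structure(s, "ct"))
#' @export
write_structure <- function(x, format = c("dotbracket", "ct", "bpseq")) {
  stopifnot(inherits(x, "rna_structure"))
  format <- match.arg(format)
  switch(format,
    dotbracket = {
      db <- dotbracket_string(x)
      header <- if (nzchar(x$name)) paste0(">", x$name, "\n") else ""
      paste0(header, x$sequence, "\n", db, "\n")
    },
    ct = {
      partner <- structure_partners(x)
      bases <- strsplit(x$sequence, "", fixed = TRUE)[[1L]]
      i <- seq_len(x$n)
      lines <- sprintf("%d %s %d %d %d %d", i, bases, i - 1L,
                       ifelse(i == x$n, 0L, i + 1L), partner, i)
      paste0(paste(c(paste(x$n, x$name), lines), collapse = "\n"), "\n")
    },
    bpseq = {
      partner <- structure_partners(x)
      bases <- strsplit(x$sequence, "", fixed = TRUE)[[1L]]
      lines <- sprintf("%d %s %d", seq_len(x$n), bases, partner)
      paste0(paste(lines, collapse = "\n"), "\n")
    }
  )
}

# Greedy layer assignment: pairs are visited sorted by (i, j) and each takes
# the first layer where it crosses nothing already placed there.
dotbracket_string <- function(x) {
  partner <- structure_partners(x) # errors on triples
  pairs <- x$pairs
  sym <- rep(".", x$n)
  if (nrow(pairs) == 0L) return(paste(sym, collapse = ""))
  ord <- order(pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  n_layers <- length(BRACKET_OPEN)
  layer_pairs <- rep(list(matrix(integer(0), ncol = 2L)), n_layers)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[[r, 1L]]; j <- pairs[[r, 2L]]
    placed <- FALSE
    for (l in seq_len(n_layers)) {
      lp <- layer_pairs[[l]]
      crossing <- nrow(lp) > 0L && any(
        (lp[, 1L] < i & i < lp[, 2L] & lp[, 2L] < j) |
        (i < lp[, 1L] & lp[, 1L] < j & j < lp[, 2L])
      )
      if (!crossing) {
        layer_pairs[[l]] <- rbind(lp, c(i, j))
        sym[[i]] <- BRACKET_OPEN[[l]]
        sym[[j]] <- BRACKET_CLOSE[[l]]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("structure needs more than ", n_layers,
           " bracket layers; not representable in dot-bracket", call. = FALSE)
    }
  }
  paste(sym, collapse = "")
}

#' Read and write structure files
#'
#' Thin file wrappers around the parsers and [write_structure()]. The format
#' is inferred from the file extension (`.db`/`.dbn` dot-bracket, `.ct` CT,
#' `.bpseq` BPSEQ) unless given.
#'
#' @param path File path.
#' @param format Format name, or `NULL` to infer from the extension.
#' @return `read_structure_file()` returns an [rna_structure()];
#'   `write_structure_file()` returns `path` invisibly.
#' @export
read_structure_file <- function(path, format = NULL) {
  format <- format %||% infer_structure_format(path)
  text <- readLines(path, warn = FALSE)
  switch(format,
    dotbracket = parse_dotbracket(text),
    ct = parse_ct(text),
    bpseq = parse_bpseq(text),
    stop("unknown structure format '", format, "'", call. = FALSE)
  )
}

#' @rdname read_structure_file
#' @param x An [rna_structure()].
#' @export
write_structure_file <- function(x, path, format = NULL) {
  format <- format %||% infer_structure_format(path)
  writeLines(sub("\n$", "", write_structure(x, format)), path)
  invisible(path)
}

infer_structure_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    db = , dbn = , dot = "dotbracket",
    ct = "ct",
    bpseq = "bpseq",
    stop("cannot infer structure format from extension '.", ext, "'",
         call. = FALSE)
  )
}

#' Read RNA sequences from FASTA
#'
#' @param path FASTA file path. T/t are read as U.
#' @return A tibble with columns `name` and `sequence`.
#' @export
read_rna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- vapply(as.character(set), normalize_rna_sequence, character(1))
  tibble::tibble(name = names(set) %||% as.character(seq_along(seqs)),
                 sequence = unname(seqs))
}

#' Write RNA sequences to FASTA
#'
#' @param x A tibble/data frame with `name` and `sequence` columns, or a
#'   named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(x, path) {
  if (is.character(x)) {
    x <- tibble::tibble(name = names(x) %||% as.character(seq_along(x)),
                        sequence = unname(x))
  }
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- x$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
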