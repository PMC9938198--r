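#' RNA secondary structure objects
#'
#' An `rna_structure` holds an RNA sequence over \{A,C,G,U\} together with its
#' set of base pairs. Pairs are stored 1-based as a two-column integer matrix
#' with `i < j` per row. A base may take part in more than one pair (base
#' triples) and pairs may cross (pseudoknots); serializers that cannot
#' represent such structures refuse them explicitly.
#'
#' @param sequence Character scalar over \{A,C,G,U\} (T is mapped to U,
#'   lowercase is uppercased).
#' @param pairs Two-column matrix (or data frame) of 1-based base-pair
#'   indices, or `NULL` for an unpaired structure. Rows are normalised so
#'   `i < j` and duplicates are dropped.
#' @param name Free-text identifier.
#' @return An object of class `rna_structure` with elements `name`,
#'   `sequence` (character scalar), `n` (length) and `pairs` (integer matrix,
#'   zero rows when unpaired).
#' @examples
#' rna_structure("GGGAAACCC", cbind(c(1, 2, 3), c(9, 8, 7)))
#' @export
rna_structure <- function(sequence, pairs = NULL, name = "") {
  sequence <- normalize_rna_sequence(sequence)
  n <- nchar(sequence)
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) > 0) {
    if (any(pairs < 1L) || any(pairs > n)) {
      stop("pair index out of range [1, ", n, "]", call. = FALSE)
    }
    flip <- pairs[, 1L] > pairs[, 2L]
    pairs[flip, ] <- pairs[flip, c(2L, 1L), drop = FALSE]
    if (any(pairs[, 1L] == pairs[, 2L])) {
      stop("a base cannot pair with itself", call. = FALSE)
    }
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  structure(
    list(name = as.character(name), sequence = sequence, n = n, pairs = pairs),
    class = "rna_structure"
  )
}

as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0) ||
      (is.data.frame(pairs) && nrow(pairs) == 0) || length(pairs) == 0) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (!is.matrix(pairs) || ncol(pairs) != 2L) {
    stop("`pairs` must be a two-column matrix of base indices", call. = FALSE)
  }
  storage.mode(pairs) <- "integer"
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

normalize_rna_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("`sequence` must be a single character string", call. = FALSE)
  }
  sequence <- chartr("t", "u", sequence)
  sequence <- toupper(sequence)
  sequence <- chartr("T", "U", sequence)
  bad <- gsub("[ACGU]", "", sequence)
  if (nzchar(bad)) {
    stop(
      "sequence contains non-ACGU symbol(s): '",
      paste(unique(strsplit(bad, "")[[1L]]), collapse = "', '"), "'",
      call. = FALSE
    )
  }
  sequence
}

#' @export
print.rna_structure <- function(x, ...) {
  nm <- if (nzchar(x$name)) x$name else "<unnamed>"
  cat("RNA secondary structure ", nm, "\n", sep = "")
  cat("  length: ", x$n, " nt, base pairs: ", nrow(x$pairs), "\n", sep = "")
  if (x$n <= 80 && single_partner(x)) {
    cat("  ", x$sequence, "\n  ", dotbracket_string(x), "\n", sep = "")
  }
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) {
  paste0("<rna_structure ", x$n, " nt, ", nrow(x$pairs), " pairs>")
}

#' @export
`==.rna_structure` <- function(e1, e2) {
  identical(e1$sequence, e2$sequence) && identical(
    pair_key(e1$pairs, e1$n), pair_key(e2$pairs, e2$n)
  )
}

pair_key <- function(pairs, n) {
  sort(as.numeric(pairs[, 1L]) * (n + 1) + as.numeric(pairs[, 2L]))
}

# TRUE when no base participates in more than one pair
single_partner <- function(x) {
  idx <- c(x$pairs[, 1L], x$pairs[, 2L])
  !anyDuplicated(idx)
}

#' Partner vector of a structure
#'
#' @param x An `rna_structure` whose bases each have at most one partner.
#' @return Integer vector of length `n`; `partner[k]` is the 1-based partner
#'   of base `k`, or 0 when unpaired.
#' @export
structure_partners <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  if (!single_partner(x)) {
    stop("structure contains base triples; no single partner vector exists",
         call. = FALSE)
  }
  partner <- integer(x$n)
  partner[x$pairs[, 1L]] <- x$pairs[, 2L]
  partner[x$pairs[, 2L]] <- x$pairs[, 1L]
  partner
}
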