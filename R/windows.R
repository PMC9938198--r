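# Channel order of the one-hot code. A '-' padding column is channel 1, so
# the code strings read left-to-right as channels 1..5:
#   '-' -> 10000, U -> 01000, G -> 00100, C -> 00010, A -> 00001
ONEHOT_ALPHABET <- c("-", "U", "G", "C", "A")

#' Slice a sequence into fixed-length windows
#'
#' Cuts an RNA into windows of length `L` starting at offsets
#' `1, 1 + step, 1 + 2*step, ...` for every offset not past the sequence end.
#' The final window (and any window extending past the end) is right-padded
#' with `'-'`. Dataset construction conventionally uses `step = L`
#' (non-overlapping); inference may use a smaller step so that overlapping
#' predictions can be averaged when stitching.
#'
#' @param sequence Character scalar over \{A,C,G,U\}.
#' @param L Window length in nt (default 200).
#' @param step Offset increment, `1 <= step <= L` (default `L`).
#' @return An object of class `rna_window_set`: a list with
#'   `parent_sequence`, `parent_length`, `window_length`, `step`, `offsets`
#'   (1-based start of each window) and `sequences` (padded window strings).
#' @examples
#' make_windows(strrep("ACGU", 60), L = 200, step = 200)
#' @export
make_windows <- function(sequence, L = 200L, step = L) {
  sequence <- normalize_rna_sequence(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("cannot window an empty sequence", call. = FALSE)
  L <- as.integer(L); step <- as.integer(step)
  if (L < 1L) stop("window length must be >= 1", call. = FALSE)
  if (step < 1L || step > L) {
    stop("`step` must satisfy 1 <= step <= L", call. = FALSE)
  }
  n_win <- max(1L, as.integer(ceiling(n / step)))
  offsets <- 1L + (seq_len(n_win) - 1L) * step
  seqs <- vapply(offsets, function(o) {
    chunk <- substring(sequence, o, min(o + L - 1L, n))
    paste0(chunk, strrep("-", L - nchar(chunk)))
  }, character(1))
  structure(
    list(parent_sequence = sequence, parent_length = n, window_length = L,
         step = step, offsets = offsets, sequences = seqs),
    class = "rna_window_set"
  )
}

#' @export
print.rna_window_set <- function(x, ...) {
  cat("Window set: ", length(x$offsets), " window(s) of ", x$window_length,
      " nt (step ", x$step, ") over ", x$parent_length, " nt\n", sep = "")
  invisible(x)
}

#' Validity masks of a window set
#'
#' @param ws An `rna_window_set`.
#' @return Logical matrix (windows x positions); `TRUE` on real bases,
#'   `FALSE` on `'-'` padding.
#' @export
window_masks <- function(ws) {
  stopifnot(inherits(ws, "rna_window_set"))
  t(vapply(ws$offsets, function(o) {
    seq_len(ws$window_length) + o - 1L <= ws$parent_length
  }, logical(ws$window_length)))
}

#' One-hot encode windows
#'
#' Encodes each window column as a 5-channel indicator in the fixed channel
#' order `(-, U, G, C, A)`: `'-'` is `10000`, `'U'` `01000`, `'G'` `00100`,
#' `'C'` `00010`, `'A'` `00001`. Exactly one channel is 1 per column.
#'
#' @param ws An `rna_window_set`, or a character vector of window strings
#'   over \{A,C,G,U,-\}.
#' @return Numeric array of dimension `(n_windows, L, 5)`.
#' @export
encode_onehot <- function(ws) {
  seqs <- if (inherits(ws, "rna_window_set")) ws$sequences else ws
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("windows have unequal lengths", call. = FALSE)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  idx <- match(chars, ONEHOT_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("unknown symbol(s) in window: '", paste(bad, collapse = "', '"),
         "'", call. = FALSE)
  }
  out <- array(0, dim = c(length(seqs), L, 5L),
               dimnames = list(NULL, NULL, ONEHOT_ALPHABET))
  flat <- cbind(as.vector(row(chars)), as.vector(col(chars)), as.vector(idx))
  out[flat] <- 1
  out
}

#' Decode one-hot windows back to strings
#'
#' @param x Array `(n_windows, L, 5)` as produced by [encode_onehot()].
#' @return Character vector of window strings.
#' @export
decode_onehot <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[[3L]] == 5L)
  apply(x, 1L, function(w) {
    paste(ONEHOT_ALPHABET[max.col(w, ties.method = "first")], collapse = "")
  })
}

#' Per-window labels and masks from a structure
#'
#' Slices the exterior labels of `structure` (or a precomputed label vector)
#' across the windows of `ws`. Padding positions are labeled 0 with mask 0,
#' so they never enter a loss or a metric.
#'
#' @param structure An [rna_structure()] of the window set's parent length,
#'   or an integer 0/1 label vector of that length.
#' @param ws An `rna_window_set`.
#' @return A list with `labels` and `mask`, both `(n_windows, L)` matrices
#'   (labels integer 0/1, mask 0/1).
#' @export
build_labels <- function(structure, ws) {
  stopifnot(inherits(ws, "rna_window_set"))
  labels <- if (inherits(structure, "rna_structure")) {
    if (structure$n != ws$parent_length) {
      stop("structure length (", structure$n,
           ") does not match window set parent length (", ws$parent_length,
           ")", call. = FALSE)
    }
    label_exterior(structure)
  } else {
    as.integer(structure)
  }
  if (length(labels) != ws$parent_length) {
    stop("labels length (", length(labels),
         ") does not match window set parent length (", ws$parent_length,
         ")", call. = FALSE)
  }
  L <- ws$window_length
  mask <- window_masks(ws)
  lab <- matrix(0L, nrow = length(ws$offsets), ncol = L)
  for (k in seq_along(ws$offsets)) {
    pos <- ws$offsets[[k]] + seq_len(L) - 1L
    real <- pos <= ws$parent_length
    lab[k, real] <- labels[pos[real]]
  }
  list(labels = lab, mask = mask * 1L)
}

#' Stitch per-window predictions onto the full sequence
#'
#' Maps window-local per-position probabilities back to parent coordinates.
#' Padding is discarded; a base covered by several overlapping windows gets
#' the arithmetic mean of its predictions. Every parent position must be
#' covered by at least one window.
#'
#' @param window_probs Numeric matrix `(n_windows, L)` of class-1
#'   probabilities.
#' @param ws The `rna_window_set` the predictions correspond to.
#' @return Numeric vector of length `parent_length`.
#' @export
stitch_predictions <- function(window_probs, ws) {
  stopifnot(inherits(ws, "rna_window_set"))
  window_probs <- as.matrix(window_probs)
  if (nrow(window_probs) != length(ws$offsets) ||
      ncol(window_probs) != ws$window_length) {
    stop("`window_probs` must be (", length(ws$offsets), " x ",
         ws$window_length, ") to match the window set", call. = FALSE)
  }
  n <- ws$parent_length
  acc <- numeric(n)
  cov <- integer(n)
  for (k in seq_along(ws$offsets)) {
    pos <- ws$offsets[[k]] + seq_len(ws$window_length) - 1L
    real <- pos <= n
    acc[pos[real]] <- acc[pos[real]] + window_probs[k, real]
    cov[pos[real]] <- cov[pos[real]] + 1L
  }
  if (any(cov == 0L)) {
    stop("coverage gap: position ", which(cov == 0L)[[1L]],
         " is covered by no window", call. = FALSE)
  }
  acc / cov
}

#' In-memory window dataset
#'
#' Bundles encoded windows with labels and masks for training or evaluation.
#'
#' @param x Array `(n_windows, L, 5)` of one-hot inputs.
#' @param y Integer matrix `(n_windows, L)` of 0/1 labels.
#' @param mask Matrix `(n_windows, L)` of 0/1 validity flags.
#' @return An object of class `rna_window_dataset`.
#' @export
window_dataset <- function(x, y, mask) {
  stopifnot(is.array(x), length(dim(x)) == 3L,
            nrow(y) == dim(x)[[1L]], ncol(y) == dim(x)[[2L]],
            identical(dim(y), dim(as.matrix(mask))))
  structure(list(x = x, y = y, mask = as.matrix(mask) * 1L),
            class = "rna_window_dataset")
}

#' @export
print.rna_window_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat("Window dataset: ", d[[1L]], " windows x ", d[[2L]], " nt; ",
      sum(x$mask), " real bases (", round(100 * mean(x$y[x$mask == 1]), 1),
      "% exterior)\n", sep = "")
  invisible(x)
}

#' Combine or subset window datasets
#'
#' @param ... `rna_window_dataset` objects (for `bind_window_datasets`).
#' @return An `rna_window_dataset`.
#' @export
bind_window_datasets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !inherits(sets[[1L]], "rna_window_dataset")) {
    sets <- sets[[1L]]
  }
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "rna_window_dataset")))
  L <- dim(sets[[1L]]$x)[[2L]]
  stopifnot(all(vapply(sets, function(s) dim(s$x)[[2L]], integer(1)) == L))
  x <- do.call(abind_rows, lapply(sets, `[[`, "x"))
  y <- do.call(rbind, lapply(sets, `[[`, "y"))
  m <- do.call(rbind, lapply(sets, `[[`, "mask"))
  window_dataset(x, y, m)
}

#' @rdname bind_window_datasets
#' @param ds An `rna_window_dataset`.
#' @param idx Integer vector of window indices to keep.
#' @export
subset_window_dataset <- function(ds, idx) {
  stopifnot(inherits(ds, "rna_window_dataset"))
  window_dataset(ds$x[idx, , , drop = FALSE], ds$y[idx, , drop = FALSE],
                 ds$mask[idx, , drop = FALSE])
}

# rbind for 3-d arrays along the first dimension
abind_rows <- function(...) {
  arrays <- list(...)
  d <- dim(arrays[[1L]])
  total <- sum(vapply(arrays, function(a) dim(a)[[1L]], integer(1)))
  out <- array(0, dim = c(total, d[[2L]], d[[3L]]),
               dimnames = list(NULL, NULL, dimnames(arrays[[1L]])[[3L]]))
  at <- 0L
  for (a in arrays) {
    out[at + seq_len(dim(a)[[1L]]), , ] <- a
    at <- at + dim(a)[[1L]]
  }
  out
}
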