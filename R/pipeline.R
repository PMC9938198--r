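#' Maximum base-pairing fold (Nussinov dynamic program)
#'
#' A deterministic built-in fragment predictor: finds a nested secondary
#' structure with the maximum number of allowed base pairs, subject to a
#' minimum hairpin loop length. Ties are broken deterministically (a base
#' stays unpaired rather than paired on equal score; among equal partners
#' the 5'-most wins), so the output is reproducible. This is a
#' combinatorial, not thermodynamic, folder — adequate as a pluggable
#' reference predictor for pipeline experiments, not a substitute for
#' energy-based tools.
#'
#' @param sequence RNA sequence over \{A,C,G,U\}.
#' @param min_loop Minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @param allowed_pairs Character vector of allowed ordered pairs.
#' @return An [rna_structure()].
#' @examples
#' nussinov_fold("GGGAAACCC")
#' @export
nussinov_fold <- function(sequence, min_loop = 3L,
                          allowed_pairs = c("AU", "UA", "GC", "CG",
                                            "GU", "UG")) {
  sequence <- normalize_rna_sequence(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence", call. = FALSE)
  pairs <- nussinov_pairs_cpp(sequence, as.integer(min_loop), allowed_pairs)
  rna_structure(sequence, pairs, name = "nussinov")
}

#' Fragment predictor constructors
#'
#' A fragment predictor is any function `f(sequence, ...)` returning an
#' [rna_structure()] of the same length; the pipeline additionally passes
#' `start` and `end` (parent coordinates) which a predictor may use or
#' ignore. `nussinov_predictor()` wraps [nussinov_fold()];
#' `oracle_predictor()` closes over a reference structure and returns the
#' true substructure of each fragment — the "exact predictor" used to test
#' the premise that perfect labels plus perfect fragment folding reconstruct
#' the full structure. `command_predictor()` adapts an external folding
#' program that reads a FASTA file and writes dot-bracket to stdout.
#'
#' @param min_loop,allowed_pairs Passed to [nussinov_fold()].
#' @return A predictor function.
#' @export
nussinov_predictor <- function(min_loop = 3L,
                               allowed_pairs = c("AU", "UA", "GC", "CG",
                                                 "GU", "UG")) {
  function(sequence, ...) nussinov_fold(sequence, min_loop, allowed_pairs)
}

#' @rdname nussinov_predictor
#' @param reference The true parent [rna_structure()].
#' @export
oracle_predictor <- function(reference) {
  stopifnot(inherits(reference, "rna_structure"))
  function(sequence, start, end, ...) {
    extract_substructure(reference, start, end)
  }
}

#' @rdname nussinov_predictor
#' @param command,args External program invoked as
#'   `command args <fasta-file>`; must print a dot-bracket line for the
#'   sequence (RNAfold-style output is accepted).
#' @export
command_predictor <- function(command, args = character(0)) {
  force(command); force(args)
  function(sequence, ...) {
    fa <- tempfile(fileext = ".fa")
    on.exit(unlink(fa))
    writeLines(c(">frag", sequence), fa)
    out <- system2(command, c(args, fa), stdout = TRUE)
    db <- grep("^[.()\\[\\]{}<>]+", out, value = TRUE)
    if (length(db) == 0L) {
      stop("external predictor produced no dot-bracket line", call. = FALSE)
    }
    db <- sub("\\s.*$", "", db[[1L]])
    parse_dotbracket(c(sequence, db))
  }
}

#' Partition, fold fragments, and assemble
#'
#' The end-to-end divide-and-conquer procedure: obtain per-base exterior
#' labels (from a trained labeler/ensemble, or supplied directly in oracle
#' mode), partition the sequence into independent fragments, predict each
#' fragment's substructure with `predictor`, and assemble the substructures
#' into the complete secondary structure. Exterior-labeled positions are
#' unpaired in the output by construction, and with an all-zero label vector
#' the result is exactly `predictor(sequence)`.
#'
#' @param sequence RNA sequence (character scalar).
#' @param labeler Either an `rna_labeler`/`rna_labeler_ensemble`, or an
#'   integer 0/1 label vector of the sequence length (oracle mode).
#' @param predictor A fragment predictor (see [nussinov_predictor()]).
#' @param threshold Probability threshold for label binarization.
#' @param step Inference window step when a model is used (default half
#'   window).
#' @param min_exterior_run Predicted exterior runs shorter than this are
#'   relabeled non-exterior before partitioning (smoothing; default 1 =
#'   off).
#' @param name Name of the assembled structure.
#' @return An [rna_structure()] of the full sequence.
#' @export
partition_predict_assemble <- function(sequence, labeler, predictor,
                                       threshold = 0.5, step = NULL,
                                       min_exterior_run = 1L,
                                       name = "assembled") {
  sequence <- normalize_rna_sequence(sequence)
  n <- nchar(sequence)
  labels <- if (is.numeric(labeler) || is.logical(labeler)) {
    lv <- as.integer(labeler)
    if (length(lv) != n) {
      stop("label vector length ", length(lv),
           " does not match sequence length ", n, call. = FALSE)
    }
    lv
  } else {
    probs <- predict_exterior_probs(labeler, sequence, step = step)
    predict_labels(probs, threshold)
  }
  if (min_exterior_run > 1L) {
    labels <- smooth_exterior_runs(labels, min_exterior_run)
  }
  fragments <- partition_ifragments(sequence, labels)
  if (nrow(fragments) == 0L) {
    return(rna_structure(sequence, NULL, name = name))
  }
  fragments$substructure <- purrr::pmap(
    fragments[c("sequence", "start", "end")],
    function(sequence, start, end) {
      sub <- predictor(sequence, start = start, end = end)
      if (!inherits(sub, "rna_structure") || sub$n != nchar(sequence)) {
        stop("predictor returned an invalid structure for fragment [",
             start, ", ", end, "]", call. = FALSE)
      }
      sub
    }
  )
  assemble_structure(sequence, fragments, name = name)
}

smooth_exterior_runs <- function(labels, min_run) {
  r <- rle(labels)
  r$values[r$values == 1L & r$lengths < min_run] <- 0L
  inverse.rle(r)
}

#' Paired evaluation of folding with and without partitioning
#'
#' For every RNA in a corpus, folds the full sequence with `predictor` alone
#' ("without") and through [partition_predict_assemble()] ("with"), scores
#' both against the reference structure with base-pair confusion metrics,
#' and summarises the paired differences — overall, by RNA-length bin, and
#' with a permutation sign test on the per-RNA F1 differences.
#'
#' @param corpus A tibble with list-columns `structure` (reference
#'   [rna_structure()]) and, for oracle mode, `labels` (as produced by
#'   [generate_corpus()]).
#' @param labeler An `rna_labeler`/ensemble, or `NULL` for oracle mode
#'   (the corpus `labels` column is used).
#' @param predictor A fragment predictor.
#' @param threshold Label threshold when a model is used.
#' @param bins Numeric breaks for RNA-length binning.
#' @param n_perm Sign-flip permutations for the paired test.
#' @param seed Seed for the permutation test.
#' @return A list with `per_rna` (per-RNA metrics for both arms),
#'   `summary` (means, mean paired F1 difference, p-value), and `by_length`.
#' @export
evaluate_with_without <- function(corpus, labeler, predictor,
                                  threshold = 0.5,
                                  bins = c(0, 100, 200, 400, 800, Inf),
                                  n_perm = 2000L, seed = 1L) {
  stopifnot(is.data.frame(corpus), nrow(corpus) >= 1L,
            "structure" %in% names(corpus))
  oracle <- is.null(labeler)
  if (oracle && !"labels" %in% names(corpus)) {
    stop("oracle mode needs a `labels` column in the corpus", call. = FALSE)
  }
  per <- purrr::map_dfr(seq_len(nrow(corpus)), function(k) {
    ref <- corpus$structure[[k]]
    without <- predictor(ref$sequence, start = 1L, end = ref$n)
    lab_arg <- if (oracle) corpus$labels[[k]] else labeler
    with_ <- partition_predict_assemble(ref$sequence, lab_arg, predictor,
                                        threshold = threshold)
    m_wo <- compute_metrics(pair_confusion(without, ref))
    m_wi <- compute_metrics(pair_confusion(with_, ref))
    tibble::tibble(
      name = if ("name" %in% names(corpus)) corpus$name[[k]] else
        paste0("rna_", k),
      length = ref$n,
      SEN_without = m_wo$SEN, SEN_with = m_wi$SEN,
      PRE_without = m_wo$PRE, PRE_with = m_wi$PRE,
      ACC_without = m_wo$ACC, ACC_with = m_wi$ACC,
      MCC_without = m_wo$MCC, MCC_with = m_wi$MCC,
      F1_without = m_wo$F1, F1_with = m_wi$F1
    )
  })
  d <- per$F1_with - per$F1_without
  d_ok <- d[!is.na(d)]
  p_value <- if (length(d_ok) == 0L) NA_real_ else withr_seed(seed, {
    obs <- mean(d_ok)
    flips <- vapply(seq_len(n_perm), function(b) {
      mean(d_ok * sample(c(-1, 1), length(d_ok), replace = TRUE))
    }, numeric(1))
    mean(abs(flips) >= abs(obs) - 1e-15)
  })
  summary <- tibble::tibble(
    n_rna = nrow(per),
    mean_F1_without = mean(per$F1_without, na.rm = TRUE),
    mean_F1_with = mean(per$F1_with, na.rm = TRUE),
    mean_F1_diff = mean(d, na.rm = TRUE),
    p_value = p_value
  )
  by_length <- per |>
    dplyr::mutate(length_bin = cut(.data$length, breaks = bins)) |>
    dplyr::group_by(.data$length_bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_F1_without = mean(.data$F1_without, na.rm = TRUE),
      mean_F1_with = mean(.data$F1_with, na.rm = TRUE),
      .groups = "drop"
    )
  list(per_rna = per, summary = summary, by_length = by_length)
}
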