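#' Confusion counts
#'
#' Container for TP/FP/TN/FN counts in one of three modes: `base` (per-base
#' exterior-loop labels), `segment` (maximal runs of the truth labels), or
#' `pair` (base pairs of two structures).
#'
#' @param TP,FP,TN,FN Non-negative counts.
#' @param mode One of `"base"`, `"segment"`, `"pair"`.
#' @return A `confusion_counts` object (also a one-row tibble).
#' @export
confusion_counts <- function(TP, FP, TN, FN, mode = "base") {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  out <- tibble::tibble(TP = as.numeric(TP), FP = as.numeric(FP),
                        TN = as.numeric(TN), FN = as.numeric(FN),
                        mode = mode)
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Per-base confusion of predicted vs true exterior labels
#'
#' The positive class is "exterior loop". Masked positions (padding) are
#' never counted.
#'
#' @param pred,truth Integer/logical 0/1 vectors of equal length.
#' @param mask Optional 0/1 vector; positions with mask 0 are ignored.
#' @return A [confusion_counts()] in `base` mode.
#' @export
base_confusion <- function(pred, truth, mask = NULL) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth lengths differ (", length(pred), " vs ",
         length(truth), ")", call. = FALSE)
  }
  if (!is.null(mask)) {
    if (length(mask) != length(pred)) {
      stop("mask length differs from labels", call. = FALSE)
    }
    keep <- as.logical(mask)
    pred <- pred[keep]; truth <- truth[keep]
  }
  confusion_counts(
    TP = sum(pred == 1L & truth == 1L),
    FP = sum(pred == 1L & truth == 0L),
    TN = sum(pred == 0L & truth == 0L),
    FN = sum(pred == 0L & truth == 1L),
    mode = "base"
  )
}

#' Segment-level confusion of predicted vs true exterior labels
#'
#' Segments are the maximal runs of constant truth label. An exterior
#' segment counts as TP when at least one base inside it is predicted
#' exterior, otherwise FN; a non-exterior segment counts as FP when at least
#' one base inside it is predicted exterior, otherwise TN. This scores
#' whether the partition boundaries are found at all, rather than each base.
#'
#' @param pred,truth Integer/logical 0/1 vectors of equal length.
#' @return A [confusion_counts()] in `segment` mode.
#' @export
segment_confusion <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth lengths differ (", length(pred), " vs ",
         length(truth), ")", call. = FALSE)
  }
  if (length(truth) == 0L) return(confusion_counts(0, 0, 0, 0, "segment"))
  r <- rle(truth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- vapply(seq_along(starts), function(k) {
    any(pred[starts[[k]]:ends[[k]]] == 1L)
  }, logical(1))
  ext <- r$values == 1L
  confusion_counts(
    TP = sum(ext & hit),
    FN = sum(ext & !hit),
    FP = sum(!ext & hit),
    TN = sum(!ext & !hit),
    mode = "segment"
  )
}

#' Base-pair confusion between two structures
#'
#' Compares predicted and reference base-pair sets on the same sequence
#' length: TP are shared pairs, FP predicted-only, FN reference-only, and TN
#' all remaining unordered position pairs.
#'
#' @param pred,ref [rna_structure()] objects of equal length.
#' @return A [confusion_counts()] in `pair` mode.
#' @export
pair_confusion <- function(pred, ref) {
  stopifnot(inherits(pred, "rna_structure"), inherits(ref, "rna_structure"))
  if (pred$n != ref$n) {
    stop("structures have different lengths (", pred$n, " vs ", ref$n, ")",
         call. = FALSE)
  }
  n <- pred$n
  kp <- pair_key(pred$pairs, n)
  kr <- pair_key(ref$pairs, n)
  TP <- length(intersect(kp, kr))
  FP <- length(kp) - TP
  FN <- length(kr) - TP
  TN <- n * (n - 1) / 2 - TP - FP - FN
  confusion_counts(TP, FP, TN, FN, mode = "pair")
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, and the F1 score
#' `2*PRE*SEN/(PRE+SEN)`. Any metric with a zero denominator is undefined
#' and reported as `NA`, never coerced to 0.
#'
#' @param counts A [confusion_counts()] (or anything with TP/FP/TN/FN
#'   fields).
#' @return A one-row tibble with columns `SEN`, `PRE`, `ACC`, `MCC`, `F1`
#'   (and the counts and mode carried along).
#' @examples
#' compute_metrics(confusion_counts(TP = 2, FN = 0, FP = 1, TN = 1))
#' @export
compute_metrics <- function(counts) {
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  TN <- as.numeric(counts$TN); FN <- as.numeric(counts$FN)
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  SEN <- ratio(TP, TP + FN)
  PRE <- ratio(TP, TP + FP)
  ACC <- ratio(TP + TN, TP + FP + TN + FN)
  mcc_den2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- ifelse(mcc_den2 > 0, (TP * TN - FP * FN) / sqrt(mcc_den2), NA_real_)
  F1 <- ifelse(!is.na(PRE) & !is.na(SEN) & (PRE + SEN) > 0,
               2 * PRE * SEN / (PRE + SEN), NA_real_)
  tibble::tibble(
    SEN = SEN, PRE = PRE, ACC = ACC, MCC = MCC, F1 = F1,
    TP = TP, FP = FP, TN = TN, FN = FN,
    mode = counts$mode %||% "base"
  )
}

#' Pool confusion counts (micro-averaging)
#'
#' @param counts_list List of [confusion_counts()] of one mode.
#' @return A single [confusion_counts()] with summed entries.
#' @export
pool_confusion <- function(counts_list) {
  stopifnot(length(counts_list) >= 1L)
  mode <- counts_list[[1L]]$mode
  sums <- Reduce(`+`, lapply(counts_list, function(cc) {
    c(cc$TP, cc$FP, cc$TN, cc$FN)
  }))
  confusion_counts(sums[[1L]], sums[[2L]], sums[[3L]], sums[[4L]], mode)
}

#' Dataset-level labeling metrics
#'
#' Evaluates predicted label vectors against truth over a corpus, both
#' pooled (micro: counts summed, metrics once) and per-sequence averaged
#' (macro: metrics per sequence, then averaged over the sequences where they
#' are defined; undefined values are excluded with a recorded count).
#'
#' @param pred_list,truth_list Lists of 0/1 label vectors.
#' @param mode `"base"` or `"segment"`.
#' @param mask_list Optional list of masks (base mode only).
#' @return A list with `micro` (one-row metrics tibble), `macro` (one-row
#'   tibble of means + `n_undefined` per metric), and `per_sequence`.
#' @export
evaluate_labels <- function(pred_list, truth_list, mode = c("base", "segment"),
                            mask_list = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(pred_list) == length(truth_list))
  counts <- purrr::map(seq_along(pred_list), function(k) {
    if (mode == "base") {
      mk <- if (is.null(mask_list)) NULL else mask_list[[k]]
      base_confusion(pred_list[[k]], truth_list[[k]], mk)
    } else {
      segment_confusion(pred_list[[k]], truth_list[[k]])
    }
  })
  per_seq <- purrr::map_dfr(counts, compute_metrics)
  macro_cols <- c("SEN", "PRE", "ACC", "MCC", "F1")
  macro <- purrr::map_dfc(macro_cols, function(cl) {
    v <- per_seq[[cl]]
    tibble::tibble("{cl}" := mean(v, na.rm = TRUE),
                   "{cl}_n_undefined" := sum(is.na(v)))
  })
  list(micro = compute_metrics(pool_confusion(counts)),
       macro = macro,
       per_sequence = per_seq)
}

#' Bootstrap mean and standard error
#'
#' Resamples the per-item values with replacement `B` times and reports the
#' sample mean together with the standard deviation of the resample means
#' (the bootstrap standard error). Seeded and reproducible.
#'
#' @param values Numeric vector of per-item (e.g. per-sequence) metric
#'   values; `NA`s (undefined metrics) are dropped first.
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return A list with `mean`, `se`, `B`, and `n` (items used).
#' @export
bootstrap_se <- function(values, B = 100L, seed = 1L) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("need at least two non-missing values for a bootstrap SE",
         call. = FALSE)
  }
  B <- as.integer(B)
  stopifnot(B >= 1L)
  withr_seed(seed, {
    means <- vapply(seq_len(B), function(b) {
      mean(values[sample.int(length(values), replace = TRUE)])
    }, numeric(1))
  })
  list(mean = mean(values), se = stats::sd(means), B = B, n = length(values))
}
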