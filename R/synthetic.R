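#' Parameters of the synthetic structure generator
#'
#' The generator emulates the anatomy of deposited RNA secondary structures:
#' 0 or more independent fragments (each a nested stem-loop domain closed by
#' an outer helix, optionally carrying one crossing pair) separated by
#' unpaired exterior linkers. Paired positions are complementary with a
#' configurable GC/AU/GU mix, and unpaired bases follow region-specific GC
#' fractions, exterior loops being GC-depleted relative to fragment
#' interiors as observed in real corpora.
#'
#' Defaults draw fragment counts so that roughly one RNA in six has more
#' than two fragments (probabilities 0.55/0.28 for 1/2 fragments and a
#' geometric tail over 3..10) and fragment lengths from a lognormal with
#' mean about 130 nt, matching the fragment-count and fragment-length shape
#' of curated corpora; resulting RNA lengths span roughly 50-1800 nt.
#'
#' @param n_fragments `NULL` for the default count distribution, a single
#'   count, a `c(min, max)` range (uniform), or a probability vector over
#'   counts `1..length(p)`.
#' @param fragment_meanlog,fragment_sdlog Lognormal parameters of fragment
#'   length (nt).
#' @param min_fragment Shortest fragment the stem-loop grammar can realise.
#' @param linker_mean Mean length of internal exterior linkers (geometric,
#'   minimum 1 nt). The default, with `end_linker_mean`, yields roughly a
#'   fifth of bases exterior, concentrated in runs of 10-20 nt, matching the
#'   exterior content implied by curated-corpus fragment statistics (mean
#'   fragment ~129 nt, ~1.5 fragments per RNA).
#' @param end_linker_mean Mean length of the 5'/3' dangling exterior ends
#'   (geometric, minimum 0 nt).
#' @param helix_min,helix_max Helix length bounds (base pairs).
#' @param hairpin_min Minimum hairpin loop length (nt).
#' @param p_branch Probability that a loop interior opens two sub-domains
#'   (multibranch) rather than one.
#' @param p_continue Probability that a loop interior continues with one
#'   sub-domain (internal loop/bulge) rather than ending in a hairpin.
#' @param pair_probs Probabilities of GC, AU, GU pair types (normalised).
#' @param exterior_gc,fragment_gc G+C fraction of unpaired bases in exterior
#'   loops and inside fragments.
#' @param pseudoknot_prob Probability that a fragment carries one crossing
#'   (pseudoknotted) pair.
#' @param label_noise Per-base label flip rate used for the coarse variant
#'   of generated datasets (emulating noisy training labels).
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_fragments = NULL,
                         fragment_meanlog = log(110), fragment_sdlog = 0.55,
                         min_fragment = 12L,
                         linker_mean = 20, end_linker_mean = 15,
                         helix_min = 2L, helix_max = 10L, hairpin_min = 3L,
                         p_branch = 0.25, p_continue = 0.5,
                         pair_probs = c(GC = 0.55, AU = 0.35, GU = 0.10),
                         exterior_gc = 0.2, fragment_gc = 0.6,
                         pseudoknot_prob = 0.05, label_noise = 0) {
  stopifnot(helix_min >= 1L, helix_max >= helix_min, hairpin_min >= 3L,
            min_fragment >= 2L * helix_min + hairpin_min,
            linker_mean >= 1, end_linker_mean >= 0,
            exterior_gc >= 0, exterior_gc <= 1,
            fragment_gc >= 0, fragment_gc <= 1,
            pseudoknot_prob >= 0, pseudoknot_prob <= 1,
            label_noise >= 0, label_noise < 1,
            all(pair_probs >= 0), sum(pair_probs) > 0)
  pair_probs <- pair_probs / sum(pair_probs)
  structure(as.list(environment()), class = "synth_params")
}

# Default fragment-count distribution: P(1)=.55, P(2)=.28, geometric tail
# over 3..10 carrying the remaining mass.
default_count_probs <- function() {
  tail <- 0.6 ^ (0:7)
  c(0.55, 0.28, 0.17 * tail / sum(tail))
}

sample_fragment_count <- function(spec) {
  if (is.null(spec)) {
    p <- default_count_probs()
    return(sample.int(length(p), 1L, prob = p))
  }
  if (length(spec) == 1L) return(as.integer(spec))
  if (length(spec) == 2L && all(spec == floor(spec)) && is.null(names(spec))) {
    return(sample(seq.int(spec[[1L]], spec[[2L]]), 1L))
  }
  sample.int(length(spec), 1L, prob = spec)
}

#' Generate one synthetic structure with ground-truth labels
#'
#' Draws alternating exterior linkers and stem-loop fragments under
#' [synth_params()]. By construction every fragment begins and ends with a
#' paired base of its outer helix, so the true exterior labels are exactly
#' the complement of the fragments and agree with [label_exterior()] applied
#' to the emitted structure.
#'
#' @param params A [synth_params()] object.
#' @param seed Optional integer seed (uses and restores the RNG state).
#' @param name Name for the structure.
#' @return A list with `structure` ([rna_structure()]), `labels` (0/1
#'   integer vector), and `fragments` (tibble of true fragment bounds).
#' @export
generate_structure <- function(params = synth_params(), seed = NULL,
                               name = "synth") {
  stopifnot(inherits(params, "synth_params"))
  if (!is.null(seed)) {
    return(withr_seed(seed, generate_structure(params, NULL, name)))
  }
  n_frag <- sample_fragment_count(params$n_fragments)
  rgeom_min <- function(k, mean, min) {
    extra_mean <- max(mean - min, 1e-9)
    min + stats::rgeom(k, 1 / (1 + extra_mean))
  }
  if (n_frag == 0L) {
    n <- max(10L, round(stats::rlnorm(1, log(60), 0.5)))
    seqchars <- sample_unpaired(n, params$exterior_gc)
    s <- rna_structure(paste(seqchars, collapse = ""), NULL, name = name)
    return(list(structure = s, labels = rep(1L, n),
                fragments = partition_ifragments(s, rep(1L, n))))
  }
  frag_lens <- pmax(params$min_fragment,
                    pmin(1200L, round(stats::rlnorm(n_frag,
                                                    params$fragment_meanlog,
                                                    params$fragment_sdlog))))
  internal <- if (n_frag > 1L) {
    rgeom_min(n_frag - 1L, params$linker_mean, 1L)
  } else integer(0)
  ends <- rgeom_min(2L, max(params$end_linker_mean, 0.01), 0L)
  # layout: end1 | frag1 | link1 | frag2 | ... | fragK | end2
  spans <- integer(0)
  starts <- integer(n_frag)
  pos <- ends[[1L]]
  for (k in seq_len(n_frag)) {
    starts[[k]] <- pos + 1L
    pos <- pos + frag_lens[[k]]
    if (k < n_frag) pos <- pos + internal[[k]]
  }
  n <- pos + ends[[2L]]
  labels <- rep(1L, n)
  pair_list <- vector("list", n_frag)
  for (k in seq_len(n_frag)) {
    labels[starts[[k]]:(starts[[k]] + frag_lens[[k]] - 1L)] <- 0L
    local_pairs <- grow_domain(frag_lens[[k]], params)
    if (stats::runif(1) < params$pseudoknot_prob) {
      local_pairs <- add_crossing_pair(local_pairs, frag_lens[[k]],
                                       params$hairpin_min)
    }
    pair_list[[k]] <- local_pairs + (starts[[k]] - 1L)
  }
  pairs <- do.call(rbind, pair_list)
  seqchars <- character(n)
  seqchars[labels == 1L] <- sample_unpaired(sum(labels), params$exterior_gc)
  unpaired_in_frag <- which(labels == 0L)
  unpaired_in_frag <- setdiff(unpaired_in_frag, c(pairs[, 1L], pairs[, 2L]))
  seqchars[unpaired_in_frag] <- sample_unpaired(length(unpaired_in_frag),
                                                params$fragment_gc)
  types <- sample(c("GC", "AU", "GU"), nrow(pairs), replace = TRUE,
                  prob = params$pair_probs)
  left <- character(nrow(pairs)); right <- character(nrow(pairs))
  flip <- stats::runif(nrow(pairs)) < 0.5
  comp <- list(GC = c("G", "C"), AU = c("A", "U"), GU = c("G", "U"))
  for (r in seq_len(nrow(pairs))) {
    duo <- comp[[types[[r]]]]
    if (flip[[r]]) duo <- rev(duo)
    left[[r]] <- duo[[1L]]; right[[r]] <- duo[[2L]]
  }
  seqchars[pairs[, 1L]] <- left
  seqchars[pairs[, 2L]] <- right
  s <- rna_structure(paste(seqchars, collapse = ""), pairs, name = name)
  list(structure = s, labels = labels,
       fragments = partition_ifragments(s, labels))
}

sample_unpaired <- function(k, gc) {
  if (k == 0L) return(character(0))
  sample(c("G", "C", "A", "U"), k, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

# Recursive stem-loop grammar over a closed span of `len` local positions:
# an outer helix, then a hairpin, one continued sub-domain, or two branched
# sub-domains inside. Returns a local pair matrix; position 1 and `len` are
# always paired so the whole span is non-exterior.
grow_domain <- function(len, params) {
  min_dom <- 2L * params$helix_min + params$hairpin_min
  stopifnot(len >= min_dom)
  h_cap <- min(params$helix_max, (len - params$hairpin_min) %/% 2L)
  h <- if (h_cap <= params$helix_min) params$helix_min else
    sample(seq.int(params$helix_min, h_cap), 1L)
  pairs <- cbind(seq_len(h), len + 1L - seq_len(h))
  inner_len <- len - 2L * h
  inner <- grow_loop(inner_len, params)
  if (nrow(inner)) pairs <- rbind(pairs, inner + h)
  pairs
}

# Interior of a loop spanning `len` unconstrained local positions. Large
# interiors keep structuring: a bare hairpin loop is only allowed while the
# span is short, since real hairpin loops are a handful of nucleotides.
grow_loop <- function(len, params) {
  empty <- matrix(integer(0), ncol = 2L)
  min_dom <- 2L * params$helix_min + params$hairpin_min
  if (len < min_dom + 2L) return(empty) # hairpin loop (len >= hairpin_min)
  u <- stats::runif(1)
  if (len >= 3L * min_dom) {
    # too long for a bare loop: renormalise between branch and continue
    u <- u * (params$p_branch + params$p_continue)
  }
  if (u < params$p_branch && len >= 2L * min_dom + 2L) {
    # two sub-domains with unpaired margins m1 | d1 | m2 | d2 | m3
    margins <- sample_margins(3L, len - 2L * min_dom)
    extra <- len - 2L * min_dom - sum(margins)
    d1 <- min_dom + sample.int(extra + 1L, 1L) - 1L
    d2 <- len - sum(margins) - d1
    o1 <- margins[[1L]]
    o2 <- margins[[1L]] + d1 + margins[[2L]]
    rbind(grow_domain(d1, params) + o1, grow_domain(d2, params) + o2)
  } else if (u < params$p_branch + params$p_continue) {
    # one sub-domain with unpaired margins (internal loop / bulge)
    margins <- sample_margins(2L, len - min_dom)
    d <- len - sum(margins)
    grow_domain(d, params) + margins[[1L]]
  } else {
    empty
  }
}

# `k` non-negative margin lengths with sum <= budget, geometric-ish small.
sample_margins <- function(k, budget) {
  m <- integer(k)
  for (i in seq_len(k)) {
    m[[i]] <- min(budget - sum(m), stats::rgeom(1, 0.35))
  }
  m
}

# One crossing pair between two unpaired positions of a fragment, if any
# candidate crosses an existing pair; otherwise the pairs are returned
# unchanged. Keeps every base single-partnered (CT-representable).
add_crossing_pair <- function(pairs, len, hairpin_min) {
  unpaired <- setdiff(seq_len(len), c(pairs[, 1L], pairs[, 2L]))
  if (length(unpaired) < 2L) return(pairs)
  cand_u <- sample(unpaired, min(length(unpaired), 15L))
  for (u in cand_u) {
    vs <- unpaired[abs(unpaired - u) > hairpin_min]
    vs <- vs[sample.int(length(vs))] # sample() would misread a scalar
    for (v in vs) {
      i <- min(u, v); j <- max(u, v)
      crossing <- any((pairs[, 1L] < i & i < pairs[, 2L] & pairs[, 2L] < j) |
                        (i < pairs[, 1L] & pairs[, 1L] < j & j < pairs[, 2L]))
      if (crossing) return(rbind(pairs, c(i, j)))
    }
  }
  pairs
}

#' Generate a corpus of synthetic structures
#'
#' @param n Number of RNAs.
#' @param params A [synth_params()].
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @return A tibble with columns `name`, `structure` (list), `labels`
#'   (list), `length`, `n_fragments`.
#' @export
generate_corpus <- function(n, params = synth_params(), seed = 1L) {
  withr_seed(seed, {
    rows <- purrr::map(seq_len(n), function(k) {
      g <- generate_structure(params, NULL, name = sprintf("synth_%04d", k))
      tibble::tibble(name = g$structure$name,
                     structure = list(g$structure),
                     labels = list(g$labels),
                     length = g$structure$n,
                     n_fragments = nrow(g$fragments))
    })
  })
  dplyr::bind_rows(rows)
}

#' Generate windowed train/val/test datasets (coarse and accurate)
#'
#' Generates a corpus, splits it into disjoint train/validation/test subsets
#' at the RNA level, windows every RNA, and builds per-window labels and
#' masks. Two label variants are produced: `accurate` (exact exterior
#' labels) and `coarse`, where each real base's label is flipped
#' independently with probability `params$label_noise`, emulating training
#' corpora whose structures are only approximately correct.
#'
#' @param n Number of RNAs in the corpus.
#' @param params A [synth_params()]; `params$label_noise` drives the coarse
#'   variant.
#' @param split Named fractions for train/val/test; must sum to 1.
#' @param L,step Window length and step for dataset construction.
#' @param seed Integer seed.
#' @return A list with `accurate` and `coarse` (each a list of
#'   `rna_window_dataset` objects named train/val/test) and `corpus` (the
#'   generated tibble plus a `split` column).
#' @export
generate_dataset <- function(n, params = synth_params(),
                             split = c(train = 0.7, val = 0.15, test = 0.15),
                             L = 200L, step = L, seed = 1L) {
  stopifnot(abs(sum(split) - 1) < 1e-8, length(split) == 3L)
  corpus <- generate_corpus(n, params, seed = seed)
  n_train <- floor(split[[1L]] * n)
  n_val <- floor(split[[2L]] * n)
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1L) {
    stop("corpus of ", n, " RNAs too small for split ",
         paste(split, collapse = "/"), call. = FALSE)
  }
  withr_seed(seed + 1L, {
    assignment <- sample(rep(c("train", "val", "test"),
                             times = c(n_train, n_val, n_test)))
    corpus$split <- assignment
    noisy_labels <- purrr::map(corpus$labels, function(lab) {
      if (params$label_noise <= 0) return(lab)
      flip <- stats::runif(length(lab)) < params$label_noise
      ifelse(flip, 1L - lab, lab)
    })
  })
  build_split <- function(which_split, label_list) {
    idx <- which(corpus$split == which_split)
    sets <- purrr::map(idx, function(k) {
      ws <- make_windows(corpus$structure[[k]]$sequence, L = L, step = step)
      bl <- build_labels(label_list[[k]], ws)
      window_dataset(encode_onehot(ws), bl$labels, bl$mask)
    })
    bind_window_datasets(sets)
  }
  list(
    accurate = list(train = build_split("train", corpus$labels),
                    val = build_split("val", corpus$labels),
                    test = build_split("test", corpus$labels)),
    coarse = list(train = build_split("train", noisy_labels),
                  val = build_split("val", noisy_labels),
                  test = build_split("test", noisy_labels)),
    corpus = corpus
  )
}
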