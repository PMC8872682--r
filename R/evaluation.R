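#' Micro-averaged Top-K precision, recall and F1
#'
#' For case `i`, `R(i)` is the first `K` entries of its ranked prediction
#' list and `T(i)` its true herb set. The micro-averaged metrics sum over
#' cases before dividing:
#' `Precision@K = sum |R(i) & T(i)| / sum |R(i)|`,
#' `Recall@K    = sum |R(i) & T(i)| / sum |T(i)|`,
#' `F1@K        = 2 P R / (P + R)`.
#'
#' @param predictions List of ranked herb character vectors (each of length
#'   `>= K`).
#' @param truth List of true herb sets (non-empty character vectors).
#' @param K Cut-off rank.
#' @return One-row tibble `(K, precision, recall, f1, n)`.
#' @export
topk_metrics <- function(predictions, truth, K) {
  if (length(predictions) != length(truth) || !length(truth)) {
    abort("predictions and truth must be equal-length, non-empty lists")
  }
  if (any(lengths(truth) == 0L)) abort("empty truth set")
  if (any(lengths(predictions) < K)) {
    abort(sprintf("every prediction list needs at least K = %d entries", K))
  }
  R <- purrr::map(predictions, ~ .x[seq_len(K)])
  hits <- sum(purrr::map2_dbl(R, truth, ~ length(intersect(.x, .y))))
  precision <- hits / sum(lengths(R))
  recall <- hits / sum(lengths(truth))
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble(K = as.integer(K), precision = precision, recall = recall,
         f1 = f1, n = length(truth))
}

#' Evaluate a recommender over several K
#'
#' @param model A trained `herb_recommender`.
#' @param cases A [case_set()] to score.
#' @param featurizer As in [train_recommender()].
#' @param K Integer vector of cut-offs.
#' @return An `eval_report` tibble with one row per `K`.
#' @export
evaluate_recommender <- function(model, cases, featurizer, K = c(5, 10, 15)) {
  probs <- predict_proba_all(model, cases$cases, featurizer)
  Kmax <- min(max(K), model$config$n_herbs)
  preds <- apply(probs, 1, function(p)
    model$herb_index[order(-p, seq_along(p))[seq_len(Kmax)]],
    simplify = FALSE)
  out <- dplyr::bind_rows(purrr::map(K[K <= Kmax], function(k)
    topk_metrics(preds, cases$cases$herbs, k)))
  class(out) <- c("eval_report", class(out))
  out
}

#' Cosine similarity of two indicator (or any nonzero) vectors
#'
#' @param u,v Equal-length numeric vectors, each with at least one nonzero
#'   entry.
#' @return `u . v / (|u| |v|)`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("vectors must have equal length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("cosine similarity of a zero vector is undefined")
  sum(u * v) / (nu * nv)
}

# cosine over two sets represented as character vectors; empty sets -> 0
set_cosine <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  length(intersect(a, b)) / sqrt(length(a) * length(b))
}

#' Prescription--symptom similarity correlation
#'
#' Checks the premise that patients with similar prescriptions have similar
#' symptoms: over a seeded sample of case pairs, the prescription
#' similarity (cosine of herb indicator vectors) assigns each pair to one
#' of ten bins `[0,0.1), ..., [0.9,1.0]`, and the mean symptom similarity
#' (cosine of the mapped symptom representation) is reported per bin.
#'
#' Mapper modes: `RAW` uses the terms themselves; `NGRAM`, `FMM`, `BMM`
#' use the token set produced by the corresponding tokenizer; `SSTM` uses
#' the union of mapped concept sets over the case's terms (requires `net`).
#'
#' @param cases A [case_set()] with `N >= 2`.
#' @param mapper One of `"RAW"`, `"NGRAM"`, `"FMM"`, `"BMM"`, `"SSTM"`.
#' @param pair_sample Maximum number of case pairs (all pairs if fewer).
#' @param seed Integer seed for pair sampling.
#' @param net Symptom network (SSTM only).
#' @param tok Tokenizer for NGRAM/FMM/BMM/SSTM; defaults to a 2-gram
#'   tokenizer for NGRAM and must carry a lexicon for FMM/BMM.
#' @param threshold SSTM retention threshold.
#' @return A `sim_corr_table` tibble: `bin_low`, `bin_high`, `n_pairs`,
#'   `mean_symptom_similarity`, with the mapper tag as attribute `mapper`.
#' @export
similarity_correlation <- function(cases,
                                   mapper = c("RAW", "NGRAM", "FMM", "BMM", "SSTM"),
                                   pair_sample = 200000, seed = 1,
                                   net = NULL, tok = NULL, threshold = 2) {
  mapper <- match.arg(mapper)
  stopifnot(inherits(cases, "case_set"))
  N <- nrow(cases$cases)
  if (N < 2) abort("need at least 2 cases")
  if (mapper == "NGRAM" && is.null(tok)) tok <- tokenizer("NGRAM", n = 2)
  if (mapper %in% c("FMM", "BMM") &&
      (is.null(tok) || tok$mode != mapper)) {
    abort(sprintf("mapper %s requires a %s tokenizer with a lexicon", mapper, mapper))
  }
  if (mapper == "SSTM" && is.null(net)) abort("SSTM mapper requires a network")

  adj <- if (mapper == "SSTM") network_adjacency(net) else NULL
  term_cache <- new.env(parent = emptyenv())
  rep_of_term <- function(term) {
    if (!is.null(term_cache[[term]])) return(term_cache[[term]])
    r <- switch(mapper,
      RAW = term,
      NGRAM = , FMM = , BMM = unique(tokenize(term, tok)),
      SSTM = suppressWarnings(
        map_term(term, net, tok, threshold, .adj = adj)$retained))
    term_cache[[term]] <- r
    r
  }
  sym_reps <- purrr::map(cases$cases$symptoms, function(terms)
    unique(unlist(purrr::map(unique(terms), rep_of_term), use.names = FALSE)))
  herb_sets <- cases$cases$herbs

  n_all <- N * (N - 1) / 2
  pairs <- if (n_all <= pair_sample) {
    which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  } else {
    withr::with_seed(seed, {
      i <- sample.int(N, pair_sample, replace = TRUE)
      j <- sample.int(N - 1L, pair_sample, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      cbind(row = pmin(i, j), col = pmax(i, j))
    })
  }
  ps <- purrr::map2_dbl(pairs[, 1], pairs[, 2],
                        ~ set_cosine(herb_sets[[.x]], herb_sets[[.y]]))
  ss <- purrr::map2_dbl(pairs[, 1], pairs[, 2],
                        ~ set_cosine(sym_reps[[.x]], sym_reps[[.y]]))
  bin <- pmin(floor(ps * 10), 9) + 1L
  out <- tibble(
    bin_low = (0:9) / 10,
    bin_high = (1:10) / 10,
    n_pairs = vapply(1:10, function(b) sum(bin == b), 0L),
    mean_symptom_similarity = vapply(1:10, function(b) {
      if (any(bin == b)) mean(ss[bin == b]) else NA_real_
    }, 0)
  )
  attr(out, "mapper") <- mapper
  class(out) <- c("sim_corr_table", class(out))
  out
}
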