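#' Map a symptom term onto a concept subnetwork
#'
#' The subnetwork term-mapping procedure: disassemble the term into words,
#' look each word up in the symptom network, gather the first-order
#' neighbors of every present word, and count for each candidate node how
#' many *distinct* words it neighbors. The mapped concept set is the
#' present words themselves plus every candidate whose cross-word frequency
#' reaches `threshold`; the induced subnetwork restricts the network's
#' edges to that set. Because composition from known words is how unseen
#' clinical phrasings usually arise, this yields a usable representation
#' for terms absent from the knowledge base.
#'
#' `threshold = 2` keeps candidates adjacent to more than one word (the
#' consensus reading of "frequency greater than 1"); `threshold = 1` keeps
#' every first-order neighbor.
#'
#' @param term Symptom term string.
#' @param net A symptom network.
#' @param tok A [tokenizer()].
#' @param threshold Minimum cross-word frequency for candidates (`>= 1`).
#' @return A `mapped_term_set`: list with `term`, `tokens`,
#'   `candidate_freq` (named integer), `retained` (character; present
#'   words first in tokenization order, then candidates by decreasing
#'   frequency and id), `subnetwork_edges` (tibble `u`, `v`) and
#'   `threshold`. If no word is present in the network, `retained` is empty
#'   and a warning is raised.
#' @examples
#' net <- assemble_network(tibble::tibble(
#'   u = c("foot sore", "foot sore", "foot pain", "foot pain",
#'         "itchy feet", "hand sore"),
#'   v = c("foot", "sore", "foot", "pain", "foot", "sore")
#' ))
#' map_term("foot sore and pain", net, tokenizer("WHITESPACE"),
#'          threshold = 2)$retained
#' @param .adj Precomputed adjacency list (internal; used by
#'   [case_featurizer()] to avoid rebuilding it per term).
#' @export
map_term <- function(term, net, tok, threshold = 2, .adj = NULL) {
  stopifnot(inherits(net, "symptom_network"), threshold >= 1)
  tokens <- unique(tokenize(term, tok))
  ids <- net$nodes$id
  present <- tokens[tokens %in% ids]
  if (!length(present)) {
    warn(sprintf("no word of '%s' is present in the symptom network", term))
    return(new_mapped_term_set(term, tokens, integer(), character(),
                               tibble(u = character(), v = character()),
                               threshold))
  }
  adj <- .adj %||% network_adjacency(net)
  neigh <- purrr::map(present, function(w) ids[adj[[match(w, ids)]]])
  freq <- table(unlist(purrr::map(neigh, unique), use.names = FALSE))
  candidate_freq <- setNames(as.integer(freq), names(freq))
  kept <- names(candidate_freq)[candidate_freq >= threshold] %||% character()
  kept <- setdiff(kept, present)
  if (length(kept)) kept <- kept[order(-candidate_freq[kept], kept)]
  retained <- c(present, kept)
  sub <- net$edges[net$edges$u %in% retained & net$edges$v %in% retained,
                   c("u", "v")]
  sub <- dplyr::distinct(sub)
  new_mapped_term_set(term, tokens, candidate_freq, retained, sub, threshold)
}

new_mapped_term_set <- function(term, tokens, candidate_freq, retained,
                                subnetwork_edges, threshold) {
  structure(list(term = term, tokens = tokens,
                 candidate_freq = candidate_freq, retained = retained,
                 subnetwork_edges = subnetwork_edges, threshold = threshold),
            class = "mapped_term_set")
}

#' @export
print.mapped_term_set <- function(x, ...) {
  cat(sprintf("<mapped_term_set> '%s' -> {%s} (threshold %d, %d edges)\n",
              x$term, paste(x$retained, collapse = ", "), x$threshold,
              nrow(x$subnetwork_edges)))
  invisible(x)
}

#' Fuse a mapped concept set into one feature vector
#'
#' Pools the embedding vectors of the retained concepts coordinate-wise:
#' `"AVG"` takes the mean over the set, `"MAX"` the maximum (max pooling).
#' An empty mapped set yields the zero vector with a warning, so wholly
#' unknown terms degrade to an uninformative feature rather than an error.
#'
#' @param mts A [map_term()] result.
#' @param tab An `embedding_table` covering the retained nodes.
#' @param method `"AVG"` or `"MAX"`.
#' @return A `fused_vector`: list with `term`, `vector` (length `dim`) and
#'   `method`.
#' @export
fuse <- function(mts, tab, method = c("AVG", "MAX")) {
  method <- match.arg(method)
  stopifnot(inherits(mts, "mapped_term_set"), inherits(tab, "embedding_table"))
  if (!length(mts$retained)) {
    warn(sprintf("empty mapped set for '%s'; fusing to the zero vector", mts$term))
    v <- numeric(tab$dim)
  } else {
    m <- embedding_vectors(tab, mts$retained)
    v <- if (method == "AVG") colMeans(m) else apply(m, 2, max)
  }
  structure(list(term = mts$term, vector = unname(v), method = method),
            class = "fused_vector")
}

#' Embed a clinical case as a (max_terms x dim) feature matrix
#'
#' Each of the case's symptom terms is mapped ([map_term()]) and fused
#' ([fuse()]) into one row; rows beyond the number of symptoms are
#' zero-padded, and cases with more than `max_terms` symptoms are truncated
#' to the first `max_terms` with a warning.
#'
#' @param case A one-row slice of a case set's `cases` tibble, or any list
#'   with a `symptoms` character vector.
#' @param net,tab,tok,threshold,method Passed to [map_term()] / [fuse()].
#' @param max_terms Number of matrix rows (`>= 1`).
#' @return Numeric matrix of shape `(max_terms, dim)`.
#' @export
embed_case <- function(case, net, tab, tok, threshold = 2,
                       method = "AVG", max_terms = 40) {
  stopifnot(max_terms >= 1)
  symptoms <- if (is.character(case)) case else unlist(case$symptoms, use.names = FALSE)
  q <- length(symptoms)
  if (q > max_terms) {
    warn(sprintf("case has %d symptoms; truncated to first %d", q, max_terms))
    symptoms <- symptoms[seq_len(max_terms)]
    q <- max_terms
  }
  out <- matrix(0, nrow = max_terms, ncol = tab$dim)
  for (j in seq_len(q)) {
    out[j, ] <- fuse(map_term(symptoms[j], net, tok, threshold), tab, method)$vector
  }
  out
}

#' Build a per-case featurizer closure
#'
#' Packages the network, embedding table, tokenizer and mapping parameters
#' into a single function `case -> (max_terms x dim) matrix` for use with
#' [train_recommender()] and [predict_proba()]. The network adjacency and
#' per-term fused vectors are computed once and cached, so featurizing a
#' corpus costs one [map_term()] per *distinct* term.
#'
#' `kind = "lookup"` is the whole-term baseline: a term's own embedding
#' vector if the term is a network node, otherwise the zero vector. It has
#' no way to represent terms absent from the network, which is exactly the
#' failure mode subnetwork mapping addresses.
#'
#' @param net,tab,tok,threshold,method,max_terms As in [embed_case()].
#' @param kind `"sstm"` (subnetwork term mapping) or `"lookup"`.
#' @return A function of one case.
#' @export
case_featurizer <- function(net, tab, tok, threshold = 2, method = "AVG",
                            max_terms = 40, kind = c("sstm", "lookup")) {
  kind <- match.arg(kind)
  cache <- new.env(parent = emptyenv())
  ids <- net$nodes$id
  adj <- network_adjacency(net)
  term_vector <- function(term) {
    key <- term
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- if (kind == "sstm") {
      suppressWarnings(
        fuse(map_term(term, net, tok, threshold, .adj = adj), tab, method)$vector)
    } else if (term %in% ids) {
      as.numeric(embedding_vectors(tab, term))
    } else {
      numeric(tab$dim)
    }
    cache[[key]] <- v
    v
  }
  function(case) {
    symptoms <- if (is.character(case)) case else unlist(case$symptoms, use.names = FALSE)
    if (length(symptoms) > max_terms) symptoms <- symptoms[seq_len(max_terms)]
    out <- matrix(0, nrow = max_terms, ncol = tab$dim)
    for (j in seq_along(symptoms)) out[j, ] <- term_vector(symptoms[j])
    out
  }
}
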