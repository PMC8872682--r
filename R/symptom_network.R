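#' Build symptom-term / symptom-word edges by word disassembly
#'
#' Every symptom term is tokenized and joined to each of its distinct
#' tokens, e.g. "foot sore" yields the two edges "foot sore"--"foot" and
#' "foot sore"--"sore", and "foot sore and pain" yields three more, giving
#' a five-edge network in which the shared words "foot" and "sore" connect
#' the two terms. A token equal to its whole term yields no edge (no
#' self-loops) and edges are deduplicated across terms.
#'
#' @param symptoms Character vector of symptom terms.
#' @param tok A [tokenizer()].
#' @return Tibble with columns `u` (term), `v` (token), `provenance`
#'   (`"WORD"`), `weight` (1).
#' @export
build_word_edges <- function(symptoms, tok) {
  symptoms <- unique(as.character(symptoms))
  if (!length(symptoms)) {
    return(tibble(u = character(), v = character(),
                  provenance = character(), weight = numeric()))
  }
  edges <- purrr::map(symptoms, function(term) {
    tokens <- setdiff(unique(tokenize(term, tok)), term)
    if (!length(tokens)) return(NULL)
    tibble(u = term, v = tokens)
  })
  edges <- dplyr::bind_rows(edges)
  if (!nrow(edges)) {
    return(tibble(u = character(), v = character(),
                  provenance = character(), weight = numeric()))
  }
  edges <- dedup_undirected(edges)
  edges$provenance <- "WORD"
  edges$weight <- 1
  edges
}

# deduplicate an undirected edge tibble on the unordered (u, v) pair,
# keeping the original orientation of the first occurrence
dedup_undirected <- function(edges) {
  key <- ifelse(edges$u <= edges$v,
                paste(edges$u, edges$v, sep = "\r"),
                paste(edges$v, edges$u, sep = "\r"))
  edges[!duplicated(key), , drop = FALSE]
}

#' Count metapath instances between symptom pairs
#'
#' For a bridge type `X` in EF/PP/MD, a metapath instance for the symptom
#' pair (SY1, SY2) is a triple (HB1, X, HB2) with HB1 != HB2 such that the
#' relations SY1--HB1, HB1--X, X--HB2 and HB2--SY2 all exist in the
#' knowledge graph: two herbs that treat the two symptoms and share the
#' bridge attribute. Counts are computed by sparse matrix products
#' \eqn{A_{sh} (A_{hx} A_{hx}^T - \mathrm{diag}) A_{sh}^T} and are symmetric
#' in the pair.
#'
#' @param kg A [knowledge_graph()].
#' @param bridge One of `"EF"`, `"PP"`, `"MD"`.
#' @return A `metapath_counts` object: list with `bridge` and `counts`, a
#'   tibble (`sy1`, `sy2`, `count`) over unordered pairs with `sy1 < sy2`
#'   and `count >= 1`.
#' @export
count_metapaths <- function(kg, bridge = c("EF", "PP", "MD")) {
  bridge <- match.arg(bridge)
  hs <- kg_edges(kg, "HB-SY")   # u = herb, v = symptom
  hx <- kg_edges(kg, paste0("HB-", bridge))
  empty <- tibble(sy1 = character(), sy2 = character(), count = numeric())
  if (!nrow(hx)) {
    warn(sprintf("knowledge graph has no HB-%s relations; empty counts", bridge))
    return(structure(list(bridge = bridge, counts = empty),
                     class = "metapath_counts"))
  }
  if (!nrow(hs)) {
    return(structure(list(bridge = bridge, counts = empty),
                     class = "metapath_counts"))
  }
  sys <- sort(unique(hs$v))
  herbs <- sort(unique(c(hs$u, hx$u)))
  xs <- sort(unique(hx$v))
  A_sh <- Matrix::sparseMatrix(
    i = match(hs$v, sys), j = match(hs$u, herbs), x = 1,
    dims = c(length(sys), length(herbs)))
  A_hx <- Matrix::sparseMatrix(
    i = match(hx$u, herbs), j = match(hx$v, xs), x = 1,
    dims = c(length(herbs), length(xs)))
  B <- Matrix::tcrossprod(A_hx)        # herbs x herbs shared-bridge counts
  Matrix::diag(B) <- 0                 # enforce HB1 != HB2
  C <- A_sh %*% B %*% Matrix::t(A_sh)  # symptom-pair path counts
  C <- Matrix::triu(C, k = 1)          # unordered pairs, no self-pairs
  tri <- Matrix::summary(C)
  tri <- tri[tri$x > 0, , drop = FALSE]
  counts <- tibble(sy1 = sys[tri$i], sy2 = sys[tri$j], count = as.numeric(tri$x))
  counts <- counts[order(counts$sy1, counts$sy2), ]
  structure(list(bridge = bridge, counts = counts), class = "metapath_counts")
}

#' Threshold metapath counts into symptom--symptom edges
#'
#' Metapath-derived relations are numerous, so only pairs whose path count
#' reaches a frequency threshold become edges; the count is kept as the edge
#' weight.
#'
#' @param mc A [count_metapaths()] result.
#' @param threshold Minimum path count (`>= 1`).
#' @return Tibble with columns `u`, `v`, `provenance` (`"EF_PATH"`,
#'   `"PP_PATH"` or `"MD_PATH"`), `weight`.
#' @export
build_metapath_edges <- function(mc, threshold) {
  stopifnot(inherits(mc, "metapath_counts"), threshold >= 1)
  keep <- mc$counts[mc$counts$count >= threshold, , drop = FALSE]
  tibble(u = keep$sy1, v = keep$sy2,
         provenance = paste0(mc$bridge, "_PATH"),
         weight = keep$count)
}

#' Assemble the symptom network
#'
#' Combines word-disassembly edges, synonymy edges and metapath-derived
#' edge sets into one undirected network with two node roles: `TERM` for
#' ids that occur as whole symptom terms (any endpoint of a synonymy or
#' metapath edge, or the term side of a word edge) and `WORD` for tokens
#' that are not themselves terms. Edges are deduplicated per unordered pair
#' and provenance; an edge appearing under several provenances is kept once
#' per provenance.
#'
#' @param word_edges Tibble from [build_word_edges()] (columns `u` = term,
#'   `v` = token; may also carry ingested word--word rows).
#' @param synonymy_edges Optional tibble with columns `u`, `v` of synonymous
#'   term pairs (e.g. the knowledge graph's SY-SY relation).
#' @param path_edge_sets Optional list of tibbles from
#'   [build_metapath_edges()].
#' @return A `symptom_network`: list with tibbles `nodes` (`id`, `role`) and
#'   `edges` (`u`, `v`, `provenance`, `weight`).
#' @export
assemble_network <- function(word_edges = NULL, synonymy_edges = NULL,
                             path_edge_sets = list()) {
  blank <- tibble(u = character(), v = character(),
                  provenance = character(), weight = numeric())
  norm <- function(e, prov, default_weight = 1) {
    if (is.null(e) || nrow(e) == 0L) return(blank)
    e <- as_tibble(e)
    if (!"provenance" %in% names(e)) e$provenance <- prov
    if (!"weight" %in% names(e)) e$weight <- default_weight
    e[, c("u", "v", "provenance", "weight")]
  }
  edges <- dplyr::bind_rows(
    norm(word_edges, "WORD"),
    norm(synonymy_edges, "SYNONYMY"),
    dplyr::bind_rows(purrr::map(path_edge_sets, norm, prov = NULL))
  )
  if (nrow(edges)) {
    edges <- edges[edges$u != edges$v, , drop = FALSE]
    key <- ifelse(edges$u <= edges$v,
                  paste(edges$u, edges$v, edges$provenance, sep = "\r"),
                  paste(edges$v, edges$u, edges$provenance, sep = "\r"))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  term_ids <- unique(c(
    edges$u[edges$provenance != "WORD"],
    edges$v[edges$provenance != "WORD"],
    edges$u[edges$provenance == "WORD"]
  ))
  all_ids <- unique(c(edges$u, edges$v))
  nodes <- tibble(
    id = withr_locale_sort(all_ids),
    role = ifelse(withr_locale_sort(all_ids) %in% term_ids, "TERM", "WORD")
  )
  prov_counts <- vapply(PROVENANCES,
                        function(p) sum(edges$provenance == p), 0L)
  inform(sprintf(
    "symptom network: %d nodes (%d TERM, %d WORD); edges %s",
    nrow(nodes), sum(nodes$role == "TERM"), sum(nodes$role == "WORD"),
    paste(sprintf("%s=%d", PROVENANCES, prov_counts), collapse = " ")))
  new_symptom_network(nodes, edges)
}

new_symptom_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  cat(sprintf("<symptom_network> %d nodes (%d TERM, %d WORD), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "TERM"),
              sum(x$nodes$role == "WORD"), nrow(x$edges)))
  invisible(x)
}

# adjacency list over node indices (sorted node order); cached on the object
network_adjacency <- function(net) {
  ids <- net$nodes$id
  n <- length(ids)
  adj <- vector("list", n)
  if (nrow(net$edges)) {
    ui <- match(net$edges$u, ids)
    vi <- match(net$edges$v, ids)
    both <- data.frame(a = c(ui, vi), b = c(vi, ui))
    both <- unique(both)
    split_b <- split(both$b, both$a)
    for (k in names(split_b)) adj[[as.integer(k)]] <- sort(split_b[[k]])
  }
  for (i in seq_len(n)) if (is.null(adj[[i]])) adj[[i]] <- integer()
  names(adj) <- ids
  adj
}

#' Serialize / read a symptom network as TSV
#'
#' Format: `u<TAB>v<TAB>provenance<TAB>weight`, one edge per line. Node
#' roles are re-inferred on read, so isolated nodes are not preserved.
#'
#' @param net A symptom network.
#' @param path File path.
#' @return `save_network()`: invisibly `path`; `load_network()`: a
#'   `symptom_network`.
#' @export
save_network <- function(net, path) {
  writeLines(sprintf("%s\t%s\t%s\t%s", net$edges$u, net$edges$v,
                     net$edges$provenance, format(net$edges$weight, digits = 12)),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(assemble_network())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    abort(sprintf("malformed network row at line %d of %s",
                  which(lengths(parts) != 4L)[1], path))
  }
  m <- do.call(rbind, parts)
  e <- tibble(u = m[, 1], v = m[, 2], provenance = m[, 3],
              weight = as.numeric(m[, 4]))
  word <- e[e$provenance == "WORD", ]
  syn <- e[e$provenance == "SYNONYMY", ]
  path_e <- e[e$provenance %in% c("EF_PATH", "MD_PATH", "PP_PATH"), ]
  suppressMessages(assemble_network(word, syn, list(path_e)))
}
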