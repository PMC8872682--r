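#' Train skip-gram embeddings over a walk corpus
#'
#' Skip-gram with negative sampling (the word2vec objective) treating each
#' walk as a sentence: DeepWalk when the corpus used uniform walks,
#' node2vec when it used p/q-biased walks. Training is single-threaded with
#' an internal seeded RNG, so a fixed seed reproduces the table bit-for-bit
#' on one platform. Network nodes that never occur in a walk receive the
#' zero vector with a warning.
#'
#' @param wc A [generate_walks()] corpus.
#' @param dim Embedding dimension (`>= 1`).
#' @param window Maximum context window (the effective window per position
#'   is sampled uniformly from `1..window`, as in word2vec).
#' @param epochs Passes over the corpus.
#' @param seed Integer seed.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial learning rate (linearly decayed to `alpha/100`).
#' @param nodes Optional character vector of all node ids that must receive
#'   a vector (defaults to the nodes seen in the corpus).
#' @return An `embedding_table`: list with `method`, `dim` and `vectors`, a
#'   numeric matrix with one named row per node.
#' @export
train_skipgram <- function(wc, dim = 200, window = 5, epochs = 5, seed = 1,
                           negative = 5, alpha = 0.025, nodes = NULL) {
  stopifnot(inherits(wc, "walk_corpus"), dim >= 1)
  if (!length(wc$walks) || !sum(lengths(wc$walks))) abort("empty walk corpus")
  walked <- withr_locale_sort(unique(unlist(wc$walks, use.names = FALSE)))
  all_nodes <- withr_locale_sort(unique(c(walked, nodes)))
  idx_walks <- purrr::map(wc$walks, function(w) match(w, walked))
  mat <- sgns_train(idx_walks, length(walked), as.integer(dim),
                    as.integer(window), as.integer(epochs),
                    as.integer(negative), alpha, alpha / 100,
                    as.integer(seed))
  vectors <- matrix(0, nrow = length(all_nodes), ncol = dim,
                    dimnames = list(all_nodes, NULL))
  vectors[walked, ] <- mat
  missing <- setdiff(all_nodes, walked)
  if (length(missing)) {
    warn(sprintf("%d node(s) absent from all walks received zero vectors",
                 length(missing)))
  }
  method <- if (wc$params$p == 1 && wc$params$q == 1) "deepwalk" else "node2vec"
  new_embedding_table(method, dim, vectors)
}

new_embedding_table <- function(method, dim, vectors) {
  structure(list(method = method, dim = as.integer(dim), vectors = vectors),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %s, %d nodes x %d dims\n",
              x$method, nrow(x$vectors), x$dim))
  invisible(x)
}

#' One-hot node encoding
#'
#' Indicator vectors under the deterministic sorted node order: dimension
#' equals the node count and distinct nodes are orthonormal.
#'
#' @param net A symptom network.
#' @return An `embedding_table` with `method = "onehot"`.
#' @export
one_hot <- function(net) {
  stopifnot(inherits(net, "symptom_network"))
  ids <- withr_locale_sort(net$nodes$id)
  n <- length(ids)
  vectors <- diag(1, n)
  rownames(vectors) <- ids
  new_embedding_table("onehot", n, vectors)
}

#' Write / read embeddings in word2vec text format
#'
#' Header line `count dim`, then one line per node: the node id followed by
#' `dim` floats. Any externally produced file in this format (e.g. LINE or
#' TransE vectors from another toolkit) can be loaded, which is the
#' provider interface for embedding methods not implemented natively.
#'
#' @param tab An `embedding_table`.
#' @param path File path.
#' @param method Method tag to attach on load.
#' @return `save_embeddings()`: invisibly `path`; `load_embeddings()`: an
#'   `embedding_table`.
#' @export
save_embeddings <- function(tab, path) {
  stopifnot(inherits(tab, "embedding_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(tab$vectors), tab$dim), con)
  if (nrow(tab$vectors)) {
    rows <- apply(tab$vectors, 1, function(v)
      paste(formatC(v, format = "g", digits = 9), collapse = " "))
    writeLines(paste(rownames(tab$vectors), rows), con)
  }
  invisible(path)
}

#' @rdname save_embeddings
#' @export
load_embeddings <- function(path, method = "external") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) abort("empty embedding file")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L) abort(sprintf("malformed header at line 1 of %s", path))
  n <- as.integer(hdr[1])
  d <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    abort(sprintf("header of %s declares %d rows but file has %d", path, n, length(body)))
  }
  if (n == 0L) {
    return(new_embedding_table(method, d, matrix(numeric(), 0, d)))
  }
  parts <- strsplit(body, "\\s+")
  if (any(lengths(parts) != d + 1L)) {
    bad <- which(lengths(parts) != d + 1L)[1]
    abort(sprintf("row at line %d of %s has %d fields, expected %d",
                  bad + 1L, path, lengths(parts)[bad], d + 1L))
  }
  m <- do.call(rbind, purrr::map(parts, function(p) as.numeric(p[-1])))
  rownames(m) <- purrr::map_chr(parts, 1)
  new_embedding_table(method, d, m)
}

# fetch vectors for a set of node ids (rows in request order)
embedding_vectors <- function(tab, ids) {
  miss <- setdiff(ids, rownames(tab$vectors))
  if (length(miss)) {
    abort(sprintf("no embedding vector for node(s): %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  tab$vectors[ids, , drop = FALSE]
}
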