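#' Generate random walks over the symptom network
#'
#' Second-order biased walks in the node2vec family: from the current node,
#' a neighbor `x` is sampled with unnormalized weight `1/p` if `x` is the
#' previous node, `1` if `x` is also a neighbor of the previous node, and
#' `1/q` otherwise. With `p = q = 1` this reduces to uniform first-order
#' walks (DeepWalk). Walks are unweighted by default regardless of any
#' path-count edge weights; set `weighted = TRUE` to bias the *first-order*
#' proposal by edge weight.
#'
#' `num_walks` walks of up to `walk_length` nodes are started from every
#' node in sorted node order; isolated nodes yield length-1 walks. The
#' corpus is a deterministic function of `(net, parameters, seed)`.
#'
#' @param net A symptom network from [assemble_network()].
#' @param num_walks Walks started per node.
#' @param walk_length Maximum nodes per walk (`>= 1`).
#' @param p,q node2vec return and in-out parameters (`> 0`).
#' @param seed Integer seed.
#' @param weighted Use edge weights in the first-order proposal.
#' @return A `walk_corpus`: list with `walks` (list of character vectors)
#'   and `params`.
#' @export
generate_walks <- function(net, num_walks = 10, walk_length = 40,
                           p = 1, q = 1, seed = 1, weighted = FALSE) {
  stopifnot(inherits(net, "symptom_network"), p > 0, q > 0)
  if (walk_length < 1) abort("walk_length must be >= 1")
  ids <- net$nodes$id
  if (!length(ids)) abort("network is empty")
  adj <- network_adjacency(net)
  wts <- NULL
  if (weighted) wts <- adjacency_weights(net, adj)
  uniform <- (p == 1 && q == 1)

  walks <- withr::with_seed(seed, {
    out <- vector("list", length(ids) * num_walks)
    k <- 0L
    for (start in seq_along(ids)) {
      for (r in seq_len(num_walks)) {
        k <- k + 1L
        out[[k]] <- one_walk(start, adj, wts, walk_length, p, q, uniform)
      }
    }
    out
  })
  walks <- purrr::map(walks, function(w) ids[w])
  structure(list(
    walks = walks,
    params = list(num_walks_per_node = num_walks, walk_length = walk_length,
                  p = p, q = q, seed = seed, weighted = weighted)
  ), class = "walk_corpus")
}

one_walk <- function(start, adj, wts, walk_length, p, q, uniform) {
  walk <- integer(walk_length)
  walk[1L] <- start
  if (walk_length == 1L || !length(adj[[start]])) return(walk[1L])
  cur <- start
  prev <- 0L
  for (step in 2:walk_length) {
    nb <- adj[[cur]]
    if (!length(nb)) return(walk[seq_len(step - 1L)])
    if (uniform || prev == 0L) {
      w <- if (is.null(wts)) NULL else wts[[cur]]
      nxt <- if (is.null(w)) {
        nb[sample.int(length(nb), 1L)]
      } else {
        nb[sample.int(length(nb), 1L, prob = w)]
      }
    } else {
      base <- if (is.null(wts)) rep(1, length(nb)) else wts[[cur]]
      bias <- ifelse(nb == prev, 1 / p,
                     ifelse(nb %in% adj[[prev]], 1, 1 / q))
      nxt <- nb[sample.int(length(nb), 1L, prob = base * bias)]
    }
    walk[step] <- nxt
    prev <- cur
    cur <- nxt
  }
  walk
}

# per-node neighbor weights aligned with the adjacency lists (max weight
# over parallel provenances)
adjacency_weights <- function(net, adj) {
  ids <- net$nodes$id
  ui <- match(net$edges$u, ids)
  vi <- match(net$edges$v, ids)
  key <- paste(c(ui, vi), c(vi, ui))
  w <- tapply(c(net$edges$weight, net$edges$weight), key, max)
  purrr::imap(adj, function(nbs, id) {
    i <- match(id, ids)
    as.numeric(w[paste(i, nbs)])
  })
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("<walk_corpus> %d walks, %.1f nodes/walk (p=%g, q=%g, seed=%d)\n",
              length(x$walks), mean(lengths(x$walks)),
              x$params$p, x$params$q, x$params$seed))
  invisible(x)
}
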