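# shared fixtures, built in code

# the toy network behind the "foot sore and pain" mapping example:
# four recorded terms joined to the words they contain
toy_mapping_network <- function() {
  suppressMessages(assemble_network(tibble::tibble(
    u = c("foot sore", "foot sore", "foot pain", "foot pain",
          "itchy feet", "hand sore"),
    v = c("foot", "sore", "foot", "pain", "foot", "sore")
  )))
}

ws_tok <- function() tokenizer("WHITESPACE")

# small deterministic case set
toy_cases <- function(n = 10) {
  withr::with_seed(42, {
    herbs_all <- paste0("h", 1:6)
    case_set(tibble::tibble(
      case_id = paste0("c", seq_len(n)),
      symptoms = purrr::map(seq_len(n), ~ paste0("s", sample(8, sample(2:4, 1)))),
      herbs = purrr::map(seq_len(n), ~ sample(herbs_all, sample(2:4, 1)))
    ))
  })
}

# random typed KG over at most max_entities entities, for oracle checks
random_kg <- function(seed, max_entities = 30) {
  withr::with_seed(seed, {
    n_sy <- sample(2:6, 1)
    n_hb <- sample(2:8, 1)
    n_ef <- sample(1:4, 1)
    sy <- paste0("sy", seq_len(n_sy))
    hb <- paste0("hb", seq_len(n_hb))
    ef <- paste0("ef", seq_len(n_ef))
    pick_pairs <- function(a, b, p, rtype) {
      grid <- expand.grid(u = a, v = b, stringsAsFactors = FALSE)
      keep <- stats::runif(nrow(grid)) < p
      if (!any(keep)) return(NULL)
      tibble::tibble(u = grid$u[keep], v = grid$v[keep], rtype = rtype)
    }
    rel <- dplyr::bind_rows(
      pick_pairs(hb, sy, 0.4, "HB-SY"),
      pick_pairs(hb, ef, 0.5, "HB-EF")
    )
    if (is.null(rel) || !nrow(rel)) {
      rel <- tibble::tibble(u = "hb1", v = "sy1", rtype = "HB-SY")
    }
    knowledge_graph(rel)
  })
}

# brute-force quadruple-loop metapath oracle
oracle_metapath_counts <- function(kg, bridge) {
  hs <- kg$relations[kg$relations$rtype == "HB-SY", ]
  hx <- kg$relations[kg$relations$rtype == paste0("HB-", bridge), ]
  sys <- sort(unique(hs$v))
  out <- list()
  for (s1 in sys) for (s2 in sys) {
    if (s1 >= s2) next
    n <- 0L
    h1s <- hs$u[hs$v == s1]
    h2s <- hs$u[hs$v == s2]
    for (h1 in h1s) for (h2 in h2s) {
      if (h1 == h2) next
      x1 <- hx$v[hx$u == h1]
      x2 <- hx$v[hx$u == h2]
      n <- n + length(intersect(x1, x2))
    }
    if (n > 0) out[[paste(s1, s2)]] <- tibble::tibble(sy1 = s1, sy2 = s2, count = n)
  }
  if (!length(out)) {
    return(tibble::tibble(sy1 = character(), sy2 = character(), count = numeric()))
  }
  dplyr::bind_rows(out)
}

# random small symptom network for property tests
random_network <- function(seed) {
  withr::with_seed(seed, {
    n_terms <- sample(3:8, 1)
    n_words <- sample(2:6, 1)
    terms <- paste0("t", seq_len(n_terms))
    words <- paste0("w", seq_len(n_words))
    grid <- expand.grid(u = terms, v = words, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < 0.35
    we <- tibble::tibble(u = grid$u[keep], v = grid$v[keep])
    if (!nrow(we)) we <- tibble::tibble(u = "t1", v = "w1")
    syn <- NULL
    if (n_terms > 2 && stats::runif(1) < 0.5) {
      syn <- tibble::tibble(u = terms[1], v = terms[2])
    }
    suppressMessages(assemble_network(we, syn))
  })
}

# deterministic featurizer-independent toy embedding table
toy_embedding <- function(ids, dim = 3, seed = 7) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(length(ids) * dim), length(ids), dim,
                dimnames = list(ids, NULL))
    herbrec:::new_embedding_table("toy", dim, m)
  })
}
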