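test_that("the mapping example retains the consensus subnetwork at threshold 2", {
  net <- toy_mapping_network()
  tok <- tokenizer("WHITESPACE", stopwords = "and")
  m <- map_term("foot sore and pain", net, tok, threshold = 2)
  expect_setequal(m$tokens, c("foot", "sore", "pain"))
  expect_setequal(m$retained,
                  c("foot", "sore", "pain", "foot sore", "foot pain"))
  expect_false(any(c("itchy feet", "hand sore") %in% m$retained))
  # the spliced subnetwork: sore--foot sore--foot--foot pain--pain
  key <- paste(pmin(m$subnetwork_edges$u, m$subnetwork_edges$v),
               pmax(m$subnetwork_edges$u, m$subnetwork_edges$v), sep = "~")
  expect_setequal(key, c("foot~foot sore", "foot sore~sore",
                         "foot~foot pain", "foot pain~pain"))
  expect_equal(m$candidate_freq[["foot sore"]], 2L)
  expect_equal(m$candidate_freq[["itchy feet"]], 1L)
})

test_that("threshold 1 keeps every first-order neighbor", {
  net <- toy_mapping_network()
  tok <- tokenizer("WHITESPACE", stopwords = "and")
  m <- map_term("foot sore and pain", net, tok, threshold = 1)
  expect_setequal(m$retained,
                  c("foot", "sore", "pain", "foot sore", "foot pain",
                    "itchy feet", "hand sore"))
})

test_that("degenerate terms map to sensible sets", {
  net <- toy_mapping_network()
  tok <- tokenizer("WHITESPACE")
  expect_warning(m <- map_term("totally unknown", net, tok, 2),
                 "present in the symptom network")
  expect_length(m$retained, 0)

  # a token that IS a node but has no neighbors
  net2 <- toy_mapping_network()
  net2$nodes <- dplyr::bind_rows(net2$nodes,
                                 tibble::tibble(id = "lonely", role = "WORD"))
  m2 <- map_term("lonely", net2, tok, 2)
  expect_equal(m2$retained, "lonely")
})

test_that("retained sets shrink as the threshold grows", {
  tok <- tokenizer("CHAR")
  withr::with_seed(23, {
    for (i in 1:30) {
      net <- random_network(sample.int(10000, 1))
      term <- paste0(sample(c("t", "w"), 1), sample(1:8, 1))
      prev <- NULL
      for (th in 1:3) {
        m <- suppressWarnings(map_term(term, net, tok, th))
        if (!is.null(prev)) expect_true(all(m$retained %in% prev))
        prev <- m$retained
      }
    }
  })
})

test_that("term mapping is pure and deterministic", {
  net <- toy_mapping_network()
  tok <- tokenizer("WHITESPACE", stopwords = "and")
  m1 <- map_term("foot sore and pain", net, tok, 2)
  m2 <- map_term("foot sore and pain", net, tok, 2)
  expect_identical(m1$retained, m2$retained)
  expect_identical(m1$candidate_freq, m2$candidate_freq)
})

test_that("fusion follows the average / maximum pooling formulas", {
  net <- toy_mapping_network()
  tab <- herbrec:::new_embedding_table("toy", 2, matrix(
    c(1, 0,
      0, 1), 2, 2, byrow = TRUE, dimnames = list(c("a", "b"), NULL)))
  mts <- herbrec:::new_mapped_term_set("t", c("a", "b"), integer(),
                                       c("a", "b"),
                                       tibble::tibble(u = character(),
                                                      v = character()), 1)
  expect_equal(fuse(mts, tab, "AVG")$vector, c(0.5, 0.5))
  expect_equal(fuse(mts, tab, "MAX")$vector, c(1, 1))

  single <- herbrec:::new_mapped_term_set("t", "a", integer(), "a",
                                          tibble::tibble(u = character(),
                                                         v = character()), 1)
  expect_equal(fuse(single, tab, "AVG")$vector, c(1, 0))
  expect_equal(fuse(single, tab, "MAX")$vector, c(1, 0))

  none <- herbrec:::new_mapped_term_set("t", character(), integer(),
                                        character(),
                                        tibble::tibble(u = character(),
                                                       v = character()), 1)
  expect_warning(fz <- fuse(none, tab, "AVG"), "zero vector")
  expect_equal(fz$vector, c(0, 0))
})

test_that("pooled vectors are bounded by their inputs", {
  withr::with_seed(11, {
    for (i in 1:20) {
      k <- sample(2:5, 1)
      d <- sample(2:6, 1)
      ids <- paste0("n", 1:k)
      tab <- toy_embedding(ids, dim = d, seed = i)
      mts <- herbrec:::new_mapped_term_set("t", ids, integer(), ids,
                                           tibble::tibble(u = character(),
                                                          v = character()), 1)
      avg <- fuse(mts, tab, "AVG")$vector
      mx <- fuse(mts, tab, "MAX")$vector
      lo <- apply(tab$vectors, 2, min)
      hi <- apply(tab$vectors, 2, max)
      expect_true(all(avg >= lo - 1e-12 & avg <= hi + 1e-12))
      expect_true(all(mx >= hi - 1e-12))
      for (j in seq_len(k)) expect_true(all(mx >= tab$vectors[j, ] - 1e-12))
    }
  })
})

test_that("case embedding pads, truncates and degrades gracefully", {
  net <- toy_mapping_network()
  tok <- tokenizer("WHITESPACE", stopwords = "and")
  tab <- toy_embedding(net$nodes$id, dim = 3)
  case2 <- list(symptoms = c("foot sore", "foot pain"))
  X <- embed_case(case2, net, tab, tok, 2, "AVG", max_terms = 4)
  expect_equal(dim(X), c(4, 3))
  expect_true(all(X[3:4, ] == 0))
  expect_false(all(X[1, ] == 0))

  case5 <- list(symptoms = rep("foot sore", 5))
  expect_warning(X5 <- embed_case(case5, net, tab, tok, 2, "AVG", max_terms = 4),
                 "truncated")
  expect_equal(dim(X5), c(4, 3))

  unknown <- list(symptoms = c("nothing here", "nope"))
  Xu <- suppressWarnings(embed_case(unknown, net, tab, tok, 2, "AVG", 4))
  expect_true(all(Xu == 0))
})

test_that("the lookup featurizer zeroes unknown terms while sstm maps them", {
  net <- toy_mapping_network()
  tok <- tokenizer("WHITESPACE", stopwords = "and")
  tab <- toy_embedding(net$nodes$id, dim = 3)
  sstm_fz <- case_featurizer(net, tab, tok, 2, "AVG", 3, kind = "sstm")
  lookup_fz <- case_featurizer(net, tab, tok, 2, "AVG", 3, kind = "lookup")
  # "foot sore and pain" is not a node: lookup gets zero, sstm does not
  case <- list(symptoms = "foot sore and pain")
  expect_true(all(lookup_fz(case)[1, ] == 0))
  expect_false(all(sstm_fz(case)[1, ] == 0))
  # a recorded term resolves to its own vector under lookup
  case2 <- list(symptoms = "foot sore")
  expect_equal(lookup_fz(case2)[1, ], unname(tab$vectors["foot sore", ]))
})
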