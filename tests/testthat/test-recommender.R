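# tiny separable corpus: symptoms "gA*" predict herbs "hA*", same for B
separable_cases <- function(n = 50, seed = 13) {
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      g <- if (i %% 2 == 0) "A" else "B"
      list(case_id = paste0("c", i),
           symptoms = paste0("g", g, sample(4, 2)),
           herbs = paste0("h", g, sample(4, 2)))
    })
    case_set(tibble::tibble(
      case_id = purrr::map_chr(rows, "case_id"),
      symptoms = purrr::map(rows, "symptoms"),
      herbs = purrr::map(rows, "herbs")
    ))
  })
}

# featurizer with fixed random vectors per symptom term
fixed_featurizer <- function(terms, dim, max_terms, seed = 3) {
  tab <- toy_embedding(terms, dim = dim, seed = seed)
  function(case) {
    symptoms <- if (is.character(case)) case else unlist(case$symptoms)
    symptoms <- head(symptoms, max_terms)
    X <- matrix(0, max_terms, dim)
    for (j in seq_along(symptoms)) X[j, ] <- tab$vectors[symptoms[j], ]
    X
  }
}

all_terms <- paste0("g", rep(c("A", "B"), each = 4), 1:4)

test_that("an initialized model emits a softmax distribution deterministically", {
  cfg <- model_config(max_terms = 4, dim = 6, n_herbs = 5, n_kernels = 8,
                      seed = 2)
  m1 <- build_model(cfg, paste0("h", 1:5))
  m2 <- build_model(cfg, paste0("h", 1:5))
  expect_identical(m1$weights, m2$weights)
  fz <- fixed_featurizer(all_terms, 6, 4)
  p <- predict_proba(m1, list(symptoms = c("gA1", "gB2")), fz)
  expect_length(p, 5)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(p, predict_proba(m1, list(symptoms = c("gA1", "gB2")), fz))
})

test_that("attention weights are a softmax over the non-padded rows", {
  cfg <- model_config(max_terms = 4, dim = 6, n_herbs = 5, n_kernels = 8,
                      seed = 2)
  model <- build_model(cfg, paste0("h", 1:5))
  fz <- fixed_featurizer(all_terms, 6, 4)
  X <- fz(list(symptoms = c("gA1", "gB2")))
  fw <- herbrec:::forward_pass(model$weights, cfg, X)
  a <- fw$attention[, 1]
  expect_equal(sum(a), 1, tolerance = 1e-9)
  expect_true(all(a[3:4] == 0))  # padded rows get no attention
})

test_that("kernel_width exceeding max_terms is rejected", {
  expect_error(model_config(max_terms = 2, dim = 4, n_herbs = 3,
                            kernel_width = 3), "kernel_width")
})

test_that("training reduces the loss on separable data", {
  cs <- separable_cases(50)
  cfg <- model_config(max_terms = 4, dim = 8, n_herbs = 8, n_kernels = 16,
                      max_epochs = 20, learning_rate = 1e-3, seed = 4)
  model <- build_model(cfg, cs$herb_vocabulary)
  fz <- fixed_featurizer(all_terms, 8, 4)
  fit <- train_recommender(model, cs, fz)
  h <- tidy(fit)
  expect_equal(nrow(h), 20)
  expect_lt(h$loss[20], h$loss[1])
  expect_true(fit$trained)
})

test_that("early stopping halts after patience epochs without improvement", {
  cs <- separable_cases(20)
  val <- separable_cases(8, seed = 14)
  cfg <- model_config(max_terms = 4, dim = 8, n_herbs = 8, n_kernels = 8,
                      max_epochs = 50, patience = 3,
                      learning_rate = 1e-12,  # no meaningful updates
                      seed = 4)
  model <- build_model(cfg, cs$herb_vocabulary)
  fz <- fixed_featurizer(all_terms, 8, 4)
  fit <- train_recommender(model, cs, fz, val_cases = val)
  # the constant validation metric improves once (epoch 1), then stalls
  expect_lte(nrow(tidy(fit)), 1 + 3)
})

test_that("unseen herb labels are reported by name", {
  cs <- separable_cases(10)
  cfg <- model_config(max_terms = 4, dim = 8, n_herbs = 3, seed = 1)
  model <- build_model(cfg, c("hA1", "hA2", "hA3"))
  fz <- fixed_featurizer(all_terms, 8, 4)
  expect_error(train_recommender(model, cs, fz), "herb label")
})

test_that("recommend ranks by probability with index-order tie-breaks", {
  probs <- c(h1 = 0.1, h2 = 0.7, h3 = 0.2)
  expect_equal(recommend(probs, 2), c("h2", "h3"))
  ties <- c(a = 0.25, b = 0.25, c = 0.25, d = 0.25)
  expect_equal(recommend(ties, 2), c("a", "b"))
  expect_equal(recommend(probs, 3), c("h2", "h3", "h1"))
  expect_error(recommend(probs, 0), "out of range")
  expect_error(recommend(probs, 4), "out of range")
})

test_that("top-K lists are prefixes of longer recommendations", {
  withr::with_seed(6, {
    for (i in 1:20) {
      p <- setNames(stats::runif(10), paste0("h", 1:10))
      for (K in 1:9) {
        expect_equal(recommend(p, K), recommend(p, K + 1)[1:K])
      }
    }
  })
})

test_that("width-1 kernels make predictions invariant to symptom order", {
  cfg <- model_config(max_terms = 4, dim = 6, n_herbs = 5, n_kernels = 8,
                      kernel_width = 1, seed = 2)
  model <- build_model(cfg, paste0("h", 1:5))
  fz <- fixed_featurizer(all_terms, 6, 4)
  p1 <- predict_proba(model, list(symptoms = c("gA1", "gB2", "gA3")), fz)
  p2 <- predict_proba(model, list(symptoms = c("gA3", "gA1", "gB2")), fz)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("sigmoid mode yields independent probabilities in [0, 1]", {
  cfg <- model_config(max_terms = 4, dim = 6, n_herbs = 5, n_kernels = 8,
                      seed = 2, loss_mode = "SIGMOID_BCE")
  model <- build_model(cfg, paste0("h", 1:5))
  fz <- fixed_featurizer(all_terms, 6, 4)
  p <- predict_proba(model, list(symptoms = "gA1"), fz)
  expect_true(all(p >= 0 & p <= 1))
  cs <- separable_cases(30)
  cfgt <- model_config(max_terms = 4, dim = 8, n_herbs = 8, n_kernels = 8,
                       max_epochs = 15, learning_rate = 1e-3, seed = 4,
                       loss_mode = "SIGMOID_BCE")
  fit <- train_recommender(build_model(cfgt, cs$herb_vocabulary), cs,
                           fixed_featurizer(all_terms, 8, 4))
  h <- tidy(fit)
  expect_lt(h$loss[nrow(h)], h$loss[1])
})

test_that("numeric gradients match backpropagation on a tiny model", {
  cfg <- model_config(max_terms = 3, dim = 4, n_herbs = 4, n_kernels = 3,
                      kernel_width = 3, fc_sizes = c(5, 4), seed = 8)
  model <- build_model(cfg, paste0("h", 1:4))
  withr::with_seed(9, {
    X <- matrix(stats::rnorm(2 * 3 * 4), 6, 4)  # two cases
    Y <- matrix(c(1, 0, 1, 0, 0, 1, 0, 0), 2, 4, byrow = TRUE)
    Y <- Y / rowSums(Y)
  })
  params <- model$weights
  fw <- herbrec:::forward_pass(params, cfg, X)
  grads <- herbrec:::backward_pass(params, cfg, fw, Y)
  loss_at <- function(p) {
    f <- herbrec:::forward_pass(p, cfg, X, want_grad_cache = FALSE)
    herbrec:::model_loss(cfg, f$probs, Y)
  }
  eps <- 1e-6
  for (nm in c("attn_w", "conv_w", "fc1_w", "fc3_b")) {
    theta <- params[[nm]]
    idx <- head(seq_along(theta), 4)
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- theta[i] + eps
      pm <- params; pm[[nm]][i] <- theta[i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(as.numeric(grads[[nm]][i]), num, tolerance = 1e-4)
    }
  }
})

test_that("glance summarizes a fitted model", {
  cs <- separable_cases(20)
  cfg <- model_config(max_terms = 4, dim = 8, n_herbs = 8, n_kernels = 8,
                      max_epochs = 5, seed = 4)
  fit <- train_recommender(build_model(cfg, cs$herb_vocabulary), cs,
                           fixed_featurizer(all_terms, 8, 4))
  g <- glance(fit)
  expect_equal(g$epochs_run, 5L)
  expect_true(g$trained)
  expect_gt(g$n_parameters, 0)
})
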