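#' Recommender model configuration
#'
#' Architecture and training settings for the herb recommender: per-row
#' attention over the `(max_terms x dim)` symptom feature matrix, a 1-D
#' convolution along the term axis with `n_kernels` kernels of width
#' `kernel_width` ("same" zero padding), global max pooling per kernel,
#' then a three-layer fully connected head of sizes `fc_sizes` and the herb
#' output layer. With `loss_mode = "SOFTMAX_CE"` the output is a softmax
#' distribution trained by cross-entropy against the sum-normalized
#' multi-hot herb vector; `"SIGMOID_BCE"` replaces the softmax by
#' element-wise sigmoids trained with binary cross-entropy.
#'
#' @param max_terms Feature matrix rows (symptom slots).
#' @param dim Embedding dimension of each row.
#' @param n_herbs Output arity; must equal the herb vocabulary size.
#' @param n_kernels Convolution kernels (default 64).
#' @param kernel_width Kernel width along the term axis (default 3; must
#'   not exceed `max_terms`).
#' @param fc_sizes Hidden layer sizes of the fully connected head.
#' @param learning_rate Adam step size (default 1e-4).
#' @param max_epochs Training epoch cap (default 100).
#' @param patience Epochs without validation Recall\@10 improvement before
#'   early stop (default 10).
#' @param batch_size Minibatch size (default 16).
#' @param seed Integer seed for weight initialization and batching.
#' @param loss_mode `"SOFTMAX_CE"` or `"SIGMOID_BCE"`.
#' @return A `model_config` list.
#' @export
model_config <- function(max_terms, dim, n_herbs, n_kernels = 64,
                         kernel_width = 3, fc_sizes = c(256, 64),
                         learning_rate = 1e-4, max_epochs = 100,
                         patience = 10, batch_size = 16, seed = 1,
                         loss_mode = c("SOFTMAX_CE", "SIGMOID_BCE")) {
  loss_mode <- match.arg(loss_mode)
  sizes <- c(max_terms = max_terms, dim = dim, n_herbs = n_herbs,
             n_kernels = n_kernels, kernel_width = kernel_width,
             fc_sizes, batch_size = batch_size)
  if (any(sizes < 1)) abort("all model sizes must be positive")
  if (kernel_width > max_terms) abort("kernel_width must not exceed max_terms")
  structure(list(max_terms = as.integer(max_terms), dim = as.integer(dim),
                 n_herbs = as.integer(n_herbs),
                 n_kernels = as.integer(n_kernels),
                 kernel_width = as.integer(kernel_width),
                 fc_sizes = as.integer(fc_sizes),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss_mode = loss_mode),
            class = "model_config")
}

#' Build an untrained herb recommender
#'
#' Initializes all weights from the configuration seed (Glorot-uniform for
#' projections, zeros for biases), so the same seed gives identical initial
#' models.
#'
#' @param cfg A [model_config()].
#' @param herb_index Ordered character vector of herb names of length
#'   `cfg$n_herbs` (the label space).
#' @return A `herb_recommender`.
#' @export
build_model <- function(cfg, herb_index) {
  stopifnot(inherits(cfg, "model_config"))
  if (length(herb_index) != cfg$n_herbs) {
    abort("herb_index length must equal cfg$n_herbs")
  }
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  params <- withr::with_seed(cfg$seed, {
    cw <- cfg$kernel_width
    list(
      attn_w = as.numeric(glorot(cfg$dim, 1)),
      attn_b = 0,
      conv_w = glorot(cw * cfg$dim, cfg$n_kernels),
      conv_b = numeric(cfg$n_kernels),
      fc1_w = glorot(cfg$n_kernels, cfg$fc_sizes[1]),
      fc1_b = numeric(cfg$fc_sizes[1]),
      fc2_w = glorot(cfg$fc_sizes[1], cfg$fc_sizes[2]),
      fc2_b = numeric(cfg$fc_sizes[2]),
      fc3_w = glorot(cfg$fc_sizes[2], cfg$n_herbs),
      fc3_b = numeric(cfg$n_herbs)
    )
  })
  structure(list(config = cfg, weights = params,
                 herb_index = as.character(herb_index), trained = FALSE),
            class = "herb_recommender")
}

#' @export
print.herb_recommender <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<herb_recommender> %s(%d x %d) -> attn -> conv(k=%d,w=%d) -> fc(%s) -> %d herbs [%s]\n",
    if (x$trained) "trained " else "untrained ", cfg$max_terms, cfg$dim,
    cfg$n_kernels, cfg$kernel_width, paste(cfg$fc_sizes, collapse = ","),
    cfg$n_herbs, cfg$loss_mode))
  invisible(x)
}

# ---- internal forward / backward --------------------------------------

# X: (B*m x d), rows grouped per case with the term index varying fastest.
# Returns everything needed for the backward pass.
forward_pass <- function(params, cfg, X, want_grad_cache = TRUE) {
  m <- cfg$max_terms
  d <- cfg$dim
  B <- nrow(X) / m
  cw <- cfg$kernel_width
  k <- cfg$n_kernels

  mask <- rowSums(abs(X)) > 0
  s <- as.numeric(X %*% params$attn_w) + params$attn_b
  S <- matrix(s, nrow = m)                       # m x B
  M <- matrix(mask, nrow = m)
  S[!M] <- -Inf
  smax <- apply(S, 2, max)
  smax[!is.finite(smax)] <- 0                    # all-masked case
  E <- exp(sweep(S, 2, smax, "-"))
  E[!M] <- 0
  Z <- colSums(E)
  Z[Z == 0] <- 1
  A <- sweep(E, 2, Z, "/")                       # attention weights, m x B
  a <- as.numeric(A)
  Xw <- X * a

  # "same"-padded shifts: block r reads term t + off[r]
  off <- seq_len(cw) - 1L - (cw - 1L) %/% 2L
  Xp <- rbind(Xw, 0)                             # padding row
  pad <- nrow(Xp)
  t_of_row <- rep(seq_len(m), times = B)
  case_of_row <- rep(seq_len(B), each = m)
  src <- matrix(0L, nrow = B * m, ncol = cw)
  for (r in seq_len(cw)) {
    tt <- t_of_row + off[r]
    ok <- tt >= 1L & tt <= m
    src[, r] <- ifelse(ok, (case_of_row - 1L) * m + tt, pad)
  }
  Zb <- matrix(0, nrow = B * m, ncol = cw * d)
  for (r in seq_len(cw)) {
    Zb[, ((r - 1L) * d + 1L):(r * d)] <- Xp[src[, r], , drop = FALSE]
  }
  Cpre <- sweep(Zb %*% params$conv_w, 2, params$conv_b, "+")
  Crelu <- pmax(Cpre, 0)                         # B*m x k

  # global max pool over the term axis, tracking the argmax
  P <- matrix(-Inf, B, k)
  argm <- matrix(1L, B, k)
  for (t in seq_len(m)) {
    rows <- seq.int(t, by = m, length.out = B)
    Ct <- Crelu[rows, , drop = FALSE]
    upd <- Ct > P
    argm[upd] <- t
    P[upd] <- Ct[upd]
  }

  H1p <- sweep(P %*% params$fc1_w, 2, params$fc1_b, "+")
  H1 <- pmax(H1p, 0)
  H2p <- sweep(H1 %*% params$fc2_w, 2, params$fc2_b, "+")
  H2 <- pmax(H2p, 0)
  logits <- sweep(H2 %*% params$fc3_w, 2, params$fc3_b, "+")

  if (cfg$loss_mode == "SOFTMAX_CE") {
    lmax <- apply(logits, 1, max)
    EX <- exp(logits - lmax)
    probs <- EX / rowSums(EX)
  } else {
    probs <- 1 / (1 + exp(-logits))
  }
  out <- list(probs = probs, attention = A)
  if (want_grad_cache) {
    out <- c(out, list(X = X, mask = mask, A = A, Xw = Xw, src = src,
                       Zb = Zb, Cpre = Cpre, argm = argm, P = P,
                       H1p = H1p, H1 = H1, H2p = H2p, H2 = H2,
                       B = B))
  }
  out
}

backward_pass <- function(params, cfg, fw, Y) {
  m <- cfg$max_terms
  d <- cfg$dim
  cw <- cfg$kernel_width
  k <- cfg$n_kernels
  B <- fw$B

  if (cfg$loss_mode == "SOFTMAX_CE") {
    dlogits <- (fw$probs - Y) / B
  } else {
    dlogits <- (fw$probs - Y) / (B * cfg$n_herbs)
  }
  g <- list()
  g$fc3_w <- crossprod(fw$H2, dlogits)
  g$fc3_b <- colSums(dlogits)
  dH2 <- tcrossprod(dlogits, params$fc3_w) * (fw$H2p > 0)
  g$fc2_w <- crossprod(fw$H1, dH2)
  g$fc2_b <- colSums(dH2)
  dH1 <- tcrossprod(dH2, params$fc2_w) * (fw$H1p > 0)
  g$fc1_w <- crossprod(fw$P, dH1)
  g$fc1_b <- colSums(dH1)
  dP <- tcrossprod(dH1, params$fc1_w)

  # un-pool: route each kernel's gradient to its argmax term row
  dCrelu <- matrix(0, nrow = B * m, ncol = k)
  for (t in seq_len(m)) {
    sel <- fw$argm == t
    if (!any(sel)) next
    Dt <- matrix(0, B, k)
    Dt[sel] <- dP[sel]
    rows <- seq.int(t, by = m, length.out = B)
    dCrelu[rows, ] <- Dt
  }
  dCpre <- dCrelu * (fw$Cpre > 0)
  g$conv_w <- crossprod(fw$Zb, dCpre)
  g$conv_b <- colSums(dCpre)
  dZb <- tcrossprod(dCpre, params$conv_w)

  dXw <- matrix(0, nrow = B * m + 1L, ncol = d)
  for (r in seq_len(cw)) {
    srcr <- fw$src[, r]
    ok <- srcr <= B * m
    block <- dZb[ok, ((r - 1L) * d + 1L):(r * d), drop = FALSE]
    dXw[srcr[ok], ] <- dXw[srcr[ok], , drop = FALSE] + block
  }
  dXw <- dXw[seq_len(B * m), , drop = FALSE]

  da <- rowSums(dXw * fw$X)
  Am <- fw$A                                    # m x B
  Dm <- matrix(da, nrow = m)
  inner <- colSums(Am * Dm)
  dS <- Am * sweep(Dm, 2, inner, "-")
  ds <- as.numeric(dS)
  g$attn_w <- as.numeric(crossprod(fw$X, ds))
  g$attn_b <- sum(ds)
  g
}

model_loss <- function(cfg, probs, Y) {
  eps <- 1e-12
  if (cfg$loss_mode == "SOFTMAX_CE") {
    -sum(Y * log(probs + eps)) / nrow(Y)
  } else {
    -mean(Y * log(probs + eps) + (1 - Y) * log(1 - probs + eps))
  }
}

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# stack featurized cases into the (B*m x d) layout used by forward_pass
stack_features <- function(cases_tbl, featurizer, m, d) {
  B <- nrow(cases_tbl)
  X <- matrix(0, nrow = B * m, ncol = d)
  for (i in seq_len(B)) {
    X[((i - 1L) * m + 1L):(i * m), ] <- featurizer(cases_tbl[i, ])
  }
  X
}

multi_hot <- function(herb_sets, herb_index, normalize) {
  Y <- matrix(0, nrow = length(herb_sets), ncol = length(herb_index))
  for (i in seq_along(herb_sets)) {
    idx <- match(herb_sets[[i]], herb_index)
    if (anyNA(idx)) {
      abort(sprintf("herb label not in herb_index: %s",
                    herb_sets[[i]][which(is.na(idx))[1]]))
    }
    Y[i, idx] <- 1
  }
  if (normalize) Y <- Y / pmax(rowSums(Y), 1)
  Y
}

#' Train the herb recommender
#'
#' Minibatch Adam on the configured loss. When `val_cases` is supplied,
#' validation Recall\@10 is computed each epoch and training stops early
#' once it has not improved for `patience` epochs, restoring the best
#' weights; without validation cases the model trains for `max_epochs`.
#'
#' @param model A [build_model()] recommender.
#' @param train_cases A [case_set()] whose herbs are all in the model's
#'   `herb_index`.
#' @param featurizer A function `case -> (max_terms x dim)` matrix, e.g.
#'   from [case_featurizer()].
#' @param val_cases Optional [case_set()] monitored for early stopping.
#' @param verbose Print per-epoch progress.
#' @return The trained `herb_recommender`, with a `history` tibble
#'   (`epoch`, `loss`, `val_recall10`) attached as `model$history`.
#' @export
train_recommender <- function(model, train_cases, featurizer,
                              val_cases = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "herb_recommender"),
            inherits(train_cases, "case_set"))
  cfg <- model$config
  m <- cfg$max_terms
  d <- cfg$dim
  X <- stack_features(train_cases$cases, featurizer, m, d)
  Y <- multi_hot(train_cases$cases$herbs, model$herb_index,
                 normalize = cfg$loss_mode == "SOFTMAX_CE")
  B <- nrow(train_cases$cases)

  Xval <- NULL
  if (!is.null(val_cases)) {
    Xval <- stack_features(val_cases$cases, featurizer, m, d)
    val_truth <- val_cases$cases$herbs
    Kval <- min(10L, cfg$n_herbs)
  }

  params <- model$weights
  state <- adam_init(params)
  best <- list(params = params, recall = -Inf, epoch = 0L)
  history <- vector("list", cfg$max_epochs)

  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(B)
      epoch_loss <- 0
      n_batches <- 0L
      for (b0 in seq(1L, B, by = cfg$batch_size)) {
        idx <- perm[b0:min(b0 + cfg$batch_size - 1L, B)]
        rows <- as.numeric(t(outer((idx - 1L) * m, seq_len(m), "+")))
        Xb <- X[rows, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        fw <- forward_pass(params, cfg, Xb)
        grads <- backward_pass(params, cfg, fw, Yb)
        upd <- adam_step(params, grads, state, cfg$learning_rate)
        params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + model_loss(cfg, fw$probs, Yb)
        n_batches <- n_batches + 1L
      }
      epoch_loss <- epoch_loss / n_batches

      val_recall <- NA_real_
      if (!is.null(Xval)) {
        fwv <- forward_pass(params, cfg, Xval, want_grad_cache = FALSE)
        preds <- apply(fwv$probs, 1, function(p)
          model$herb_index[order(-p, seq_along(p))[seq_len(Kval)]],
          simplify = FALSE)
        val_recall <- micro_recall(preds, val_truth)
        if (val_recall > best$recall + 1e-9) {
          best <- list(params = params, recall = val_recall, epoch = epoch)
        }
      }
      history[[epoch]] <- tibble(epoch = epoch, loss = epoch_loss,
                                 val_recall10 = val_recall)
      if (verbose) {
        inform(sprintf("epoch %3d loss %.4f val recall@10 %s", epoch,
                       epoch_loss,
                       ifelse(is.na(val_recall), "-", sprintf("%.3f", val_recall))))
      }
      if (!is.null(Xval) && epoch - best$epoch >= cfg$patience) break
    }
  })

  if (!is.null(Xval) && is.finite(best$recall)) params <- best$params
  model$weights <- params
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(history)
  model
}

micro_recall <- function(preds, truth) {
  hits <- sum(purrr::map2_dbl(preds, truth, ~ length(intersect(.x, .y))))
  hits / sum(lengths(truth))
}

#' Predict per-herb probabilities for one case
#'
#' Deterministic forward pass. In softmax mode the result is a probability
#' distribution over the herb vocabulary (entries sum to 1); in sigmoid
#' mode each entry is an independent probability in \[0, 1\].
#'
#' @param model A (typically trained) `herb_recommender`.
#' @param case One case (a one-row `cases` slice or a character vector of
#'   symptom terms).
#' @param featurizer As in [train_recommender()].
#' @return Named numeric vector over the model's `herb_index`.
#' @export
predict_proba <- function(model, case, featurizer) {
  cfg <- model$config
  X <- featurizer(case)
  stopifnot(nrow(X) == cfg$max_terms, ncol(X) == cfg$dim)
  fw <- forward_pass(model$weights, cfg, X, want_grad_cache = FALSE)
  setNames(as.numeric(fw$probs[1, ]), model$herb_index)
}

# batched version used by evaluation drivers
predict_proba_all <- function(model, cases_tbl, featurizer) {
  cfg <- model$config
  X <- stack_features(cases_tbl, featurizer, cfg$max_terms, cfg$dim)
  fw <- forward_pass(model$weights, cfg, X, want_grad_cache = FALSE)
  colnames(fw$probs) <- model$herb_index
  fw$probs
}

#' Top-K herb recommendation from a probability vector
#'
#' The `K` herbs with the highest probabilities; ties are broken by
#' position in the herb index, so recommendations are deterministic.
#'
#' @param probs Named numeric vector (names = herb index order).
#' @param K Number of herbs, `1 <= K <= length(probs)`.
#' @return Character vector of `K` herb names, best first.
#' @export
recommend <- function(probs, K) {
  if (K < 1 || K > length(probs)) abort("K out of range")
  names(probs)[order(-probs, seq_along(probs))[seq_len(K)]]
}
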