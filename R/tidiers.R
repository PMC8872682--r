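#' Tidy a mapped term set
#'
#' @param x A [map_term()] result.
#' @param ... Unused.
#' @return Tibble with one row per candidate or token: `node`, `frequency`
#'   (NA for tokens absent from the candidate pool), `retained`, `is_token`.
#' @export
tidy.mapped_term_set <- function(x, ...) {
  nodes <- union(x$retained, names(x$candidate_freq))
  tibble(
    node = nodes,
    frequency = unname(x$candidate_freq[nodes]),
    retained = nodes %in% x$retained,
    is_token = nodes %in% x$tokens
  )
}

#' Tidy / summarize a fitted herb recommender
#'
#' `tidy()` returns the training history (per-epoch loss and validation
#' Recall\@10); `glance()` a one-row model summary.
#'
#' @param x A `herb_recommender`.
#' @param ... Unused.
#' @export
tidy.herb_recommender <- function(x, ...) {
  x$history %||% tibble(epoch = integer(), loss = numeric(),
                        val_recall10 = numeric())
}

#' @rdname tidy.herb_recommender
#' @export
glance.herb_recommender <- function(x, ...) {
  h <- x$history
  tibble(
    n_parameters = sum(purrr::map_dbl(x$weights, length)),
    n_herbs = x$config$n_herbs,
    loss_mode = x$config$loss_mode,
    trained = x$trained,
    epochs_run = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h) || !nrow(h)) NA_real_ else h$loss[nrow(h)],
    best_val_recall10 = if (is.null(h) || all(is.na(h$val_recall10))) NA_real_
                        else max(h$val_recall10, na.rm = TRUE)
  )
}

#' Plot the training history of a recommender
#'
#' @param object A trained `herb_recommender`.
#' @param ... Unused.
#' @return A ggplot object: loss and validation Recall\@10 against epoch.
#' @export
autoplot.herb_recommender <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("loss", "val_recall10"),
                              names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}

#' Plot an evaluation report
#'
#' @param object An `eval_report` from [evaluate_recommender()].
#' @param ... Unused.
#' @return A ggplot object: precision, recall and F1 against K.
#' @export
autoplot.eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$K, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "K", y = "micro-averaged metric",
                  title = "Top-K evaluation")
}

#' Plot a prescription--symptom similarity correlation table
#'
#' @param object A `sim_corr_table` from [similarity_correlation()].
#' @param ... Unused.
#' @return A ggplot object: mean symptom similarity per prescription-
#'   similarity bin.
#' @export
autoplot.sim_corr_table <- function(object, ...) {
  d <- as_tibble(object)
  d$bin_mid <- (d$bin_low + d$bin_high) / 2
  ggplot2::ggplot(d[!is.na(d$mean_symptom_similarity), ],
                  ggplot2::aes(x = .data$bin_mid,
                               y = .data$mean_symptom_similarity)) +
    ggplot2::geom_col(width = 0.08) +
    ggplot2::labs(x = "prescription similarity bin",
                  y = "mean symptom similarity",
                  title = sprintf("Mapper: %s", attr(object, "mapper")))
}
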