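#' Synthetic-corpus generator configuration
#'
#' The generator emulates the statistical shape of a curated herbal
#' case corpus and its knowledge graph with a shared latent structure:
#' herbs and symptoms are partitioned into `n_efficacy` groups, herb--
#' symptom links fall within a group with probability `1 - noise_rate`,
#' and symptom surface strings are composed of group-biased words, so the
#' word level carries the same signal the graph does. Cases draw their
#' symptoms and herbs from a common group mixture, which makes the
#' symptom-to-herb mapping learnable end to end; with
#' `unrecorded_fraction > 0` a symptom term is replaced by a *novel*
#' string, absent from the knowledge graph but composed of in-group words
#' -- the unrecorded-term mechanism subnetwork mapping is designed for.
#'
#' Symptom and herb counts per case are Poisson at the corpus means
#' observed after long-tail screening (11.45 symptoms, 11.31 herbs),
#' resampled into the screening bounds (1--39 / 1--19).
#'
#' @param n_words Word vocabulary size.
#' @param n_symptoms,n_herbs Entity counts (herbs `>= 20`).
#' @param n_efficacy,n_property,n_meridian Attribute entity counts.
#' @param words_per_symptom `(min, max)` words per composed term.
#' @param mean_symptoms_per_case,mean_herbs_per_case Poisson means.
#' @param n_cases Corpus size.
#' @param unrecorded_fraction Probability a case symptom is replaced by a
#'   novel in-group composition.
#' @param noise_rate Probability a herb--symptom link or case draw crosses
#'   groups.
#' @param sy_links_per_herb Symptom links per herb in the graph.
#' @param mixture_weights Two probabilities for a case's primary and
#'   secondary latent group. Cases always mix two groups so the herb count
#'   can exceed one group's herb pool; a dominant primary weight keeps the
#'   symptom-to-herb signal strong (herbs within a group are exchangeable,
#'   so the achievable Top-10 recall is capped by how concentrated the
#'   mixture is).
#' @param synonym_fraction Fraction of same-group symptom pairs joined by a
#'   synonymy relation.
#' @param separator Word separator in composed terms; the default space
#'   makes `WHITESPACE` tokenization exact, `""` gives unsegmented
#'   CJK-style strings for exercising FMM/BMM.
#' @param seed Integer seed; all outputs are deterministic in `(cfg, seed)`.
#' @return A `gen_config` list.
#' @export
gen_config <- function(n_words = 60, n_symptoms = 150, n_herbs = 100,
                       n_efficacy = 5, n_property = 4, n_meridian = 6,
                       words_per_symptom = c(2, 3),
                       mean_symptoms_per_case = 11.45,
                       mean_herbs_per_case = 11.31,
                       n_cases = 1000, unrecorded_fraction = 0,
                       noise_rate = 0.05, sy_links_per_herb = 8,
                       mixture_weights = c(0.85, 0.15),
                       synonym_fraction = 0.02, separator = " ",
                       seed = 1) {
  cfg <- list(n_words = n_words, n_symptoms = n_symptoms, n_herbs = n_herbs,
              n_efficacy = n_efficacy, n_property = n_property,
              n_meridian = n_meridian, words_per_symptom = words_per_symptom,
              mean_symptoms_per_case = mean_symptoms_per_case,
              mean_herbs_per_case = mean_herbs_per_case, n_cases = n_cases,
              unrecorded_fraction = unrecorded_fraction,
              noise_rate = noise_rate, sy_links_per_herb = sy_links_per_herb,
              mixture_weights = mixture_weights,
              synonym_fraction = synonym_fraction, separator = separator,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_words", "n_symptoms", "n_herbs", "n_efficacy",
                         "n_property", "n_meridian", "n_cases")])
  if (any(counts < 1)) abort("all counts must be positive")
  if (cfg$unrecorded_fraction < 0 || cfg$unrecorded_fraction > 1 ||
      cfg$noise_rate < 0 || cfg$noise_rate > 1) {
    abort("fractions must lie in [0, 1]")
  }
  if (n_symptoms < n_efficacy || n_herbs < n_efficacy) {
    abort("every latent group needs at least one symptom and one herb")
  }
  structure(cfg, class = "gen_config")
}

#' Preset generator configurations
#'
#' `"easy"`: 50 herbs in 5 groups, 5% cross-group noise, 625 cases (a
#' 500/125 split at 8:2), seed 11 -- strong recoverable signal.
#' `"hard"`: 100 herbs in 10 groups with 25% noise.
#' `"nosignal"`: the easy corpus; pair with `shuffle_labels = TRUE` in
#' [recovery_benchmark()] for the no-signal control.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [gen_config()].
#' @return A `gen_config`.
#' @export
preset_config <- function(name = c("easy", "hard", "nosignal"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    easy = , nosignal = list(n_herbs = 50, n_efficacy = 5, noise_rate = 0.05,
                             n_cases = 625, seed = 11L),
    hard = list(n_herbs = 100, n_efficacy = 10, noise_rate = 0.25,
                n_cases = 625, seed = 11L))
  do.call(gen_config, utils::modifyList(base, list(...)))
}

# group assignment round-robin over 1..n_groups
round_robin <- function(n, n_groups) rep(seq_len(n_groups), length.out = n)

#' Generate a synthetic knowledge graph with latent group structure
#'
#' @param cfg A [gen_config()].
#' @return List with `kg` (a [knowledge_graph()]) and `gt`, the ground
#'   truth: `group_of_symptom`, `group_of_herb` (named integers),
#'   `group_words` (list of per-group word pools) and `shared_words` (the
#'   cross-group pool).
#' @export
make_kg <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  withr::with_seed(cfg$seed, {
    G <- cfg$n_efficacy
    words <- sprintf("w%03d", seq_len(cfg$n_words))
    n_shared <- max(1L, round(0.2 * cfg$n_words))
    shared <- words[seq_len(n_shared)]
    own <- words[-seq_len(n_shared)]
    group_of_word <- round_robin(length(own), G)
    group_words <- purrr::map(seq_len(G), ~ own[group_of_word == .x])
    if (any(lengths(group_words) < max(cfg$words_per_symptom))) {
      abort("word vocabulary too small for the group count")
    }

    # compose unique symptom surface strings from group-biased words
    group_of_symptom <- round_robin(cfg$n_symptoms, G)
    seen <- character()
    symptoms <- character(cfg$n_symptoms)
    for (i in seq_len(cfg$n_symptoms)) {
      g <- group_of_symptom[i]
      for (try in 1:200) {
        nw <- sample(cfg$words_per_symptom[1]:cfg$words_per_symptom[2], 1)
        pool <- if (runif(1) < 0.85) group_words[[g]] else shared
        # at least one in-group word so the group signal is always present
        first <- sample(group_words[[g]], 1)
        rest <- sample(setdiff(pool, first), min(nw - 1L, length(setdiff(pool, first))))
        term <- paste(c(first, rest), collapse = cfg$separator)
        if (!term %in% seen) break
      }
      if (term %in% seen) term <- paste0(term, cfg$separator, sprintf("w%03dx", i))
      seen <- c(seen, term)
      symptoms[i] <- term
    }
    herbs <- sprintf("herb%03d", seq_len(cfg$n_herbs))
    group_of_herb <- round_robin(cfg$n_herbs, G)
    eff <- sprintf("eff%02d", seq_len(G))
    props <- sprintf("prop%02d", seq_len(cfg$n_property))
    merids <- sprintf("merid%02d", seq_len(cfg$n_meridian))

    hb_ef <- tibble(u = herbs, v = eff[group_of_herb], rtype = "HB-EF")
    hb_pp <- tibble(u = herbs, v = sample(props, cfg$n_herbs, replace = TRUE),
                    rtype = "HB-PP")
    hb_md <- dplyr::bind_rows(purrr::map(seq_len(cfg$n_herbs), function(i) {
      k <- sample(1:2, 1)
      tibble(u = herbs[i], v = sample(merids, k), rtype = "HB-MD")
    }))

    hb_sy <- dplyr::bind_rows(purrr::map(seq_len(cfg$n_herbs), function(i) {
      g <- group_of_herb[i]
      in_group <- symptoms[group_of_symptom == g]
      out_group <- symptoms[group_of_symptom != g]
      k <- min(cfg$sy_links_per_herb, cfg$n_symptoms)
      cross <- runif(k) < cfg$noise_rate
      tgt_in <- if (sum(!cross)) sample(in_group, min(sum(!cross), length(in_group))) else character()
      tgt_out <- if (sum(cross) && length(out_group)) {
        sample(out_group, min(sum(cross), length(out_group)))
      } else character()
      tibble(u = herbs[i], v = unique(c(tgt_in, tgt_out)), rtype = "HB-SY")
    }))

    sy_sy <- dplyr::bind_rows(purrr::map(seq_len(G), function(g) {
      sg <- symptoms[group_of_symptom == g]
      if (length(sg) < 2) return(NULL)
      pr <- t(utils::combn(sg, 2))
      keep <- runif(nrow(pr)) < cfg$synonym_fraction
      if (!any(keep)) return(NULL)
      tibble(u = pr[keep, 1], v = pr[keep, 2], rtype = "SY-SY")
    }))

    kg <- knowledge_graph(dplyr::bind_rows(hb_sy, sy_sy, hb_ef, hb_pp, hb_md))
    gt <- list(
      group_of_symptom = setNames(group_of_symptom, symptoms),
      group_of_herb = setNames(group_of_herb, herbs),
      group_words = group_words,
      shared_words = shared
    )
    list(kg = kg, gt = gt)
  })
}

#' Generate a synthetic clinical case corpus
#'
#' Each case samples a two-group mixture at `cfg$mixture_weights`,
#' Poisson-distributed symptom and herb counts at the configured
#' means (resampled into the screening bounds), draws symptoms and herbs
#' from the same mixture -- cross-group with probability `noise_rate` --
#' and replaces each symptom with probability `unrecorded_fraction` by a
#' novel term composed of words from the same group that appear in
#' recorded terms.
#'
#' @param kg,gt A [make_kg()] result.
#' @param cfg The same [gen_config()].
#' @return A [case_set()].
#' @export
make_cases <- function(kg, gt, cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  G <- cfg$n_efficacy
  symptoms_by_group <- split(names(gt$group_of_symptom), gt$group_of_symptom)
  herbs_by_group <- split(names(gt$group_of_herb), gt$group_of_herb)
  all_symptoms <- names(gt$group_of_symptom)
  all_herbs <- names(gt$group_of_herb)
  # words usable for novel terms: in-group words seen in recorded terms
  sep_pat <- if (nzchar(cfg$separator)) cfg$separator else NULL
  used_words_by_group <- purrr::map(seq_len(G), function(g) {
    toks <- unlist(purrr::map(symptoms_by_group[[as.character(g)]], function(s) {
      if (!is.null(sep_pat)) strsplit(s, sep_pat, fixed = TRUE)[[1]]
      else unlist(strsplit(s, ""))
    }))
    intersect(gt$group_words[[g]], toks)
  })

  trunc_pois <- function(mean, lo, hi) {
    repeat {
      x <- rpois(1, mean)
      if (x >= lo && x <= hi) return(x)
    }
  }
  draw_from_mixture <- function(k, by_group, all_items, gmix, wmix) {
    chosen <- character(0)
    guard <- 0L
    while (length(chosen) < k && guard < 1000L) {
      guard <- guard + 1L
      g <- if (runif(1) < cfg$noise_rate) sample.int(G, 1)
           else sample(gmix, 1, prob = wmix)
      pool <- setdiff(by_group[[as.character(g)]], chosen)
      if (!length(pool)) pool <- setdiff(all_items, chosen)
      if (!length(pool)) break
      chosen <- c(chosen, sample(pool, 1))
    }
    chosen
  }

  withr::with_seed(cfg$seed + 1L, {
    rows <- purrr::map(seq_len(cfg$n_cases), function(i) {
      g1 <- sample.int(G, 1)
      g2 <- if (G > 1) sample(setdiff(seq_len(G), g1), 1) else g1
      gmix <- c(g1, g2)
      wmix <- cfg$mixture_weights
      n_sy <- trunc_pois(cfg$mean_symptoms_per_case, 1, 39)
      n_hb <- trunc_pois(cfg$mean_herbs_per_case, 1,
                         min(19, length(all_herbs)))
      sys <- draw_from_mixture(n_sy, symptoms_by_group, all_symptoms, gmix, wmix)
      hbs <- draw_from_mixture(n_hb, herbs_by_group, all_herbs, gmix, wmix)
      if (cfg$unrecorded_fraction > 0) {
        sys <- vapply(sys, function(s) {
          if (runif(1) >= cfg$unrecorded_fraction) return(s)
          g <- gt$group_of_symptom[[s]]
          pool <- used_words_by_group[[g]]
          if (length(pool) < 2) return(s)
          for (try in 1:50) {
            nw <- sample(cfg$words_per_symptom[1]:cfg$words_per_symptom[2], 1)
            novel <- paste(sample(pool, min(nw, length(pool))),
                           collapse = cfg$separator)
            if (!novel %in% all_symptoms) return(novel)
          }
          s
        }, "", USE.NAMES = FALSE)
        sys <- unique(sys)
      }
      list(case_id = sprintf("case%05d", i), symptoms = sys, herbs = hbs)
    })
    suppressWarnings(case_set(tibble(
      case_id = purrr::map_chr(rows, "case_id"),
      symptoms = purrr::map(rows, "symptoms"),
      herbs = purrr::map(rows, "herbs")
    )))
  })
}

#' Build the symptom network and embeddings for a synthetic corpus
#'
#' Pipeline stage shared by [recovery_benchmark()] and scripts: word
#' disassembly of the knowledge graph's symptom vocabulary, synonymy
#' ingestion, metapath edges at thresholds matched to the generator's path-
#' count scale, uniform walks and skip-gram training.
#'
#' @param kg A [knowledge_graph()].
#' @param cfg The generator configuration (for the separator).
#' @param embed_dim Embedding dimension.
#' @param seed Integer seed for walks and skip-gram.
#' @param ef_threshold,md_threshold,pp_threshold Metapath frequency
#'   thresholds. Efficacy paths carry the latent-group signal, so their
#'   threshold is low; property/meridian attributes are uniform (pure
#'   noise) and their thresholds sit above the typical path count.
#' @param p,q node2vec parameters (1/1 = DeepWalk).
#' @param lexicon Word lexicon for FMM segmentation, required when the
#'   generator produced unsegmented terms (`separator = ""`).
#' @return List with `net`, `tab` and `tok`.
#' @export
build_synthetic_features <- function(kg, cfg, embed_dim = 32, seed = 1,
                                     ef_threshold = 3, md_threshold = 40,
                                     pp_threshold = 40, p = 1, q = 1,
                                     lexicon = NULL) {
  tok <- if (nzchar(cfg$separator)) {
    tokenizer("WHITESPACE")
  } else {
    if (is.null(lexicon)) {
      abort("unsegmented terms (separator = \"\") need a `lexicon` for FMM")
    }
    tokenizer("FMM", lexicon = lexicon)
  }
  sy <- kg_entity_ids(kg, "SY")
  word_edges <- build_word_edges(sy, tok)
  syn_edges <- kg_edges(kg, "SY-SY")
  paths <- list(
    build_metapath_edges(count_metapaths(kg, "EF"), ef_threshold),
    build_metapath_edges(count_metapaths(kg, "MD"), md_threshold),
    build_metapath_edges(count_metapaths(kg, "PP"), pp_threshold)
  )
  net <- suppressMessages(assemble_network(word_edges, syn_edges, paths))
  wc <- generate_walks(net, num_walks = 10, walk_length = 40,
                       p = p, q = q, seed = seed)
  tab <- suppressWarnings(train_skipgram(wc, dim = embed_dim, window = 5,
                                         epochs = 5, seed = seed,
                                         nodes = net$nodes$id))
  list(net = net, tab = tab, tok = tok)
}

#' End-to-end signal-recovery benchmark
#'
#' Runs the full pipeline on a synthetic corpus -- generate the knowledge
#' graph and cases, build the symptom network, embed it, featurize cases
#' by subnetwork term mapping, train the recommender, and score held-out
#' Top-10 recall against the `K / n_herbs` random baseline. Several
#' featurization variants can share one generated corpus and embedding.
#'
#' @param cfg A [gen_config()] (e.g. [preset_config()]).
#' @param variants Tibble with columns `featurizer` (`"sstm"`/`"lookup"`),
#'   `fusion` (`"AVG"`/`"MAX"`), `threshold`, `shuffle_labels`; default is
#'   the single standard variant (sstm, AVG, threshold 2).
#' @param seed Seed for the split, training and any label shuffling
#'   (defaults to the generator seed).
#' @param embed_dim,max_terms,n_kernels Feature and model sizes, scaled to
#'   the synthetic corpus.
#' @param test_fraction Held-out fraction (8:2 by default).
#' @param val_fraction Fraction of the training half used for early-stop
#'   monitoring.
#' @param K Evaluation cut-off.
#' @param ... Passed to [build_synthetic_features()].
#' @return A `recovery_report` tibble: one row per variant with columns
#'   `featurizer`, `fusion`, `threshold`, `shuffle_labels`, `precision`,
#'   `recall`, `f1`, `baseline_recall`, `n_train`, `n_test`, `epochs_run`.
#' @export
recovery_benchmark <- function(cfg = preset_config("easy"),
                               variants = NULL, seed = cfg$seed,
                               embed_dim = 32, max_terms = 30,
                               n_kernels = 64, test_fraction = 0.2,
                               val_fraction = 0.12, K = 10, ...) {
  if (is.null(variants)) {
    variants <- tibble(featurizer = "sstm", fusion = "AVG",
                       threshold = 2, shuffle_labels = FALSE)
  }
  made <- make_kg(cfg)
  cases <- make_cases(made$kg, made$gt, cfg)
  cases <- screen_cases(cases)
  halves <- split_cases(cases, test_fraction, seed = seed)
  inner <- split_cases(halves$train, val_fraction, seed = seed + 1L)
  feats <- build_synthetic_features(made$kg, cfg, embed_dim = embed_dim,
                                    seed = seed, ...)
  n_herbs <- length(cases$herb_vocabulary)

  out <- purrr::pmap(variants, function(featurizer, fusion, threshold,
                                        shuffle_labels) {
    fz <- case_featurizer(feats$net, feats$tab, feats$tok,
                          threshold = threshold, method = fusion,
                          max_terms = max_terms, kind = featurizer)
    fit_cs <- inner$train
    val_cs <- inner$test
    if (shuffle_labels) {
      fit_cs$cases$herbs <- withr::with_seed(
        seed + 2L, fit_cs$cases$herbs[sample.int(nrow(fit_cs$cases))])
      val_cs$cases$herbs <- withr::with_seed(
        seed + 3L, val_cs$cases$herbs[sample.int(nrow(val_cs$cases))])
    }
    cfg_m <- model_config(max_terms = max_terms, dim = embed_dim,
                          n_herbs = n_herbs, n_kernels = n_kernels,
                          seed = seed)
    model <- build_model(cfg_m, cases$herb_vocabulary)
    model <- train_recommender(model, fit_cs, fz, val_cases = val_cs)
    rep <- evaluate_recommender(model, halves$test, fz, K = K)
    tibble(featurizer = featurizer, fusion = fusion, threshold = threshold,
           shuffle_labels = shuffle_labels,
           precision = rep$precision, recall = rep$recall, f1 = rep$f1,
           baseline_recall = K / n_herbs,
           n_train = nrow(halves$train$cases), n_test = nrow(halves$test$cases),
           epochs_run = nrow(model$history))
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("recovery_report", class(out))
  out
}
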