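#' Create a symptom-term tokenizer
#'
#' Symptom terms are disassembled into "symptom words" before network
#' construction and term mapping. Five modes are supported:
#'
#' * `CHAR` -- one token per character (the natural unit for unsegmented
#'   Chinese text when no lexicon is available);
#' * `WHITESPACE` -- split on runs of whitespace;
#' * `FMM` -- forward maximum matching: scan left to right, greedily taking
#'   the longest lexicon word at each position, emitting unmatched single
#'   characters as singletons;
#' * `BMM` -- backward maximum matching: the same greedy scan right to left;
#' * `NGRAM` -- all contiguous substrings of length `n` (a term shorter
#'   than `n` yields itself, so every term keeps a representation).
#'
#' @param mode One of `"CHAR"`, `"WHITESPACE"`, `"FMM"`, `"BMM"`, `"NGRAM"`.
#' @param lexicon Character vector of dictionary words (required for
#'   FMM/BMM).
#' @param n N-gram length, `>= 1` (required for NGRAM).
#' @param stopwords Optional character vector of function words (e.g.
#'   conjunctions) removed from the token stream after segmentation; the
#'   usual way segmentation pipelines keep only content-bearing symptom
#'   words.
#' @return A `tokenizer` object for use with [tokenize()].
#' @examples
#' tokenize("foot sore", tokenizer("WHITESPACE"))
#' tokenize("abcd", tokenizer("FMM", lexicon = c("ab", "abc", "d")))
#' @export
tokenizer <- function(mode = c("CHAR", "WHITESPACE", "FMM", "BMM", "NGRAM"),
                      lexicon = NULL, n = NULL, stopwords = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("FMM", "BMM") && is.null(lexicon)) {
    abort(sprintf("%s tokenization requires a lexicon", mode))
  }
  if (mode == "NGRAM") {
    if (is.null(n) || n < 1) abort("NGRAM tokenization requires n >= 1")
    n <- as.integer(n)
  }
  structure(list(mode = mode, lexicon = unique(as.character(lexicon)), n = n,
                 stopwords = unique(as.character(stopwords))),
            class = "tokenizer")
}

#' @export
print.tokenizer <- function(x, ...) {
  extra <- switch(x$mode,
    FMM = , BMM = sprintf(" (%d lexicon words)", length(x$lexicon)),
    NGRAM = sprintf(" (n=%d)", x$n),
    "")
  cat(sprintf("<tokenizer> %s%s\n", x$mode, extra))
  invisible(x)
}

#' Tokenize a symptom term into words
#'
#' @param term A non-empty string.
#' @param tok A [tokenizer()].
#' @return Ordered character vector of tokens (duplicates preserved; callers
#'   that need set semantics apply `unique()` themselves).
#' @export
tokenize <- function(term, tok) {
  stopifnot(inherits(tok, "tokenizer"))
  if (!is.character(term) || length(term) != 1L || !nzchar(term)) {
    abort("term must be a single non-empty string")
  }
  out <- switch(tok$mode,
    CHAR = strsplit(term, "", fixed = FALSE)[[1]],
    WHITESPACE = {
      parts <- strsplit(trimws(term), "\\s+")[[1]]
      parts[nzchar(parts)]
    },
    FMM = max_match(term, tok$lexicon, backward = FALSE),
    BMM = max_match(term, tok$lexicon, backward = TRUE),
    NGRAM = {
      chars <- strsplit(term, "")[[1]]
      L <- length(chars)
      if (L < tok$n) return(term)
      vapply(seq_len(L - tok$n + 1L),
             function(i) paste(chars[i:(i + tok$n - 1L)], collapse = ""), "")
    }
  )
  if (length(tok$stopwords)) out <- out[!out %in% tok$stopwords]
  out
}

# greedy longest-match dictionary segmentation; works on characters so that
# multibyte text segments correctly
max_match <- function(term, lexicon, backward = FALSE) {
  chars <- strsplit(term, "")[[1]]
  L <- length(chars)
  maxw <- max(nchar(lexicon), 1L)
  out <- character()
  if (!backward) {
    i <- 1L
    while (i <= L) {
      found <- FALSE
      for (w in seq(min(maxw, L - i + 1L), 2L)) {
        if (w < 2L) break
        cand <- paste(chars[i:(i + w - 1L)], collapse = "")
        if (cand %in% lexicon) {
          out <- c(out, cand)
          i <- i + w
          found <- TRUE
          break
        }
      }
      if (!found) {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
  } else {
    j <- L
    while (j >= 1L) {
      found <- FALSE
      for (w in seq(min(maxw, j), 2L)) {
        if (w < 2L) break
        cand <- paste(chars[(j - w + 1L):j], collapse = "")
        if (cand %in% lexicon) {
          out <- c(cand, out)
          j <- j - w
          found <- TRUE
          break
        }
      }
      if (!found) {
        out <- c(chars[j], out)
        j <- j - 1L
      }
    }
  }
  out
}
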