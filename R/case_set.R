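#' Build a clinical case set
#'
#' A case set couples a tibble of clinical cases (one row per patient
#' encounter, symptom terms and prescribed herbs as list-columns) with the
#' herb and symptom vocabularies taken over all cases. Vocabularies are
#' sorted by Unicode code point so label indices are reproducible.
#'
#' @param cases A data frame with columns `case_id` (character), `symptoms`
#'   (list of character vectors, order kept) and `herbs` (list of character
#'   vectors; duplicates collapse with a warning).
#' @return A `case_set`: list with `cases` (tibble), `herb_vocabulary`,
#'   `symptom_vocabulary`.
#' @examples
#' cs <- case_set(tibble::tibble(
#'   case_id = c("a", "b"),
#'   symptoms = list(c("cough", "fever"), "cough"),
#'   herbs = list(c("licorice", "ephedra"), "licorice")
#' ))
#' cs$herb_vocabulary
#' @export
case_set <- function(cases) {
  cases <- as_tibble(cases)[, c("case_id", "symptoms", "herbs")]
  cases$case_id <- as.character(cases$case_id)
  if (anyDuplicated(cases$case_id)) abort("duplicate case_id")
  n_sym <- lengths(cases$symptoms)
  n_hrb <- lengths(cases$herbs)
  if (any(n_sym == 0L)) {
    abort(sprintf("case '%s' has an empty symptom list",
                  cases$case_id[which(n_sym == 0L)[1]]))
  }
  if (any(n_hrb == 0L)) {
    abort(sprintf("case '%s' has an empty herb list",
                  cases$case_id[which(n_hrb == 0L)[1]]))
  }
  deduped <- purrr::map(cases$herbs, unique)
  if (any(lengths(deduped) != n_hrb)) {
    warn(sprintf("duplicate herbs collapsed in %d case(s)",
                 sum(lengths(deduped) != n_hrb)))
  }
  cases$herbs <- deduped
  new_case_set(cases)
}

new_case_set <- function(cases, herb_vocabulary = NULL) {
  vocab_sort <- function(x) {
    withr_locale_sort(unique(x))
  }
  structure(list(
    cases = cases,
    herb_vocabulary = herb_vocabulary %||%
      vocab_sort(unlist(cases$herbs, use.names = FALSE)),
    symptom_vocabulary = vocab_sort(unlist(cases$symptoms, use.names = FALSE))
  ), class = "case_set")
}

# code-point sort, independent of the session locale
withr_locale_sort <- function(x) {
  if (!length(x)) return(character())
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x, method = "radix")
}

#' @export
print.case_set <- function(x, ...) {
  cat(sprintf(
    "<case_set> %d cases, %d herbs, %d symptom terms\n",
    nrow(x$cases), length(x$herb_vocabulary), length(x$symptom_vocabulary)))
  cat(sprintf("mean symptoms/case %.2f, mean herbs/case %.2f\n",
              mean(lengths(x$cases$symptoms)), mean(lengths(x$cases$herbs))))
  invisible(x)
}

#' Read clinical cases from a JSON-lines file
#'
#' One JSON object per line with fields `case_id`, `symptoms` (array of
#' strings) and `herbs` (array of strings).
#'
#' @param path Path to a JSONL file (UTF-8).
#' @return A [case_set()].
#' @export
load_cases <- function(path) {
  rlang::check_installed("jsonlite")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::imap(lines, function(l, i) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    missing <- setdiff(c("case_id", "symptoms", "herbs"), names(x))
    if (length(missing)) {
      abort(sprintf("line %d of %s: missing field(s) %s",
                    i, path, paste(missing, collapse = ", ")))
    }
    list(case_id = as.character(x$case_id),
         symptoms = as.character(x$symptoms),
         herbs = as.character(x$herbs))
  })
  case_set(tibble(
    case_id = purrr::map_chr(recs, "case_id"),
    symptoms = purrr::map(recs, "symptoms"),
    herbs = purrr::map(recs, "herbs")
  ))
}

#' Write a case set to a JSON-lines file
#'
#' @param cs A [case_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_cases <- function(cs, path) {
  rlang::check_installed("jsonlite")
  lines <- purrr::pmap_chr(cs$cases, function(case_id, symptoms, herbs) {
    as.character(jsonlite::toJSON(
      list(case_id = jsonlite::unbox(case_id),
           symptoms = symptoms, herbs = herbs)))
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Screen cases by symptom and herb counts
#'
#' Retains exactly the cases with strictly fewer than `max_symptoms` symptom
#' terms and strictly fewer than `max_herbs` herbs; the defaults are the
#' long-tail screening bounds used when curating clinical records (cases at
#' the boundary are removed). Vocabularies are recomputed on the survivors.
#'
#' @param cs A [case_set()].
#' @param max_symptoms,max_herbs Positive integer bounds (exclusive).
#' @return A screened [case_set()].
#' @export
screen_cases <- function(cs, max_symptoms = 40, max_herbs = 20) {
  stopifnot(inherits(cs, "case_set"), max_symptoms > 0, max_herbs > 0)
  keep <- lengths(cs$cases$symptoms) < max_symptoms &
    lengths(cs$cases$herbs) < max_herbs
  if (!any(keep)) warn("screening removed every case")
  new_case_set(cs$cases[keep, ])
}

#' Split a case set into training and test halves
#'
#' Deterministic seeded partition into `round(N * (1 - test_fraction))`
#' training cases and the remainder. Both halves keep the **full** herb
#' vocabulary of the input so the label space is fixed before splitting
#' (the recommender's output layer is sized by the total herb count).
#'
#' @param cs A [case_set()] with at least 2 cases.
#' @param test_fraction Fraction in (0, 1) assigned to the test half.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list with elements `train` and `test`, each a [case_set()].
#' @export
split_cases <- function(cs, test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(cs, "case_set"),
            test_fraction > 0, test_fraction < 1)
  n <- nrow(cs$cases)
  if (n < 2L) abort("need at least 2 cases to split")
  n_train <- as.integer(round(n * (1 - test_fraction)))
  perm <- withr::with_seed(seed, sample.int(n))
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[-seq_len(n_train)])
  list(
    train = new_case_set(cs$cases[train_idx, ], herb_vocabulary = cs$herb_vocabulary),
    test = new_case_set(cs$cases[test_idx, ], herb_vocabulary = cs$herb_vocabulary)
  )
}
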