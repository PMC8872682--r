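test_that("load_kg reads TSV edge lists, dedups and types entities", {
  dir <- withr::local_tempdir()
  writeLines(c("h1\ts1\tHB-SY", "h1\ts1\tHB-SY", "h2\ts1\tHB-SY",
               "h1\ts2\tHB-SY"), file.path(dir, "hb_sy.tsv"))
  writeLines(c("# comment", "h1\te1\tHB-EF", "h2\te1\tHB-EF"),
             file.path(dir, "hb_ef.tsv"))
  writeLines("s1\ts2\tSY-SY", file.path(dir, "sy_sy.tsv"))
  kg <- suppressMessages(load_kg(list.files(dir, full.names = TRUE)))
  s <- kg_summary(kg)
  expect_equal(sum(s$entities$count), 5)  # h1 h2 s1 s2 e1
  expect_equal(s$relations$count[s$relations$rtype == "HB-SY"], 3L)
  expect_equal(s$relations$count[s$relations$rtype == "HB-EF"], 2L)
  expect_equal(s$relations$count[s$relations$rtype == "SY-SY"], 1L)
})

test_that("load_kg rejects malformed rows and inconsistent typing", {
  dir <- withr::local_tempdir()
  writeLines("h1\ts1", file.path(dir, "bad.tsv"))
  expect_error(suppressMessages(load_kg(file.path(dir, "bad.tsv"))),
               "malformed row")
  writeLines(c("h1\ts1\tHB-SY", "s1\te1\tHB-EF"), file.path(dir, "mix.tsv"))
  expect_error(suppressMessages(load_kg(file.path(dir, "mix.tsv"))),
               "typed inconsistently")
  writeLines("h1\ts1\tNOT-A-TYPE", file.path(dir, "rt.tsv"))
  expect_error(suppressMessages(load_kg(file.path(dir, "rt.tsv"))),
               "unknown relation type")
})

test_that("empty knowledge graph summarizes to zero counts", {
  s <- kg_summary(knowledge_graph())
  expect_true(all(s$entities$count == 0))
  expect_true(all(s$relations$count == 0))
  expect_equal(s$entities$etype, c("SY", "HB", "EF", "PP", "MD"))
})

test_that("knowledge_graph forbids self-loops and dedups unordered pairs", {
  expect_error(knowledge_graph(tibble::tibble(u = "s1", v = "s1",
                                              rtype = "SY-SY")), "self-loop")
  kg <- knowledge_graph(tibble::tibble(u = c("s1", "s2"), v = c("s2", "s1"),
                                       rtype = "SY-SY"))
  expect_equal(nrow(kg$relations), 1L)
})

test_that("save_kg / load_kg round-trips", {
  kg <- random_kg(5)
  dir <- withr::local_tempdir()
  save_kg(kg, dir)
  kg2 <- suppressMessages(load_kg(list.files(dir, full.names = TRUE)))
  expect_equal(kg2$entities, kg$entities)
  expect_equal(kg2$relations, kg$relations)
})

test_that("case_set derives sorted vocabularies and collapses duplicate herbs", {
  cs <- case_set(tibble::tibble(
    case_id = c("a", "b"),
    symptoms = list("s1", c("s2", "s1")),
    herbs = list(c("hb", "ha"), c("hb", "hc"))
  ))
  expect_equal(cs$herb_vocabulary, c("ha", "hb", "hc"))
  expect_equal(cs$symptom_vocabulary, c("s1", "s2"))
  expect_warning(
    case_set(tibble::tibble(case_id = "a", symptoms = list("s"),
                            herbs = list(c("x", "x", "y")))),
    "duplicate herbs")
  expect_error(
    case_set(tibble::tibble(case_id = "a", symptoms = list(character()),
                            herbs = list("x"))),
    "empty symptom")
})

test_that("save_cases / load_cases is the identity on content", {
  cs <- toy_cases(8)
  path <- withr::local_tempfile(fileext = ".jsonl")
  save_cases(cs, path)
  cs2 <- load_cases(path)
  expect_equal(cs2$cases$case_id, cs$cases$case_id)
  expect_equal(cs2$cases$symptoms, cs$cases$symptoms)
  expect_equal(cs2$cases$herbs, cs$cases$herbs)
  expect_equal(cs2$herb_vocabulary, cs$herb_vocabulary)
})

test_that("load_cases reports missing fields with the line number", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"case_id":"a","symptoms":["s"],"herbs":["h"]}',
               '{"case_id":"b","herbs":["h"]}'), path)
  expect_error(load_cases(path), "line 2")
})

test_that("screening is strict at both bounds and recomputes vocabularies", {
  mk <- function(ns, nh, id) {
    list(case_id = id, symptoms = paste0("s", seq_len(ns), "_", id),
         herbs = paste0("h", seq_len(nh), "_", id))
  }
  rows <- list(mk(40, 5, "a"), mk(39, 19, "b"), mk(10, 10, "c"),
               mk(50, 10, "d"), mk(10, 25, "e"))
  cs <- case_set(tibble::tibble(
    case_id = purrr::map_chr(rows, "case_id"),
    symptoms = purrr::map(rows, "symptoms"),
    herbs = purrr::map(rows, "herbs")
  ))
  out <- screen_cases(cs)
  expect_setequal(out$cases$case_id, c("b", "c"))
  expect_false(any(grepl("_a$", out$symptom_vocabulary)))
})

test_that("screening is idempotent and monotone in its thresholds", {
  cs <- toy_cases(10)
  s1 <- screen_cases(cs, 4, 4)
  expect_equal(screen_cases(s1, 4, 4)$cases, s1$cases)
  for (th in list(c(3, 3), c(4, 3), c(3, 4), c(5, 5))) {
    wider <- screen_cases(cs, th[1] + 1, th[2] + 1)
    narrower <- screen_cases(cs, th[1], th[2])
    expect_gte(nrow(wider$cases), nrow(narrower$cases))
  }
})

test_that("split_cases partitions deterministically with a fixed label space", {
  cs <- toy_cases(10)
  sp <- split_cases(cs, 0.2, seed = 7)
  expect_equal(nrow(sp$train$cases), 8L)
  expect_equal(nrow(sp$test$cases), 2L)
  expect_length(intersect(sp$train$cases$case_id, sp$test$cases$case_id), 0)
  expect_setequal(c(sp$train$cases$case_id, sp$test$cases$case_id),
                  cs$cases$case_id)
  sp2 <- split_cases(cs, 0.2, seed = 7)
  expect_identical(sp$train$cases$case_id, sp2$train$cases$case_id)
  # label space frozen before the split
  expect_equal(sp$train$herb_vocabulary, cs$herb_vocabulary)
  expect_equal(sp$test$herb_vocabulary, cs$herb_vocabulary)
})

test_that("an 8:2 split of 8218 cases gives 6574 training and 1644 test cases", {
  cs <- case_set(tibble::tibble(
    case_id = sprintf("c%05d", 1:8218),
    symptoms = rep(list("s"), 8218),
    herbs = rep(list("h"), 8218)
  ))
  sp <- split_cases(cs, 0.2, seed = 1)
  expect_equal(nrow(sp$train$cases), 6574L)
  expect_equal(nrow(sp$test$cases), 1644L)
})
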