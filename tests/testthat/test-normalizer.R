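test_that("canonicalize_text trims, folds case, and repairs O-for-zero typos", {
  expect_identical(canonicalize_text("  20/40 "), "20/40")
  expect_identical(canonicalize_text("2O/2O"), "20/20")
  expect_identical(canonicalize_text("2O/1OO"), "20/100")
  expect_identical(canonicalize_text("O/40"), "0/40")
  expect_identical(canonicalize_text("CF @ 3FT"), "cf @ 3ft")
  expect_identical(canonicalize_text("20/20   in  lighted\troom"),
                   "20/20 in lighted room")
  # prose letters o are never touched
  expect_identical(canonicalize_text("blinking with ointment"),
                   "blinking with ointment")
  expect_identical(canonicalize_text(c(NA, "", "   ")), c("", "", ""))
})

test_that("vocabulary loading validates targets and duplicate keys", {
  vocab <- default_vocabulary()
  expect_s3_class(vocab, "acuity_vocabulary")
  expect_false(anyDuplicated(vocab$raw_text) > 0)

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("raw_text,target", "20/40,20/40", " 20/40 ,20/40"), path)
  expect_error(read_acuity_vocabulary(path), "line\\(s\\) 3")
  writeLines(c("raw_text,target", "20/40,20/41"), path)
  expect_error(read_acuity_vocabulary(path), "invalid vocabulary target")
  writeLines(c("raw_text,target", "j1,NEAR", "not tested,UNMAPPED",
               "cf,CF"), path)
  expect_identical(nrow(read_acuity_vocabulary(path)), 3L)
})

test_that("vocab_lookup is exact and signals misses distinctly from UNMAPPED", {
  hit <- vocab_lookup(c("20/40", "J1", "no light perception", "not tested",
                        "totally novel text"))
  expect_identical(hit$status,
                   c("VOCAB_HIT", "NEAR", "VOCAB_HIT", "UNMAPPED", NA))
  expect_identical(hit$label, c("20/40", NA, "NLP", NA, NA))
})

test_that("fallback_scan finds literal tokens and snaps them to the scale", {
  fb <- fallback_scan(c("20/20 slow",
                        "20/60 w/head tilted down",
                        "after waiting 1 min 20/20 in lighted room",
                        "20/60 blinking with ointment",
                        "no view", ""))
  expect_identical(fb$label, c("20/20", "20/60", "20/20", "20/60", NA, NA))
  expect_identical(fb$status[5:6], c("UNMAPPED", "EMPTY"))
  expect_identical(fb$matched_token[1:4],
                   c("20/20", "20/60", "20/20", "20/60"))

  # line modifiers strip to the base line; unicode minus handled
  expect_identical(fallback_scan(c("20/25+2", "20/30-1", "20/30−1"))$label,
                   c("20/25", "20/30", "20/30"))
  # off-scale denominators snap
  expect_identical(fallback_scan("sees 20/15 today")$label, "20/20")
  # qualitative keywords, long and short forms
  expect_identical(
    fallback_scan(c("cf @ 3ft", "counting fingers at 2 feet", "hand motions",
                    "lp only", "no light perception ou"))$label,
    c("CF", "CF", "HM", "LP", "NLP"))
  # "no light perception" must not be read as light perception, and the
  # lp inside nlp must not fire
  expect_identical(fallback_scan("nlp")$label, "NLP")
})

test_that("multiple tokens in one field resolve to the best-ranked token", {
  set.seed(11)
  for (i in 1:100) {
    toks <- sample(all_labels(), sample(2:4, 1), replace = TRUE)
    txt <- paste(toks, collapse = " then ")
    fb <- fallback_scan(txt)
    expect_identical(fb$label, oracle_best(toks))
  }
})

test_that("any token embedded in random annotation text is recovered", {
  long_forms <- c(CF = "counting fingers", HM = "hand motion",
                  LP = "light perception", NLP = "no light perception")
  set.seed(23)
  for (i in 1:200) {
    label <- sample(all_labels(), 1)
    rendered <- label
    if (label %in% names(long_forms) && runif(1) < 0.5) {
      rendered <- long_forms[[label]]
    }
    words <- sample(safe_words(), sample(0:6, 1), replace = TRUE)
    slot <- sample(0:length(words), 1)
    txt <- paste(append(words, rendered, after = slot), collapse = " ")
    fb <- fallback_scan(txt)
    expect_identical(fb$status, "FALLBACK_HIT")
    expect_identical(fb$label, label)
  }
  # and token-free annotation text is never a hit
  for (i in 1:50) {
    txt <- paste(sample(safe_words(), sample(1:6, 1), replace = TRUE),
                 collapse = " ")
    expect_identical(fallback_scan(txt)$status, "UNMAPPED")
  }
})

test_that("the curated vocabulary always wins over the fallback scan", {
  path <- withr::local_tempfile(fileext = ".csv")
  # adversarial curation: entries whose embedded token disagrees on purpose
  writeLines(c("raw_text,target",
               "20/400 historic,UNMAPPED",
               "20/100 see refraction,20/40"), path)
  vocab <- read_acuity_vocabulary(path)
  got <- normalize_acuity(c("20/400 historic", "20/100 see refraction",
                            "20/400 new note"), vocab)
  expect_identical(got$status, c("UNMAPPED", "VOCAB_HIT", "FALLBACK_HIT"))
  expect_identical(got$label, c(NA, "20/40", "20/400"))
})

test_that("normalize_acuity is idempotent at the category level", {
  raws <- c("20/60 blinking with ointment", "2O/2O", "counting fingers",
            "20/25+2", "20/15")
  first <- normalize_acuity(raws)
  again <- normalize_acuity(first$label)
  expect_identical(again$label, first$label)
  expect_true(all(again$status == "VOCAB_HIT"))
})

test_that("unmapped_report tallies unmapped raw texts, most frequent first", {
  entries <- data.frame(
    response_text = c("poor view", "20/40", "poor view", "no read", "zzz",
                      "no read", "no read"),
    status = c("UNMAPPED", "VOCAB_HIT", "UNMAPPED", "UNMAPPED", "UNMAPPED",
               "UNMAPPED", "UNMAPPED"))
  rep <- unmapped_report(entries)
  expect_identical(rep$raw_text, c("no read", "poor view", "zzz"))
  expect_identical(rep$n, c(3L, 2L, 1L))

  expect_identical(nrow(unmapped_report(
    data.frame(response_text = "20/40", status = "VOCAB_HIT"))), 0L)

  # counting oracle on a randomized entry set
  set.seed(5)
  texts <- sample(c("a", "b", "c", "dd"), 60, replace = TRUE)
  status <- sample(c("UNMAPPED", "VOCAB_HIT"), 60, replace = TRUE)
  rep <- unmapped_report(data.frame(response_text = texts, status = status))
  brute <- table(texts[status == "UNMAPPED"])
  expect_identical(sum(rep$n), sum(brute))
  for (k in rep$raw_text) expect_identical(rep$n[rep$raw_text == k],
                                           as.integer(brute[[k]]))
})
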