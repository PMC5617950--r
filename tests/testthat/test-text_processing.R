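test_that("tokenize lowercases, keeps punctuation sentinels, drops digits and short tokens", {
  expect_equal(tokenize("No discrete mass."), c("no", "discrete", "mass", "."))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("T2 lesion x 3"), "lesion")
  expect_equal(tokenize("CT 12/03/2014: two 5 mm nodules"),
               c("ct", ":", "two", "mm", "nodules"))
})

test_that("porter stemmer reproduces classic behaviour", {
  classic <- c(caresses = "caress", ponies = "poni", ties = "ti",
               caress = "caress", cats = "cat", feed = "feed",
               agreed = "agre", plastered = "plaster", bled = "bled",
               motoring = "motor", sing = "sing", hopping = "hop",
               tanned = "tan", falling = "fall", hissing = "hiss",
               failing = "fail", filing = "file", happy = "happi",
               sky = "sky", relational = "relat", conditional = "condit",
               rational = "ration", adjustable = "adjust",
               dependent = "depend", effective = "effect", roll = "roll",
               controll = "control")
  expect_equal(porter_stem(names(classic)), unname(classic))
})

test_that("conjugation and plural variants of radiology vocabulary conflate", {
  pairs <- list(c("metastases", "metastasis"),
                c("hypoattenuating", "hypoattenuated"),
                c("recurrent", "recurrence"),
                c("diagnosis", "diagnoses"),
                c("enhancing", "enhanced"))
  for (p in pairs) {
    s <- porter_stem(p)
    expect_equal(s[1], s[2], info = paste(p, collapse = "/"))
  }
})

test_that("stems are deterministic, lowercase and whitespace-free", {
  set.seed(7)
  words <- replicate(200, paste0(sample(letters, sample(3:10, 1),
                                        replace = TRUE), collapse = ""))
  s1 <- porter_stem(words)
  s2 <- porter_stem(words)
  expect_identical(s1, s2)
  expect_true(all(nzchar(s1)))
  expect_false(any(grepl("[[:space:][:upper:]]", s1)))
})

test_that("negation scope covers the window after a cue", {
  terms <- tag_negation(tokenize("no discrete nodule"))
  expect_equal(terms$stem, c("discret", "nodul"))
  expect_true(all(terms$negated))
  expect_equal(terms$display, c("[no] discrete", "[no] nodule"))

  plain <- tag_negation(tokenize("few scattered lesions"))
  expect_false(any(plain$negated))
})

test_that("negation scope ends at terminators and is restarted by a new cue", {
  # "." cuts the 3-token window before "numerous"
  terms <- tag_negation(tokenize("no evidence. numerous lesions"))
  expect_equal(terms$negated[terms$stem == "numer"], FALSE)
  expect_equal(terms$negated[terms$stem == "evid"], TRUE)

  # "but" terminates mid-sentence
  terms <- tag_negation(tokenize("no discrete mass but discrete calcification"))
  expect_equal(terms$display,
               c("[no] discrete", "[no] mass", "discrete", "calcification"))

  # window exhausts after `window` word tokens
  terms <- tag_negation(tokenize("no small hepatic lesions seen today"))
  expect_equal(terms$negated,
               c(TRUE, TRUE, TRUE, FALSE, FALSE))

  # multi-word cue; ";" ends the scope
  terms <- tag_negation(tokenize("liver free of metastases; lungs clear"))
  expect_true(terms$negated[terms$stem == "metastas"])
  expect_false(terms$negated[terms$stem == "lung"])

  # a fresh cue restarts the scope
  terms <- tag_negation(tokenize("no mass no nodule enlargement seen here"),
                        negation_config(window = 2L))
  expect_equal(terms$negated, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("cues and terminators never emit terms", {
  cfg <- negation_config()
  terms <- tag_negation(tokenize("no mass but not without however absent change"), cfg)
  expect_false(any(terms$stem %in% c("no", "not", "without", "absent",
                                     "but", "however", ".", ";")))
})

test_that("process_report returns the distinct term set with negated/plain kept apart", {
  s <- process_report("Numerous lesions. Numerous nodules.")
  expect_equal(sum(s$stem == "numer"), 1L)

  s <- process_report("No discrete mass but discrete calcification")
  expect_setequal(s$display[s$stem == "discret"],
                  c("[no] discrete", "discrete"))
})

test_that("process_report equals the hand composition of its stages", {
  text <- "No discrete mass is seen. Innumerable hepatic metastases. Few scattered nodules, but no recurrent disease."
  cfg <- negation_config()
  manual <- tag_negation(tokenize(text), cfg)
  manual <- manual[!duplicated(manual$key), ]
  expect_equal(process_report(text, cfg), manual)
  # and is deterministic
  expect_identical(process_report(text, cfg), process_report(text, cfg))
})

test_that("term sets are invariant to sentence permutation", {
  sentences <- c("No discrete mass seen.", "Innumerable metastases present.",
                 "Few scattered calcifications.")
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  sets <- lapply(perms, function(p)
    sort(process_report(paste(sentences[p], collapse = " "))$key))
  expect_equal(sets[[1]], sets[[2]])
  expect_equal(sets[[1]], sets[[3]])
})

test_that("process_corpus matches per-report processing and counts vocabulary", {
  corp <- make_corpus(
    c("Innumerable metastases. No discrete mass.",
      "Few lesions; no abnormal enhancement."),
    c("MUTANT", "WILDTYPE"))
  pc <- process_corpus(corp)
  expect_equal(pc$term_sets[[1]], process_report(corp$reports$text[1]),
               ignore_attr = TRUE)
  expect_equal(pc$term_sets[[2]], process_report(corp$reports$text[2]),
               ignore_attr = TRUE)
  expect_equal(pc$stats$n_reports, c(1L, 1L))
  expect_equal(pc$stats$distinct_terms,
               c(nrow(pc$term_sets[[1]]), nrow(pc$term_sets[[2]])))
  # token instances count emitted word tokens (cues emit none)
  expect_equal(pc$stats$token_instances[1], 4L)
})
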