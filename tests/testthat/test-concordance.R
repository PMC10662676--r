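test_that("concordance lines carry node and truncated contexts", {
  tk <- analyze_corpus(mini_corpus("alpha beta node gamma delta"))
  lines <- extract_concordances(tk, "node", context = 20)
  expect_equal(nrow(lines), 1)
  expect_equal(lines$left, "alpha beta")
  expect_equal(lines$right, "gamma delta")
  expect_equal(lines$node_start, 2L)
  expect_equal(lines$node_end, 3L)
  # node at post start: empty left context
  tk2 <- analyze_corpus(mini_corpus("node after words"))
  l2 <- extract_concordances(tk2, "node")
  expect_equal(l2$left, "")
  # absent lemma: empty result with warning
  expect_warning(l3 <- extract_concordances(tk, "missing"), "not occur")
  expect_equal(nrow(l3), 0)
})

test_that("context windows respect width and post boundaries", {
  body <- paste(c(sprintf("l%02d", 1:25), "node", sprintf("r%02d", 1:25)),
                collapse = " ")
  tk <- analyze_corpus(mini_corpus(c(body, "node alone here")))
  lines <- extract_concordances(tk, "node", context = 20)
  expect_equal(nrow(lines), 2)
  expect_length(strsplit(lines$left[1], " ")[[1]], 20)
  expect_length(strsplit(lines$right[1], " ")[[1]], 20)
  # second post's line must not leak context from the first post
  expect_equal(lines$left[2], "")
  expect_equal(lines$right[2], "alone here")
})

test_that("line count per lemma equals the frequency-table count", {
  g <- synth_generate(small_synth_config(seed = 6))
  tk <- analyze_corpus(g$corpus)
  ft <- build_frequency_table(g$corpus, tk)
  for (l in c("hope", "therapy", "w00001")) {
    want <- ft$table$freq[ft$table$lemma == l]
    if (length(want) == 0) want <- 0
    lines <- extract_concordances(tk, l)
    expect_equal(nrow(lines), as.numeric(want))
  }
})

test_that("sorting reads the left context outward from the node", {
  tk <- analyze_corpus(mini_corpus(c(
    "zebra apple node x", "apple berry node x", "apple apple node x"
  )))
  lines <- sort_concordances(extract_concordances(tk, "node"))
  # nearest-left words: apple, berry, apple -> ties broken by next-left word
  nearest <- vapply(strsplit(lines$left, " "),
                    function(w) w[length(w)], character(1))
  expect_equal(nearest, c("apple", "apple", "berry"))
  second <- vapply(strsplit(lines$left, " "), function(w) w[1], character(1))
  expect_equal(second[1:2], c("apple", "zebra"))
})

test_that("sorting is stable and permutation-invariant", {
  g <- synth_generate(small_synth_config(seed = 10))
  tk <- analyze_corpus(g$corpus)
  lines <- extract_concordances(tk, "hope")
  sorted <- sort_concordances(lines)
  shuffled <- lines[withr::with_seed(1, sample(nrow(lines))), ]
  resorted <- sort_concordances(shuffled)
  expect_equal(resorted$line_id, sorted$line_id)
  # identical lines keep input order
  dup <- lines[c(1, 1, 1), ]
  dup$line_id <- c("a", "b", "c")
  expect_equal(sort_concordances(dup)$line_id, c("a", "b", "c"))
})

test_that("coding samples are uniform, exhaustive when small, reproducible", {
  g <- synth_generate(small_synth_config(seed = 12))
  tk <- analyze_corpus(g$corpus)
  lines <- extract_concordances(tk, "w00001")  # a frequent background lemma
  expect_gt(nrow(lines), 30)
  s <- sample_for_coding(lines, n = 30, seed = 5)
  expect_equal(nrow(s), 30)
  expect_equal(anyDuplicated(s$line_id), 0)
  expect_identical(s, sample_for_coding(lines, n = 30, seed = 5))
  few <- lines[1:12, ]
  expect_warning(s2 <- sample_for_coding(few, n = 30, seed = 5), "12")
  expect_equal(nrow(s2), 12)
})

poetic_frame <- function() {
  coding_frame(list(
    "Purpose and meaning" = c("Paid or voluntary work", "Quality of life"),
    "Connectedness" = c("Relationships", "Support from others"),
    "Empowerment" = c("Self-management and personal responsibility")
  ))
}

mk_ft <- function(lemmas, freqs) {
  structure(list(
    table = tibble::tibble(lemma = lemmas, freq = freqs,
                           doc_freq = freqs, user_freq = freqs),
    total_tokens = sum(freqs), total_posts = 10, total_users = 10,
    name = "toy", analyzer = "rules-en 1.0"), class = "cfa_freq_table")
}

test_that("category frequencies scale proportionally from coded samples", {
  frame <- poetic_frame()
  coded <- tibble::tibble(
    lemma = "partner",
    line_id = sprintf("l%02d", 1:30),
    label = c(rep("Relationships", 15), rep("Quality of life", 15))
  )
  got <- extrapolate_category_frequencies(coded, mk_ft("partner", 300), frame)
  cats <- got$categories
  expect_equal(cats$mass[cats$category == "Relationships"], 150)
  expect_equal(cats$mass[cats$category == "Quality of life"], 150)
  expect_equal(sum(got$domains$mass), 300)
  # all lines outside the frame -> all mass outside the frame
  coded2 <- coded
  coded2$label <- "Not-frame"
  got2 <- extrapolate_category_frequencies(coded2, mk_ft("partner", 300),
                                           frame)
  expect_equal(got2$domains$mass[got2$domains$domain == "Not-frame"], 300)
  expect_equal(sum(got2$categories$mass), 300)
})

test_that("single-label extrapolation conserves total key-lemma frequency", {
  frame <- poetic_frame()
  labels <- frame_labels <- c(frame$categories$category, "Not-frame")
  withr::with_seed(31, {
    for (rep in 1:20) {
      lemmas <- sprintf("lemma%d", 1:5)
      freqs <- sample(40:500, 5)
      n_coded <- sample(10:30, 5)
      coded <- do.call(rbind, lapply(1:5, function(i) {
        tibble::tibble(
          lemma = lemmas[i],
          line_id = sprintf("%s:%d", lemmas[i], seq_len(n_coded[i])),
          label = sample(labels, n_coded[i], replace = TRUE)
        )
      }))
      got <- extrapolate_category_frequencies(coded, mk_ft(lemmas, freqs),
                                              frame)
      expect_equal(sum(got$categories$mass), sum(freqs), tolerance = 1e-9)
      expect_equal(sum(got$domains$mass), sum(freqs), tolerance = 1e-9)
    }
  })
})

test_that("a fixed share of frame-external lines yields that share of mass", {
  # 16% of coded lines outside the frame, uniform lemma frequencies
  frame <- poetic_frame()
  coded <- do.call(rbind, lapply(1:4, function(i) {
    tibble::tibble(
      lemma = sprintf("lm%d", i),
      line_id = sprintf("lm%d:%d", i, 1:25),
      label = c(rep("Not-frame", 4), rep("Relationships", 21))
    )
  }))
  got <- extrapolate_category_frequencies(
    coded, mk_ft(sprintf("lm%d", 1:4), rep(100, 4)), frame)
  outside <- got$domains$mass[got$domains$domain == "Not-frame"]
  expect_equal(outside / sum(got$domains$mass), 0.16, tolerance = 1e-12)
})

test_that("multi-label lines give each label full proportional mass", {
  frame <- poetic_frame()
  coded <- tibble::tibble(
    lemma = "dual", line_id = c("l1", "l1", "l2"),
    label = c("Relationships", "Quality of life", "Relationships")
  )
  got <- extrapolate_category_frequencies(coded, mk_ft("dual", 100), frame)
  cats <- got$categories
  expect_equal(cats$mass[cats$category == "Relationships"], 100)
  expect_equal(cats$mass[cats$category == "Quality of life"], 50)
  expect_equal(sum(cats$mass), 150) # exceeds F under multi-labelling
})

test_that("extrapolation validates labels and lemma coverage", {
  frame <- poetic_frame()
  coded <- tibble::tibble(lemma = "x", line_id = "l1", label = "Nonsense")
  expect_error(extrapolate_category_frequencies(coded, mk_ft("x", 10), frame),
               "not in the coding frame")
  coded2 <- tibble::tibble(lemma = "y", line_id = "l1",
                           label = "Relationships")
  expect_error(
    extrapolate_category_frequencies(coded2, mk_ft("x", 10), frame),
    "absent")
})
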