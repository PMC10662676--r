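toy_terms <- function() term_list(c("hope", "work", "take care"))

test_that("relevance scores match a hand-computed tf-idf cosine oracle", {
  x <- mini_corpus(c(
    "hope work hope",
    "take care work",
    "nothing else here"
  ))
  sc <- score_relevance(x, toy_terms())
  # manual arithmetic: N = 3; df(hope)=1, df(work)=2, df(take care)=1
  idf_hope <- log(4 / 2) + 1
  idf_work <- log(4 / 3) + 1
  idf_tc <- log(4 / 2) + 1
  qn <- sqrt(idf_hope^2 + idf_work^2 + idf_tc^2)
  v1 <- c(2 * idf_hope, 1 * idf_work, 0)
  s1 <- sum(v1 * c(idf_hope, idf_work, idf_tc)) / (sqrt(sum(v1^2)) * qn)
  v2 <- c(0, 1 * idf_work, 1 * idf_tc)
  s2 <- sum(v2 * c(idf_hope, idf_work, idf_tc)) / (sqrt(sum(v2^2)) * qn)
  expect_equal(sc$score, c(s1, s2, 0), tolerance = 1e-12)
})

test_that("a post equal to the full term list scores exactly 1", {
  x <- mini_corpus("hope work take care")
  sc <- score_relevance(x, toy_terms())
  expect_equal(sc$score, 1, tolerance = 1e-12)
})

test_that("scores are bounded and invariant to tf scaling", {
  g <- synth_generate(small_synth_config(seed = 8))
  tl <- term_list(g$truth$config$planted_terms)
  sc <- score_relevance(g$corpus, tl)
  expect_true(all(sc$score >= 0 & sc$score <= 1 + 1e-12))
  shares <- sc$score == 0
  # zero iff no term is shared with the list
  m <- count_terms(analyze_corpus(g$corpus), tl)
  expect_setequal(sc$post_id[!shares], unique(m$post_id))
  # doubling a post's text leaves its score unchanged
  b <- "hope work and hope again"
  x1 <- mini_corpus(c(b, "work alone", "take care now"))
  x2 <- x1; x2$body[1] <- paste(b, b)
  s1 <- score_relevance(x1, toy_terms())$score[1]
  s2 <- score_relevance(corpus(x2, "mini"), toy_terms())$score[1]
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("terms absent from every post are dropped without effect", {
  x <- mini_corpus(c("hope alone", "nothing"))
  tl <- term_list(c("hope", "unseen"))
  expect_message(sc <- score_relevance(x, tl), "no post")
  expect_equal(sc$score[2], 0)
  expect_equal(sc$score[1], 1, tolerance = 1e-12) # only feature left
})

test_that("decile sampling merges constant zero bins", {
  scores <- tibble::tibble(
    post_id = sprintf("p%04d", 1:1000),
    score = c(rep(0, 200), seq(0.001, 0.8, length.out = 800))
  )
  ids <- decile_sample(scores, per_decile = 10, seed = 3)
  expect_length(ids, 90)
  expect_equal(anyDuplicated(ids), 0)
  # all-distinct scores: 100 ids, 10 per decile
  scores2 <- tibble::tibble(post_id = sprintf("p%04d", 1:1000),
                            score = seq_len(1000) / 1000)
  ids2 <- decile_sample(scores2, per_decile = 10, seed = 3)
  expect_length(ids2, 100)
  ranks <- match(ids2, scores2$post_id)
  expect_equal(as.integer(table(ceiling(ranks / 100))), rep(10L, 10))
  # determinism
  expect_identical(ids, decile_sample(scores, per_decile = 10, seed = 3))
  expect_false(identical(ids2, decile_sample(scores2, 10, seed = 4)))
  # undersized bins are taken whole with a warning
  scores3 <- tibble::tibble(post_id = sprintf("p%02d", 1:20),
                            score = seq_len(20))
  w <- testthat::capture_warnings(
    ids3 <- decile_sample(scores3, per_decile = 10, seed = 1))
  expect_true(all(grepl("taking all", w)))
  expect_length(ids3, 20)
})

test_that("corpus split applies strict cutoffs and the length gate", {
  long <- function(w) paste(rep(w, 100), collapse = " ")
  x <- mini_corpus(c(long("hope"), long("tree"), long("rock"),
                     paste(rep("hope", 50), collapse = " ")))
  sc <- tibble::tibble(post_id = x$post_id,
                       score = c(0.05, 0.02, 0.001, 0.05))
  halves <- split_corpus(x, sc, split_config())
  expect_equal(halves$target$post_id, "p001")
  expect_equal(halves$reference$post_id, "p003")
  # the 50-word post scored 0.05 is excluded by the length gate
  expect_false("p004" %in% c(halves$target$post_id,
                             halves$reference$post_id))
  # a 94-word post passes the gate inclusively
  x2 <- mini_corpus(c(paste(rep("hope", 94), collapse = " "), long("tree")))
  sc2 <- tibble::tibble(post_id = x2$post_id, score = c(0.05, 0.001))
  halves2 <- split_corpus(x2, sc2, split_config())
  expect_equal(halves2$target$post_id, "p001")
  # empty side is a hard error
  sc3 <- tibble::tibble(post_id = x2$post_id, score = c(0.05, 0.05))
  expect_error(split_corpus(x2, sc3, split_config()), "reference.*empty")
})

test_that("raising the upper cutoff never grows the target corpus", {
  g <- synth_generate(small_synth_config(seed = 17))
  tl <- term_list(g$truth$config$planted_terms)
  sc <- score_relevance(g$corpus, tl)
  cuts <- c(0.02, 0.05, 0.1, 0.2)
  sizes <- vapply(cuts, function(u) {
    sum(sc$score > u &
          word_count(post_text(g$corpus)) >= 30)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("split configuration validates its bounds", {
  expect_error(split_config(upper_cutoff = 0.01, lower_cutoff = 0.02))
  expect_s3_class(split_config(0.5, 0.1, 0), "cfa_split_config")
})
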