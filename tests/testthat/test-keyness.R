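test_that("frequency tables count lemmas, posts and users", {
  x <- mini_corpus(c("recover recover hope"))
  ft <- build_frequency_table(x)
  expect_equal(ft$total_tokens, 3)
  tab <- ft$table
  expect_equal(tab$freq[tab$lemma == "recover"], 2)
  expect_equal(tab$freq[tab$lemma == "hope"], 1)
  x2 <- mini_corpus(c("hope", "hope"), user_id = c("uA", "uB"))
  ft2 <- build_frequency_table(x2)
  expect_equal(ft2$table$user_freq[ft2$table$lemma == "hope"], 2)
  expect_error(build_frequency_table(mini_corpus(character(0))), "empty")
})

test_that("frequency tables equal a naive per-post recount", {
  g <- synth_generate(small_synth_config(seed = 9))
  ft <- build_frequency_table(g$corpus)
  # independent recount: analyze posts one at a time, accumulate in a list
  env <- new.env()
  for (i in seq_len(nrow(g$corpus))) {
    tk <- analyze(paste(g$corpus$title[i], g$corpus$body[i], sep = "\n"))
    for (l in tk$lemma[tk$is_word]) {
      env[[l]] <- (if (is.null(env[[l]])) 0 else env[[l]]) + 1
    }
  }
  want <- unlist(as.list(env))
  got <- stats::setNames(as.numeric(ft$table$freq), ft$table$lemma)
  expect_setequal(names(got), names(want))
  expect_equal(as.numeric(got[names(want)]), as.numeric(want))
  expect_equal(sum(ft$table$freq), ft$total_tokens)
  expect_true(all(ft$table$freq >= ft$table$doc_freq))
  expect_true(all(ft$table$doc_freq >= ft$table$user_freq))
})

test_that("log-likelihood is zero iff relative frequencies are equal", {
  expect_equal(log_likelihood(10, 20, 1000, 2000), 0)
  expect_equal(log_likelihood(10, 20, 1000, 2000, variant = "2cell"), 0)
  expect_gt(log_likelihood(30, 10, 10000, 10000), 0)
})

test_that("the two-cell variant matches its defining arithmetic", {
  # E1 = E2 = 20 for (30, 10, 10000, 10000)
  want <- 2 * (30 * log(30 / 20) + 10 * log(10 / 20))
  expect_equal(log_likelihood(30, 10, 10000, 10000, variant = "2cell"),
               want, tolerance = 1e-12)
})

test_that("the default G2 equals an independent 4-cell G oracle", {
  withr::with_seed(42, {
    cc <- sample(1000:50000, 500, replace = TRUE)
    dd <- sample(1000:50000, 500, replace = TRUE)
    a <- rbinom(500, pmin(cc, 500), 0.3)
    b <- rbinom(500, pmin(dd, 500), 0.3)
    keep <- a + b >= 1
    got <- log_likelihood(a[keep], b[keep], cc[keep], dd[keep])
    want <- g_stat_oracle(a[keep], b[keep], cc[keep], dd[keep])
    expect_equal(got, as.numeric(want), tolerance = 1e-9)
  })
})

test_that("G2 is symmetric and monotone away from proportionality", {
  expect_equal(log_likelihood(30, 10, 1e4, 2e4),
               log_likelihood(10, 30, 2e4, 1e4))
  # for fixed a+b, minimized at proportional a, increasing outward
  ab <- 60; cc <- 1e4; dd <- 2e4
  a <- 0:ab
  g <- log_likelihood(a, ab - a, cc, dd)
  prop <- ab * cc / (cc + dd)
  expect_equal(which.min(g), which.min(abs(a - prop)))
  right <- g[a >= ceiling(prop)]
  expect_true(all(diff(right) > 0))
  left <- g[a <= floor(prop)]
  expect_true(all(diff(left) < 0))
  # monotone in a when b = 0
  g0 <- log_likelihood(1:20, 0, 1e4, 1e4)
  expect_true(all(diff(g0) > 0) && all(g0 > 0))
})

test_that("log-likelihood rejects invalid contingency inputs", {
  expect_error(log_likelihood(1, 1, 0, 10), "positive")
  expect_error(log_likelihood(0, 0, 10, 10), "at least 1")
  expect_error(log_likelihood(11, 0, 10, 10), "exceed")
})

test_that("overuse ratio smooths only the zero reference cell", {
  expect_equal(overuse_ratio(30, 10, 10000, 10000), 3)
  expect_equal(overuse_ratio(10, 10, 1000, 1000), 1)
  expect_equal(overuse_ratio(5, 0, 1000, 2000), 20)
  expect_equal(overuse_ratio(0, 5, 1000, 2000), 0)
})

test_that("the significance gate derives from the chi-square quantile", {
  # independent derivation: invert the chi-square(1) CDF numerically
  want <- stats::uniroot(function(x) stats::pchisq(x, 1) - (1 - 1e-4),
                         c(1, 50), tol = 1e-12)$root
  expect_equal(g2_critical(1e-4), want, tolerance = 1e-8)
  expect_equal(round(g2_critical(1e-4), 2), 15.14)
})

test_that("key-lemma selection applies all gates conjunctively", {
  mk_ft <- function(df, tokens, posts, users, name) {
    structure(list(table = df, total_tokens = tokens, total_posts = posts,
                   total_users = users, name = name, analyzer = "rules-en 1.0"),
              class = "cfa_freq_table")
  }
  tgt <- mk_ft(tibble::tibble(
    lemma = c("strong", "weakratio", "concentrated", "rare"),
    freq = c(80, 120, 90, 2),
    doc_freq = c(40, 60, 3, 2),
    user_freq = c(30, 50, 1, 2)
  ), tokens = 10000, posts = 100, users = 100, name = "t")
  ref <- mk_ft(tibble::tibble(
    lemma = c("strong", "weakratio", "concentrated", "onlyref"),
    freq = c(20, 80, 10, 50),
    doc_freq = c(15, 60, 8, 40),
    user_freq = c(12, 50, 6, 30)
  ), tokens = 10000, posts = 100, users = 120, name = "r")
  k <- select_key_lemmas(tgt, ref)
  row <- function(l) k[k$lemma == l, ]
  expect_true(row("strong")$is_key)        # passes all gates
  expect_false(row("weakratio")$is_key)    # ratio 1.5 < 2
  expect_lt(row("weakratio")$ratio, 2)
  expect_false(row("concentrated")$is_key) # 1 user = 1% < 5% dispersion
  expect_true(row("concentrated")$ratio >= 2)
  expect_false(row("rare")$is_key)         # not significant
  expect_false(row("onlyref")$is_key)      # a = 0
  # the is_key flag is re-derivable from the row columns
  crit <- g2_critical(1e-4)
  redo <- k$ratio >= 2 & k$g2 >= crit & k$user_share >= 0.05 &
    k$a / k$c > k$b / k$d
  expect_equal(k$is_key, redo)
  # sorted by g2 descending
  expect_true(all(diff(k$g2) <= 0))
})

test_that("absent terms split into missing and underused disjointly", {
  tl <- term_list(c("ghost", "gloom", "steady", "take care"))
  tgt <- analyze_corpus(mini_corpus(paste(
    c(rep("gloom", 2), rep("steady", 3), rep("filler", 95)),
    collapse = " ")))
  ref <- analyze_corpus(mini_corpus(paste(
    c(rep("gloom", 6), rep("steady", 3), rep("filler", 91)),
    collapse = " ")))
  got <- find_absent_terms(tl, tgt, ref)
  expect_setequal(got$missing$term, c("ghost", "take care"))
  expect_equal(got$underused$term, "gloom")  # 2/100 < 6/100
  # equal relative frequencies -> neither list
  expect_false("steady" %in% c(got$missing$term, got$underused$term))
  expect_length(intersect(got$missing$term, got$underused$term), 0)
})

test_that("multiword term frequencies use match spans", {
  tl <- term_list(c("take care", "lonely"))
  tgt <- analyze_corpus(mini_corpus("take care and take care again"))
  ref <- analyze_corpus(mini_corpus("take care once lonely lonely here"))
  got <- find_absent_terms(tl, tgt, ref)
  expect_equal(got$missing$term, "lonely")
  expect_length(got$underused$term, 0)  # 2/6 > 1/6
})
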