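# Synthetic forum-corpus generator with planted ground truth.
#
# Posts are bags of lemmas rendered as space-joined pseudo-words plus a
# closed function-word set and light punctuation; every statistic in the
# pipeline is frequency-based, so no grammar model is needed. Background
# lemmas follow a Zipfian distribution; a planted fraction of "relevant"
# posts is enriched in a set of concept terms (including multiword
# phrases); self-reporting users carry one first-person diagnosis
# disclosure; planted collocates are inserted adjacent to their node.

.generator_function_words <- base::c(
  "the", "and", "to", "of", "a", "in", "that", "it", "for", "on", "with",
  "this", "but", "not", "be", "have", "do", "at", "by", "from", "so", "if",
  "about", "out", "up", "what", "when", "how", "all", "just", "my", "you",
  "we", "they", "i"
)

#' Default planted concept terms
#'
#' Twenty recovery-flavoured terms (three of them multiword phrases), all
#' fixed points of the default analyzer's lemmatizer.
#'
#' @return Character vector of 20 terms.
#' @export
default_planted_terms <- function() {
  base::c(
    "hope", "recover", "therapy", "medication", "work", "sleep", "exercise",
    "support", "family", "friend", "goal", "routine", "mindfulness",
    "gratitude", "purpose", "connect", "accept",
    "self care", "support group", "take care"
  )
}

#' Synthetic corpus configuration
#'
#' The defaults define the simulation conditions used throughout the
#' package's tests and analyses: 200 users writing 5-15 posts of 50-150
#' words over a 5000-lemma Zipfian vocabulary (exponent 1.1), 20% of posts
#' relevant, 20 planted concept terms at a background rate of 1.5e-3 per
#' content token each and 4-fold enrichment in relevant posts, half the
#' users disclosing a diagnosis, 40% of posts mentioning the condition,
#' and 70% of posts in condition-specific subforums.
#'
#' @param seed Integer RNG seed; the whole corpus is a deterministic
#'   function of the config.
#' @param n_users Number of users.
#' @param posts_per_user Integer range `c(min, max)` of posts per user.
#' @param words_per_post Integer range `c(min, max)` of body words per post.
#' @param vocab_size Background vocabulary size.
#' @param zipf_exponent Zipf exponent of the background lemma distribution.
#' @param relevant_fraction Probability that a post is relevant.
#' @param planted_terms Character vector of concept terms (may contain
#'   multiword phrases).
#' @param planted_base_rate Per-content-token probability of each planted
#'   term in non-relevant posts.
#' @param enrichment Multiplier on `planted_base_rate` in relevant posts
#'   (>= 1).
#' @param self_report_fraction Fraction of users who disclose a diagnosis.
#' @param condition_term Condition name inserted into mentioning posts.
#' @param condition_mention_rate Probability that a post mentions the
#'   condition.
#' @param planted_collocations Data frame `node`, `collocate`, `rate`:
#'   for each occurrence of `node`, the collocate is inserted adjacent
#'   with probability `rate`. Nodes must be single-word planted terms.
#' @param subforum_names,subforum_probs Subforum labels and sampling
#'   probabilities; the first two names are treated as condition subforums
#'   by the analysis drivers.
#' @param function_word_rate Per-token probability of a function word.
#' @return A validated `cfa_synth_config`.
#' @export
synth_config <- function(
    seed = 1,
    n_users = 200,
    posts_per_user = base::c(5, 15),
    words_per_post = base::c(50, 150),
    vocab_size = 5000,
    zipf_exponent = 1.1,
    relevant_fraction = 0.2,
    planted_terms = default_planted_terms(),
    planted_base_rate = 0.0015,
    enrichment = 4,
    self_report_fraction = 0.5,
    condition_term = "bipolar",
    condition_mention_rate = 0.4,
    planted_collocations = data.frame(
      node = base::c("therapy", "medication"),
      collocate = base::c("helpful", "lithium"),
      rate = base::c(0.6, 0.6)
    ),
    subforum_names = base::c("bipolar", "bipolarsupport", "mentalhealth",
                             "offtopic"),
    subforum_probs = base::c(0.4, 0.3, 0.2, 0.1),
    function_word_rate = 0.35) {
  stopifnot(
    n_users >= 1, length(posts_per_user) == 2, length(words_per_post) == 2,
    posts_per_user[1] >= 1, posts_per_user[1] <= posts_per_user[2],
    words_per_post[1] >= 1, words_per_post[1] <= words_per_post[2],
    vocab_size >= length(planted_terms), zipf_exponent > 0,
    relevant_fraction >= 0, relevant_fraction <= 1, enrichment >= 1,
    self_report_fraction >= 0, self_report_fraction <= 1,
    condition_mention_rate >= 0, condition_mention_rate <= 1,
    planted_base_rate >= 0, function_word_rate >= 0, function_word_rate < 1,
    length(subforum_names) == length(subforum_probs),
    all(subforum_probs >= 0)
  )
  max_term_len <- max(lengths(strsplit(planted_terms, "\\s+")))
  if (words_per_post[1] < max_term_len + 2) {
    stop("words_per_post minimum is too small to hold a planted multiword ",
         "term", call. = FALSE)
  }
  p_planted <- length(planted_terms) * planted_base_rate * enrichment
  if (p_planted >= 0.9) {
    stop("planted term mass in relevant posts would exceed 90% of content ",
         "tokens; lower planted_base_rate or enrichment", call. = FALSE)
  }
  if (length(planted_collocations) > 0 && nrow(planted_collocations) > 0) {
    single <- planted_terms[!grepl("\\s", planted_terms)]
    if (!all(planted_collocations$node %in% single)) {
      stop("collocation nodes must be single-word planted terms",
           call. = FALSE)
    }
  }
  structure(as.list(environment())[base::c(
    "seed", "n_users", "posts_per_user", "words_per_post", "vocab_size",
    "zipf_exponent", "relevant_fraction", "planted_terms",
    "planted_base_rate", "enrichment", "self_report_fraction",
    "condition_term", "condition_mention_rate", "planted_collocations",
    "subforum_names", "subforum_probs", "function_word_rate"
  )], class = "cfa_synth_config")
}

# Background vocabulary: pseudo-lemmas whose suffix encodes the coarse POS
# the analyzer will assign (plain -> NOUN, -ly -> ADV, -ful -> ADJ,
# -ify -> VERB), so generated POS and analyzed POS agree by construction.
synth_vocab <- function(vocab_size) {
  id <- sprintf("w%05d", seq_len(vocab_size))
  sfx <- rep("", vocab_size)
  sfx[seq_len(vocab_size) %% 10 == 3] <- "ly"
  sfx[seq_len(vocab_size) %% 10 == 6] <- "ful"
  sfx[seq_len(vocab_size) %% 10 == 9] <- "ify"
  paste0(id, sfx)
}

#' Generate a synthetic forum corpus with ground truth
#'
#' Fully deterministic under `config$seed`: the same config yields a
#' byte-identical corpus.
#'
#' @param config A [synth_config()].
#' @return List with `corpus` (a `cfa_corpus`) and `truth`: tibbles
#'   `posts` (`post_id`, `user_id`, `is_relevant`, `mentions_condition`),
#'   `users` (`user_id`, `is_self_reporter`), `lemmas` (`lemma`,
#'   `planted`), `collocations`, plus the `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "cfa_synth_config"))
  withr::with_seed(config$seed, synth_generate_impl(config))
}

synth_generate_impl <- function(cfg) {
  n_terms <- length(cfg$planted_terms)
  vocab <- synth_vocab(cfg$vocab_size)
  zipf_p <- seq_len(cfg$vocab_size)^(-cfg$zipf_exponent)
  zipf_p <- zipf_p / sum(zipf_p)
  fw <- .generator_function_words
  fw_p <- seq_along(fw)^(-1)
  fw_p <- fw_p / sum(fw_p)

  user_id <- sprintf("u%04d", seq_len(cfg$n_users))
  is_reporter <- seq_len(cfg$n_users) %in%
    sample(cfg$n_users, round(cfg$self_report_fraction * cfg$n_users))
  n_posts_user <- sample(cfg$posts_per_user[1]:cfg$posts_per_user[2],
                         cfg$n_users, replace = TRUE)
  n_posts <- sum(n_posts_user)
  post_user <- rep(seq_len(cfg$n_users), n_posts_user)
  post_id <- sprintf("p%06d", seq_len(n_posts))
  subforum <- sample(cfg$subforum_names, n_posts, replace = TRUE,
                     prob = cfg$subforum_probs)
  is_relevant <- runif(n_posts) < cfg$relevant_fraction
  mentions <- runif(n_posts) < cfg$condition_mention_rate
  created <- format(
    as.POSIXct("2015-01-01 00:00:00", tz = "UTC") +
      sort(sample.int(1.3e8, n_posts)),
    "%Y-%m-%dT%H:%M:%SZ")

  m <- sample(cfg$words_per_post[1]:cfg$words_per_post[2], n_posts,
              replace = TRUE)
  total <- sum(m)
  tok_post <- rep(seq_len(n_posts), m)

  # token category: function word / planted term / background lemma
  p_term <- n_terms * cfg$planted_base_rate *
    ifelse(is_relevant[tok_post], cfg$enrichment, 1)
  u <- runif(total)
  is_fw <- u < cfg$function_word_rate
  is_planted <- !is_fw &
    (u - cfg$function_word_rate) < (1 - cfg$function_word_rate) * p_term
  tokens <- character(total)
  tokens[is_fw] <- sample(fw, sum(is_fw), replace = TRUE, prob = fw_p)
  tokens[is_planted] <- sample(cfg$planted_terms, sum(is_planted),
                               replace = TRUE)
  n_bg <- total - sum(is_fw) - sum(is_planted)
  tokens[!is_fw & !is_planted] <- sample(vocab, n_bg, replace = TRUE,
                                         prob = zipf_p)

  # planted collocates: inserted adjacent to a node occurrence
  pc <- cfg$planted_collocations
  if (length(pc) > 0 && nrow(pc) > 0) {
    for (k in seq_len(nrow(pc))) {
      occ <- which(is_planted & tokens == pc$node[k])
      ins <- occ[runif(length(occ)) < pc$rate[k]]
      if (length(ins) > 0) {
        left <- runif(length(ins)) < 0.5
        tokens[ins] <- ifelse(left,
                              paste(pc$collocate[k], tokens[ins]),
                              paste(tokens[ins], pc$collocate[k]))
      }
    }
  }

  # condition mentions: one insertion per mentioning post
  post_start <- base::c(1, cumsum(m)[-n_posts] + 1)
  mpost <- which(mentions)
  if (length(mpost) > 0) {
    slot <- post_start[mpost] + floor(runif(length(mpost)) * m[mpost])
    tokens[slot] <- paste(tokens[slot], cfg$condition_term)
  }

  # light punctuation: sentence breaks after ~8% of tokens
  dot <- runif(total) < 0.08
  tokens[dot] <- paste(tokens[dot], ".")

  # self-report disclosure: one evidence sentence in the user's first post
  reporter_first_post <- match(which(is_reporter), post_user)
  if (length(reporter_first_post) > 0) {
    slot <- post_start[reporter_first_post]
    tokens[slot] <- paste("I was diagnosed with", cfg$condition_term,
                          "a while ago .", tokens[slot])
    mentions[reporter_first_post] <- TRUE
  }

  body <- vapply(split(tokens, tok_post), paste, character(1),
                 collapse = " ")
  names(body) <- NULL

  has_title <- runif(n_posts) < 0.6
  title <- character(n_posts)
  nt <- sum(has_title)
  if (nt > 0) {
    tw <- sample(3:6, nt, replace = TRUE)
    tt <- sample(vocab, sum(tw), replace = TRUE, prob = zipf_p)
    title[has_title] <- vapply(split(tt, rep(seq_len(nt), tw)), paste,
                               character(1), collapse = " ")
  }

  posts <- tibble::tibble(
    post_id = post_id, user_id = user_id[post_user], subforum = subforum,
    created = created, title = title, body = body
  )
  # collocates of planted nodes inherit the node's enrichment (they are
  # inserted per node occurrence), so they are planted-enriched lemmas too
  planted_lemmas <- unique(base::c(
    unlist(strsplit(cfg$planted_terms, "\\s+")),
    if (length(pc) > 0 && nrow(pc) > 0) pc$collocate else character(0)
  ))
  truth <- list(
    posts = tibble::tibble(post_id = post_id, user_id = user_id[post_user],
                           is_relevant = is_relevant,
                           mentions_condition = mentions),
    users = tibble::tibble(user_id = user_id,
                           is_self_reporter = is_reporter),
    lemmas = tibble::tibble(lemma = planted_lemmas, planted = TRUE),
    collocations = tibble::as_tibble(pc),
    config = cfg
  )
  list(corpus = corpus(posts, name = sprintf("synthetic-seed%d", cfg$seed)),
       truth = truth)
}
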