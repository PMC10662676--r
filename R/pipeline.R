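# Staged corpus-construction + keyness pipeline with flow-chart logging:
# cohort detection -> subforum filter -> condition-mention filter ->
# relevance scoring -> target/reference split -> keyness.

#' Run the corpus construction and keyness pipeline
#'
#' Applies the four corpus-construction steps in order (self-reported
#' diagnosis cohort, condition subforums, condition mention, relevance
#' split by TF-IDF cosine score and minimum length), logging the post count
#' after each stage (counts are monotonically non-increasing), then
#' computes frequency tables and key lemmas for the resulting target vs
#' reference corpora.
#'
#' @param x A `cfa_corpus` of all posts.
#' @param terms Concept `cfa_term_list` used for relevance scoring.
#' @param patterns `cfa_self_report_patterns` for cohort detection.
#' @param subforums Character vector of condition subforum names.
#' @param condition_terms `cfa_term_list` naming the condition.
#' @param split Target/reference [split_config()].
#' @param alpha,min_ratio,min_user_share Keyness gates, see
#'   [select_key_lemmas()].
#' @param analyzer Analyzer, see [default_analyzer()].
#' @param verbose Print the stage log as it grows.
#' @return List with `stages` (tibble `stage`, `n_posts`, `n_users`),
#'   `cohort_users`, `scores`, `target`, `reference`, `target_freq`,
#'   `reference_freq`, `keyness`, `tokens` (token table of the filtered
#'   corpus).
#' @export
run_pipeline <- function(x, terms,
                         patterns = default_self_report_patterns(),
                         subforums = base::c("bipolar", "bipolarsupport"),
                         condition_terms = term_list("bipolar"),
                         split = split_config(),
                         alpha = 1e-4, min_ratio = 2, min_user_share = 0.05,
                         analyzer = default_analyzer(),
                         verbose = TRUE) {
  stopifnot(inherits(x, "cfa_corpus"))
  stages <- list()
  log_stage <- function(stage, corp) {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = stage, n_posts = nrow(corp),
      n_users = length(unique(corp$user_id)))
    if (verbose) {
      message(sprintf("%-28s %7d posts  %6d users", stage, nrow(corp),
                      length(unique(corp$user_id))))
    }
  }
  log_stage("all posts", x)

  cohort <- find_self_report_users(x, patterns)
  step1 <- filter_users(x, cohort$user_id)
  log_stage("self-reported cohort", step1)

  step2 <- filter_subforum(step1, subforums)
  log_stage("condition subforums", step2)

  tokens2 <- analyze_corpus(step2, analyzer)
  step3 <- filter_condition_mention(step2, condition_terms, tokens = tokens2)
  log_stage("condition mention", step3)

  tokens3 <- subset_tokens(tokens2, step3$post_id)
  scores <- score_relevance(step3, terms, tokens = tokens3)
  halves <- split_corpus(step3, scores, split, tokens = tokens3)
  log_stage("target (relevant)", halves$target)
  log_stage("reference (non-relevant)", halves$reference)

  target_tokens <- subset_tokens(tokens3, halves$target$post_id)
  reference_tokens <- subset_tokens(tokens3, halves$reference$post_id)
  target_freq <- build_frequency_table(halves$target, target_tokens)
  reference_freq <- build_frequency_table(halves$reference, reference_tokens)
  key <- select_key_lemmas(target_freq, reference_freq, alpha = alpha,
                           min_ratio = min_ratio,
                           min_user_share = min_user_share)

  list(
    stages = do.call(rbind, stages),
    cohort_users = cohort,
    scores = scores,
    target = halves$target,
    reference = halves$reference,
    target_tokens = target_tokens,
    reference_tokens = reference_tokens,
    target_freq = target_freq,
    reference_freq = reference_freq,
    keyness = key,
    tokens = tokens3
  )
}
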