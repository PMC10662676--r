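# Rule-based English analyzer: tokenization, lemmatization, coarse POS.
#
# No statistical NLP model is involved: the analyzer is a deterministic set
# of tokenization regexes, an irregular-form dictionary, and ordered suffix
# rules. Its name and version travel with every derived table so results can
# be tied to the normalization that produced them.

# Function words: lemmatize to themselves and tag OTHER. Content/function
# distinction is what the collocation filter needs; the list is deliberately
# closed and small.
.function_words <- c(
  "the", "a", "an", "and", "or", "but", "not", "no", "nor", "of", "to", "in",
  "on", "at", "by", "for", "with", "about", "against", "between", "into",
  "through", "during", "before", "after", "above", "below", "from", "up",
  "down", "out", "off", "over", "under", "again", "further", "then", "once",
  "here", "there", "when", "where", "why", "how", "all", "any", "both",
  "each", "few", "more", "most", "other", "some", "such", "only", "own",
  "same", "so", "than", "too", "very", "just", "because", "as", "until",
  "while", "if", "that", "these", "those", "this", "i", "me", "my", "mine",
  "myself", "we", "us", "our", "ours", "ourselves", "you", "your", "yours",
  "yourself", "he", "him", "his", "himself", "she", "her", "hers", "herself",
  "it", "its", "itself", "they", "them", "their", "theirs", "themselves",
  "what", "which", "who", "whom", "whose", "am", "is", "are", "was", "were",
  "be", "been", "being", "have", "has", "had", "having", "do", "does", "did",
  "doing", "will", "would", "shall", "should", "may", "might", "must", "can",
  "could", "ought", "dont", "cant", "wont", "im", "ive", "id", "youre", "yes"
)

# Irregular forms the suffix rules cannot reach.
.lemma_exceptions <- c(
  was = "be", were = "be", is = "be", are = "are", am = "be", been = "be",
  being = "be", has = "have", had = "have", having = "have", does = "do",
  did = "do", done = "do", doing = "do", went = "go", gone = "go",
  going = "go", goes = "go", said = "say", saying = "say", says = "say",
  made = "make", making = "make", got = "get", gotten = "get",
  getting = "get", felt = "feel", took = "take", taken = "take",
  taking = "take", gave = "give", given = "give", giving = "give",
  came = "come", coming = "come", knew = "know", known = "know",
  thought = "think", told = "tell", found = "find", left = "leave",
  kept = "keep", began = "begin", begun = "begin", brought = "bring",
  children = "child", men = "man", women = "woman", people = "people",
  better = "good", best = "good", worse = "bad", worst = "bad",
  lives = "life", lying = "lie", dying = "die", tried = "try",
  tries = "try", trying = "try", used = "use", using = "use",
  lost = "lose", meds = "med", feelings = "feeling"
)
.lemma_exceptions["are"] <- "be"

# Small open-class cues for the 5-way POS collapse.
.verb_lemmas <- c(
  "be", "have", "do", "go", "get", "make", "take", "give", "come", "know",
  "think", "say", "tell", "find", "leave", "keep", "begin", "bring", "feel",
  "work", "help", "support", "recover", "sleep", "try", "use", "live",
  "want", "need", "love", "hate", "talk", "write", "read", "cope", "manage",
  "struggle", "diagnose", "treat", "hope", "care", "exercise", "lose",
  "raise", "bear", "enjoy", "die", "lie", "stay", "start", "stop", "learn"
)
.adj_lemmas <- c(
  "good", "bad", "happy", "sad", "manic", "depressed", "stable", "high",
  "low", "hard", "easy", "new", "old", "big", "small", "mental", "bipolar",
  "hypomanic", "anxious", "healthy", "ill", "well", "okay", "great"
)

#' Rule-based text analyzer
#'
#' Returns the default analyzer used by every normalization step: a
#' deterministic tokenizer (URLs and user mentions collapsed to placeholder
#' tokens), a dictionary-plus-suffix-rule lemmatizer, and a heuristic tagger
#' collapsing parts of speech to `NOUN`, `VERB`, `ADJ`, `ADV`, `OTHER`. The
#' analyzer's name and version are recorded in derived tables so that all
#' frequencies are reproducible.
#'
#' @return An object of class `cfa_analyzer` with `name` and `version`.
#' @export
default_analyzer <- function() {
  structure(list(name = "rules-en", version = "1.0"), class = "cfa_analyzer")
}

#' @export
print.cfa_analyzer <- function(x, ...) {
  cat("<cfa_analyzer> ", x$name, " ", x$version, "\n", sep = "")
  invisible(x)
}

analyzer_id <- function(analyzer) paste(analyzer$name, analyzer$version)

.token_pattern <- paste0(
  "(?i)https?://\\S+|www\\.\\S+",          # URLs
  "|/?u/[A-Za-z0-9_-]+|@\\w+",             # user mentions
  "|[A-Za-z0-9](?:[A-Za-z0-9'-]*[A-Za-z0-9])?", # words
  "|[^\\sA-Za-z0-9]"                        # punctuation, one char at a time
)

# Lemmatize a character vector of lowercased word surfaces.
lemmatize_words <- function(w) {
  out <- w
  fn <- w %in% .function_words
  exc <- match(w, names(.lemma_exceptions))
  hit <- !is.na(exc) & !fn
  out[hit] <- unname(.lemma_exceptions[exc[hit]])
  todo <- !fn & !hit
  out[todo] <- vapply(w[todo], strip_suffix, character(1), USE.NAMES = FALSE)
  out
}

# Ordered suffix rules with doubled-consonant undoing and limited
# e-restoration; minimum stem length 3 so short words pass through.
strip_suffix <- function(w) {
  n <- nchar(w)
  if (n <= 3 || grepl("[0-9'-]$", w)) return(w)
  # plural endings
  if (grepl("ies$", w) && n > 4) return(paste0(substr(w, 1, n - 3), "y"))
  if (grepl("(sses|ches|shes|xes|zes)$", w)) return(substr(w, 1, n - 2))
  if (grepl("[^su]s$", w) && !grepl("ss$", w) && !grepl("is$", w)) {
    return(substr(w, 1, n - 1))
  }
  # participle endings
  stem <- NULL
  if (grepl("ied$", w) && n > 4) return(paste0(substr(w, 1, n - 3), "y"))
  if (grepl("ing$", w) && n > 5) stem <- substr(w, 1, n - 3)
  if (is.null(stem) && grepl("ed$", w) && n > 4) stem <- substr(w, 1, n - 2)
  if (is.null(stem)) return(w)
  stem <- undouble(stem)
  restore_e(stem)
}

undouble <- function(s) {
  n <- nchar(s)
  if (n >= 2) {
    last <- substr(s, n, n)
    if (last == substr(s, n - 1, n - 1) &&
        last %in% c("b", "d", "g", "m", "n", "p", "r", "t")) {
      return(substr(s, 1, n - 1))
    }
  }
  s
}

restore_e <- function(s) {
  n <- nchar(s)
  if (n < 2) return(s)
  tail2 <- substr(s, n - 1, n)
  last <- substr(s, n, n)
  if (tail2 %in% c("at", "iz", "bl")) return(paste0(s, "e"))
  if (last %in% c("c", "v", "z", "u") && !tail2 %in% c("au", "ou")) {
    return(paste0(s, "e"))
  }
  if (last == "s" && !tail2 %in% c("ss", "us", "is")) return(paste0(s, "e"))
  # short consonant-vowel-consonant stems: mak -> make, hop -> hope
  if (n <= 4 && grepl("[^aeiou][aeiou][^aeiouwxy]$", s)) return(paste0(s, "e"))
  s
}

pos_tag_lemmas <- function(lem) {
  out <- rep("NOUN", length(lem))
  out[lem %in% .function_words] <- "OTHER"
  out[lem %in% .verb_lemmas] <- "VERB"
  out[lem %in% .adj_lemmas] <- "ADJ"
  adv <- endsWith(lem, "ly") & nchar(lem) > 3 & !lem %in% .function_words
  out[adv] <- "ADV"
  adj_sfx <- grepl("(ous|ful|ive|able|ible|ish)$", lem)
  out[adj_sfx & out == "NOUN"] <- "ADJ"
  vrb_sfx <- grepl("(ize|ise|ify)$", lem)
  out[vrb_sfx & out == "NOUN"] <- "VERB"
  out
}

# Classify raw token surfaces into (surface, lemma, pos, is_word).
classify_tokens <- function(raw) {
  if (length(raw) == 0) {
    return(tibble::tibble(
      surface = character(), lemma = character(),
      pos = character(), is_word = logical()
    ))
  }
  is_url <- grepl("^(https?://|www\\.)", raw, ignore.case = TRUE)
  is_mention <- !is_url & grepl("^(/?u/|@)", raw)
  surface <- raw
  surface[is_url] <- "<url>"
  surface[is_mention] <- "<user>"
  is_word <- !is_url & !is_mention & grepl("^[A-Za-z0-9]", raw)
  lower <- stringr::str_to_lower(surface)
  lemma <- lower
  if (any(is_word)) {
    uw <- unique(lower[is_word])
    ul <- lemmatize_words(uw)
    lemma[is_word] <- ul[match(lower[is_word], uw)]
  }
  pos <- rep("OTHER", length(raw))
  if (any(is_word)) {
    ulm <- unique(lemma[is_word])
    upos <- pos_tag_lemmas(ulm)
    pos[is_word] <- upos[match(lemma[is_word], ulm)]
  }
  tibble::tibble(surface = surface, lemma = lemma, pos = pos, is_word = is_word)
}

#' Tokenize, lemmatize and tag one text
#'
#' Deterministically segments `text` into tokens, lowercases and lemmatizes
#' word tokens (e.g. "recovering" and "recovered" both map to the lemma
#' "recover"), collapses URLs and user mentions to non-word placeholder
#' tokens, and assigns a coarse part of speech.
#'
#' @param text A single character string (may be empty).
#' @param analyzer Analyzer object, see [default_analyzer()].
#' @return A tibble with columns `surface`, `lemma`, `pos`
#'   (`NOUN`/`VERB`/`ADJ`/`ADV`/`OTHER`) and `is_word`; one row per token,
#'   in text order. The analyzer id is attached as attribute `analyzer`.
#' @examples
#' analyze("I was diagnosed with bipolar.")
#' @export
analyze <- function(text, analyzer = default_analyzer()) {
  stopifnot(is.character(text), length(text) == 1)
  raw <- stringr::str_extract_all(text, .token_pattern)[[1]]
  out <- classify_tokens(raw)
  attr(out, "analyzer") <- analyzer_id(analyzer)
  out
}

#' Count words in a text
#'
#' A word is an alphabetic/alphanumeric token as segmented by [analyze()];
#' punctuation, URLs and user mentions do not count. Used for the minimum
#' post-length gate when splitting corpora.
#'
#' @param text Character vector; each element counted separately.
#' @inheritParams analyze
#' @return Integer vector of word counts.
#' @export
word_count <- function(text, analyzer = default_analyzer()) {
  if (length(text) == 0) return(integer())
  raw <- stringr::str_extract_all(text, .token_pattern)
  vapply(raw, function(r) {
    sum(!grepl("^(https?://|www\\.|/?u/|@)", r, ignore.case = TRUE) &
          grepl("^[A-Za-z0-9]", r))
  }, integer(1))
}
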