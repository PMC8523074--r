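# Linguistic preprocessing and the averaged-embedding utterance
# representation shared by the kNN and SVM models and the RNN input layer.
#
# The chain: lower-case; normalize sentence-end marks and comma spacing;
# whitespace tokenization; misspelling and contraction rewriting via frozen
# maps; numeral rewriting; punctuation stripping; stop-word removal. The
# default word lists are small frozen snapshots committed to the package so
# results are machine-independent; all are overridable.

#' Frozen default English stop-word list
#'
#' A snapshot of a standard English stop-word list, committed to the package
#' rather than resolved from an external resource at run time.
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  c("i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his",
    "himself", "she", "her", "hers", "herself", "it", "its", "itself",
    "they", "them", "their", "theirs", "themselves", "what", "which",
    "who", "whom", "this", "that", "these", "those", "am", "is", "are",
    "was", "were", "be", "been", "being", "have", "has", "had", "having",
    "do", "does", "did", "doing", "a", "an", "the", "and", "but", "if",
    "or", "because", "as", "until", "while", "of", "at", "by", "for",
    "with", "about", "against", "between", "into", "through", "during",
    "before", "after", "above", "below", "to", "from", "up", "down", "in",
    "out", "on", "off", "over", "under", "further", "then", "once",
    "here", "there", "when", "where", "why", "how", "all", "any", "both",
    "each", "few", "more", "most", "some", "such", "no", "nor", "not",
    "only", "own", "same", "so", "than", "too", "very", "s", "t", "can",
    "will", "just", "don", "should", "now", "would", "could", "wont",
    "also", "im", "ive", "id")
}

#' Frozen default contraction expansions
#'
#' Keys include both apostrophe and apostrophe-less spellings since informal
#' text frequently omits the apostrophe.
#'
#' @return Named character vector mapping contraction to expansion.
#' @export
default_contractions <- function() {
  c("don't" = "do not",      "dont" = "do not",
    "can't" = "can not",     "cant" = "can not",
    "won't" = "will not",
    "isn't" = "is not",      "isnt" = "is not",
    "aren't" = "are not",    "arent" = "are not",
    "wasn't" = "was not",    "wasnt" = "was not",
    "weren't" = "were not",  "werent" = "were not",
    "doesn't" = "does not",  "doesnt" = "does not",
    "didn't" = "did not",    "didnt" = "did not",
    "couldn't" = "could not", "couldnt" = "could not",
    "shouldn't" = "should not", "shouldnt" = "should not",
    "wouldn't" = "would not", "wouldnt" = "would not",
    "i'm" = "i am", "i've" = "i have", "i'll" = "i will", "i'd" = "i would",
    "it's" = "it is", "that's" = "that is", "there's" = "there is",
    "he's" = "he is", "she's" = "she is", "they're" = "they are",
    "we're" = "we are", "you're" = "you are", "let's" = "let us")
}

#' Frozen default misspelling corrections
#'
#' @return Named character vector mapping misspelling to correction.
#' @export
default_misspellings <- function() {
  c("teh" = "the", "recieve" = "receive", "alot" = "a lot",
    "freind" = "friend", "freinds" = "friends",
    "definately" = "definitely", "seperate" = "separate",
    "untill" = "until", "becuase" = "because", "beleive" = "believe",
    "wierd" = "weird", "occured" = "occurred", "realy" = "really",
    "thier" = "their", "embarassed" = "embarrassed")
}

#' Preprocessing configuration
#'
#' @param misspelling_map Named character vector, misspelling to correction.
#' @param contraction_map Named character vector, contraction to expansion
#'   (multi-word expansions are split into tokens).
#' @param number_policy `"drop"` (default) removes numeral tokens after the
#'   rewrite stage; `"spell"` spells out single digits 0-9 and drops other
#'   numerals.
#' @param stopword_list Frozen stop-word set.
#' @param lowercase Lower-case the text first (default `TRUE`).
#' @return A `prep_config` list.
#' @export
prep_config <- function(misspelling_map = default_misspellings(),
                        contraction_map = default_contractions(),
                        number_policy = c("drop", "spell"),
                        stopword_list = default_stopwords(),
                        lowercase = TRUE) {
  number_policy <- match.arg(number_policy)
  if (anyDuplicated(names(misspelling_map)) || anyDuplicated(names(contraction_map))) {
    stop("rewrite maps must be functions: no key may map to two targets",
         call. = FALSE)
  }
  structure(list(misspelling_map = misspelling_map,
                 contraction_map = contraction_map,
                 number_policy = number_policy,
                 stopword_list = stopword_list,
                 lowercase = lowercase),
            class = "prep_config")
}

DIGIT_WORDS <- c("zero", "one", "two", "three", "four", "five", "six",
                 "seven", "eight", "nine")

#' Preprocess an utterance into tokens
#'
#' Applies the full chain: lower-casing, punctuation/sentence-mark
#' normalization, whitespace tokenization, misspelling then contraction
#' rewriting, numeral policy, punctuation stripping, stop-word removal, and
#' removal of empty tokens. Deterministic for a fixed configuration;
#' idempotent in the sense that re-preprocessing the joined token list
#' returns the same tokens.
#'
#' @param text A character string (possibly empty or multi-sentence).
#' @param config A [prep_config()].
#' @return Character vector of tokens (possibly empty).
#' @export
preprocess <- function(text, config = prep_config()) {
  if (length(text) != 1L || is.na(text)) stop("text must be a single string")
  if (config$lowercase) text <- tolower(text)
  # normalize sentence end marks and comma spacing, then isolate punctuation
  text <- gsub("([.!?,;:])", " \\1 ", text)
  text <- gsub("\\s+", " ", trimws(text))
  if (!nzchar(text)) return(character(0))
  tokens <- strsplit(text, " ", fixed = TRUE)[[1]]
  # strip surrounding punctuation but keep internal apostrophes for the maps
  tokens <- gsub("^[^a-z0-9']+|[^a-z0-9']+$", "", tokens)
  tokens <- rewrite_tokens(tokens, config$misspelling_map)
  tokens <- rewrite_tokens(tokens, config$contraction_map)
  # numeral policy
  is_num <- grepl("^[0-9]+([.,][0-9]+)?$", tokens)
  if (config$number_policy == "spell") {
    single <- is_num & tokens %in% as.character(0:9)
    tokens[single] <- DIGIT_WORDS[as.integer(tokens[single]) + 1L]
    tokens <- tokens[!(is_num & !single)]
  } else {
    tokens <- tokens[!is_num]
  }
  # drop all remaining non-letter characters (incl. apostrophes)
  tokens <- gsub("[^a-z]", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!tokens %in% config$stopword_list]
  tokens
}

# apply a token rewrite map; multi-word targets expand to several tokens
rewrite_tokens <- function(tokens, map) {
  if (length(map) == 0L || length(tokens) == 0L) return(tokens)
  hit <- tokens %in% names(map)
  if (!any(hit)) return(tokens)
  out <- as.list(tokens)
  out[hit] <- strsplit(unname(map[tokens[hit]]), " ", fixed = TRUE)
  unlist(out, use.names = FALSE)
}

#' Averaged normalized-embedding utterance representation
#'
#' Each in-vocabulary token's vector is L2-normalized, and the element-wise
#' mean over contributing tokens is returned. Out-of-vocabulary tokens are
#' skipped and counted; an empty or all-out-of-vocabulary utterance yields
#' the zero vector with the `all_oov` flag set (its cosine similarity to
#' anything is defined as 0 downstream).
#'
#' @param tokens Character vector of preprocessed tokens.
#' @param table An [embedding_table()].
#' @return List with `values` (numeric vector of the table's dimension),
#'   `n_in_vocab` (count of contributing tokens) and `all_oov` (flag).
#' @export
embed_utterance <- function(tokens, table) {
  d <- table$dimension
  idx <- match(tokens, rownames(table$vectors))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    return(list(values = numeric(d), n_in_vocab = 0L, all_oov = TRUE))
  }
  v <- table$vectors[idx, , drop = FALSE]
  norms <- sqrt(rowSums(v^2))
  norms[norms == 0] <- 1
  v <- v / norms
  list(values = colMeans(v), n_in_vocab = length(idx), all_oov = FALSE)
}

#' Embed every utterance of a corpus
#'
#' Convenience wrapper running [preprocess()] and [embed_utterance()] over
#' all rows of a corpus.
#'
#' @param corpus A corpus table.
#' @param table An [embedding_table()].
#' @param prep A [prep_config()].
#' @return List with `matrix` (utterances x dimension), `n_in_vocab`
#'   (integer vector), `all_oov` (logical vector) and `tokens` (list of
#'   token vectors, reused by the sequence models).
#' @export
embed_corpus <- function(corpus, table, prep = prep_config()) {
  toks <- lapply(corpus$text, preprocess, config = prep)
  emb <- lapply(toks, embed_utterance, table = table)
  list(matrix = do.call(rbind, lapply(emb, `[[`, "values")),
       n_in_vocab = vapply(emb, `[[`, integer(1), "n_in_vocab"),
       all_oov = vapply(emb, `[[`, logical(1), "all_oov"),
       tokens = toks)
}
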