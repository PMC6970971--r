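# Five-step post normalization:
#   1 emoticon conversion, 2 lowercasing, 3 tokenization + stopword removal
#   (with contraction splitting), 4 special-character stripping, 5 number
#   removal. Sentence boundaries are recorded before token-level steps so the
#   phrase module can segment within sentence-like spans.

#' Replace emoticons and emoji by their textual names
#'
#' Every symbol present in [emoticon_map()] is replaced by its space-separated
#' textual name; unmapped symbols are left untouched (they are removed later by
#' special-character stripping). Pure replacement: no case change.
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @examples
#' convert_emoticons(":-)")   # "Happy face smiley"
#' @export
convert_emoticons <- function(text) {
  out <- text
  map <- .caloscope_emoticons
  for (i in order(-nchar(names(map)))) {
    out <- gsub(names(map)[i], paste0(" ", map[[i]], " "), out, fixed = TRUE)
  }
  squish(out)
}

squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

#' Unicode-aware lowercasing
#'
#' @param text Character vector.
#' @return Lowercased text; idempotent.
#' @export
to_lowercase <- function(text) stringi::stri_trans_tolower(text)

#' Tokenize on whitespace with contraction splitting
#'
#' Splits on whitespace; known contractions are split by a fixed rule table
#' ("gonna" -> "gon", "na"). The '#' character stays attached at this stage;
#' embedded punctuation is handled by [strip_special_characters()].
#'
#' @param text A single string.
#' @return Character vector of tokens.
#' @export
tokenize <- function(text) {
  toks <- strsplit(squish(text), " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character(0))
  expand_contractions(toks)
}

expand_contractions <- function(toks) {
  hit <- match(tolower(toks), names(.caloscope_contractions))
  if (all(is.na(hit))) return(toks)
  out <- as.list(toks)
  out[!is.na(hit)] <- .caloscope_contractions[hit[!is.na(hit)]]
  unlist(out, use.names = FALSE)
}

#' Remove stopwords
#'
#' Drops tokens present in [stopword_list()] (case-insensitive); all other
#' tokens are kept in order.
#'
#' @param tokens Character vector of tokens.
#' @return Filtered token vector.
#' @export
remove_stopwords <- function(tokens) {
  tokens[!(tolower(tokens) %in% .caloscope_stopwords)]
}

#' Strip special characters from tokens
#'
#' Deletes non-alphanumeric characters within each token ("#rofl" -> "rofl");
#' tokens emptied by stripping are dropped. URLs and @mentions are dropped
#' whole, since their alphanumeric residue is non-lexical noise.
#'
#' @param tokens Character vector of tokens.
#' @return Filtered token vector.
#' @export
strip_special_characters <- function(tokens) {
  if (!length(tokens)) return(character(0))
  drop <- grepl("^@.", tokens) | grepl("^(https?://|www\\.)", tokens,
                                       ignore.case = TRUE)
  tokens <- tokens[!drop]
  tokens <- gsub("[^A-Za-z0-9]+", "", tokens)
  tokens[nzchar(tokens)]
}

#' Remove numbers from tokens
#'
#' Tokens consisting solely of digits are dropped; digits inside mixed tokens
#' are deleted ("b4" -> "b").
#'
#' @param tokens Character vector of tokens.
#' @return Filtered token vector.
#' @export
remove_numbers <- function(tokens) {
  if (!length(tokens)) return(character(0))
  tokens <- gsub("[0-9]+", "", tokens)
  tokens[nzchar(tokens)]
}

# Token-level steps 3-5 applied to one lowercased sentence string, with a
# final stopword pass so residues uncovered by stripping ("it's" -> "its")
# cannot survive.
clean_sentence_tokens <- function(sentence) {
  remove_stopwords(
    remove_numbers(strip_special_characters(remove_stopwords(tokenize(sentence)))))
}

# URLs and @mentions are deleted on the raw text, before sentence splitting
# would break them apart at dots.
drop_urls_mentions <- function(x) {
  x <- gsub("(https?://|www\\.)[^[:space:]]*", " ", x, ignore.case = TRUE)
  gsub("(^|[[:space:]])@[^[:space:]]+", " ", x)
}

#' Clean one post's text into content tokens
#'
#' Applies the full pipeline: Unicode NFKC, emoticon conversion, lowercasing,
#' sentence splitting (on `.!?;`), tokenization with contraction splitting,
#' stopword removal, special-character stripping and number removal.
#'
#' @param text A single string (may be empty).
#' @return Character vector of lowercase alphabetic content tokens with an
#'   integer `sentence` attribute giving each token's sentence-like span.
#' @examples
#' clean_text("I am getting 2 old to be mango Gonna retire soon :-)")
#' @export
clean_text <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(structure(character(0), sentence = integer(0)))
  }
  x <- stringi::stri_trans_nfkc(text)
  x <- drop_urls_mentions(to_lowercase(convert_emoticons(x)))
  sents <- strsplit(x, "[.!?;]+")[[1]]
  sents <- sents[nzchar(squish(sents))]
  toks <- lapply(sents, clean_sentence_tokens)
  structure(unlist(toks, use.names = FALSE) %||% character(0),
            sentence = rep(seq_along(toks), lengths(toks)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clean a raw post into a `clean_post`
#'
#' @param id Post identifier.
#' @param text Raw post text.
#' @param region Region code (e.g. ISO 3166-2:CA).
#' @return A `clean_post`: list with `id`, `region`, `tokens` and a parallel
#'   integer `sentence` vector.
#' @export
clean_post <- function(id, text, region = NA_character_) {
  toks <- clean_text(text)
  structure(
    list(id = as.character(id), region = as.character(region),
         tokens = as.character(toks),
         sentence = attr(toks, "sentence")),
    class = "clean_post"
  )
}

#' @export
print.clean_post <- function(x, ...) {
  cat("<clean_post ", x$id, " [", x$region, "]> ",
      paste(x$tokens, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Clean a corpus of raw posts
#'
#' Vectorized version of [clean_post()] for a data frame of raw posts.
#'
#' @param posts Data frame with columns `id`, `text`, `region`.
#' @return List of `clean_post` objects.
#' @export
clean_posts <- function(posts) {
  stopifnot(is.data.frame(posts), all(c("id", "text", "region") %in% names(posts)))
  n <- nrow(posts)
  if (n == 0L) return(list())
  x <- stringi::stri_trans_nfkc(ifelse(is.na(posts$text), "", posts$text))
  x <- drop_urls_mentions(to_lowercase(convert_emoticons(x)))
  sents <- strsplit(x, "[.!?;]+")
  n_sent <- lengths(sents)
  flat <- unlist(sents, use.names = FALSE)
  post_of_sent <- rep(seq_len(n), n_sent)
  sent_in_post <- sequence(n_sent)
  tok_lists <- strsplit(squish(flat), " ", fixed = TRUE)
  toks <- unlist(tok_lists, use.names = FALSE)
  if (is.null(toks)) toks <- character(0)
  keep0 <- nzchar(toks)
  toks <- toks[keep0]
  idx <- rep(seq_along(tok_lists), lengths(tok_lists))[keep0]
  # contraction expansion
  hit <- match(toks, names(.caloscope_contractions))
  if (any(!is.na(hit))) {
    reps <- ifelse(is.na(hit), 1L,
                   lengths(.caloscope_contractions)[hit])
    new_toks <- vector("list", length(toks))
    new_toks[is.na(hit)] <- toks[is.na(hit)]
    new_toks[!is.na(hit)] <- .caloscope_contractions[hit[!is.na(hit)]]
    idx <- rep(idx, reps)
    toks <- unlist(new_toks, use.names = FALSE)
  }
  # stopwords, URLs/mentions, special characters, numbers
  keep <- !(toks %in% .caloscope_stopwords)
  toks <- toks[keep]; idx <- idx[keep]
  drop <- grepl("^@.", toks) | grepl("^(https?://|www\\.)", toks)
  toks <- toks[!drop]; idx <- idx[!drop]
  toks <- gsub("[^a-z0-9]+", "", toks)
  toks <- gsub("[0-9]+", "", toks)
  keep <- nzchar(toks) & !(toks %in% .caloscope_stopwords)
  toks <- toks[keep]; idx <- idx[keep]

  post_id <- post_of_sent[idx]
  sent_id <- sent_in_post[idx]
  ids <- as.character(posts$id)
  regions <- as.character(posts$region)
  out <- vector("list", n)
  ord <- order(idx)              # strsplit order is already grouped; be safe
  toks <- toks[ord]; post_id <- post_id[ord]; sent_id <- sent_id[ord]
  split_tok <- split(toks, factor(post_id, levels = seq_len(n)))
  split_sent <- split(sent_id, factor(post_id, levels = seq_len(n)))
  for (i in seq_len(n)) {
    si <- split_sent[[i]]
    out[[i]] <- structure(
      list(id = ids[i], region = regions[i],
           tokens = split_tok[[i]],
           sentence = if (length(si)) match(si, sort(unique(si))) else integer(0)),
      class = "clean_post"
    )
  }
  out
}

#' The five intermediate texts of the cleaning pipeline
#'
#' Returns the text as rendered after each cleaning step, for inspection and
#' conformance checking. In the step-1 rendering, hashtag tokens and inserted
#' emoticon names keep their case (emoticon names are inserted in their
#' canonical dictionary capitalization) while all other words are shown
#' lowercase; step 2 lowercases everything, so the final tokens are identical
#' to composing the exported step functions.
#'
#' @param text A single raw string.
#' @return Character vector of length 5, one rendered string per step.
#' @export
clean_steps <- function(text) {
  x <- stringi::stri_trans_nfkc(text)
  # step 1: emoticon conversion (placeholders protect inserted names)
  map <- .caloscope_emoticons
  ph <- x
  for (i in order(-nchar(names(map)))) {
    ph <- gsub(names(map)[i], sprintf(" \001%d\001 ", i), ph, fixed = TRUE)
  }
  toks <- strsplit(squish(ph), " ", fixed = TRUE)[[1]]
  keep_case <- startsWith(toks, "#") | startsWith(toks, "\001")
  toks[!keep_case] <- to_lowercase(toks[!keep_case])
  s1 <- paste(toks, collapse = " ")
  for (i in seq_along(map)) {
    s1 <- gsub(sprintf("\001%d\001", i), map[[i]], s1, fixed = TRUE)
  }
  s2 <- to_lowercase(s1)
  s3 <- paste(remove_stopwords(tokenize(s2)), collapse = " ")
  s4 <- paste(strip_special_characters(remove_stopwords(tokenize(s2))),
              collapse = " ")
  s5 <- paste(clean_sentence_tokens(s2), collapse = " ")
  c(step1_emoticons = squish(s1), step2_lowercase = s2,
    step3_stopwords = s3, step4_special = s4, step5_numbers = s5)
}
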