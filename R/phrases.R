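# Multiword-expression detection over content tokens. Because cleaning
# removes stopwords first, inventory forms are stored stopword-free
# ("apple of my eye" -> "apple eye"), which makes linker-based segmentation
# over raw text and greedy matching over content tokens equivalent.

MAX_FORM_LEN <- 4L

#' Build a phrase inventory
#'
#' Canonicalizes multiword forms (lowercase, stopword-free, singularized).
#' Forms that reduce to fewer than 2 content tokens are dropped; forms longer
#' than 4 content tokens are truncated to their first 4 with a warning.
#'
#' @param phrases Character vector of surface phrases ("apple of my eye").
#' @param tags Optional character vector of source tags per phrase
#'   (e.g. "idiom" or "compound"); recycled if length 1.
#' @return A `phrase_inventory`: canonical form keys with tags.
#' @export
phrase_inventory <- function(phrases, tags = "idiom") {
  tags <- rep_len(as.character(tags), length(phrases))
  keys <- canonical_key(phrases)
  lens <- lengths(strsplit(keys, " ", fixed = TRUE))
  if (any(lens > MAX_FORM_LEN)) {
    warning(sprintf("%d form(s) longer than %d content tokens truncated",
                    sum(lens > MAX_FORM_LEN), MAX_FORM_LEN))
    long <- lens > MAX_FORM_LEN
    keys[long] <- vapply(strsplit(keys[long], " ", fixed = TRUE), function(t)
      paste(t[seq_len(MAX_FORM_LEN)], collapse = " "), character(1))
  }
  keep <- lens >= 2L
  keep <- keep & !duplicated(keys)
  structure(list(forms = keys[keep], tags = tags[keep], raw = phrases[keep]),
            class = "phrase_inventory")
}

#' @export
print.phrase_inventory <- function(x, ...) {
  cat(sprintf("<phrase inventory: %d forms (%s)>\n", length(x$forms),
              paste(sprintf("%s: %d", names(table(x$tags)), table(x$tags)),
                    collapse = ", ")))
  invisible(x)
}

#' Load a phrase inventory from a plain-text file
#'
#' One phrase per line, with an optional tab-separated tag column
#' (`idiom` or `compound`). Blank lines and `#` comment lines are skipped.
#'
#' @param path Path to the file.
#' @return A `phrase_inventory`.
#' @export
load_phrase_inventory <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  phrases <- vapply(parts, `[`, character(1), 1)
  tags <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "idiom",
                 character(1))
  phrase_inventory(phrases, tags)
}

#' The packaged gold-standard idiom and compound inventory
#'
#' A fixture list of about one hundred English food-word idioms and common
#' food compounds, covering the classical idioms ("piece of cake", "apple of
#' my eye", "smart cookie", "bring home the bacon", "crying over spilled
#' milk", "cup of tea").
#'
#' @return A `phrase_inventory`.
#' @export
default_idiom_inventory <- function() {
  load_phrase_inventory(system.file("extdata", "idiom_inventory.txt",
                                    package = "caloscope", mustWork = TRUE))
}

# Greedy leftmost-longest matching of canonical tokens against a set of form
# keys. `blocked` marks positions that may not participate; matches never
# cross a blocked position. Returns a list of matches (start, len, key),
# disjoint by construction.
greedy_match <- function(canon, form_set, max_len = MAX_FORM_LEN,
                         min_len = 2L, blocked = NULL) {
  n <- length(canon)
  if (!n || !length(form_set)) return(list())
  if (is.null(blocked)) blocked <- logical(n)
  matches <- list()
  i <- 1L
  while (i <= n) {
    if (blocked[i]) { i <- i + 1L; next }
    avail <- min(max_len, n - i + 1L)
    if (avail < min_len) break
    matched <- FALSE
    for (len in seq(avail, min_len)) {
      span <- i:(i + len - 1L)
      if (any(blocked[span])) next
      key <- paste(canon[span], collapse = " ")
      if (key %in% form_set) {
        matches[[length(matches) + 1L]] <-
          list(key = key, start = i, len = len, positions = span)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  matches
}

#' Partition a cleaned post into content-token groups
#'
#' Tokens are partitioned into spans at sentence-like boundaries recorded
#' before cleaning (one span if the source had none). Each span's content
#' tokens become a `phrase_group` with empty matches.
#'
#' @param post A `clean_post`, or a character vector of tokens (treated as one
#'   span).
#' @return List of `phrase_group` objects: `surface` (tokens), `positions`
#'   (indices into the post's token vector), `matches` (empty list).
#' @export
extract_content_groups <- function(post) {
  if (inherits(post, "clean_post")) {
    toks <- post$tokens
    sent <- post$sentence %||% rep(1L, length(toks))
  } else {
    toks <- as.character(post)
    sent <- rep(1L, length(toks))
  }
  if (!length(toks)) return(list())
  lapply(split(seq_along(toks), sent), function(pos) {
    structure(list(surface = toks[pos], positions = pos, matches = list()),
              class = "phrase_group")
  })
}

#' Match multiword expressions within a group
#'
#' Greedy leftmost-longest matching of canonical (singularized) adjacent
#' content tokens against the inventory forms; at each left edge the longest
#' matching form (up to 4 content tokens) wins and matching resumes after it,
#' so matched spans are disjoint.
#'
#' @param group A `phrase_group` from [extract_content_groups()].
#' @param inventory A `phrase_inventory`.
#' @return The group with `matches` filled: each match has the inventory
#'   `key`, its `tag`, and the surface token `positions` it covers.
#' @export
match_mwe <- function(group, inventory) {
  stopifnot(inherits(group, "phrase_group"))
  canon <- singularize_tokens(group$surface)
  ms <- greedy_match(canon, inventory$forms)
  group$matches <- lapply(ms, function(m) {
    list(key = m$key,
         tag = inventory$tags[match(m$key, inventory$forms)],
         positions = group$positions[m$positions])
  })
  group
}

#' Token set of a matched group
#'
#' The unordered set of content tokens in a group (matched plus residual),
#' which is how detected phrases are reported.
#'
#' @param group A `phrase_group`.
#' @return Character vector of unique surface tokens.
#' @export
group_token_set <- function(group) unique(group$surface)

#' Idiom exclusion mask for a cleaned post
#'
#' Marks every token that lies inside a matched idiomatic multiword
#' expression. Masked tokens are invisible to caloric counting and to
#' weak-supervision labeling. Idiom matches take precedence over food-lexicon
#' forms: idioms are matched first, and food phrases are only matched on the
#' unmasked remainder.
#'
#' @param post A `clean_post`.
#' @param idiom_inventory A `phrase_inventory` of idioms.
#' @param food_lexicon Unused for masking itself (idioms always win); accepted
#'   so callers can pass the full matching context.
#' @return Logical vector parallel to `post$tokens`; `TRUE` = masked.
#' @export
flag_food_idioms <- function(post, idiom_inventory, food_lexicon = NULL) {
  toks <- if (inherits(post, "clean_post")) post$tokens else as.character(post)
  mask <- logical(length(toks))
  if (!length(toks) || is.null(idiom_inventory) ||
      !length(idiom_inventory$forms)) return(mask)
  for (g in extract_content_groups(post)) {
    g <- match_mwe(g, idiom_inventory)
    for (m in g$matches) {
      if (identical(m$tag, "idiom")) mask[m$positions] <- TRUE
    }
  }
  mask
}
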