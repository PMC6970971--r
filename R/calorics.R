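# Caloric aggregation. C_in and C_out are mention-weighted means:
#   C_in  = sum_w cal(w) f(w) / sum_w f(w)   over unmasked food phrases w,
#   C_out = sum_a cal(a) f(a) / sum_a f(a)   over activity phrases a,
#   C_rat = C_in / C_out,
# so C_rat is a dimensionless intensity ratio comparable across regions of
# different post volume. Undefined quantities (no mentions, zero burn) are
# signalled as NA, never coerced to 0 or Inf.

#' Engine configuration for caloric computation
#'
#' @param reference_weight Reference body weight (kg) at which activity
#'   lexicon values are stated; default 80.7 (average Canadian adult).
#' @param subject_weight Optional subject body weight (kg); when given,
#'   activity burn values are scaled by `subject_weight / reference_weight`.
#' @param min_mentions_per_region Minimum total mentions for a region to be
#'   summarized rather than flagged insufficient.
#' @return An `engine_config` list.
#' @export
engine_config <- function(reference_weight = 80.7, subject_weight = NULL,
                          min_mentions_per_region = 1L) {
  stopifnot(reference_weight > 0, is.null(subject_weight) || subject_weight > 0)
  structure(list(reference_weight = reference_weight,
                 subject_weight = subject_weight,
                 min_mentions_per_region = as.integer(min_mentions_per_region)),
            class = "engine_config")
}

# Count lexicon-phrase mentions across posts. Returns a named integer vector
# (canonical phrase -> count, strictly positive) over alphabetically sorted
# keys. `masks` is an optional list of logical vectors parallel to each
# post's tokens (TRUE = excluded from counting; matches never cross masked
# positions).
count_mentions <- function(posts, lexicon, masks = NULL) {
  keys <- lexicon_keys(lexicon)
  if (!length(keys)) schema_error("empty %s lexicon", lexicon$kind)
  max_len <- max(lengths(strsplit(keys, " ", fixed = TRUE)))
  hits <- character(0)
  for (i in seq_along(posts)) {
    p <- posts[[i]]
    toks <- if (inherits(p, "clean_post")) p$tokens else as.character(p)
    if (!length(toks)) next
    canon <- singularize_tokens(toks)
    blocked <- if (!is.null(masks)) masks[[i]] else logical(length(toks))
    sent <- if (inherits(p, "clean_post")) p$sentence %||% rep(1L, length(toks))
            else rep(1L, length(toks))
    for (pos in split(seq_along(toks), sent)) {
      ms <- greedy_match(canon[pos], keys, max_len = max_len, min_len = 1L,
                         blocked = blocked[pos])
      for (m in ms) hits[length(hits) + 1L] <- m$key
    }
  }
  if (!length(hits)) return(integer(0))
  tab <- table(hits)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(names(counts))]
}

weighted_mention_mean <- function(counts, values) {
  # deterministic reduction over alphabetically sorted keys
  counts <- counts[order(names(counts))]
  v <- values[names(counts)]
  sum(v * counts) / sum(counts)
}

#' Caloric intake from food mentions
#'
#' Counts unmasked food-phrase mentions across the posts and returns the
#' mention-weighted mean caloric value: `C_in = sum(cal(w) f(w)) / sum(f(w))`,
#' with `cal(w)` the lexicon's per-100 g energy (times any serving
#' multiplier).
#'
#' @param posts List of `clean_post` objects (or token vectors).
#' @param food_lexicon A food lexicon.
#' @param masks Optional list of per-post logical masks from
#'   [flag_food_idioms()]; masked tokens are invisible to counting.
#' @return List with `c_in` (kcal; `NA` when there are no food mentions —
#'   undefined, not 0), `table` (named mention counts) and `n_mentions`.
#' @export
caloric_intake <- function(posts, food_lexicon, masks = NULL) {
  stopifnot(food_lexicon$kind == "food")
  counts <- count_mentions(posts, food_lexicon, masks)
  if (!length(counts)) {
    return(list(c_in = NA_real_, table = integer(0), n_mentions = 0L))
  }
  vals <- lexicon_values(food_lexicon)
  list(c_in = weighted_mention_mean(counts, vals), table = counts,
       n_mentions = sum(counts))
}

#' Caloric burn from activity mentions
#'
#' `C_out = sum(cal(a) f(a)) / sum(f(a))` over activity-phrase mentions, with
#' `cal(a)` the lexicon burn value, rescaled by
#' `subject_weight / reference_weight` when a subject weight is configured.
#'
#' @param posts List of `clean_post` objects (or token vectors).
#' @param activity_lexicon An activity lexicon.
#' @param config An [engine_config()].
#' @param masks Optional list of per-post logical masks.
#' @return List with `c_out` (kcal; `NA` when there are no activity
#'   mentions), `table` and `n_mentions`.
#' @export
caloric_burn <- function(posts, activity_lexicon, config = engine_config(),
                         masks = NULL) {
  stopifnot(activity_lexicon$kind == "activity")
  counts <- count_mentions(posts, activity_lexicon, masks)
  if (!length(counts)) {
    return(list(c_out = NA_real_, table = integer(0), n_mentions = 0L))
  }
  vals <- lexicon_values(activity_lexicon)
  if (!is.null(config$subject_weight)) {
    vals <- vals * (config$subject_weight / config$reference_weight)
  }
  list(c_out = weighted_mention_mean(counts, vals), table = counts,
       n_mentions = sum(counts))
}

#' Caloric ratio
#'
#' `C_rat = C_in / C_out`. Values above 1 indicate mention-level caloric
#' consumption exceeding expenditure. Undefined when either input is
#' undefined or `c_out` is 0; the undefined result is `NA`, never 0 or `Inf`.
#'
#' @param c_in,c_out Kcal values (possibly `NA`).
#' @return The exact quotient, or `NA_real_` when undefined.
#' @export
caloric_ratio <- function(c_in, c_out) {
  if (is.na(c_in) || is.na(c_out) || c_out <= 0) return(NA_real_)
  c_in / c_out
}

#' Per-region caloric summaries
#'
#' Partitions posts by region and computes C_in, C_out and C_rat per region
#' independently. Regions whose total mention count falls below
#' `config$min_mentions_per_region` are flagged `insufficient`; regions with
#' no activity (or no food) mentions carry an undefined (`NA`) ratio and a
#' corresponding flag, and are excluded from ratio-based aggregation.
#'
#' @param posts List of `clean_post` objects carrying region codes.
#' @param food_lexicon,activity_lexicon Lexicons.
#' @param idiom_inventory Optional `phrase_inventory`; when given, idiom
#'   masking is applied before food counting.
#' @param config An [engine_config()].
#' @return A `caloric_summary_table`: data frame with columns `region, c_in,
#'   c_out, c_rat, n_food_mentions, n_activity_mentions, flag`, with the
#'   per-region frequency tables in `attr(x, "tables")`.
#' @export
regional_summary <- function(posts, food_lexicon, activity_lexicon,
                             idiom_inventory = NULL,
                             config = engine_config()) {
  regions <- vapply(posts, function(p) p$region %||% NA_character_,
                    character(1))
  by_region <- split(seq_along(posts), regions)
  rows <- list(); tables <- list()
  for (r in sort(names(by_region))) {
    idx <- by_region[[r]]
    sub <- posts[idx]
    masks <- if (!is.null(idiom_inventory)) {
      lapply(sub, flag_food_idioms, idiom_inventory = idiom_inventory)
    } else NULL
    cin <- caloric_intake(sub, food_lexicon, masks)
    cout <- caloric_burn(sub, activity_lexicon, config, masks)
    total <- cin$n_mentions + cout$n_mentions
    flag <- if (total < config$min_mentions_per_region) "insufficient"
            else if (cout$n_mentions == 0L) "no_activity"
            else if (cin$n_mentions == 0L) "no_food"
            else "ok"
    crat <- if (flag == "ok") caloric_ratio(cin$c_in, cout$c_out) else NA_real_
    rows[[r]] <- data.frame(
      region = r, c_in = cin$c_in, c_out = cout$c_out, c_rat = crat,
      n_food_mentions = cin$n_mentions,
      n_activity_mentions = cout$n_mentions, flag = flag,
      stringsAsFactors = FALSE)
    tables[[r]] <- list(food = cin$table, activity = cout$table)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, tables = tables, class = c("caloric_summary_table",
                                            "data.frame"))
}

#' @export
print.caloric_summary_table <- function(x, ...) {
  cat("Per-region caloric summary (C_rat = C_in / C_out; NA = undefined):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Top-k ranking of a frequency table
#'
#' @param table Named mention counts (a `table` element of
#'   [caloric_intake()] / [caloric_burn()] output).
#' @param k Number of entries (>= 1); ties broken lexicographically.
#' @return Data frame with columns `rank`, `phrase`, `count`, of length
#'   `min(k, number of distinct phrases)`.
#' @export
top_k <- function(table, k) {
  stopifnot(k >= 1)
  if (!length(table)) {
    return(data.frame(rank = integer(0), phrase = character(0),
                      count = integer(0)))
  }
  ord <- order(-as.numeric(table), names(table))
  take <- utils::head(ord, k)
  data.frame(rank = seq_along(take), phrase = names(table)[take],
             count = as.integer(table[take]), row.names = NULL)
}

#' Population share above a caloric-ratio threshold
#'
#' `100 * sum(pop(r) for summarized regions r with c_rat(r) >= threshold) /
#' sum(pop(r) over all summarized regions)`. Regions with undefined ratios
#' count toward the denominator only.
#'
#' @param summaries A `caloric_summary_table`, or a named numeric vector of
#'   per-region `c_rat` values.
#' @param populations Named numeric vector (or two-column data frame
#'   `region, population`) of region populations; every summarized region
#'   must have an entry.
#' @param threshold Ratio threshold, default 1.0.
#' @return Percentage in [0, 100].
#' @export
population_share_above <- function(summaries, populations, threshold = 1.0) {
  crat <- if (inherits(summaries, "data.frame")) {
    stats::setNames(summaries$c_rat, summaries$region)
  } else summaries
  if (is.data.frame(populations)) {
    populations <- stats::setNames(populations$population, populations$region)
  }
  missing_pop <- setdiff(names(crat), names(populations))
  if (length(missing_pop)) {
    schema_error("missing population for region(s): %s",
                 paste(missing_pop, collapse = ", "))
  }
  pop <- populations[names(crat)]
  above <- !is.na(crat) & crat >= threshold
  100 * sum(pop[above]) / sum(pop)
}
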