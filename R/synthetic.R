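# Seeded synthetic post corpora with recorded ground truth. The generator
# emulates regional short-post streams: neutral chatter with injected casing,
# stopwords, digits and emoticons, plus food mentions, activity mentions and
# food-word idioms at controlled rates. Ground truth is computed from what
# was actually emitted (the mention log), not from the sampling
# distribution, so recovery tests carry no Monte-Carlo tolerance.

#' Default neutral chatter vocabulary
#'
#' Everyday non-food, non-activity words, chosen disjoint (after
#' canonicalization) from the packaged lexicons and idiom inventory so that
#' chatter never produces accidental mentions.
#'
#' @return Character vector.
#' @export
default_chatter_vocab <- function() .caloscope_chatter

.caloscope_chatter <- c(
  "meeting", "traffic", "weather", "movie", "music", "homework", "deadline",
  "morning", "tonight", "weekend", "budget", "project", "office", "travel",
  "flight", "airport", "hotel", "laptop", "phone", "charger", "battery",
  "update", "software", "garden", "window", "ticket", "concert", "library",
  "lecture", "exam", "assignment", "neighbour", "puppy", "kitten", "sunset",
  "sunrise", "holiday", "birthday", "paycheck", "landlord", "apartment",
  "furniture", "painting", "novel", "podcast", "headphone", "umbrella",
  "snowstorm", "thunder", "sunshine", "parade", "festival", "museum",
  "gallery", "subway", "commute", "carpool", "colleague", "manager",
  "printer", "keyboard", "monitor", "backpack", "wallet", "sweater",
  "jacket", "scarf", "mitten", "shovel", "driveway", "garage", "basement",
  "renovation", "plumber", "electrician", "invoice", "receipt", "warranty",
  "coupon", "lineup", "appointment", "dentist", "haircut", "barber"
)

#' Generator configuration
#'
#' Fully parameterizes the synthetic corpus. Each post is chatter, a food
#' post, or an activity post; with probability `idiom_rate` a food post
#' carries a food-word idiom instead of a true food mention (and is therefore
#' a non-food post with food-looking tokens — the bias the idiom mask
#' removes).
#'
#' @param regions Character vector of region codes (default: the 13 ISO
#'   3166-2:CA provinces and territories).
#' @param posts_per_region Posts per region (>= 0), default 1000.
#' @param food_mix Named probability vector over food phrases (canonical
#'   keys), or a per-region named list of such vectors; `NULL` = uniform over
#'   the food lexicon. Must sum to 1.
#' @param activity_mix As `food_mix`, for activities.
#' @param idiom_rate Probability a food post contains an idiom instead of a
#'   true mention; default 0.1.
#' @param chatter_vocab Neutral token pool.
#' @param label_noise Probability of flipping a post's gold label; default 0.
#' @param seed Integer seed.
#' @param p_food,p_activity Probability a post is a food / activity post
#'   (remainder is pure chatter); defaults 0.45 / 0.35.
#' @param emoticon_rate Probability a post ends with an emoticon; default 0.2.
#' @param digit_rate Probability a post contains a number token; default 0.15.
#' @param separable If `TRUE`, food and non-food posts draw chatter from
#'   disjoint halves of `chatter_vocab`, making the class vocabularies
#'   disjoint (the separable classification benchmark); default `FALSE`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(regions = paste0("CA-", c("ON", "QC", "BC", "AB",
                                                       "MB", "SK", "NS", "NB",
                                                       "NL", "PE", "YT", "NT",
                                                       "NU")),
                             posts_per_region = 1000L,
                             food_mix = NULL, activity_mix = NULL,
                             idiom_rate = 0.1,
                             chatter_vocab = default_chatter_vocab(),
                             label_noise = 0, seed = 1L,
                             p_food = 0.45, p_activity = 0.35,
                             emoticon_rate = 0.2, digit_rate = 0.15,
                             separable = FALSE) {
  stopifnot(posts_per_region >= 0,
            idiom_rate >= 0, idiom_rate <= 1,
            label_noise >= 0, label_noise <= 1,
            p_food >= 0, p_activity >= 0, p_food + p_activity <= 1,
            emoticon_rate >= 0, emoticon_rate <= 1)
  check_mix <- function(mix, what) {
    if (is.null(mix)) return(invisible())
    vecs <- if (is.list(mix)) mix else list(mix)
    for (v in vecs) {
      stopifnot(is.numeric(v), !is.null(names(v)), all(v >= 0), all(v <= 1))
      if (abs(sum(v) - 1) > 1e-8) {
        schema_error("%s probabilities must sum to 1", what)
      }
    }
  }
  check_mix(food_mix, "food_mix"); check_mix(activity_mix, "activity_mix")
  structure(list(regions = regions,
                 posts_per_region = as.integer(posts_per_region),
                 food_mix = food_mix, activity_mix = activity_mix,
                 idiom_rate = idiom_rate, chatter_vocab = chatter_vocab,
                 label_noise = label_noise, seed = as.integer(seed),
                 p_food = p_food, p_activity = p_activity,
                 emoticon_rate = emoticon_rate, digit_rate = digit_rate,
                 separable = isTRUE(separable)),
            class = "generator_config")
}

region_mix <- function(mix, region, keys) {
  if (is.null(mix)) {
    return(stats::setNames(rep(1 / length(keys), length(keys)), keys))
  }
  v <- if (is.list(mix)) mix[[region]] else mix
  if (is.null(v)) schema_error("no mix for region %s", region)
  v
}

capitalize <- function(w) {
  paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
}

# Per-region summary from a mention log, reduced over alphabetically sorted
# keys — the same deterministic reduction caloric_intake/caloric_burn use.
#' Recompute per-region caloric truth from a mention log
#'
#' @param mention_log Data frame with columns `region`, `kind`
#'   ("food"/"activity"), `key` (canonical phrase).
#' @param regions Regions to summarize (defaults to those in the log).
#' @param food_lexicon,activity_lexicon Lexicons supplying caloric values.
#' @return Data frame `region, c_in, c_out, c_rat, n_food_mentions,
#'   n_activity_mentions` (NA where undefined).
#' @export
truth_from_mentions <- function(mention_log, food_lexicon, activity_lexicon,
                                regions = sort(unique(mention_log$region))) {
  fv <- lexicon_values(food_lexicon)
  av <- lexicon_values(activity_lexicon)
  rows <- lapply(regions, function(r) {
    sub <- mention_log[mention_log$region == r, , drop = FALSE]
    fcount <- table(sub$key[sub$kind == "food"])
    acount <- table(sub$key[sub$kind == "activity"])
    cin <- if (length(fcount)) {
      weighted_mention_mean(stats::setNames(as.integer(fcount), names(fcount)), fv)
    } else NA_real_
    cout <- if (length(acount)) {
      weighted_mention_mean(stats::setNames(as.integer(acount), names(acount)), av)
    } else NA_real_
    data.frame(region = r, c_in = cin, c_out = cout,
               c_rat = caloric_ratio(cin, cout),
               n_food_mentions = sum(fcount),
               n_activity_mentions = sum(acount),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic corpus with recorded ground truth
#'
#' Deterministic given `config$seed`. Posts are assembled as chatter with
#' natural casing, injected stopwords, digits and emoticons (so the cleaning
#' pipeline is exercised), plus sampled food mentions, activity mentions and
#' food-word idioms. Emoticons whose textual names contain lexicon words are
#' never injected as noise.
#'
#' @param config A [generator_config()].
#' @param food_lexicon,activity_lexicon Lexicons the mixes refer to.
#' @param idiom_inventory A `phrase_inventory`; idiom-tagged entries are
#'   sampled for idiom posts.
#' @return List with `posts` (data frame `id, text, region, timestamp`) and
#'   `truth` (a `ground_truth`: per-region summary computed from the emitted
#'   mention log, per-post gold `labels`, and the `mention_log` itself).
#' @export
generate_corpus <- function(config = generator_config(),
                            food_lexicon = default_food_lexicon(),
                            activity_lexicon = default_activity_lexicon(),
                            idiom_inventory = default_idiom_inventory()) {
  fkeys <- lexicon_keys(food_lexicon)
  akeys <- lexicon_keys(activity_lexicon)
  for (r in config$regions) {
    fm <- region_mix(config$food_mix, r, fkeys)
    am <- region_mix(config$activity_mix, r, akeys)
    unknown <- c(setdiff(names(fm), fkeys), setdiff(names(am), akeys))
    if (length(unknown)) {
      schema_error("mix references unknown phrase(s): %s",
                   paste(unique(unknown), collapse = ", "))
    }
  }
  idioms <- idiom_inventory$raw[idiom_inventory$tags == "idiom"]
  # emoticons safe to inject: names free of lexicon and idiom-form tokens,
  # so injected noise can never create or destroy a phrase match
  lex_toks <- unique(unlist(strsplit(c(fkeys, akeys, idiom_inventory$forms),
                                     " ", fixed = TRUE)))
  emo_ok <- vapply(.caloscope_emoticons, function(nm) {
    !any(singularize_tokens(clean_sentence_tokens(to_lowercase(nm))) %in% lex_toks)
  }, logical(1))
  emo_pool <- names(.caloscope_emoticons)[emo_ok]

  set.seed(config$seed)
  n_total <- length(config$regions) * config$posts_per_region
  ids <- character(n_total); texts <- character(n_total)
  regs <- character(n_total); labels <- character(n_total)
  log_region <- character(n_total); log_kind <- character(n_total)
  log_key <- character(n_total); log_id <- character(n_total)
  n_log <- 0L; k <- 0L
  stop_fill <- c("the", "some", "my", "a")
  half <- length(config$chatter_vocab) %/% 2L
  pool_food <- if (config$separable) config$chatter_vocab[seq_len(half)]
               else config$chatter_vocab
  pool_other <- if (config$separable) {
    config$chatter_vocab[(half + 1L):length(config$chatter_vocab)]
  } else config$chatter_vocab
  for (r in config$regions) {
    fm <- region_mix(config$food_mix, r, fkeys)
    am <- region_mix(config$activity_mix, r, akeys)
    for (i in seq_len(config$posts_per_region)) {
      k <- k + 1L
      id <- sprintf("%s-%06d", r, i)
      u <- stats::runif(1)
      label <- "non-food"
      insertion <- NULL
      is_true_food <- u < config$p_food &&
        !(stats::runif(1) < config$idiom_rate && length(idioms))
      words <- sample(if (is_true_food) pool_food else pool_other,
                      sample(3:8, 1), replace = TRUE)
      if (u < config$p_food) {
        if (!is_true_food) {
          insertion <- sample(idioms, 1)
        } else {
          key <- sample(names(fm), 1, prob = fm)
          insertion <- key
          label <- "food"
          n_log <- n_log + 1L
          log_region[n_log] <- r; log_kind[n_log] <- "food"
          log_key[n_log] <- key; log_id[n_log] <- id
        }
      } else if (u < config$p_food + config$p_activity) {
        key <- sample(names(am), 1, prob = am)
        insertion <- key
        n_log <- n_log + 1L
        log_region[n_log] <- r; log_kind[n_log] <- "activity"
        log_key[n_log] <- key; log_id[n_log] <- id
      }
      if (!is.null(insertion)) {
        if (stats::runif(1) < 0.3) {
          insertion <- paste(sample(stop_fill, 1), insertion)
        }
        pos <- sample(0:length(words), 1)
        words <- append(words, insertion, after = pos)
      }
      if (stats::runif(1) < config$digit_rate) {
        words <- append(words, as.character(sample(1:2019, 1)),
                        after = sample(0:length(words), 1))
      }
      words[1] <- capitalize(words[1])
      if (stats::runif(1) < 0.1) {
        j <- sample(seq_along(words), 1)
        words[j] <- toupper(words[j])
      }
      text <- paste(words, collapse = " ")
      if (length(emo_pool) && stats::runif(1) < config$emoticon_rate) {
        text <- paste(text, sample(emo_pool, 1))
      }
      if (config$label_noise > 0 && stats::runif(1) < config$label_noise) {
        label <- setdiff(c("food", "non-food"), label)
      }
      ids[k] <- id; texts[k] <- text; regs[k] <- r; labels[k] <- label
    }
  }
  mention_log <- data.frame(id = log_id[seq_len(n_log)],
                            region = log_region[seq_len(n_log)],
                            kind = log_kind[seq_len(n_log)],
                            key = log_key[seq_len(n_log)],
                            stringsAsFactors = FALSE)
  truth <- structure(list(
    summary = truth_from_mentions(mention_log, food_lexicon,
                                  activity_lexicon,
                                  regions = sort(config$regions)),
    labels = data.frame(id = ids, label = labels, stringsAsFactors = FALSE),
    mention_log = mention_log), class = "ground_truth")
  posts <- data.frame(
    id = ids, text = texts, region = regs,
    timestamp = sprintf("2018-01-01T%02d:%02d:%02dZ",
                        (seq_len(n_total) %/% 3600L) %% 24L,
                        (seq_len(n_total) %/% 60L) %% 60L,
                        seq_len(n_total) %% 60L),
    stringsAsFactors = FALSE)
  list(posts = posts, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground truth: %d mentions, %d posts>\n",
              nrow(x$mention_log), nrow(x$labels)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Verify stored ground truth against brute-force recomputation
#'
#' Recomputes every per-region C_in / C_out / C_rat from the mention log and
#' compares with the stored summary. Freshly generated corpora verify by
#' construction; any perturbed count or value does not.
#'
#' @param truth A `ground_truth`.
#' @param food_lexicon,activity_lexicon The lexicons used at generation.
#' @return `TRUE` iff the stored truths equal the recomputation (NA patterns
#'   included).
#' @export
verify_truth <- function(truth, food_lexicon = default_food_lexicon(),
                         activity_lexicon = default_activity_lexicon()) {
  ref <- truth_from_mentions(truth$mention_log, food_lexicon,
                             activity_lexicon,
                             regions = truth$summary$region)
  isTRUE(all.equal(ref, as.data.frame(truth$summary), tolerance = 0))
}
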