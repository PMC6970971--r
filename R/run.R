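# Pipeline interface: file formats, reproducible run commands and manifests.
# Posts travel as JSON-lines {id, text, region, timestamp} (CSV with the
# same header is also accepted); cleaned posts as JSON-lines
# {id, region, tokens}.

config_hash <- function(x) {
  # 31-bit polynomial rolling hash over the UTF-8 bytes, as 8 hex digits
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a posts file
#'
#' Accepts JSON-lines (one object per line with keys `id`, `text`, `region`,
#' optional `timestamp`) or CSV with the same header. Malformed JSON lines
#' and records without an id are skipped with a logged message.
#'
#' @param path Input file.
#' @return Data frame `id, text, region, timestamp`; the number of skipped
#'   records is in `attr(x, "skipped")`.
#' @export
read_posts <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    missing_cols <- setdiff(c("id", "text", "region"), names(df))
    if (length(missing_cols)) {
      schema_error("posts CSV is missing column(s): %s",
                   paste(missing_cols, collapse = ", "))
    }
    if (!"timestamp" %in% names(df)) df$timestamp <- NA_character_
    return(structure(df[c("id", "text", "region", "timestamp")], skipped = 0L))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  skipped <- 0L
  for (i in seq_along(lines)) {
    r <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    if (is.null(r) || is.null(r$id) || is.null(r$text)) {
      skipped <- skipped + 1L
      message(sprintf("read_posts: skipping malformed record at line %d", i))
      next
    }
    recs[[i]] <- data.frame(id = as.character(r$id),
                            text = as.character(r$text),
                            region = as.character(r$region %||% NA_character_),
                            timestamp = as.character(r$timestamp %||% NA_character_),
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(df)) {
    df <- data.frame(id = character(0), text = character(0),
                     region = character(0), timestamp = character(0))
  }
  structure(df, skipped = skipped)
}

#' Write posts as JSON-lines
#'
#' @param posts Data frame with `id`, `text`, `region` (and optionally
#'   `timestamp`).
#' @param path Output file.
#' @export
write_posts_jsonl <- function(posts, path) {
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    jsonlite::toJSON(list(id = posts$id[i], text = posts$text[i],
                          region = posts$region[i],
                          timestamp = posts$timestamp[i] %||% NA_character_),
                     auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

write_manifest <- function(dir, command, config, seed) {
  cfg_json <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                            null = "null", digits = NA))
  manifest <- list(
    tool = "caloscope",
    version = as.character(utils::packageVersion("caloscope")),
    command = command,
    seed = seed,
    config = config,
    config_hash = config_hash(cfg_json),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(dir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Clean a posts file
#'
#' Streams posts through the cleaning pipeline and writes JSON-lines
#' `{id, region, tokens}`. Malformed input records are skipped with a logged
#' id; counts are reported.
#'
#' @param posts_path Input posts file (JSON-lines or CSV).
#' @param out Output JSON-lines file.
#' @return Invisibly, a list with `n_in`, `n_out`, `n_skipped`.
#' @export
run_clean <- function(posts_path, out) {
  posts <- read_posts(posts_path)
  cleaned <- clean_posts(posts)
  lines <- vapply(cleaned, function(p) {
    as.character(jsonlite::toJSON(list(id = p$id, region = p$region,
                                       tokens = p$tokens),
                                  auto_unbox = TRUE, na = "null"))
  }, character(1))
  writeLines(lines, out, useBytes = TRUE)
  message(sprintf("run_clean: %d posts in, %d out, %d skipped",
                  nrow(posts) + attr(posts, "skipped"), length(cleaned),
                  attr(posts, "skipped")))
  invisible(list(n_in = nrow(posts) + attr(posts, "skipped"),
                 n_out = length(cleaned), n_skipped = attr(posts, "skipped")))
}

#' Read cleaned posts from JSON-lines
#'
#' @param path JSON-lines file written by [run_clean()].
#' @return List of `clean_post` objects (each a single span).
#' @export
read_clean_posts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(lines[nzchar(lines)], function(l) {
    r <- jsonlite::fromJSON(l)
    toks <- as.character(r$tokens)
    structure(list(id = as.character(r$id), region = as.character(r$region),
                   tokens = toks, sentence = rep(1L, length(toks))),
              class = "clean_post")
  })
}

# Feature inventory for classification: idioms plus multiword lexicon forms,
# so phrases enter tf-idf as single features.
combined_feature_inventory <- function(idiom_inventory, food_lexicon = NULL,
                                       activity_lexicon = NULL) {
  phrases <- idiom_inventory$raw
  tags <- idiom_inventory$tags
  for (lex in list(food_lexicon, activity_lexicon)) {
    if (is.null(lex)) next
    multi <- lexicon_keys(lex)[grepl(" ", lexicon_keys(lex))]
    phrases <- c(phrases, multi)
    tags <- c(tags, rep("compound", length(multi)))
  }
  phrase_inventory(phrases, tags)
}

#' Train a classifier from a posts file with weak-supervision labels
#'
#' Cleans the posts, derives weak labels from the food lexicon (idiom-masked
#' tokens do not count), builds tf-idf features with phrases as single
#' features, trains the classifier and saves a versioned model artifact with
#' an embedded feature-spec manifest (JSON).
#'
#' @param posts_path Input posts file.
#' @param model_out Output model artifact path (.rds).
#' @param kind Classifier kind: `"nb"`, `"lr"`, `"rf"`, `"svm"`.
#' @param seed Integer seed.
#' @param food_lexicon,activity_lexicon,idiom_inventory Pipeline resources.
#' @param labels Optional gold labels (data frame `id, label`) overriding the
#'   weak-supervision labels.
#' @return Invisibly, the trained `food_classifier`.
#' @export
run_train <- function(posts_path, model_out, kind = "rf", seed = 1L,
                      food_lexicon = default_food_lexicon(),
                      activity_lexicon = default_activity_lexicon(),
                      idiom_inventory = default_idiom_inventory(),
                      labels = NULL) {
  posts <- read_posts(posts_path)
  cleaned <- clean_posts(posts)
  inv <- combined_feature_inventory(idiom_inventory, food_lexicon,
                                    activity_lexicon)
  if (is.null(labels)) {
    masks <- lapply(cleaned, flag_food_idioms, idiom_inventory = idiom_inventory)
    y <- weak_labels(cleaned, food_lexicon, masks)
  } else {
    y <- factor(labels$label[match(posts$id, labels$id)], levels = CLASS_LEVELS)
  }
  feats <- build_features(cleaned, inv)
  model <- food_classifier(kind, feats$x, y, seed = seed)
  artifact <- list(
    format_version = 1L,
    kind = kind, seed = seed,
    model = model,
    feature_spec = feats$spec,
    feature_spec_json = as.character(
      jsonlite::toJSON(feats$spec[c("vocabulary", "idf", "norm")],
                       auto_unbox = TRUE, digits = NA)),
    inventory = inv)
  saveRDS(artifact, model_out)
  write_manifest(dirname(model_out), "train",
                 list(posts = posts_path, kind = kind), seed)
  invisible(model)
}

#' Classify a posts file with a saved model
#'
#' @param model_path Model artifact from [run_train()].
#' @param posts_path Input posts file.
#' @param out Output JSON-lines file `{id, label}`.
#' @return Invisibly, the predicted labels (factor).
#' @export
run_classify <- function(model_path, posts_path, out) {
  if (!file.exists(model_path)) {
    schema_error("model artifact not found: %s", model_path)
  }
  artifact <- readRDS(model_path)
  posts <- read_posts(posts_path)
  cleaned <- clean_posts(posts)
  feats <- build_features(cleaned, artifact$inventory,
                          spec = artifact$feature_spec)
  pred <- predict(artifact$model, feats$x)
  lines <- vapply(seq_along(cleaned), function(i) {
    as.character(jsonlite::toJSON(list(id = cleaned[[i]]$id,
                                       label = as.character(pred[i])),
                                  auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, out, useBytes = TRUE)
  write_manifest(dirname(out), "classify",
                 list(model = model_path, posts = posts_path),
                 artifact$seed)
  invisible(pred)
}

#' Compute caloric summaries, rankings and population share from a posts file
#'
#' Runs [regional_summary()], [top_k()] and (when populations are supplied)
#' [population_share_above()], writing `summary.csv`, `ranking_food.csv`,
#' `ranking_activity.csv` and `population_share.json` under `out_dir`.
#'
#' @param posts_path Input posts file.
#' @param out_dir Output directory (created if needed).
#' @param food_lexicon,activity_lexicon,idiom_inventory Pipeline resources.
#' @param populations Optional named vector or data frame
#'   (`region, population`).
#' @param config An [engine_config()].
#' @param k Ranking depth (default 10).
#' @param threshold Ratio threshold for the population share (default 1.0).
#' @param idiom_mask Apply idiom masking (default TRUE; disable for
#'   bias-demonstration runs).
#' @param seed Seed recorded in the manifest (the computation itself is
#'   deterministic).
#' @return Invisibly, a list with the summary table, rankings and share.
#' @export
run_calories <- function(posts_path, out_dir,
                         food_lexicon = default_food_lexicon(),
                         activity_lexicon = default_activity_lexicon(),
                         idiom_inventory = default_idiom_inventory(),
                         populations = NULL,
                         config = engine_config(), k = 10,
                         threshold = 1.0, idiom_mask = TRUE, seed = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  posts <- read_posts(posts_path)
  cleaned <- clean_posts(posts)
  summ <- regional_summary(cleaned, food_lexicon, activity_lexicon,
                           idiom_inventory = if (idiom_mask) idiom_inventory,
                           config = config)
  utils::write.csv(as.data.frame(summ), file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  tables <- attr(summ, "tables")
  pool <- function(kind) {
    keys <- unlist(lapply(tables, function(t) names(t[[kind]])),
                   use.names = FALSE)
    vals <- unlist(lapply(tables, function(t) unname(t[[kind]])),
                   use.names = FALSE)
    if (!length(keys)) return(integer(0))
    tapply(vals, keys, sum)
  }
  rk_food <- top_k(pool("food"), k)
  rk_act <- top_k(pool("activity"), k)
  utils::write.csv(rk_food, file.path(out_dir, "ranking_food.csv"),
                   row.names = FALSE)
  utils::write.csv(rk_act, file.path(out_dir, "ranking_activity.csv"),
                   row.names = FALSE)
  share <- NULL
  if (!is.null(populations)) {
    share <- population_share_above(summ, populations, threshold)
    jsonlite::write_json(
      list(threshold = threshold, population_share_percent = share),
      file.path(out_dir, "population_share.json"), auto_unbox = TRUE,
      digits = NA)
  }
  write_manifest(out_dir, "calories",
                 list(posts = posts_path, idiom_mask = idiom_mask,
                      reference_weight = config$reference_weight,
                      min_mentions = config$min_mentions_per_region,
                      threshold = threshold), seed)
  invisible(list(summary = summ, ranking_food = rk_food,
                 ranking_activity = rk_act, population_share = share))
}

#' Generate a synthetic corpus to disk
#'
#' Writes `posts.jsonl` (the pipeline's input format) and `truth.json`
#' (per-region ground truth, gold labels and the mention log) under
#' `out_dir`.
#'
#' @param out_dir Output directory.
#' @param config A [generator_config()].
#' @param food_lexicon,activity_lexicon,idiom_inventory Generation resources.
#' @return Invisibly, the [generate_corpus()] result.
#' @export
run_simulate <- function(out_dir, config = generator_config(),
                         food_lexicon = default_food_lexicon(),
                         activity_lexicon = default_activity_lexicon(),
                         idiom_inventory = default_idiom_inventory()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_corpus(config, food_lexicon, activity_lexicon,
                         idiom_inventory)
  write_posts_jsonl(sim$posts, file.path(out_dir, "posts.jsonl"))
  jsonlite::write_json(
    list(summary = sim$truth$summary, labels = sim$truth$labels,
         mention_log = sim$truth$mention_log),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  write_manifest(out_dir, "simulate",
                 config[setdiff(names(config), "chatter_vocab")],
                 config$seed)
  invisible(sim)
}
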