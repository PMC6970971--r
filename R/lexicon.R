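# Food and activity lexicons. Keys are canonicalized with the same
# normalization applied to posts (lowercase, stopword-free, singularized) so
# that lexicon lookup after cleaning is a fixed point.

# Match-time plural stripping: drop a trailing "s", with the -es ending
# handled for stems where English adds "es" (potatoes -> potato,
# dishes -> dish, glasses -> glass). Words ending in "ss" alone are kept.
singularize_tokens <- function(tokens) {
  out <- tokens
  es <- grepl("(o|x|ch|sh|ss)es$", out)
  out[es] <- sub("es$", "", out[es])
  plain <- !es & grepl("[^s]s$", out)
  out[plain] <- sub("s$", "", out[plain])
  ifelse(nzchar(out), out, tokens)
}

#' Canonical phrase key
#'
#' Applies the cleaning pipeline's token-level steps (lowercasing,
#' tokenization, stopword removal, special-character and number stripping) plus
#' trailing-"s" singularization, and joins the result with single spaces.
#' Canonicalization is a fixed point: keys round-trip through cleaning
#' unchanged.
#'
#' @param phrase Character vector of phrases.
#' @return Character vector of canonical keys ("" if nothing survives).
#' @export
canonical_key <- function(phrase) {
  vapply(phrase, function(p) {
    if (is.na(p)) return("")
    toks <- clean_sentence_tokens(to_lowercase(stringi::stri_trans_nfkc(p)))
    paste(singularize_tokens(toks), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

infer_category <- function(key) {
  toks <- strsplit(key, " ", fixed = TRUE)[[1]]
  if (any(toks %in% .caloscope_juices)) return("juice")
  if (any(toks %in% .caloscope_fruits)) return("fruit")
  if (any(toks %in% .caloscope_vegetables)) return("vegetable")
  "other"
}

#' Vegan / non-vegan rule
#'
#' A food entry is vegan iff the token "vegan" appears in its name, or its
#' category is one of vegetable, fruit or juice. Any other food is non-vegan.
#'
#' @param entry A food entry (element of a food lexicon), or a list with
#'   `food_name` and optional `category`.
#' @return Logical scalar.
#' @export
classify_vegan <- function(entry) {
  toks <- strsplit(canonical_key(entry$food_name), " ", fixed = TRUE)[[1]]
  cat <- entry$category %||% "other"
  ("vegan" %in% toks) || (cat %in% c("vegetable", "fruit", "juice"))
}

new_lexicon <- function(entries, kind, rejected = 0L) {
  structure(list(kind = kind, entries = entries),
            rejected = rejected, class = "caloscope_lexicon")
}

#' @export
print.caloscope_lexicon <- function(x, ...) {
  cat(sprintf("<%s lexicon: %d entries>\n", x$kind, length(x$entries)))
  invisible(x)
}

#' @export
length.caloscope_lexicon <- function(x) length(x$entries)

#' Lexicon keys and per-mention caloric values
#'
#' @param lexicon A lexicon from [load_food_lexicon()] or
#'   [load_activity_lexicon()].
#' @return For `lexicon_values`, a named numeric vector of kcal per mention
#'   (food: `energy_100g` times the serving multiplier; activity:
#'   `caloric_value`); for `lexicon_keys`, the canonical keys.
#' @export
lexicon_values <- function(lexicon) {
  if (lexicon$kind == "food") {
    vapply(lexicon$entries,
           function(e) e$energy_100g * (e$serving_multiplier %||% 1),
           numeric(1))
  } else {
    vapply(lexicon$entries, function(e) e$caloric_value, numeric(1))
  }
}

#' @rdname lexicon_values
#' @export
lexicon_keys <- function(lexicon) names(lexicon$entries)

#' Load a food lexicon
#'
#' Reads a CSV with columns `food_name, food_ingredients, fat_100g,
#' energy_100g, carbohydrate_100g` and optional `category` (one of vegetable,
#' fruit, juice, other) and `serving_multiplier`. Names are canonicalized;
#' rows with missing, non-finite or negative nutrients are rejected with a
#' logged reason; duplicate canonical names are merged by the arithmetic mean
#' of each nutrient (with a warning). When no category column is given, the
#' category is inferred from packaged vegetable/fruit/juice keyword lists — an
#' approximation of curated labels. The vegan flag is always derived via
#' [classify_vegan()], never read from the file.
#'
#' @param path Path to the CSV file, or a data frame with the same columns.
#' @return A food lexicon (class `caloscope_lexicon`); the number of rejected
#'   rows is available as `attr(x, "rejected")`.
#' @export
load_food_lexicon <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("food_name", "food_ingredients", "fat_100g", "energy_100g",
                "carbohydrate_100g")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    schema_error("food lexicon is missing required column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  nutr <- c("fat_100g", "energy_100g", "carbohydrate_100g")
  for (f in nutr) df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  if ("serving_multiplier" %in% names(df)) {
    df$serving_multiplier <- suppressWarnings(as.numeric(df$serving_multiplier))
  } else df$serving_multiplier <- 1
  keys <- canonical_key(df$food_name)
  ok <- nzchar(keys)
  for (f in c(nutr, "serving_multiplier")) {
    ok <- ok & is.finite(df[[f]]) & df[[f]] >= 0
  }
  n_rej <- sum(!ok)
  if (n_rej > 0) {
    message(sprintf("load_food_lexicon: rejected %d row(s) with empty names or invalid nutrients", n_rej))
  }
  df <- df[ok, , drop = FALSE]; keys <- keys[ok]
  if (anyDuplicated(keys)) {
    warning("duplicate food names merged by arithmetic mean of nutrients")
  }
  entries <- list()
  for (k in unique(keys)) {
    rows <- df[keys == k, , drop = FALSE]
    cat <- if ("category" %in% names(df)) {
      cats <- rows$category[rows$category %in% c("vegetable", "fruit", "juice")]
      if (length(cats)) cats[[1]] else "other"
    } else infer_category(k)
    ing <- unique(unlist(lapply(strsplit(rows$food_ingredients, ";"), function(s) {
      s <- canonical_key(s); s[nzchar(s)]
    })))
    e <- list(
      food_name = k,
      food_ingredients = ing %||% character(0),
      fat_100g = mean(rows$fat_100g),
      energy_100g = mean(rows$energy_100g),
      carbohydrate_100g = mean(rows$carbohydrate_100g),
      serving_multiplier = mean(rows$serving_multiplier),
      category = cat
    )
    e$is_vegan <- classify_vegan(e)
    entries[[k]] <- e
  }
  new_lexicon(entries, "food", rejected = n_rej)
}

#' Load an activity lexicon
#'
#' Reads a CSV with columns `activity_name, caloric_value` (kcal burned per
#' mention at the reference body weight). Rows with non-numeric, non-finite or
#' negative caloric values are rejected; duplicate canonical names are merged
#' by arithmetic mean.
#'
#' @param path Path to the CSV file, or a data frame with the same columns.
#' @return An activity lexicon (class `caloscope_lexicon`).
#' @export
load_activity_lexicon <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(c("activity_name", "caloric_value"), names(df))
  if (length(missing_cols)) {
    schema_error("activity lexicon is missing required column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("activity lexicon file has a header but no rows")
    return(new_lexicon(list(), "activity"))
  }
  vals <- suppressWarnings(as.numeric(df$caloric_value))
  keys <- canonical_key(df$activity_name)
  ok <- nzchar(keys) & is.finite(vals) & vals >= 0
  n_rej <- sum(!ok)
  if (n_rej > 0) {
    message(sprintf("load_activity_lexicon: rejected %d row(s)", n_rej))
  }
  keys <- keys[ok]; vals <- vals[ok]
  if (anyDuplicated(keys)) {
    warning("duplicate activity names merged by arithmetic mean")
  }
  entries <- lapply(split(vals, keys)[unique(keys)], function(v) {
    list(caloric_value = mean(v))
  })
  for (k in names(entries)) entries[[k]]$activity_name <- k
  new_lexicon(entries, "activity", rejected = n_rej)
}

#' Nutrient density profile of a food lexicon
#'
#' Normalized Gaussian kernel density estimate of one nutrient across the
#' lexicon, optionally split into vegan and non-vegan groups. Bandwidth is
#' Scott's rule (`stats::bw.nrd`); the density is evaluated on a 512-point
#' grid spanning `[min - 3h, max + 3h]`. Each returned curve integrates to 1.
#'
#' @param lexicon A food lexicon.
#' @param field One of `"fat_100g"`, `"energy_100g"`, `"carbohydrate_100g"`.
#' @param split_vegan If `TRUE`, estimate separate densities for vegan and
#'   non-vegan entries (plus the pooled "all" group).
#' @return Data frame with columns `group`, `grid_value`, `density`.
#' @export
nutrient_profile <- function(lexicon, field = c("fat_100g", "energy_100g",
                                                "carbohydrate_100g"),
                             split_vegan = FALSE) {
  stopifnot(inherits(lexicon, "caloscope_lexicon"), lexicon$kind == "food")
  field <- match.arg(field)
  vals <- vapply(lexicon$entries, function(e) e[[field]], numeric(1))
  vegan <- vapply(lexicon$entries, function(e) isTRUE(e$is_vegan), logical(1))
  groups <- list(all = vals)
  if (split_vegan) {
    if (!any(vegan) || all(vegan)) {
      warning("one vegan split group is empty; returning the pooled profile only")
    } else {
      groups$vegan <- vals[vegan]
      groups$`non-vegan` <- vals[!vegan]
    }
  }
  out <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (length(x) < 2) {
      undefined_result_error("nutrient_profile: group '%s' has fewer than 2 values", g)
    }
    bw <- if (stats::sd(x) > 0) stats::bw.nrd(x) else max(abs(x[1]), 1) * 1e-3
    d <- stats::density(x, bw = bw, kernel = "gaussian", n = 512, cut = 3)
    # renormalize on the evaluation grid (trapezoid) so the curve integrates
    # to 1 exactly on the stated support
    dx <- diff(d$x)
    area <- sum(dx * (utils::head(d$y, -1) + utils::tail(d$y, -1)) / 2)
    data.frame(group = g, grid_value = d$x, density = d$y / area)
  })
  do.call(rbind, out)
}
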