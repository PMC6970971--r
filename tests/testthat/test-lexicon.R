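# Lexicon loading, the vegan rule, and nutrient density profiles.

test_that("a well-formed food row loads with a canonical key", {
  lex <- load_food_lexicon(data.frame(
    food_name = "coffee", food_ingredients = "coffee",
    fat_100g = 0, energy_100g = 1, carbohydrate_100g = 0,
    stringsAsFactors = FALSE))
  expect_length(lex, 1)
  expect_equal(lexicon_keys(lex), "coffee")
  expect_equal(lex$entries$coffee$energy_100g, 1)
})

test_that("rows with negative nutrients are rejected and counted", {
  df <- data.frame(
    food_name = c("tea", "badfood"), food_ingredients = c("tea", "x"),
    fat_100g = c(0, 1), energy_100g = c(1, -5), carbohydrate_100g = c(0, 1),
    stringsAsFactors = FALSE)
  expect_message(lex <- load_food_lexicon(df), "rejected 1 row")
  expect_length(lex, 1)
  expect_equal(attr(lex, "rejected"), 1L)
})

test_that("duplicate food names merge by arithmetic mean with a warning", {
  df <- data.frame(
    food_name = c("pizza", "pizza"), food_ingredients = c("dough", "dough"),
    fat_100g = c(10, 12), energy_100g = c(250, 270),
    carbohydrate_100g = c(30, 34), stringsAsFactors = FALSE)
  expect_warning(lex <- load_food_lexicon(df), "merged")
  expect_length(lex, 1)
  expect_equal(lex$entries$pizza$energy_100g, 260)
  expect_equal(lex$entries$pizza$fat_100g, 11)
})

test_that("missing required columns raise a schema error naming them", {
  df <- data.frame(food_name = "x", fat_100g = 1, stringsAsFactors = FALSE)
  err <- tryCatch(load_food_lexicon(df), error = identity)
  expect_s3_class(err, "caloscope_schema_error")
  expect_match(conditionMessage(err), "energy_100g")
})

test_that("activity lexicon loads, warns on empty file, rejects non-numeric", {
  lex <- load_activity_lexicon(data.frame(
    activity_name = "running", caloric_value = "600",
    stringsAsFactors = FALSE))
  expect_equal(lex$entries$running$caloric_value, 600)

  empty <- tempfile(fileext = ".csv")
  writeLines("activity_name,caloric_value", empty)
  expect_warning(lex0 <- load_activity_lexicon(empty), "no rows")
  expect_length(lex0, 0)

  lex2 <- load_activity_lexicon(data.frame(
    activity_name = c("walking", "running"), caloric_value = c(200, 600),
    stringsAsFactors = FALSE))
  expect_length(lex2, 2)
  expect_message(
    lex3 <- load_activity_lexicon(data.frame(
      activity_name = c("walking", "odd"), caloric_value = c("200", "abc"),
      stringsAsFactors = FALSE)),
    "rejected 1")
  expect_equal(lexicon_keys(lex3), "walking")
})

test_that("the vegan rule matches the two-clause definition exhaustively", {
  fixture <- data.frame(
    name = c("vegan burger", "Vegan Chili", "orange juice", "apple",
             "sweet potatoes", "chicken masala", "bacon", "vegan"),
    category = c("other", "other", "juice", "fruit", "vegetable", "other",
                 "other", "other"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(fixture))) {
    entry <- list(food_name = fixture$name[i], category = fixture$category[i])
    # two-clause rule evaluated by hand: "vegan" in the name, or category
    # in {vegetable, fruit, juice}; otherwise non-vegan
    by_hand <- grepl("vegan", tolower(fixture$name[i])) ||
      fixture$category[i] %in% c("vegetable", "fruit", "juice")
    expect_identical(classify_vegan(entry), by_hand, label = fixture$name[i])
  }
})

test_that("loading a lexicon twice yields identical entries (idempotent merge)", {
  p <- write_food_csv(tiny_food_df())
  a <- load_food_lexicon(p)
  b <- load_food_lexicon(p)
  expect_identical(a$entries, b$entries)
})

test_that("lexicon keys are fixed points of canonicalization and cleaning", {
  for (lex in list(default_food_lexicon(), default_activity_lexicon())) {
    for (k in lexicon_keys(lex)) {
      expect_identical(canonical_key(k), k, label = k)
      cleaned <- as.character(clean_text(k))
      expect_identical(
        paste(caloscope:::singularize_tokens(cleaned), collapse = " "), k,
        label = paste("clean round-trip:", k))
    }
  }
})

test_that("nutrient densities integrate to 1 on their grid", {
  set.seed(91)
  nm <- paste0("food", apply(expand.grid(letters[1:10], letters[1:10]), 1,
                             paste0, collapse = ""))
  df <- data.frame(
    food_name = nm,
    food_ingredients = "x",
    fat_100g = round(abs(rnorm(100, 15, 8)), 2),
    energy_100g = round(abs(rnorm(100, 250, 120)), 1),
    carbohydrate_100g = round(abs(rnorm(100, 30, 15)), 2),
    stringsAsFactors = FALSE)
  lex <- load_food_lexicon(df)
  for (field in c("fat_100g", "energy_100g", "carbohydrate_100g")) {
    prof <- nutrient_profile(lex, field)
    # quadrature over the evaluation grid
    integral <- sum(diff(prof$grid_value) *
                      (head(prof$density, -1) + tail(prof$density, -1)) / 2)
    expect_true(abs(integral - 1) < 1e-3, label = field)
  }
})

test_that("identical nutrient values concentrate the density at that value", {
  df <- data.frame(
    food_name = paste0("food", letters[1:5]), food_ingredients = "x",
    fat_100g = 7, energy_100g = 100, carbohydrate_100g = 3,
    stringsAsFactors = FALSE)
  lex <- load_food_lexicon(df)
  prof <- nutrient_profile(lex, "fat_100g")
  mode_at <- prof$grid_value[which.max(prof$density)]
  expect_equal(mode_at, prof$grid_value[which.min(abs(prof$grid_value - 7))])
})

test_that("vegan split with an empty group falls back to pooled with warning", {
  df <- tiny_food_df()
  df$category <- "other"
  df$food_name <- paste0("dish", letters[seq_len(nrow(df))])  # nothing vegan
  lex <- load_food_lexicon(df)
  expect_warning(prof <- nutrient_profile(lex, "fat_100g", split_vegan = TRUE),
                 "empty")
  expect_equal(unique(prof$group), "all")
})

test_that("profiles on fewer than two values are a degenerate-input error", {
  lex <- load_food_lexicon(tiny_food_df()[1, ])
  err <- tryCatch(nutrient_profile(lex, "fat_100g"), error = identity)
  expect_s3_class(err, "caloscope_undefined_result")
})
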