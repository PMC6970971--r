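# Shared in-code fixtures.

mk_post <- function(tokens, region = "CA-ON", id = "p1", sentence = NULL) {
  structure(list(id = id, region = region, tokens = tokens,
                 sentence = sentence %||% rep(1L, length(tokens))),
            class = "clean_post")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_food_df <- function() {
  data.frame(
    food_name = c("coffee", "pizza", "cake", "sweet potatoes", "orange juice",
                  "vegan burger", "chicken masala"),
    food_ingredients = c("coffee beans", "dough;cheese", "flour;sugar",
                         "sweet potato", "orange", "soy", "chicken;spices"),
    fat_100g = c(0, 10.1, 15, 0.1, 0.2, 9, 9),
    energy_100g = c(2, 266, 347, 86, 45, 177, 195),
    carbohydrate_100g = c(0, 33, 50, 20, 10, 15, 6),
    category = c("other", "other", "other", "vegetable", "juice", "other",
                 "other"),
    stringsAsFactors = FALSE)
}

tiny_food_lexicon <- function() load_food_lexicon(tiny_food_df())

tiny_activity_df <- function() {
  data.frame(activity_name = c("running", "walking", "swimming"),
             caloric_value = c(700, 280, 560), stringsAsFactors = FALSE)
}

tiny_activity_lexicon <- function() load_activity_lexicon(tiny_activity_df())

write_food_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# Brute-force per-mention average: expands the frequency of each phrase into
# individual mentions and takes the plain mean. Independent of the
# frequency-table reduction used by the package.
per_mention_oracle <- function(keys, values_by_key) {
  if (!length(keys)) return(NA_real_)
  mean(values_by_key[keys])
}
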