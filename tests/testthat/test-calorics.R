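# C_in, C_out, C_rat, regional summaries, rankings, population shares.

test_that("caloric intake is the mention-weighted mean of lexicon energies", {
  lex <- tiny_food_lexicon()
  # one food (pizza, 266) mentioned 4x
  posts <- replicate(4, mk_post("pizza"), simplify = FALSE)
  res <- caloric_intake(posts, lex)
  expect_equal(res$c_in, 266)
  expect_equal(unname(res$table["pizza"]), 4L)

  # 2 (coffee) x 1 mention + 266 (pizza) x 3 mentions, vs per-mention oracle
  posts2 <- list(mk_post("coffee"), mk_post("pizza"), mk_post("pizza"),
                 mk_post("pizza"))
  res2 <- caloric_intake(posts2, lex)
  oracle <- per_mention_oracle(c("coffee", "pizza", "pizza", "pizza"),
                               lexicon_values(lex))
  expect_equal(res2$c_in, oracle)
})

test_that("a corpus with only masked food words signals undefined intake", {
  lex <- tiny_food_lexicon()
  p <- mk_post(c("piece", "cake"))
  res <- caloric_intake(list(p), lex,
                        masks = list(c(FALSE, TRUE)))
  expect_true(is.na(res$c_in))
  expect_equal(res$n_mentions, 0L)
})

test_that("caloric burn averages per mention and scales with subject weight", {
  lex <- tiny_activity_lexicon()
  posts <- list(mk_post("running"), mk_post("running"))
  expect_equal(caloric_burn(posts, lex)$c_out, 700)

  posts2 <- list(mk_post("walking"), mk_post("walking"),
                 mk_post("running"), mk_post("running"))
  oracle <- per_mention_oracle(c("walking", "walking", "running", "running"),
                               lexicon_values(lex))
  expect_equal(caloric_burn(posts2, lex)$c_out, oracle)

  cfg <- engine_config(reference_weight = 80.7, subject_weight = 161.4)
  expect_equal(caloric_burn(list(mk_post("walking")), lex, cfg)$c_out,
               2 * 280)
})

test_that("the caloric ratio is an exact quotient with undefined signalling", {
  expect_equal(caloric_ratio(2000, 1000), 2.0)
  for (x in c(0.5, 1, 250, 1e6)) expect_equal(caloric_ratio(x, x), 1.0)
  expect_equal(caloric_ratio(250, 400), 0.625)
  expect_true(is.na(caloric_ratio(100, 0)))
  expect_true(is.na(caloric_ratio(NA_real_, 100)))
  expect_true(is.na(caloric_ratio(100, NA_real_)))
})

test_that("c_in and c_out are bounded by the lexicon value range", {
  lex <- tiny_food_lexicon(); alex <- tiny_activity_lexicon()
  set.seed(55)
  fk <- lexicon_keys(lex)[!grepl(" ", lexicon_keys(lex))]
  ak <- lexicon_keys(alex)
  for (i in 1:20) {
    posts <- lapply(seq_len(sample(3:10, 1)), function(j) {
      mk_post(c(sample(fk, sample(1:2, 1)), sample(ak, 1)))
    })
    cin <- caloric_intake(posts, lex)$c_in
    cout <- caloric_burn(posts, alex)$c_out
    vals <- lexicon_values(lex)
    expect_gte(cin, min(vals)); expect_lte(cin, max(vals))
    avals <- lexicon_values(alex)
    expect_gte(cout, min(avals)); expect_lte(cout, max(avals))
  }
})

test_that("scaling every food energy by a > 0 scales c_in and c_rat by a", {
  df <- tiny_food_df()
  posts <- list(mk_post(c("coffee", "pizza")), mk_post("cake"))
  base <- caloric_intake(posts, load_food_lexicon(df))$c_in
  for (a in c(0.5, 3)) {
    df2 <- df; df2$energy_100g <- df2$energy_100g * a
    scaled <- caloric_intake(posts, load_food_lexicon(df2))$c_in
    expect_equal(scaled, a * base)
    expect_equal(caloric_ratio(scaled, 400), a * caloric_ratio(base, 400))
  }
})

test_that("adding idiom-masked food tokens never changes c_in", {
  lex <- tiny_food_lexicon()
  posts <- list(mk_post(c("coffee", "pizza")))
  base <- caloric_intake(posts, lex, masks = list(c(FALSE, FALSE)))$c_in
  posts2 <- c(posts, list(mk_post(c("piece", "cake"))))
  masks2 <- list(c(FALSE, FALSE), c(TRUE, TRUE))
  expect_identical(caloric_intake(posts2, lex, masks2)$c_in, base)
})

test_that("c_in/c_out equal the brute-force per-mention oracle on random corpora", {
  lex <- tiny_food_lexicon(); alex <- tiny_activity_lexicon()
  fv <- lexicon_values(lex); av <- lexicon_values(alex)
  fk <- names(fv)[!grepl(" ", names(fv))]
  set.seed(2024)
  for (i in 1:100) {
    food_ment <- sample(fk, sample(1:12, 1), replace = TRUE)
    act_ment <- sample(names(av), sample(1:12, 1), replace = TRUE)
    posts <- c(lapply(food_ment, mk_post), lapply(act_ment, mk_post))
    cin <- caloric_intake(posts, lex)$c_in
    cout <- caloric_burn(posts, alex)$c_out
    expect_lt(abs(cin - per_mention_oracle(food_ment, fv)) /
                per_mention_oracle(food_ment, fv), 1e-9)
    expect_lt(abs(cout - per_mention_oracle(act_ment, av)) /
                per_mention_oracle(act_ment, av), 1e-9)
  }
})

test_that("regional summaries match per-region oracles and flag undefined", {
  lex <- tiny_food_lexicon(); alex <- tiny_activity_lexicon()
  posts <- list(
    mk_post(c("pizza", "running"), region = "CA-ON", id = "1"),
    mk_post("coffee", region = "CA-ON", id = "2"),
    mk_post(c("cake", "walking"), region = "CA-QC", id = "3"),
    mk_post("walking", region = "CA-QC", id = "4"))
  summ <- regional_summary(posts, lex, alex)
  on <- summ[summ$region == "CA-ON", ]
  qc <- summ[summ$region == "CA-QC", ]
  expect_equal(on$c_in, mean(c(266, 2)))
  expect_equal(on$c_out, 700)
  expect_equal(on$c_rat, mean(c(266, 2)) / 700)
  expect_equal(qc$c_rat, 347 / 280)

  # a region with no activity mentions is flagged with an undefined ratio
  posts2 <- list(mk_post("pizza", region = "CA-NU", id = "5"))
  summ2 <- regional_summary(posts2, lex, alex)
  expect_equal(summ2$flag, "no_activity")
  expect_true(is.na(summ2$c_rat))

  # single-region corpus equals the corpus-level computation
  sub <- posts[1:2]
  summ3 <- regional_summary(sub, lex, alex)
  expect_equal(summ3$c_in, caloric_intake(sub, lex)$c_in)
  expect_equal(summ3$c_out, caloric_burn(sub, alex)$c_out)
})

test_that("pooling regions equals the mention-weighted combination", {
  lex <- tiny_food_lexicon()
  set.seed(9)
  fk <- lexicon_keys(lex)[!grepl(" ", lexicon_keys(lex))]
  posts <- lapply(1:40, function(i) {
    mk_post(sample(fk, sample(1:3, 1), replace = TRUE),
            region = sample(c("A", "B", "C"), 1), id = as.character(i))
  })
  summ <- regional_summary(posts, lex, tiny_activity_lexicon())
  pooled <- caloric_intake(posts, lex)
  w <- summ$n_food_mentions
  expect_equal(sum(summ$c_in * w) / sum(w), pooled$c_in)
  expect_equal(sum(w), pooled$n_mentions)
})

test_that("top_k ranks by count with lexicographic ties", {
  expect_equal(top_k(c(coffee = 5L, tea = 3L), 10)$phrase, c("coffee", "tea"))
  t2 <- top_k(c(b = 2L, a = 2L), 1)
  expect_equal(t2$phrase, "a")
  set.seed(31)
  counts <- setNames(sample(1:20, 50, replace = TRUE), paste0("ph", 1:50))
  got <- top_k(counts, 50)
  ord <- order(-counts, names(counts))  # full sort oracle
  expect_equal(got$phrase, names(counts)[ord])
  expect_equal(got$count, unname(counts[ord]))
})

test_that("population share sums populations of regions at/above threshold", {
  s <- c(A = 1.2, B = 1.5)
  pops <- c(A = 10, B = 5)
  expect_equal(population_share_above(s, pops, 1.0), 100)
  expect_equal(population_share_above(c(A = 0.5, B = 0.9), pops, 1.0), 0)
  expect_equal(population_share_above(c(A = 1.1, B = 0.9),
                                      c(A = 60, B = 40), 1.0), 60)
  err <- tryCatch(population_share_above(s, c(A = 10)), error = identity)
  expect_s3_class(err, "caloscope_schema_error")
  expect_match(conditionMessage(err), "B")
})
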