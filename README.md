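# caloscope

Idiom-aware, lexicon-based caloric analysis of short social-media posts, for
digital-epidemiology work that wants population-level diet and activity
indicators without surveys.

Plain lexicon counting treats every food word as food: "the test was a piece
of cake" inflates a region's apparent caloric intake although it has nothing
to do with eating. `caloscope` normalizes posts, detects multiword
expressions so idiomatic food words can be excluded, classifies posts as
food / non-food, and aggregates per-region caloric indicators:

- **C_in** — mention-weighted mean caloric value of food phrases,
  `C_in = Σ_w cal(w) f(w) / Σ_w f(w)`, with `cal(w)` the lexicon's kcal per
  100 g and `f(w)` the mention count of phrase `w`;
- **C_out** — the same mention-weighted mean over activity phrases, with
  kcal-per-mention values stated at a reference body weight of 80.7 kg
  (rescalable by `subject_weight / reference_weight`);
- **C_rat = C_in / C_out** — a dimensionless intensity ratio: values above 1
  indicate mention-level consumption exceeding expenditure. Undefined ratios
  (no activity mentions) are reported as `NA`, never 0 or ∞.

The pipeline stages:

1. **Cleaning** (`clean_posts`) — emoticons/emoji to textual names,
   lowercasing, tokenization with contraction splitting ("gonna" → "gon na"),
   stopword removal, special-character stripping (hashtag text kept, URLs and
   @mentions dropped), number removal.
2. **Lexicons** (`load_food_lexicon`, `load_activity_lexicon`) — canonical
   phrase keys, per-100 g nutrients, a two-clause vegan rule ("vegan" in the
   name, or category ∈ {vegetable, fruit, juice}), and kernel-density
   nutrient profiles (`nutrient_profile`).
3. **Phrases** (`match_mwe`, `flag_food_idioms`) — greedy leftmost-longest
   matching of canonical content tokens against a phrase inventory; tokens
   inside matched idioms are masked out of caloric counting.
4. **Classification** (`food_classifier`) — tf-idf features (detected
   phrases are single features), with naive Bayes, logistic regression,
   random forest and linear SVM back-ends, plus confusion-matrix reports and
   learning curves.
5. **Calorics** (`caloric_intake`, `caloric_burn`, `regional_summary`,
   `top_k`, `population_share_above`) — per-region summaries, rankings and
   population shares above a ratio threshold.
6. **Synthesis** (`generate_corpus`) — seeded synthetic corpora with
   recorded ground truth, so every stage is testable without any download.

## Worked example

```r
library(caloscope)

clean_text("I am getting 2 old to be mango Gonna retire soon :-)")
#>  [1] "getting" "old"     "mango"   "gon"     "na"      "retire"  "soon"
#>  [8] "happy"   "face"    "smiley"

cfg  <- generator_config(regions = c("CA-ON", "CA-QC", "CA-BC"),
                         posts_per_region = 2000, idiom_rate = 0.1, seed = 42)
sim  <- generate_corpus(cfg)
posts <- clean_posts(sim$posts)
regional_summary(posts, default_food_lexicon(), default_activity_lexicon(),
                 default_idiom_inventory())
#> Per-region caloric summary (C_rat = C_in / C_out; NA = undefined):
#>  region  c_in c_out  c_rat n_food_mentions n_activity_mentions flag
#>   CA-BC 221.6 408.4 0.5425             801                 699   ok
#>   CA-ON 224.2 411.9 0.5443             820                 661   ok
#>   CA-QC 217.4 416.3 0.5222             857                 664   ok
```

Each row is one region: `c_in` is the average kcal value per food mention,
`c_out` the average kcal burn per activity mention, and `c_rat` their ratio —
here about 0.52–0.54, meaning the synthetic corpus mentions relatively more
(or more calorific) activity than food. Because 10% of the food posts carry
idioms instead of real mentions, disabling idiom masking
(`regional_summary(..., idiom_inventory = NULL)`) visibly shifts `c_in` away
from the generator's recorded ground truth; with masking the recovery is
exact.

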