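---
title: "Methods: idiom-aware caloric analysis of social-media posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: idiom-aware caloric analysis of social-media posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caloscope)
```

## The measurement model

`caloscope` estimates three population-level indicators from short posts:

* `C_in`, the mention-weighted mean caloric value of food phrases:
  `C_in = Σ_w cal(w) f(w) / Σ_w f(w)`, where `f(w)` counts corpus-level
  mentions of phrase `w` and `cal(w)` is the lexicon's energy per 100 g of
  that food, in kcal;
* `C_out`, the same mention-weighted mean over activity phrases, whose
  lexicon values are kcal burned per mention at a reference body weight;
* `C_rat = C_in / C_out`, a dimensionless intensity ratio. Being normalized
  by total mention counts, it is comparable across regions with very
  different posting volumes; a value above 1 means the region's food
  mentions are, per mention, more calorific than its activity mentions.

The central assumption is that mention frequency is a usable proxy for
behaviour. Two known violations are handled explicitly:

* **Idioms.** Food words inside idiomatic multiword expressions ("piece of
  cake", "apple of my eye") are not food. The phrase module masks them out
  of counting; disabling the mask reproduces the bias of naive lexicon
  counting, and the package's tests quantify that bias on synthetic corpora
  with known truth.
* **Quantity.** The model counts mentions, not servings: one apple and ten
  apples are one mention each. `cal(w)` is a per-100 g proxy; an optional
  per-entry `serving_multiplier` column lets a curated lexicon rescale
  individual foods, but no quantity inference is attempted.

Undefined quantities are signalled, never coerced: a scope with no food
mentions has `C_in = NA`, a scope with no activity mentions has
`C_rat = NA` and is excluded from ratio-based aggregation (it still counts
in the denominator of population shares).

## Cleaning

Cleaning applies, in order: Unicode NFKC; emoticon/emoji conversion to
textual names from a fixed packaged table (so output cannot drift with an
external emoji library's version); lowercasing; sentence splitting on
`.!?;`; whitespace tokenization with a fixed contraction table
("gonna" → "gon na"); stopword removal; special-character stripping (the
text of hashtags survives, `#rofl` → `rofl`); number removal; and a final
stopword pass so that stripping residues such as "its" (from "it's") cannot
survive. URLs and @mentions — never informative after stripping — are
deleted whole from the raw text, before sentence splitting would break them
at dots.

The stopword list is fixed and versioned inside the package
(`stopword_list()`): a Snowball-style core plus perception verbs ("saw",
"see") and apostrophe-free contraction residues. A fixed list is a
correctness requirement here, not a convenience: phrase canonicalization
must agree exactly between lexicon keys and cleaned posts, so the list is
part of the package contract.

Plural stripping happens at match time only: a trailing "s" is dropped,
with the `-es` ending handled for stems where English adds "es"
("potatoes" → "potato", "dishes" → "dish"); words ending in "ss" are kept.
This is a deliberately shallow, dictionary-free rule — adequate for lexicon
phrase matching, not lemmatization.

## Lexicons and the vegan rule

Food lexicons are CSV tables with per-100 g `fat_100g`, `energy_100g`
(kcal) and `carbohydrate_100g`; activity lexicons carry `caloric_value` in
kcal per mention at the reference weight. Keys are canonicalized with the
same pipeline as posts, so every key is a fixed point of cleaning.
Duplicate names (multi-source lexicons collide routinely) are merged by the
arithmetic mean of each nutrient, with a warning — a neutral choice in the
absence of source-reliability information. Rows with missing, non-finite or
negative values are rejected and counted, not silently fixed.

A food is **vegan** iff the token "vegan" appears in its name or its
category is vegetable, fruit or juice; everything else is non-vegan. When a
lexicon ships no category column, the category is inferred from packaged
vegetable/fruit/juice keyword lists; keyword membership is an approximation
of curated labels (a "potato chip" would be tagged vegetable) and is
documented as such.

Nutrient profiles use a Gaussian kernel density estimate with Scott's-rule
bandwidth (`stats::bw.nrd`) on a 512-point grid spanning
`[min − 3h, max + 3h]`, renormalized by trapezoidal quadrature so each
curve integrates to 1 on its stated support. Groups need at least two
entries; two-or-more identical values degrade gracefully to a narrow spike
centred on the common value (bandwidth `max(|v|, 1)·10⁻³`), since a rule-of-
thumb bandwidth is undefined at zero variance.

## Phrase detection and idiom masking

The phrase inventory stores canonical, stopword-free, singularized forms of
two to four content tokens ("apple of my eye" → "apple eye"); longer forms
are truncated with a warning. Because cleaning removes function-word
linkers first, matching adjacent content tokens is equivalent to
linker-based segmentation over raw text, and a single normalization path
serves both posts and inventory.

Matching is greedy leftmost-longest within sentence-like spans: at each
position the longest matching form (up to 4 tokens) wins and matching
resumes after it, so matches are disjoint by construction. Greedy matching
does not globally maximize coverage — it is the standard, predictable
choice for gazetteer segmentation, and the tests verify its local
dominance property against a brute-force enumerator. Inventory membership
is boolean; a graded "relatedness" score is a noted extension point, not
implemented.

Masking applies only to idiom-tagged entries: idioms are matched first, and
lexicon phrases are matched on the unmasked remainder, so a token inside an
idiom can never be counted as food. Compound-tagged entries ("sweet
potato") are not masked — they exist so multiword foods match as units and
appear as single tf-idf features.

## Classification

Features are tf-idf with the smoothed dialect fixed exactly: raw term
frequency, `idf = ln((1 + N)/(1 + df)) + 1`, L2-normalized rows. Detected
phrases enter the vocabulary as single features and consume their component
unigrams. Four classifier kinds are supported behind one interface, in the
fixed class order (food, non-food):

* `nb` — multinomial naive Bayes with Laplace smoothing, implemented in the
  package (about twenty lines). Gaussian naive Bayes on sparse tf-idf
  columns is degenerate — most features have zero within-class variance —
  and no installed package provides the multinomial variant;
* `lr` — ridge-penalized logistic regression fitted along a `glmnet`
  lambda path (50 values, 1 to 10⁻⁴), predicting at the smallest penalty.
  Fitting a path rather than one small lambda is both faster and more
  accurate with `glmnet`'s warm starts;
* `rf` — `ranger` random forest, 200 trees, single-threaded with an
  explicit seed for determinism;
* `svm` — `e1071` linear-kernel SVM, cost 1, no rescaling (rows are already
  L2-normalized).

Training requires both classes and is deterministic given a seed.
Evaluation reports the 2×2 confusion matrix (rows = truth), row-normalized
proportions, accuracy, and the false-positive rate
(true non-food predicted food). Learning curves use a stratified 80/20
split with a fixed seed for the common held-out set, and stratified
subsamples of the training pool per (size, seed) pair.

When no gold labels exist, weak-supervision labels are derived from the
lexicon: "food" iff at least one unmasked token or phrase matches the food
lexicon. Synthetic gold labels override weak labels in tests, so the
classifier benchmark measures the learners, not the labeler.

## The synthetic generator

`generate_corpus()` emulates regional short-post streams: each post is
chatter (neutral vocabulary), a food post, or an activity post
(defaults 0.20 / 0.45 / 0.35); a food post carries an idiom instead of a
true mention with probability `idiom_rate` (default 0.1 — idioms are common
but not dominant in casual text). Posts get natural casing, optional
stopword fill words, digits (p = 0.15) and emoticons (p = 0.2) so that
cleaning is genuinely exercised. Ground truth (per-region `C_in`, `C_out`,
`C_rat`, per-post gold labels) is computed from the *emitted* mention log,
not the sampling distribution, so recovery tests carry no Monte-Carlo
tolerance.

Two vocabulary-hygiene rules make exact recovery meaningful: the default
chatter vocabulary is disjoint (after canonicalization) from lexicon and
idiom tokens, and emoticons whose textual names contain lexicon or
idiom-form tokens are never injected as noise (a pizza emoji next to a food
post would otherwise create a phantom mention). With those rules,
`idiom_rate = 0` and unambiguous vocabularies, the full pipeline reproduces
the recorded truth bit-exactly — both sides reduce their frequency tables
over alphabetically sorted keys, so even floating-point summation order
agrees. The `separable = TRUE` mode additionally draws chatter for food and
non-food posts from disjoint halves of the vocabulary, which is the
separable classification benchmark.

What the generator does **not** emulate: real spelling variation, slang,
code-switching, sarcasm, regional dialect, user networks, temporal
dynamics, or the heavy class imbalance of real streams. Passing recovery
and benchmark tests therefore demonstrates the pipeline's internal
correctness — counting, masking, aggregation, learning machinery — not
field accuracy on real posts.

## Numerical and design choices

* Reference body weight defaults to 80.7 kg (average Canadian adult);
  activity values scale linearly by `subject_weight / reference_weight`.
  Sources also quote 80.3 kg for the same average; 80.7 is used
  consistently and both are reachable through `engine_config()`.
* Rankings sort by count descending with lexicographic tie-breaks, so
  output is total-ordered and reproducible.
* Population share above a ratio threshold is
  `100 · Σ pop(r | C_rat ≥ t) / Σ pop(r)` over summarized regions; regions
  with undefined ratios count in the denominator only.
* Region codes follow ISO 3166-2:CA in all packaged defaults.
* Manifest hashing uses a 31-bit polynomial rolling hash of the canonical
  config JSON — enough to detect config drift between runs; it is not a
  cryptographic digest.
* Whether phrase frequency should be counted within posts or corpus-wide is
  ambiguous in mention-weighted means; corpus-level counting is implemented,
  and the two coincide under per-mention enumeration, which the oracle
  tests exploit.
* Ingredients do not participate in the vegan rule — only the name and the
  category, keeping the rule total and auditable; ingredient-aware
  classification would require a curated ingredient taxonomy.

## Problem sizes used by the test suite

The suite and acceptance script size their simulations to be decisive yet
quick: 1,000 fifteen-post corpora for oracle equivalence; ten regions of
5,000 posts for exact ratio recovery; twenty seeds of 600-post corpora at
`idiom_rate = 0.3` for the bias comparison; and a 10,000-post separable
corpus for the classifier benchmark. These sizes were chosen so each check
is statistically overwhelming for the property it tests while the whole
suite stays in the low minutes.

## Limitations

Lexicon coverage bounds everything: unlisted foods and activities are
invisible, and per-100 g energy is a crude stand-in for a serving. The
idiom inventory is a fixture-scale gold list, not a trained MWE tagger;
novel idioms pass through unmasked. Weak-supervision labels inherit every
lexicon gap. None of the packaged lexicons attempt to reproduce any
large-scale multi-source nutrition database; they are curated,
fixture-scale tables for demonstration, testing and synthesis.
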