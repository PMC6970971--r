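# Fixed, versioned language resources. These are shipped in code (not read
# from an external library at run time) so that cleaning output does not
# drift with dependency versions.

#' English stopword list used by the cleaning pipeline
#'
#' A fixed, versioned list. It is a Snowball-style core (pronouns,
#' auxiliaries, determiners, prepositions, conjunctions) extended with a small
#' set of high-frequency verbs of perception ("saw", "see") and apostrophe-free
#' contraction residues ("dont", "im") that arise after special-character
#' stripping. Content words such as "getting", "old", "soon" and the
#' contraction fragments "gon", "na" are deliberately not stopwords.
#'
#' @return Character vector of lowercase stopwords.
#' @export
stopword_list <- function() .caloscope_stopwords

.caloscope_stopwords <- c(
  # pronouns
  "i", "me", "my", "myself", "we", "our", "ours", "ourselves",
  "you", "your", "yours", "yourself", "yourselves",
  "he", "him", "his", "himself", "she", "her", "hers", "herself",
  "it", "its", "itself", "they", "them", "their", "theirs", "themselves",
  # interrogatives / demonstratives
  "what", "which", "who", "whom", "this", "that", "these", "those",
  "when", "where", "why", "how",
  # auxiliaries and copulas
  "am", "is", "are", "was", "were", "be", "been", "being",
  "have", "has", "had", "having", "do", "does", "did", "doing",
  "will", "would", "shall", "should", "can", "could", "may", "might",
  "must", "ought",
  # determiners, conjunctions, prepositions
  "a", "an", "the", "and", "but", "if", "or", "because", "as",
  "until", "while", "of", "at", "by", "for", "with", "about", "against",
  "between", "into", "through", "during", "before", "after", "above",
  "below", "to", "from", "up", "down", "in", "out", "on", "off", "over",
  "under", "again", "further", "then", "once", "here", "there",
  "all", "any", "both", "each", "few", "more", "most", "other", "some",
  "such", "no", "nor", "not", "only", "own", "same", "so", "than", "too",
  "very", "s", "t", "just", "also",
  # perception verbs common in chatter
  "saw", "see", "seen",
  # apostrophe-free contraction residues
  "im", "ive", "id", "ill", "youre", "youve", "hes", "shes", "thats",
  "isnt", "arent", "wasnt", "werent", "dont", "doesnt", "didnt", "cant",
  "couldnt", "wont", "wouldnt", "shouldnt"
)

#' Emoticon and emoji name mapping
#'
#' Symbol-to-name table used by [convert_emoticons()]. Shipped as a fixed
#' mapping so results are reproducible across environments.
#'
#' @return Named character vector: names are symbols, values are their
#'   space-separated textual names.
#' @export
emoticon_map <- function() .caloscope_emoticons

.caloscope_emoticons <- c(
  ":-)"  = "Happy face smiley",
  ":)"   = "Happy face smiley",
  ":-D"  = "Laughing big grin",
  ":D"   = "Laughing big grin",
  ":-("  = "Frown sad",
  ":("   = "Frown sad",
  ";-)"  = "Wink smiley",
  ";)"   = "Wink smiley",
  ":-P"  = "Tongue sticking out",
  ":P"   = "Tongue sticking out",
  ":-O"  = "Surprise",
  ":-o"  = "Surprise",
  ":'("  = "Crying",
  ":-|"  = "Straight face",
  ":-*"  = "Kiss",
  "</3"  = "Broken heart",
  "<3"   = "Heart",
  "\U0001F600" = "Grinning face",
  "\U0001F602" = "Face with tears of joy",
  "\U0001F642" = "Slightly smiling face",
  "\U0001F60D" = "Smiling face with heart eyes",
  "\U0001F44D" = "Thumbs up",
  "\U0001F389" = "Party popper",
  "❤"     = "Red heart",
  "\U0001F355" = "Pizza",
  "\U0001F354" = "Hamburger",
  "☕"     = "Hot beverage",
  "\U0001F3C3" = "Person running",
  "\U0001F6B4" = "Person biking"
)

# Contraction split table applied at tokenization ("gonna" -> "gon" "na").
.caloscope_contractions <- list(
  gonna = c("gon", "na"),
  wanna = c("wan", "na"),
  gotta = c("got", "ta"),
  outta = c("out", "ta"),
  lemme = c("lem", "me"),
  gimme = c("gim", "me"),
  dunno = c("dun", "no")
)

# Keyword fallbacks for the vegan rule's category clauses when a lexicon has
# no explicit category column. Names are canonical (singularized) tokens.
# Keyword membership is an approximation of true category labels.
.caloscope_vegetables <- c(
  "vegetable", "veggie", "potato", "carrot", "broccoli", "spinach", "kale",
  "onion", "lettuce", "cucumber", "pea", "bean", "corn", "cabbage",
  "cauliflower", "celery", "zucchini", "squash", "beet", "radish",
  "asparagus", "pumpkin", "eggplant", "turnip", "yam", "leek", "garlic"
)
.caloscope_fruits <- c(
  "fruit", "apple", "banana", "orange", "mango", "grape", "berry",
  "strawberry", "blueberry", "raspberry", "cranberry", "peach", "pear",
  "plum", "cherry", "melon", "watermelon", "pineapple", "kiwi", "lemon",
  "lime", "apricot", "fig", "papaya", "guava", "avocado"
)
.caloscope_juices <- c("juice", "lemonade", "smoothie", "cider", "nectar")
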