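#' Load a sub-aspect keyword lexicon
#'
#' Reads a YAML (or JSON) file mapping each of the eight sub-aspect names to
#' a list of complaint phrases and single-word triggers, validates it, and
#' normalizes every phrase (lowercase, punctuation stripped). The package
#' ships a default lexicon seeded from the inspection-checklist exemplar
#' phrases; `default_lexicon()` loads it.
#'
#' Validation rejects lexicons that miss any of the eight sub-aspects, have
#' an empty phrase list, or assign the same normalized phrase to more than
#' one sub-aspect (every keyword must map to exactly one sub-aspect).
#'
#' @param path Path to a YAML/JSON lexicon file.
#' @return An object of class `subaspect_lexicon`: a named list of
#'   normalized phrase vectors, one per sub-aspect, in canonical order.
#' @export
load_lexicon <- function(path) {
  raw <- yaml::read_yaml(path)
  as_lexicon(raw)
}

#' @rdname load_lexicon
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "subaspect_lexicon.yaml",
                           package = "foodsig", mustWork = TRUE))
}

as_lexicon <- function(x) {
  missing <- setdiff(SUBASPECTS, names(x))
  if (length(missing)) {
    stop("lexicon is missing sub-aspect(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(x), SUBASPECTS)
  if (length(extra)) {
    stop("lexicon has unknown sub-aspect(s): ", paste(extra, collapse = ", "))
  }
  lex <- lapply(x[SUBASPECTS], function(p) {
    p <- unique(vapply(unlist(p), normalize_text, character(1)))
    p[nzchar(p)]
  })
  if (any(lengths(lex) == 0L)) {
    stop("every sub-aspect needs at least one phrase")
  }
  all_phrases <- unlist(lex, use.names = FALSE)
  dup <- unique(all_phrases[duplicated(all_phrases)])
  if (length(dup)) {
    stop("phrase(s) assigned to more than one sub-aspect: ",
         paste(dup, collapse = "; "))
  }
  structure(lex, class = "subaspect_lexicon")
}

#' @export
print.subaspect_lexicon <- function(x, ...) {
  cat("<subaspect_lexicon> 8 sub-aspects,",
      sum(lengths(x)), "phrases\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %d phrase(s)\n", nm, length(x[[nm]])))
  }
  invisible(x)
}

normalize_text <- function(text) {
  paste(tokenize(text)[[1L]], collapse = " ")
}

# A phrase matches when its tokens occur consecutively in the normalized
# text, each as a stem prefix of the corresponding text token ("rat"
# matches "rats"; "stomach ache" matches "stomach aches").
phrase_regex <- function(phrase) {
  toks <- strsplit(phrase, " ", fixed = TRUE)[[1L]]
  paste0("\\b", paste(toks, collapse = "[[:alnum:]]* "), "[[:alnum:]]*\\b")
}

#' Classify a negative hygiene review into sub-aspects
#'
#' Matches the normalized review text against the lexicon. A sub-aspect
#' matches when any of its phrases occurs in the text (consecutive tokens,
#' stem-prefix per token), so a single review can carry several sub-aspects
#' ("rat droppings and the floor was dirty" hits both pest control and
#' cleanliness). Matching is deterministic and case-insensitive. Only
#' negative-polarity reviews are sub-classified; positive reviews return an
#' empty match set.
#'
#' @param text Review text (length 1).
#' @param lexicon A `subaspect_lexicon`, see [load_lexicon()].
#' @param polarity `"negative"`, `"positive"` or `"none"`. `NA` signals an
#'   unlabeled review and is an error here; route such reviews through
#'   [fallback_polarity()] or skip them.
#' @return Character vector of matched sub-aspect names (possibly empty).
#' @export
#' @examples
#' classify_review("found a fly in the soup", default_lexicon())
classify_review <- function(text, lexicon, polarity = "negative") {
  stopifnot(length(text) == 1L, inherits(lexicon, "subaspect_lexicon"))
  if (is.na(polarity)) {
    stop("review has no hygiene polarity label; label it first ",
         "(see fallback_polarity) or skip it")
  }
  if (!identical(polarity, "negative")) return(character(0))
  norm <- normalize_text(text)
  hits <- vapply(lexicon, function(phrases) {
    any(vapply(phrases, function(p) grepl(phrase_regex(p), norm),
               logical(1)))
  }, logical(1))
  names(lexicon)[hits]
}

#' Classify a table of reviews
#'
#' Vectorized wrapper around [classify_review()]: adds a list-column
#' `matched_subaspects` to the review table. Rows whose polarity is not
#' `"negative"` get an empty match set.
#'
#' @param reviews Tibble with `text` and `hygiene_polarity` columns.
#' @param lexicon A `subaspect_lexicon`.
#' @return `reviews` with an added `matched_subaspects` list-column.
#' @export
classify_reviews <- function(reviews, lexicon) {
  stopifnot(all(c("text", "hygiene_polarity") %in% names(reviews)))
  reviews$matched_subaspects <- purrr::map2(
    reviews$text, reviews$hygiene_polarity,
    function(txt, pol) {
      if (is.na(pol) || !identical(pol, "negative")) return(character(0))
      classify_review(txt, lexicon, polarity = pol)
    }
  )
  reviews
}

#' Default cue lists for the polarity override
#'
#' Negative cues are staleness/texture complaints that sentiment models
#' routinely miss when the surrounding vocabulary is appetitive; food nouns
#' anchor the cue to the food itself; positive cues veto the override.
#'
#' @return List with `negative`, `food_nouns` and `positive` phrase vectors.
#' @export
default_cue_lists <- function() {
  list(
    negative = c("hard", "week ago", "days old", "stale", "fungus", "smelly",
                 "rotten", "undercooked", "soggy", "rancid"),
    food_nouns = c("bread", "cake", "doughnut", "donut", "chicken", "paneer",
                   "cheese", "fish", "food", "curry", "rice", "milk", "cream",
                   "mayonnaise", "biryani", "sandwich", "pastry", "dish"),
    positive = c("fresh", "crispy", "juicy", "delicious", "tasty", "yummy")
  )
}

#' Rule-based override of an upstream hygiene polarity
#'
#' Upstream sentiment labellers can mark a review positive on appetitive
#' keywords even when it reports stale or spoiled food ("the cream doughnut
#' was so hard it must have been made a week ago"). The override flips an
#' upstream positive to negative when a negative cue co-occurs with a food
#' noun and no stronger positive cue is present; in every other case the
#' upstream label stands.
#'
#' @param text Review text (length 1).
#' @param upstream Upstream polarity, `"positive"`/`"negative"`/`"none"`.
#' @param cues Cue lists, see [default_cue_lists()].
#' @return List with `polarity` (possibly flipped) and logical `overridden`.
#' @export
polarity_override <- function(text, upstream, cues = default_cue_lists()) {
  stopifnot(length(text) == 1L)
  norm <- normalize_text(text)
  has_any <- function(phrases) {
    any(vapply(phrases, function(p) grepl(phrase_regex(p), norm), logical(1)))
  }
  flip <- identical(upstream, "positive") &&
    has_any(cues$negative) && has_any(cues$food_nouns) &&
    !has_any(cues$positive)
  list(
    polarity = if (flip) "negative" else upstream,
    overridden = flip
  )
}

#' Lexicon fallback labeller for unlabeled reviews
#'
#' Lower-fidelity stand-in used only when a review arrives without an
#' upstream hygiene sentiment label (when enabled in the pipeline config):
#' a lexicon sub-aspect hit or a negative cue with a food noun labels the
#' review hygiene-negative; a positive cue co-occurring with a hygiene or
#' food term labels it hygiene-positive; otherwise the review is treated as
#' not hygiene-related.
#'
#' @inheritParams classify_review
#' @param cues Cue lists, see [default_cue_lists()].
#' @return `"negative"`, `"positive"` or `"none"`.
#' @export
fallback_polarity <- function(text, lexicon, cues = default_cue_lists()) {
  norm <- normalize_text(text)
  has_any <- function(phrases) {
    any(vapply(phrases, function(p) grepl(phrase_regex(p), norm), logical(1)))
  }
  if (length(classify_review(text, lexicon, "negative"))) return("negative")
  if (has_any(cues$negative) && has_any(cues$food_nouns)) return("negative")
  hygiene_terms <- c("clean", "hygienic", "spotless", "hygiene")
  if (has_any(cues$positive) && has_any(c(cues$food_nouns, hygiene_terms))) {
    return("positive")
  }
  if (has_any(hygiene_terms)) return("positive")
  "none"
}

#' Tally negative reviews per sub-aspect
#'
#' Counts, over one restaurant's assessment window, how many negative
#' hygiene reviews matched each sub-aspect. A multi-label review increments
#' every sub-aspect it matched, so the tally counts review instances per
#' sub-aspect and its sum can exceed the number of matched reviews.
#'
#' @param classified A tibble from [classify_reviews()] (needs
#'   `hygiene_polarity` and `matched_subaspects`), or a bare list of
#'   matched-sub-aspect character vectors from negative reviews.
#' @return Named integer vector over the eight sub-aspects.
#' @export
tally_subaspects <- function(classified) {
  if (is.data.frame(classified)) {
    stopifnot(all(c("hygiene_polarity", "matched_subaspects")
                  %in% names(classified)))
    matched <- classified$matched_subaspects[
      !is.na(classified$hygiene_polarity) &
        classified$hygiene_polarity == "negative"]
  } else {
    matched <- classified
  }
  counts <- setNames(integer(length(SUBASPECTS)), SUBASPECTS)
  hits <- unlist(matched, use.names = FALSE)
  if (length(hits)) {
    tab <- table(factor(hits, levels = SUBASPECTS))
    counts[] <- as.integer(tab)
  }
  counts
}
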