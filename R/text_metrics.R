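#' Tokenize review text
#'
#' Normalizes free text into word tokens: optionally lowercased, with
#' non-alphanumeric characters stripped (so alphanumeric tokens such as
#' "5th" or "50off" survive), then split on whitespace. The policy is
#' deterministic and idempotent: tokenizing the space-joined output of a
#' previous call reproduces it.
#'
#' @param text Character vector of raw review texts.
#' @param lowercase Lowercase before splitting? Default `TRUE`.
#' @param strip_punct Replace non-alphanumeric characters with spaces?
#'   Default `TRUE`.
#' @return A list of character vectors, one per element of `text`. Empty or
#'   all-punctuation input yields `character(0)`.
#' @export
#' @examples
#' tokenize("Good ambience and service.")[[1]]
tokenize <- function(text, lowercase = TRUE, strip_punct = TRUE) {
  stopifnot(is.character(text))
  x <- text
  if (lowercase) x <- tolower(x)
  if (strip_punct) x <- gsub("[^[:alnum:] ]+", " ", x)
  x <- trimws(gsub("[[:space:]]+", " ", x))
  out <- strsplit(x, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

#' Type-token ratio (lexical diversity)
#'
#' Ratio of distinct tokens to total tokens. High values indicate diverse
#' word usage; reviews pasted together from a template score low. Used when
#' profiling whether two reviews of the same restaurant were plausibly
#' written by the same individual.
#'
#' @param tokens Character vector of tokens (one sequence).
#' @return A ratio in (0, 1], or `NA_real_` (with a warning) for an empty
#'   sequence, where the ratio is undefined.
#' @export
#' @examples
#' type_token_ratio(c("a", "a", "b"))  # 2/3
type_token_ratio <- function(tokens) {
  stopifnot(is.character(tokens))
  if (length(tokens) == 0L) {
    warning("type-token ratio undefined for an empty token sequence")
    return(NA_real_)
  }
  length(unique(tokens)) / length(tokens)
}

#' Jaccard similarity of two token sequences
#'
#' Intersection-over-union of the unique word sets. Symmetric; 1 for
#' identical vocabularies, 0 for disjoint ones.
#'
#' @param a,b Character vectors of tokens.
#' @return Numeric in \[0, 1\], or `NA_real_` (with a warning) when both
#'   sequences are empty.
#' @export
jaccard_similarity <- function(a, b) {
  ua <- unique(a)
  ub <- unique(b)
  n_union <- length(union(ua, ub))
  if (n_union == 0L) {
    warning("Jaccard similarity undefined when both sequences are empty")
    return(NA_real_)
  }
  length(intersect(ua, ub)) / n_union
}

token_bigrams <- function(tokens) {
  if (length(tokens) < 2L) return(character(0))
  unique(paste(tokens[-length(tokens)], tokens[-1L]))
}

#' Bigram overlap of two token sequences
#'
#' Number of distinct adjacent word pairs shared by the two sequences.
#' Shared bigrams indicate shared phrasing; zero overlap points to distinct
#' authors. Returns 0 when either sequence has fewer than two tokens.
#'
#' @param a,b Character vectors of tokens.
#' @return Non-negative integer count.
#' @export
bigram_overlap <- function(a, b) {
  length(intersect(token_bigrams(a), token_bigrams(b)))
}

#' Pattern-recognition comparison of two reviews
#'
#' Computes the full authorship-profiling panel for a pair of reviews of
#' the same restaurant: per-review type-token ratios, Jaccard similarity of
#' the unique word sets (with the intersection and union sizes), and the
#' bigram overlap. `screen_pair()` adds the same-author decision used for
#' duplicate exclusion: a pair is flagged when its Jaccard similarity or
#' bigram overlap reaches the respective threshold. The defaults (Jaccard
#' 0.6, bigrams 3) separate verbatim and lightly mutated copies from
#' independently written reviews, which in practice share only function
#' words (Jaccard well below 0.2) and no bigrams.
#'
#' @param text_a,text_b Raw review texts (length-1 character).
#' @param jaccard_threshold Same-author flag fires at or above this Jaccard
#'   similarity. Default 0.6.
#' @param bigram_threshold Same-author flag fires at or above this many
#'   shared bigrams. Default 3.
#' @param lowercase,strip_punct Tokenization policy, see [tokenize()].
#' @return One-row tibble with columns `ttr_a`, `ttr_b`, `jaccard`,
#'   `common_word_count`, `union_word_count`, `bigram_overlap` and (for
#'   `screen_pair`) `same_author_flag`.
#' @export
#' @examples
#' screen_pair("found a rat near the table", "found a rat near the table")
compare_patterns <- function(text_a, text_b, lowercase = TRUE,
                             strip_punct = TRUE) {
  stopifnot(length(text_a) == 1L, length(text_b) == 1L)
  toks <- tokenize(c(text_a, text_b), lowercase = lowercase,
                   strip_punct = strip_punct)
  a <- toks[[1L]]
  b <- toks[[2L]]
  ua <- unique(a)
  ub <- unique(b)
  common <- length(intersect(ua, ub))
  uni <- length(union(ua, ub))
  tibble::tibble(
    ttr_a = if (length(a)) type_token_ratio(a) else NA_real_,
    ttr_b = if (length(b)) type_token_ratio(b) else NA_real_,
    jaccard = if (uni > 0L) common / uni else NA_real_,
    common_word_count = common,
    union_word_count = uni,
    bigram_overlap = bigram_overlap(a, b)
  )
}

#' @rdname compare_patterns
#' @export
screen_pair <- function(text_a, text_b, jaccard_threshold = 0.6,
                        bigram_threshold = 3, lowercase = TRUE,
                        strip_punct = TRUE) {
  cmp <- compare_patterns(text_a, text_b, lowercase = lowercase,
                          strip_punct = strip_punct)
  cmp$same_author_flag <-
    (!is.na(cmp$jaccard) && cmp$jaccard >= jaccard_threshold) ||
    cmp$bigram_overlap >= bigram_threshold
  cmp
}

# Pairwise same-author screen for all reviews of one restaurant, done with
# binary incidence matrices so the all-pairs comparison stays cheap at
# desk scale (a few hundred reviews). Returns a logical adjacency matrix.
same_author_matrix <- function(tokens, jaccard_threshold, bigram_threshold) {
  n <- length(tokens)
  if (n < 2L) return(matrix(FALSE, n, n))
  incidence <- function(sets) {
    vocab <- unique(unlist(sets, use.names = FALSE))
    m <- matrix(0L, nrow = length(sets), ncol = length(vocab))
    for (i in seq_along(sets)) {
      m[i, match(sets[[i]], vocab)] <- 1L
    }
    m
  }
  usets <- lapply(tokens, unique)
  m1 <- incidence(usets)
  common <- tcrossprod(m1)
  sizes <- rowSums(m1)
  uni <- outer(sizes, sizes, "+") - common
  jac <- ifelse(uni > 0, common / uni, NA_real_)
  bsets <- lapply(tokens, token_bigrams)
  if (any(lengths(bsets) > 0)) {
    m2 <- incidence(bsets)
    bov <- tcrossprod(m2)
  } else {
    bov <- matrix(0L, n, n)
  }
  adj <- (!is.na(jac) & jac >= jaccard_threshold) | (bov >= bigram_threshold)
  diag(adj) <- FALSE
  adj
}

#' Mark near-duplicate reviews within each restaurant
#'
#' Screens every within-restaurant pair of reviews with the same-author
#' metrics and groups flagged pairs into connected components. Within each
#' component the earliest review by date is kept; later members are marked
#' excluded as duplicates (noise), so a copied complaint cannot inflate the
#' hygiene signal.
#'
#' @param reviews Tibble with at least `restaurant_id`, `date` (Date) and
#'   `text` columns.
#' @inheritParams screen_pair
#' @return `reviews` with two added columns: integer `duplicate_group`
#'   (NA for unflagged reviews; groups are numbered within restaurant) and
#'   logical `excluded_duplicate`.
#' @export
mark_duplicates <- function(reviews, jaccard_threshold = 0.6,
                            bigram_threshold = 3, lowercase = TRUE,
                            strip_punct = TRUE) {
  stopifnot(all(c("restaurant_id", "date", "text") %in% names(reviews)))
  reviews$duplicate_group <- NA_integer_
  reviews$excluded_duplicate <- FALSE
  for (rid in unique(reviews$restaurant_id)) {
    idx <- which(reviews$restaurant_id == rid)
    if (length(idx) < 2L) next
    toks <- tokenize(reviews$text[idx], lowercase = lowercase,
                     strip_punct = strip_punct)
    adj <- same_author_matrix(toks, jaccard_threshold, bigram_threshold)
    if (!any(adj)) next
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)
    grp <- 0L
    for (k in seq_len(comp$no)) {
      members <- idx[comp$membership == k]
      if (length(members) < 2L) next
      grp <- grp + 1L
      reviews$duplicate_group[members] <- grp
      keep <- members[order(reviews$date[members], members)][1L]
      reviews$excluded_duplicate[setdiff(members, keep)] <- TRUE
    }
  }
  reviews
}
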