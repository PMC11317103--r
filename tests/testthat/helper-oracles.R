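# Independent brute-force oracles, kept deliberately naive: explicit
# enumeration loops rather than R's set operations, so they share no code
# path with the implementation they check.

oracle_unique <- function(tokens) {
  out <- character(0)
  for (t in tokens) {
    seen <- FALSE
    for (u in out) if (identical(u, t)) seen <- TRUE
    if (!seen) out <- c(out, t)
  }
  out
}

oracle_jaccard <- function(a, b) {
  ua <- oracle_unique(a)
  ub <- oracle_unique(b)
  common <- 0L
  for (x in ua) for (y in ub) if (identical(x, y)) common <- common + 1L
  total <- length(ua) + length(ub) - common
  if (total == 0L) return(NA_real_)
  common / total
}

oracle_bigram_overlap <- function(a, b) {
  bigrams <- function(t) {
    if (length(t) < 2L) return(character(0))
    out <- character(0)
    for (i in seq_len(length(t) - 1L)) {
      out <- c(out, paste(t[i], t[i + 1L]))
    }
    oracle_unique(out)
  }
  ba <- bigrams(a)
  bb <- bigrams(b)
  n <- 0L
  for (x in ba) for (y in bb) if (identical(x, y)) n <- n + 1L
  n
}

oracle_gof <- function(observed, totals) {
  expected <- totals * sum(observed) / sum(totals)
  stat <- 0
  for (i in seq_along(observed)) {
    stat <- stat + (observed[i] - expected[i])^2 / expected[i]
  }
  list(statistic = stat,
       p_value = stats::pchisq(stat, length(observed) - 1,
                               lower.tail = FALSE))
}

# random token sequences over a small alphabet, for property tests
random_tokens <- function(n, alphabet = letters[1:8]) {
  sample(alphabet, n, replace = TRUE)
}

# the bundled eight-month illustration series
example_series <- function() {
  s <- utils::read.csv(foodsig_example("monthly_series_example.csv"),
                       stringsAsFactors = FALSE)
  s$month <- as.Date(s$month)
  s
}

# the bundled per-category worked-example counts
example_assessments <- function() {
  utils::read.csv(foodsig_example("worked_example_assessments.csv"),
                  stringsAsFactors = FALSE)
}

# the bundled pair of independently written reviews
example_review_pair <- function() {
  utils::read.csv(foodsig_example("review_pair_example.csv"),
                  stringsAsFactors = FALSE)$text
}

# minimal eligible profile for hand-built pipeline inputs
make_profile <- function(id, category = "CASUAL_DINING",
                         total_reviews = 1500,
                         first_review = as.Date("2019-01-01")) {
  tibble::tibble(
    restaurant_id = id, category = category,
    lat = 12.905, lon = 77.645,
    total_review_count = total_reviews,
    first_review_date = first_review
  )
}
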