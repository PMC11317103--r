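#' Sub-aspect severity weights
#'
#' Points per negative review contributed by each sub-aspect, proportional
#' to the weighting of the corresponding items in the regulatory inspection
#' checklist. The `"default"` preset (cleanliness 2, external objects 3,
#' handling 2, packaging 1, pest control 3, undercooked/rotten/smelly 3,
#' health outcomes 4, upkeep 2) sums to 20, so one negative review under
#' every sub-aspect scores 20 points. The `"alternate"` preset lowers
#' cleanliness and upkeep to 1 point each; it reflects a second internally
#' consistent reading of the published worked examples and is provided so
#' both readings stay testable, never merged.
#'
#' @param preset `"default"`, `"alternate"`, or a named numeric vector
#'   giving a custom weight for each of the eight sub-aspects.
#' @return Named integer-valued numeric vector over the eight sub-aspects.
#' @export
#' @examples
#' sum(subaspect_weights())  # 20
subaspect_weights <- function(preset = "default") {
  if (is.numeric(preset)) {
    w <- preset
  } else {
    w <- switch(match.arg(preset, c("default", "alternate")),
      default = c(
        CLEANLINESS_DINING = 2, EXTERNAL_OBJECTS = 3, FOOD_HANDLING = 2,
        FOOD_PACKAGING = 1, PEST_CONTROL = 3,
        UNDERCOOKED_ROTTEN_SMELLY = 3, UNINTENDED_HEALTH_OUTCOME = 4,
        UPKEEP_INFRA = 2
      ),
      alternate = c(
        CLEANLINESS_DINING = 1, EXTERNAL_OBJECTS = 3, FOOD_HANDLING = 2,
        FOOD_PACKAGING = 1, PEST_CONTROL = 3,
        UNDERCOOKED_ROTTEN_SMELLY = 3, UNINTENDED_HEALTH_OUTCOME = 4,
        UPKEEP_INFRA = 1
      )
    )
  }
  if (!setequal(names(w), SUBASPECTS) || anyNA(w) || any(w <= 0)) {
    stop("weights must name all eight sub-aspects with positive values")
  }
  w[SUBASPECTS]
}

#' Causality Assessment Index
#'
#' The CAI for a restaurant is the ratio of negative to positive
#' hygiene-aspect reviews over the assessment window. A CAI above 1 means
#' complaints outnumber praise on hygiene and establishes a genuine concern
#' warranting regulatory attention (the causality flag). With no positive
#' hygiene reviews but some negatives the index is infinite (flag raised);
#' with no hygiene reviews at all it is not assessable (`NA`, flag down).
#'
#' @param n_negative,n_positive Non-negative counts of negative and
#'   positive hygiene-aspect reviews (vectorized).
#' @return Numeric vector: the ratio, `Inf`, or `NA_real_`. Report with
#'   [format_cai()] for the conventional 2-decimal display.
#' @export
#' @examples
#' compute_cai(6, 2)        # 3
#' causality_flag(compute_cai(6, 4))
compute_cai <- function(n_negative, n_positive) {
  if (any(is.na(n_negative)) || any(is.na(n_positive)) ||
      any(n_negative < 0) || any(n_positive < 0)) {
    stop("review counts must be non-negative and non-missing")
  }
  dplyr::case_when(
    n_positive > 0 ~ n_negative / n_positive,
    n_negative > 0 ~ Inf,
    .default = NA_real_
  )
}

#' @rdname compute_cai
#' @param cai A CAI value (vectorized; may be `Inf` or `NA`).
#' @export
causality_flag <- function(cai) {
  !is.na(cai) & cai > 1
}

#' @rdname compute_cai
#' @export
format_cai <- function(cai) {
  dplyr::case_when(
    is.na(cai) ~ "NA",
    is.infinite(cai) ~ "Inf",
    .default = sprintf("%.2f", cai)
  )
}

#' Severity Assessment Score
#'
#' Weighted sum of per-sub-aspect negative review counts:
#' `SAS = sum(count[s] * weight[s])` over the eight sub-aspects. Severity
#' is assessed once causality is established (CAI above 1); the score
#' prioritizes regulatory action by grading into five public-health risk
#' bands.
#'
#' @param counts Named vector of negative-review counts per sub-aspect
#'   (missing names count 0), e.g. from [tally_subaspects()].
#' @param weights Weight vector from [subaspect_weights()].
#' @return Single numeric score (integer-valued under integer weights).
#' @export
#' @examples
#' compute_sas(c(FOOD_HANDLING = 1, UNDERCOOKED_ROTTEN_SMELLY = 5))  # 17
compute_sas <- function(counts, weights = subaspect_weights()) {
  weights <- subaspect_weights(weights)
  if (is.null(names(counts))) {
    stop("counts must be named by sub-aspect")
  }
  unknown <- setdiff(names(counts), SUBASPECTS)
  if (length(unknown)) {
    stop("unknown sub-aspect(s) in counts: ", paste(unknown, collapse = ", "))
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  full <- setNames(numeric(length(SUBASPECTS)), SUBASPECTS)
  full[names(counts)] <- counts
  sum(full * weights)
}

#' Grade a severity score into a public-health risk band
#'
#' Five bands on the Severity Assessment Score: up to 5 points is low risk,
#' 6-10 slightly higher, 11-15 high, 16-20 higher, and above 20 the highest
#' risk to public health. Band edges are inclusive upper bounds and
#' configurable.
#'
#' @param score Numeric score(s), non-negative.
#' @param bands Increasing numeric vector of the four inner band edges,
#'   default `c(5, 10, 15, 20)`.
#' @return Character vector of grades: `"LOW"`, `"SLIGHTLY_HIGHER"`,
#'   `"HIGH"`, `"HIGHER"`, `"HIGHEST"`.
#' @export
#' @examples
#' grade_sas(c(5, 17, 21))
grade_sas <- function(score, bands = c(5, 10, 15, 20)) {
  stopifnot(length(bands) == 4L, !is.unsorted(bands))
  if (any(score < 0, na.rm = TRUE)) stop("score must be non-negative")
  as.character(cut(score, breaks = c(-Inf, bands, Inf),
                   labels = c("LOW", "SLIGHTLY_HIGHER", "HIGH",
                              "HIGHER", "HIGHEST")))
}

#' Assemble a per-restaurant signal assessment
#'
#' Composes the scoring chain for one restaurant over one assessment
#' window: CAI from the hygiene review counts, the causality flag, and —
#' only when causality is established — the Severity Assessment Score and
#' its risk grade. Restaurants excluded upstream (for instance when
#' duplicate screening removed most of their hygiene reviews) carry the
#' exclusion reason and are neither indexed nor graded.
#'
#' @param restaurant_id Identifier.
#' @param n_negative,n_positive Hygiene review counts after screening.
#' @param subaspect_counts Named counts from [tally_subaspects()].
#' @param temporal Optional `temporal_result` from [temporal_verdict()].
#' @param weights,bands Scoring configuration.
#' @param excluded,exclusion_reason Exclusion status from screening.
#' @return One-row tibble with columns `restaurant_id`, `n_negative`,
#'   `n_positive`, `cai`, `causality`, `sas`, `grade`, `temporal_p`,
#'   `temporal_verdict`, `spike_months` (list-column), `excluded`,
#'   `exclusion_reason`.
#' @export
assess_restaurant <- function(restaurant_id, n_negative, n_positive,
                              subaspect_counts,
                              temporal = NULL,
                              weights = subaspect_weights(),
                              bands = c(5, 10, 15, 20),
                              excluded = FALSE,
                              exclusion_reason = NA_character_) {
  if (excluded) {
    cai <- NA_real_
    flag <- FALSE
    sas <- NA_real_
    grade <- "NOT_GRADED"
  } else {
    cai <- compute_cai(n_negative, n_positive)
    flag <- causality_flag(cai)
    sas <- compute_sas(subaspect_counts, weights)
    grade <- if (flag) grade_sas(sas, bands) else "NOT_GRADED"
  }
  tibble::tibble(
    restaurant_id = restaurant_id,
    n_negative = as.integer(n_negative),
    n_positive = as.integer(n_positive),
    cai = cai,
    causality = flag,
    sas = sas,
    grade = grade,
    subaspect_counts = list({
      full <- setNames(integer(length(SUBASPECTS)), SUBASPECTS)
      if (!excluded && !is.null(names(subaspect_counts))) {
        full[names(subaspect_counts)] <- as.integer(subaspect_counts)
      }
      full
    }),
    temporal_p = if (is.null(temporal)) NA_real_ else temporal$p_value,
    temporal_verdict = if (is.null(temporal)) NA_character_
                       else temporal$verdict,
    spike_months = list(if (is.null(temporal)) as.Date(character(0))
                        else temporal$spike_months),
    excluded = excluded,
    exclusion_reason = exclusion_reason
  )
}
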