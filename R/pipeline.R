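#' Surveillance configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults:
#' eligibility at 1000 total reviews and more than 2 years of listing
#' history; a 12-month assessment window; same-author screening at Jaccard
#' 0.6 or 3 shared bigrams, with a restaurant excluded outright when more
#' than half of its hygiene reviews are removed as duplicates; temporal
#' screen at alpha 0.05 with spike months at standardized residual 2;
#' default severity weights and grade bands; geo jitter of 5-10 metres.
#'
#' @param ... Named overrides of any default (unknown names are an error).
#' @return A named list of class `surveillance_config`.
#' @export
#' @examples
#' surveillance_config(temporal_alpha = 0.01)
surveillance_config <- function(...) {
  cfg <- list(
    min_reviews = 1000,
    min_age_years = 2,
    window_months = 12,
    tokenize_lowercase = TRUE,
    tokenize_strip_punct = TRUE,
    jaccard_threshold = 0.6,
    bigram_threshold = 3,
    dup_exclusion_fraction = 0.5,
    temporal_alpha = 0.05,
    spike_residual_threshold = 2,
    weights_preset = "default",
    grade_bands = c(5, 10, 15, 20),
    jitter_m = c(5, 10),
    use_fallback_labeller = FALSE,
    apply_polarity_override = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "surveillance_config")
}

#' @rdname surveillance_config
#' @param path YAML file of config overrides.
#' @export
read_config <- function(path) {
  do.call(surveillance_config, yaml::read_yaml(path))
}

#' Eligibility filter for surveillance
#'
#' A restaurant enters surveillance only with enough review history for
#' signal detection: at least `min_reviews` total platform reviews and a
#' listing older than `min_age_years` at the reference date. Every
#' exclusion is logged with its reason.
#'
#' @param profiles Tibble with `restaurant_id`, `total_review_count` and
#'   `first_review_date` columns.
#' @param min_reviews Minimum lifetime review count, default 1000.
#' @param min_age_years Minimum listing age in years (strict), default 2.
#' @param ref_date Date the age is measured at; defaults to today.
#' @return List with `eligible` (subset of `profiles`) and `exclusions`
#'   (tibble of `restaurant_id`, `reason`).
#' @export
filter_eligible <- function(profiles, min_reviews = 1000, min_age_years = 2,
                            ref_date = Sys.Date()) {
  stopifnot(all(c("restaurant_id", "total_review_count", "first_review_date")
                %in% names(profiles)))
  age_years <- as.numeric(ref_date - as.Date(profiles$first_review_date)) /
    365.25
  too_few <- profiles$total_review_count < min_reviews
  too_young <- !(age_years > min_age_years)
  reason <- dplyr::case_when(
    too_few & too_young ~ "below review threshold; listing too young",
    too_few ~ "below review threshold",
    too_young ~ "listing too young",
    .default = NA_character_
  )
  list(
    eligible = profiles[is.na(reason), , drop = FALSE],
    exclusions = tibble::tibble(
      restaurant_id = profiles$restaurant_id[!is.na(reason)],
      reason = reason[!is.na(reason)]
    )
  )
}

validate_reviews <- function(reviews) {
  required <- c("restaurant_id", "date", "text")
  missing <- setdiff(required, names(reviews))
  if (length(missing)) {
    stop("reviews table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"hygiene_polarity" %in% names(reviews)) {
    reviews$hygiene_polarity <- NA_character_
  }
  bad_pol <- which(!is.na(reviews$hygiene_polarity) &
                     !reviews$hygiene_polarity %in%
                       c("positive", "negative", "none"))
  if (length(bad_pol)) {
    stop("invalid hygiene_polarity at row(s) ",
         paste(head(bad_pol, 5), collapse = ", "),
         " (allowed: positive/negative/none/NA)")
  }
  dates <- as.Date(reviews$date)
  bad_date <- which(is.na(dates))
  if (length(bad_date)) {
    stop("unparseable or missing date at row(s) ",
         paste(head(bad_date, 5), collapse = ", "))
  }
  reviews$date <- dates
  reviews
}

validate_profiles <- function(profiles) {
  required <- c("restaurant_id", "category", "lat", "lon",
                "total_review_count", "first_review_date")
  missing <- setdiff(required, names(profiles))
  if (length(missing)) {
    stop("profiles table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad_cat <- which(!profiles$category %in% RESTAURANT_CATEGORIES)
  if (length(bad_cat)) {
    stop("unknown category at row(s) ", paste(head(bad_cat, 5), collapse = ", "))
  }
  bad_coord <- which(abs(profiles$lat) > 90 | abs(profiles$lon) > 180)
  if (length(bad_coord)) {
    stop("coordinates out of range at row(s) ",
         paste(head(bad_coord, 5), collapse = ", "))
  }
  profiles
}

#' Run the full surveillance pipeline
#'
#' End-to-end passive surveillance over a review table and a restaurant
#' profile table: eligibility filtering, optional fallback labelling of
#' unlabeled reviews, polarity override of mislabelled positives,
#' within-restaurant near-duplicate exclusion, the monthly chi-square
#' temporal screen, sub-aspect classification of negative reviews, CAI,
#' SAS and risk grading, and category-level aggregation. Every input
#' review ends up in exactly one disposition: `non-hygiene`,
#' `hygiene-positive`, `hygiene-negative`, `excluded-duplicate` or
#' `unlabeled-skipped`. The run is deterministic for a fixed config.
#'
#' @param reviews Tibble of reviews: `restaurant_id`, `date`, `text`,
#'   optional `hygiene_polarity` (`positive`/`negative`/`none`/`NA`).
#' @param profiles Tibble of restaurant profiles: `restaurant_id`,
#'   `category`, `lat`, `lon`, `total_review_count`, `first_review_date`.
#' @param config A [surveillance_config()].
#' @param lexicon Sub-aspect lexicon, default the shipped one.
#' @param ref_date Reference date for eligibility and window placement;
#'   defaults to the latest review date (keeps runs reproducible).
#' @return A `surveillance_report` list: `assessments` (per-restaurant
#'   tibble), `category_summary`, `dispositions` (per-review tibble),
#'   `eligibility_exclusions`, `window`, `config`.
#' @export
run_surveillance <- function(reviews, profiles,
                             config = surveillance_config(),
                             lexicon = default_lexicon(),
                             ref_date = NULL) {
  stopifnot(inherits(config, "surveillance_config"))
  reviews <- validate_reviews(tibble::as_tibble(reviews))
  profiles <- validate_profiles(tibble::as_tibble(profiles))
  if (is.null(ref_date)) ref_date <- max(reviews$date)
  ref_date <- as.Date(ref_date)
  window_start <- seq(floor_month(ref_date), by = "-1 month",
                      length.out = config$window_months)
  window <- c(min(window_start), ref_date)

  elig <- filter_eligible(profiles, config$min_reviews,
                          config$min_age_years, ref_date = ref_date)
  weights <- subaspect_weights(config$weights_preset)

  # review-level working state
  reviews$.row <- seq_len(nrow(reviews))
  reviews$polarity_final <- reviews$hygiene_polarity
  reviews$overridden <- FALSE
  reviews$fallback_labelled <- FALSE

  unlab <- is.na(reviews$polarity_final)
  if (config$use_fallback_labeller && any(unlab)) {
    reviews$polarity_final[unlab] <- vapply(
      reviews$text[unlab], fallback_polarity, character(1),
      lexicon = lexicon
    )
    reviews$fallback_labelled[unlab] <- TRUE
  }
  pos <- !is.na(reviews$polarity_final) & reviews$polarity_final == "positive"
  if (config$apply_polarity_override && any(pos)) {
    ov <- lapply(reviews$text[pos], polarity_override, upstream = "positive")
    reviews$polarity_final[pos] <- vapply(ov, `[[`, character(1), "polarity")
    reviews$overridden[pos] <- vapply(ov, `[[`, logical(1), "overridden")
  }

  in_window <- reviews$date >= window[1] & reviews$date <= window[2]
  in_scope <- in_window &
    reviews$restaurant_id %in% elig$eligible$restaurant_id

  # duplicate screen over in-scope hygiene reviews
  hyg_idx <- which(in_scope & !is.na(reviews$polarity_final) &
                     reviews$polarity_final %in% c("positive", "negative"))
  dup <- mark_duplicates(reviews[hyg_idx, , drop = FALSE],
                         jaccard_threshold = config$jaccard_threshold,
                         bigram_threshold = config$bigram_threshold,
                         lowercase = config$tokenize_lowercase,
                         strip_punct = config$tokenize_strip_punct)
  reviews$excluded_duplicate <- FALSE
  reviews$excluded_duplicate[dup$.row] <- dup$excluded_duplicate

  reviews$disposition <- dplyr::case_when(
    reviews$excluded_duplicate ~ "excluded-duplicate",
    is.na(reviews$polarity_final) ~ "unlabeled-skipped",
    reviews$polarity_final == "positive" ~ "hygiene-positive",
    reviews$polarity_final == "negative" ~ "hygiene-negative",
    .default = "non-hygiene"
  )

  reviews <- classify_reviews(
    dplyr::mutate(reviews, hygiene_polarity = dplyr::if_else(
      .data$disposition == "hygiene-negative", "negative",
      .data$polarity_final
    )),
    lexicon
  )

  assessments <- purrr::map_dfr(
    elig$eligible$restaurant_id,
    function(rid) {
      rr <- reviews[reviews$restaurant_id == rid & in_window[reviews$.row], ,
                    drop = FALSE]
      n_hyg_all <- sum(rr$disposition %in%
                         c("hygiene-positive", "hygiene-negative",
                           "excluded-duplicate"))
      n_dup <- sum(rr$disposition == "excluded-duplicate")
      if (n_hyg_all > 0 &&
          n_dup / n_hyg_all > config$dup_exclusion_fraction) {
        return(assess_restaurant(
          rid, 0L, 0L, tally_subaspects(list()),
          weights = weights, bands = config$grade_bands,
          excluded = TRUE,
          exclusion_reason = sprintf(
            "duplicate fraction %.2f > %.2f", n_dup / n_hyg_all,
            config$dup_exclusion_fraction)
        ))
      }
      clean <- rr[rr$disposition != "excluded-duplicate", , drop = FALSE]
      series <- aggregate_monthly(
        dplyr::transmute(
          clean,
          date = .data$date,
          hygiene_polarity = dplyr::case_when(
            .data$disposition == "hygiene-positive" ~ "positive",
            .data$disposition == "hygiene-negative" ~ "negative",
            .default = "none"
          )
        ),
        window = window
      )
      temporal <- temporal_verdict(series,
                                   alpha = config$temporal_alpha,
                                   spike_threshold =
                                     config$spike_residual_threshold)
      neg <- clean[clean$disposition == "hygiene-negative", , drop = FALSE]
      assess_restaurant(
        rid,
        n_negative = nrow(neg),
        n_positive = sum(clean$disposition == "hygiene-positive"),
        subaspect_counts = tally_subaspects(neg$matched_subaspects),
        temporal = temporal,
        weights = weights,
        bands = config$grade_bands
      )
    }
  )
  assessments <- dplyr::left_join(
    assessments,
    dplyr::select(profiles, "restaurant_id", "category"),
    by = "restaurant_id"
  )

  structure(
    list(
      assessments = assessments,
      category_summary = summarize_by_category(assessments),
      dispositions = dplyr::select(
        reviews,
        dplyr::any_of("review_id"),
        "restaurant_id", "date", "disposition",
        "overridden", "fallback_labelled"
      ),
      eligibility_exclusions = elig$exclusions,
      window = window,
      config = unclass(config)
    ),
    class = "surveillance_report"
  )
}

#' @export
print.surveillance_report <- function(x, ...) {
  cat("<surveillance_report>\n")
  cat(sprintf("  window: %s to %s\n", x$window[1], x$window[2]))
  cat(sprintf("  restaurants assessed: %d (%d excluded in screening)\n",
              nrow(x$assessments), sum(x$assessments$excluded)))
  cat(sprintf("  causality flags (CAI > 1): %d\n",
              sum(x$assessments$causality)))
  cat(sprintf("  reviews by disposition: %s\n",
              paste(names(table(x$dispositions$disposition)),
                    table(x$dispositions$disposition),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Category-level summary of assessments
#'
#' Per restaurant category: restaurants assessed, restaurants whose data
#' qualified (not excluded in screening), restaurants with CAI above 1,
#' mean CAI (over qualified restaurants with a finite index; infinite and
#' not-assessable values are left out of the mean) and mean SAS over graded
#' restaurants only. The overall fraction of qualified restaurants with
#' CAI above 1 is attached as attribute `cai_above_1_fraction`.
#'
#' @param assessments Assessment tibble with a `category` column.
#' @return Summary tibble, one row per category present.
#' @export
summarize_by_category <- function(assessments) {
  stopifnot("category" %in% names(assessments))
  out <- assessments |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_restaurants = dplyr::n(),
      n_qualified = sum(!.data$excluded),
      n_cai_above_1 = sum(.data$causality, na.rm = TRUE),
      mean_cai = mean(.data$cai[!.data$excluded & is.finite(.data$cai)]),
      mean_sas = mean(.data$sas[.data$grade != "NOT_GRADED"]),
      .groups = "drop"
    )
  qualified <- !assessments$excluded & !is.na(assessments$cai)
  attr(out, "cai_above_1_fraction") <-
    if (any(qualified)) mean(assessments$causality[qualified]) else NA_real_
  out
}

# metres -> degrees at a given latitude (local flat-earth approximation
# with WGS84 degree lengths; error is far below 1 cm at the 10 m scale of
# the privacy jitter)
jitter_offset <- function(lat_deg, distance_m, bearing_rad) {
  phi <- lat_deg * pi / 180
  m_per_deg_lat <- 111132.954 - 559.822 * cos(2 * phi) +
    1.175 * cos(4 * phi)
  m_per_deg_lon <- 111412.84 * cos(phi) - 93.5 * cos(3 * phi) +
    0.118 * cos(5 * phi)
  c(dlat = distance_m * cos(bearing_rad) / m_per_deg_lat,
    dlon = distance_m * sin(bearing_rad) / m_per_deg_lon)
}

#' Export assessments as privacy-jittered GeoJSON
#'
#' Writes one point feature per assessed restaurant (RFC 7946). To avoid
#' exact identification of establishments, each point is displaced by a
#' uniformly random bearing and a uniformly random distance between the
#' jitter bounds (default 5-10 metres), seeded for reproducibility: the
#' same seed gives byte-identical output. Features carry category, CAI,
#' SAS and grade; restaurants with causality established are styled in
#' orange with marker size growing with SAS, the rest in green.
#'
#' @param assessments Assessment tibble (e.g. `report$assessments`).
#' @param profiles Profile tibble supplying `lat`/`lon` per restaurant.
#' @param path Output file; when `NULL` nothing is written.
#' @param jitter_m Length-2 numeric, min and max displacement in metres.
#' @param seed Integer seed for the jitter draws.
#' @return The feature collection as a list, invisibly when writing.
#' @export
export_geojson <- function(assessments, profiles, path = NULL,
                           jitter_m = c(5, 10), seed = 1L) {
  stopifnot(length(jitter_m) == 2L, jitter_m[1] <= jitter_m[2])
  df <- dplyr::left_join(
    assessments,
    dplyr::select(profiles, "restaurant_id", "lat", "lon"),
    by = "restaurant_id"
  )
  has_coord <- !is.na(df$lat) & !is.na(df$lon)
  if (any(!has_coord)) {
    warning(sum(!has_coord), " feature(s) skipped: missing coordinates")
    df <- df[has_coord, , drop = FALSE]
  }
  n <- nrow(df)
  feats <- withr::with_seed(seed, {
    bearing <- runif(n, 0, 2 * pi)
    dist <- runif(n, jitter_m[1], jitter_m[2])
    lapply(seq_len(n), function(i) {
      off <- jitter_offset(df$lat[i], dist[i], bearing[i])
      flagged <- isTRUE(df$causality[i])
      list(
        type = "Feature",
        geometry = list(
          type = "Point",
          coordinates = c(df$lon[i] + off[["dlon"]],
                          df$lat[i] + off[["dlat"]])
        ),
        properties = list(
          restaurant_id = df$restaurant_id[i],
          category = df$category[i],
          cai = if (is.na(df$cai[i]) || is.infinite(df$cai[i]))
                  format_cai(df$cai[i]) else round(df$cai[i], 2),
          sas = df$sas[i],
          grade = df$grade[i],
          causality = flagged,
          `marker-color` = if (flagged) "#ff7f0e" else "#2ca02c",
          `marker-size` = if (flagged && !is.na(df$sas[i]))
                            round(6 + 0.5 * df$sas[i], 1) else 6
        )
      )
    })
  })
  fc <- list(type = "FeatureCollection", features = feats)
  if (!is.null(path)) {
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    return(invisible(fc))
  }
  fc
}
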