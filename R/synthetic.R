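# Vocabulary for synthetic review text. The filler pool is deliberately
# disjoint from the lexicon triggers and the override cue lists (as token
# prefixes), so planted ground truth and lexicon classification coincide
# exactly. Hygiene review texts are sampled word salads rather than fixed
# templates: fixed templates would share long runs of bigrams across
# independent reviews and trip the same-author screen.
FILLER_WORDS <- c(
  "place", "service", "staff", "ambience", "portions", "menu", "visit",
  "family", "value", "money", "parking", "options", "music", "loud",
  "weekend", "lunch", "evening", "crowd", "corner", "seating", "quick",
  "friendly", "generous", "decent", "office", "locality", "famous",
  "paneer", "tikka", "lassi", "biryani", "thali", "dosa", "order",
  "billing", "counter", "manager", "window", "courtyard", "terrace",
  "buffet", "starters", "dessert", "beverage", "coffee", "tea", "snacks",
  "dinner", "breakfast", "festival", "holiday", "birthday", "celebration",
  "group", "couple", "kids", "elders", "colleagues", "friends", "neighbour",
  "highway", "avenue", "street", "signal", "landmark", "entrance", "lobby",
  "balcony", "rooftop", "garden", "fountain", "lighting", "decor",
  "painting", "plates", "cutlery", "glasses", "napkin", "chairs", "sofa",
  "booth", "queue", "token", "coupon", "discount", "offer", "combo",
  "platter", "portion", "quantity", "variety", "timing", "delivery",
  "packing", "takeaway"
)

# fixed sentences are only ever used for non-hygiene reviews, which the
# duplicate screen never touches
NON_HYGIENE_SENTENCES <- c(
  "the service was quick and the staff were friendly",
  "good ambience and generous portions",
  "loved the paneer tikka and the lassi",
  "will definitely visit again with family",
  "value for money and easy parking",
  "the menu has many options for vegetarians",
  "music was a bit loud on the weekend",
  "waiting time was long during lunch hour",
  "the biryani here is famous in the locality",
  "decent place for a quick bite near the office"
)

POSITIVE_HYGIENE_TERMS <- c("clean", "spotless", "fresh", "hygienic",
                            "well maintained")

random_filler <- function(n_words) {
  paste(sample(FILLER_WORDS, n_words), collapse = " ")
}

#' Describe a synthetic suburb scenario
#'
#' Parameter object for the seeded review-stream generator. The defaults
#' emulate the study regime of an urban Indian suburb: 156 listed
#' restaurants of which 93 clear the 1000-review eligibility bar, split
#' 63 casual dining / 2 fine dining / 4 buffet / 13 quick service /
#' 11 food truck-dhaba; a 12-month window; monthly review volumes drawn
#' from category-specific Poisson means; about 20% of reviews touching the
#' hygiene aspect; and a baseline where negative hygiene reviews run at
#' roughly 10% of all reviews (half of the hygiene stream). On top of the
#' baseline the scenario plants, with known ground truth: deficient
#' restaurants with an elevated negative share and a sub-aspect deficiency
#' profile, spike events that multiply one month's negative rate, and
#' near-duplicate review clusters.
#'
#' @param n_eligible Named counts of eligible restaurants per category.
#' @param n_ineligible Listed restaurants below the eligibility bar.
#' @param months Window length in months.
#' @param monthly_volume Named Poisson means of monthly review totals.
#' @param hygiene_fraction Probability a review is hygiene-related.
#' @param baseline_neg_share Probability a hygiene review is negative, at
#'   baseline.
#' @param n_deficient Number of planted deficient restaurants.
#' @param deficient_neg_share Negative share of hygiene reviews at planted
#'   restaurants (default 0.75, i.e. negatives outnumber positives 3:1).
#' @param n_spike Restaurants given one spike month.
#' @param spike_multiplier Multiplier on the negative share in the spike
#'   month (capped at 0.95).
#' @param n_duplicate_clusters Restaurants given a duplicate cluster.
#' @param duplicate_cluster_size Reviews per cluster (1 original + copies).
#' @param duplicate_mutation_rate Per-token mutation probability in copies.
#' @param fixed_totals Optional integer vector of exact monthly review
#'   totals (recycled over restaurants) replacing the Poisson draw, for
#'   exact-replication tests.
#' @param center Named lat/lon of the suburb centre.
#' @return A `suburb_scenario` list.
#' @export
suburb_scenario <- function(n_eligible = c(CASUAL_DINING = 63,
                                           FINE_DINING = 2,
                                           BUFFET = 4,
                                           QUICK_SERVICE = 13,
                                           FOOD_TRUCK_DHABA = 11),
                            n_ineligible = 63,
                            months = 12,
                            monthly_volume = c(CASUAL_DINING = 40,
                                               FINE_DINING = 35,
                                               BUFFET = 45,
                                               QUICK_SERVICE = 50,
                                               FOOD_TRUCK_DHABA = 25),
                            hygiene_fraction = 0.2,
                            baseline_neg_share = 0.5,
                            n_deficient = 8,
                            deficient_neg_share = 0.75,
                            n_spike = 3,
                            spike_multiplier = 5,
                            n_duplicate_clusters = 3,
                            duplicate_cluster_size = 6,
                            duplicate_mutation_rate = 0,
                            fixed_totals = NULL,
                            center = c(lat = 12.905, lon = 77.645)) {
  sc <- list(
    n_eligible = n_eligible, n_ineligible = n_ineligible, months = months,
    monthly_volume = monthly_volume, hygiene_fraction = hygiene_fraction,
    baseline_neg_share = baseline_neg_share, n_deficient = n_deficient,
    deficient_neg_share = deficient_neg_share, n_spike = n_spike,
    spike_multiplier = spike_multiplier,
    n_duplicate_clusters = n_duplicate_clusters,
    duplicate_cluster_size = duplicate_cluster_size,
    duplicate_mutation_rate = duplicate_mutation_rate,
    fixed_totals = fixed_totals, center = center
  )
  stopifnot(
    setequal(names(sc$n_eligible), RESTAURANT_CATEGORIES),
    all(sc$n_eligible >= 0), sc$n_ineligible >= 0, sc$months >= 1,
    all(sc$monthly_volume > 0),
    sc$hygiene_fraction >= 0, sc$hygiene_fraction <= 1,
    sc$baseline_neg_share >= 0, sc$baseline_neg_share <= 1,
    sc$deficient_neg_share >= 0, sc$deficient_neg_share <= 1,
    sc$spike_multiplier >= 1, sc$duplicate_cluster_size >= 1,
    sc$duplicate_mutation_rate >= 0, sc$duplicate_mutation_rate <= 1,
    sc$n_deficient + sc$n_spike + sc$n_duplicate_clusters <=
      sum(sc$n_eligible)
  )
  structure(sc, class = "suburb_scenario")
}

# Negative hygiene text: a short trigger phrase (at most two tokens, so
# independent reviews citing the same deficiency share at most one bigram)
# embedded at a random position in a random filler salad.
make_negative_text <- function(lexicon, aspect) {
  phrases <- lexicon[[aspect]]
  short <- phrases[lengths(strsplit(phrases, " ", fixed = TRUE)) <= 2L]
  if (!length(short)) short <- phrases
  phrase <- sample(short, 1L)
  filler <- sample(FILLER_WORDS, 9L)
  at <- sample.int(10L, 1L)
  paste(append(filler, phrase, after = at - 1L), collapse = " ")
}

make_positive_text <- function() {
  paste(random_filler(8L), sample(POSITIVE_HYGIENE_TERMS, 1L))
}

mutate_tokens <- function(text, rate) {
  if (rate <= 0) return(text)
  toks <- tokenize(text)[[1L]]
  flip <- runif(length(toks)) < rate
  toks[flip] <- sample(FILLER_WORDS, sum(flip), replace = TRUE)
  paste(toks, collapse = " ")
}

#' Generate a synthetic suburb with known ground truth
#'
#' Draws restaurant profiles and a full year (or `months`) of daily-dated
#' review streams from a [suburb_scenario()], deterministically for a
#' fixed seed. Review texts are template-based: lexicon phrases embedded
#' in filler for negative hygiene reviews (so the planted sub-aspect is
#' recoverable exactly when the mutation rate is 0), positive-hygiene and
#' non-hygiene templates otherwise. The returned ground truth records, per
#' restaurant, the planted regime (deficient or baseline), the realized
#' per-sub-aspect negative counts, planted spike months, and planted
#' duplicate clusters.
#'
#' @param scenario A [suburb_scenario()].
#' @param seed Integer seed; same scenario and seed give identical tables.
#' @param end_date Last day of the generated window.
#' @return List with `reviews`, `profiles` and `truth` (list with
#'   `restaurants`, `spikes`, `duplicates`, `scenario`, `seed`).
#' @export
generate_scenario <- function(scenario = suburb_scenario(), seed = 1L,
                              end_date = as.Date("2023-12-31")) {
  stopifnot(inherits(scenario, "suburb_scenario"))
  lexicon <- default_lexicon()
  withr::with_seed(seed, {
    month_starts <- rev(seq(floor_month(end_date), by = "-1 month",
                            length.out = scenario$months))
    n_elig <- sum(scenario$n_eligible)
    n_all <- n_elig + scenario$n_ineligible
    ids <- sprintf("R%03d", seq_len(n_all))
    category <- c(
      rep(names(scenario$n_eligible), scenario$n_eligible),
      sample(RESTAURANT_CATEGORIES, scenario$n_ineligible, replace = TRUE)
    )
    eligible <- c(rep(TRUE, n_elig), rep(FALSE, scenario$n_ineligible))
    profiles <- tibble::tibble(
      restaurant_id = ids,
      category = category,
      lat = scenario$center[["lat"]] + runif(n_all, -0.012, 0.012),
      lon = scenario$center[["lon"]] + runif(n_all, -0.012, 0.012),
      total_review_count = ifelse(
        eligible,
        1000L + rpois(n_all, 2000),
        sample(50:999, n_all, replace = TRUE)
      ),
      first_review_date = end_date - ifelse(
        eligible,
        round(runif(n_all, 2.2 * 365, 8 * 365)),
        round(runif(n_all, 100, 3 * 365))
      )
    )

    elig_ids <- ids[eligible]
    planted <- sample(elig_ids,
                      scenario$n_deficient + scenario$n_spike +
                        scenario$n_duplicate_clusters)
    deficient_ids <- planted[seq_len(scenario$n_deficient)]
    spike_ids <- planted[scenario$n_deficient + seq_len(scenario$n_spike)]
    dup_ids <- planted[scenario$n_deficient + scenario$n_spike +
                         seq_len(scenario$n_duplicate_clusters)]
    spike_month <- setNames(
      sample(format(month_starts, "%Y-%m"), length(spike_ids),
             replace = TRUE),
      spike_ids
    )
    # per-restaurant sub-aspect deficiency profile: deficient restaurants
    # concentrate on 2 sub-aspects, baseline restaurants complain uniformly
    profile_weights <- lapply(elig_ids, function(rid) {
      w <- rep(1, length(SUBASPECTS))
      if (rid %in% deficient_ids) {
        w[sample(seq_along(SUBASPECTS), 2L)] <- 8
      }
      w / sum(w)
    })
    names(profile_weights) <- elig_ids

    rows <- list()
    truth_counts <- list()
    for (rid in elig_ids) {
      cat_r <- category[match(rid, ids)]
      neg_share0 <- if (rid %in% deficient_ids) {
        scenario$deficient_neg_share
      } else {
        scenario$baseline_neg_share
      }
      aspect_counts <- setNames(integer(length(SUBASPECTS)), SUBASPECTS)
      for (m in seq_along(month_starts)) {
        mstart <- month_starts[m]
        mdays <- as.integer(seq(mstart, by = "month", length.out = 2)[2] -
                              mstart)
        total <- if (!is.null(scenario$fixed_totals)) {
          scenario$fixed_totals[(m - 1L) %% length(scenario$fixed_totals) + 1L]
        } else {
          rpois(1L, scenario$monthly_volume[[cat_r]])
        }
        if (total == 0L) next
        # per-review probabilities of the three dispositions; a spike month
        # multiplies the negative share of *all* reviews (an incident draws
        # extra complaints), as in real complaint bursts
        p_neg <- scenario$hygiene_fraction * neg_share0
        p_pos <- scenario$hygiene_fraction * (1 - neg_share0)
        if (rid %in% spike_ids &&
            format(mstart, "%Y-%m") == spike_month[[rid]]) {
          p_neg <- min(0.9, p_neg * scenario$spike_multiplier)
          p_pos <- min(p_pos, (0.95 - p_neg) / 2)
        }
        cnt <- as.vector(stats::rmultinom(1L, total,
                                          c(p_neg, p_pos,
                                            1 - p_neg - p_pos)))
        n_neg <- cnt[1L]
        n_pos <- cnt[2L]
        n_other <- cnt[3L]
        pol <- c(rep("negative", n_neg), rep("positive", n_pos),
                 rep("none", n_other))
        aspects <- if (n_neg > 0) {
          sample(SUBASPECTS, n_neg, replace = TRUE,
                 prob = profile_weights[[rid]])
        } else {
          character(0)
        }
        if (n_neg > 0) {
          tab <- table(factor(aspects, levels = SUBASPECTS))
          aspect_counts <- aspect_counts + as.integer(tab)
        }
        text <- character(total)
        if (n_neg > 0) {
          text[seq_len(n_neg)] <- vapply(aspects, make_negative_text,
                                         character(1), lexicon = lexicon)
        }
        if (n_pos > 0) {
          text[n_neg + seq_len(n_pos)] <-
            vapply(seq_len(n_pos), function(i) make_positive_text(),
                   character(1))
        }
        if (n_other > 0) {
          text[n_neg + n_pos + seq_len(n_other)] <-
            sample(NON_HYGIENE_SENTENCES, n_other, replace = TRUE)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          restaurant_id = rid,
          date = mstart + sample.int(mdays, total, replace = TRUE) - 1L,
          text = text,
          hygiene_polarity = pol
        )
      }
      truth_counts[[rid]] <- aspect_counts
    }
    reviews <- dplyr::bind_rows(rows)
    reviews$review_id <- sprintf("V%06d", seq_len(nrow(reviews)))

    # duplicate clusters: near-copies of one existing hygiene review,
    # appended with later dates so the keep-earliest rule retains the
    # original; ground truth tracks the copy ids
    dup_truth <- list()
    for (rid in dup_ids) {
      cand <- which(reviews$restaurant_id == rid &
                      reviews$hygiene_polarity == "negative")
      if (!length(cand)) {
        cand <- which(reviews$restaurant_id == rid &
                        reviews$hygiene_polarity == "positive")
      }
      if (!length(cand)) next
      src <- sample(cand, 1L)
      n_copies <- as.integer(scenario$duplicate_cluster_size) - 1L
      copies <- tibble::tibble(
        restaurant_id = rid,
        date = reviews$date[src] + seq_len(n_copies),
        text = vapply(seq_len(n_copies), function(i) {
          mutate_tokens(reviews$text[src],
                        scenario$duplicate_mutation_rate)
        }, character(1)),
        hygiene_polarity = reviews$hygiene_polarity[src],
        review_id = sprintf("%s-D%02d", reviews$review_id[src],
                            seq_len(n_copies))
      )
      reviews <- dplyr::bind_rows(reviews, copies)
      dup_truth[[rid]] <- list(source_id = reviews$review_id[src],
                               copy_ids = copies$review_id,
                               n_copies = n_copies)
      # copies inflate the planted sub-aspect tally only if kept; ground
      # truth tracks the deduplicated stream, so counts stay as planted
    }
    reviews <- dplyr::arrange(reviews, .data$restaurant_id, .data$date)

    truth <- list(
      restaurants = tibble::tibble(
        restaurant_id = elig_ids,
        category = category[match(elig_ids, ids)],
        deficient = elig_ids %in% deficient_ids,
        neg_share = ifelse(elig_ids %in% deficient_ids,
                           scenario$deficient_neg_share,
                           scenario$baseline_neg_share),
        subaspect_counts = unname(truth_counts[elig_ids])
      ),
      spikes = tibble::tibble(
        restaurant_id = spike_ids,
        month = unname(spike_month[spike_ids])
      ),
      duplicates = tibble::tibble(
        restaurant_id = names(dup_truth),
        n_copies = vapply(dup_truth, `[[`, integer(1), "n_copies"),
        copy_ids = unname(lapply(dup_truth, `[[`, "copy_ids"))
      ),
      scenario = scenario,
      seed = seed
    )
    list(reviews = reviews, profiles = profiles, truth = truth)
  })
}

#' Compare a surveillance report against planted ground truth
#'
#' Recovery metrics for a report produced from a generated scenario:
#' sensitivity and specificity of the causality flag against the planted
#' deficient regime, agreement of recovered per-sub-aspect counts with the
#' planted counts, detection rate of planted duplicate copies, and recall
#' of planted spike months among the annotated ones.
#'
#' @param report A `surveillance_report` from [run_surveillance()].
#' @param truth Ground truth from [generate_scenario()].
#' @return List with `causality` (per-restaurant tibble), `sensitivity`,
#'   `specificity`, `subaspect_agreement` (fraction of planted restaurants
#'   whose recovered counts match exactly), `duplicate_detection_rate`,
#'   `spike_recall`.
#' @export
ground_truth_compare <- function(report, truth) {
  stopifnot(inherits(report, "surveillance_report"))
  a <- report$assessments
  tr <- truth$restaurants
  if (!all(tr$restaurant_id %in% a$restaurant_id)) {
    stop("report does not cover the scenario's restaurants; ",
         "scenario/report mismatch")
  }
  j <- dplyr::left_join(
    tr,
    dplyr::select(a, "restaurant_id", "cai", "causality", "sas",
                  "excluded"),
    by = "restaurant_id"
  )
  planted <- j$deficient & !j$excluded
  clean <- !j$deficient & !j$excluded
  sens <- if (any(planted)) mean(j$causality[planted]) else NA_real_
  spec <- if (any(clean)) mean(!j$causality[clean]) else NA_real_

  # exact per-sub-aspect agreement (duplicate copies are screened out, so
  # at mutation rate 0 recovered tallies should equal the planted counts)
  not_excl <- which(!j$excluded)
  agree <- if (length(not_excl)) {
    mean(vapply(not_excl, function(i) {
      rid <- tr$restaurant_id[i]
      rec <- a$subaspect_counts[[match(rid, a$restaurant_id)]]
      identical(unname(as.integer(rec)),
                unname(as.integer(tr$subaspect_counts[[i]])))
    }, logical(1)))
  } else {
    NA_real_
  }

  dup_rate <- if (nrow(truth$duplicates) &&
                    "review_id" %in% names(report$dispositions)) {
    copy_ids <- unlist(truth$duplicates$copy_ids, use.names = FALSE)
    d <- report$dispositions
    mean(d$disposition[match(copy_ids, d$review_id)] ==
           "excluded-duplicate")
  } else {
    NA_real_
  }

  spike_recall <- if (nrow(truth$spikes)) {
    found <- vapply(seq_len(nrow(truth$spikes)), function(i) {
      rid <- truth$spikes$restaurant_id[i]
      sm <- a$spike_months[[match(rid, a$restaurant_id)]]
      truth$spikes$month[i] %in% format(sm, "%Y-%m")
    }, logical(1))
    mean(found)
  } else {
    NA_real_
  }

  list(
    causality = dplyr::select(j, "restaurant_id", "deficient", "causality",
                              "cai", "excluded"),
    sensitivity = sens,
    specificity = spec,
    subaspect_agreement = agree,
    duplicate_detection_rate = dup_rate,
    spike_recall = spike_recall
  )
}
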