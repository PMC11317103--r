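test_that("scenario validation rejects infeasible configurations", {
  expect_error(suburb_scenario(baseline_neg_share = 1.2))
  expect_error(suburb_scenario(spike_multiplier = 0.5))
  expect_error(suburb_scenario(
    n_eligible = c(CASUAL_DINING = 2, FINE_DINING = 0, BUFFET = 0,
                   QUICK_SERVICE = 0, FOOD_TRUCK_DHABA = 0),
    n_deficient = 2, n_spike = 1, n_duplicate_clusters = 1
  ))
})

tiny_scenario <- function(n = 4, ...) {
  suburb_scenario(
    n_eligible = c(CASUAL_DINING = n, FINE_DINING = 0, BUFFET = 0,
                   QUICK_SERVICE = 0, FOOD_TRUCK_DHABA = 0),
    n_ineligible = 1,
    monthly_volume = c(CASUAL_DINING = 20, FINE_DINING = 20, BUFFET = 20,
                       QUICK_SERVICE = 20, FOOD_TRUCK_DHABA = 20),
    ...
  )
}

test_that("generation is deterministic for a fixed seed", {
  sc <- tiny_scenario(n_deficient = 1, n_spike = 1,
                      n_duplicate_clusters = 1)
  one <- generate_scenario(sc, seed = 5)
  two <- generate_scenario(sc, seed = 5)
  expect_identical(one, two)
  other <- generate_scenario(sc, seed = 6)
  expect_false(identical(one$reviews, other$reviews))
})

test_that("fixed monthly totals reproduce the requested volumes", {
  sc <- tiny_scenario(n = 1, n_deficient = 0, n_spike = 0,
                      n_duplicate_clusters = 0, months = 8,
                      fixed_totals = c(50, 40, 60, 45, 55, 30, 50, 40))
  sim <- generate_scenario(sc, seed = 2)
  rid <- sim$truth$restaurants$restaurant_id[1]
  agg <- aggregate_monthly(sim$reviews[sim$reviews$restaurant_id == rid, ])
  expect_equal(agg$total_reviews, c(50, 40, 60, 45, 55, 30, 50, 40))
})

test_that("planted sub-aspect counts equal the classifier tally exactly", {
  sc <- tiny_scenario(n_deficient = 2, n_spike = 0,
                      n_duplicate_clusters = 1,
                      duplicate_mutation_rate = 0)
  sim <- generate_scenario(sc, seed = 13)
  rep <- run_surveillance(sim$reviews, sim$profiles)
  gt <- ground_truth_compare(rep, sim$truth)
  expect_equal(gt$subaspect_agreement, 1)
  expect_equal(gt$duplicate_detection_rate, 1)
})

test_that("null scenario flag rate is bounded by the binomial oracle", {
  sc <- suburb_scenario(
    n_eligible = c(CASUAL_DINING = 20, FINE_DINING = 0, BUFFET = 0,
                   QUICK_SERVICE = 0, FOOD_TRUCK_DHABA = 0),
    n_ineligible = 0,
    monthly_volume = c(CASUAL_DINING = 25, FINE_DINING = 25, BUFFET = 25,
                       QUICK_SERVICE = 25, FOOD_TRUCK_DHABA = 25),
    n_deficient = 0, n_spike = 0, n_duplicate_clusters = 0
  )
  sim <- generate_scenario(sc, seed = 19)
  rep <- run_surveillance(sim$reviews, sim$profiles)
  a <- rep$assessments
  # per restaurant, P(flag) under the null is P(Bin(n_hyg, 1/2) > n_hyg/2)
  n_hyg <- a$n_negative + a$n_positive
  p_flag <- 1 - stats::pbinom(floor(n_hyg / 2), n_hyg, 0.5)
  expect_true(all(!a$excluded))
  bound <- mean(p_flag) +
    3 * sqrt(sum(p_flag * (1 - p_flag))) / length(p_flag)
  expect_lte(mean(a$causality), bound)
  # and nothing gets a grade beyond what its SAS merits by chance alone
  expect_true(all(a$grade[!a$causality] == "NOT_GRADED"))
})

test_that("recovered sensitivity is non-decreasing in planted effect size", {
  effects <- c(0.5, 0.62, 0.8)
  sens <- vapply(effects, function(es) {
    hits <- vapply(1:6, function(s) {
      sim <- generate_scenario(
        tiny_scenario(n = 4, n_deficient = 3, n_spike = 0,
                      n_duplicate_clusters = 0,
                      deficient_neg_share = es),
        seed = 100 + s
      )
      rep <- run_surveillance(sim$reviews, sim$profiles)
      gt <- ground_truth_compare(rep, sim$truth)
      gt$sensitivity
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(!is.unsorted(sens))
  expect_gt(sens[3], 0.9)
})

test_that("ground-truth comparison rejects a mismatched report", {
  sim_a <- generate_scenario(tiny_scenario(n_deficient = 1, n_spike = 0,
                                           n_duplicate_clusters = 0),
                             seed = 3)
  sc_b <- suburb_scenario(
    n_eligible = c(CASUAL_DINING = 0, FINE_DINING = 0, BUFFET = 2,
                   QUICK_SERVICE = 0, FOOD_TRUCK_DHABA = 0),
    n_ineligible = 0, n_deficient = 0, n_spike = 0,
    n_duplicate_clusters = 0
  )
  sim_b <- generate_scenario(sc_b, seed = 3)
  rep_b <- run_surveillance(sim_b$reviews, sim_b$profiles)
  # rep_b covers 2 buffet ids, not the casual-dining ids of sim_a
  expect_error(ground_truth_compare(rep_b, sim_a$truth), "mismatch")
})
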