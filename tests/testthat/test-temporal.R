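test_that("monthly aggregation round-trips the illustration series", {
  series <- example_series()
  # synthesize per-review records matching the monthly counts, re-aggregate
  rows <- lapply(seq_len(nrow(series)), function(i) {
    n <- series$total_reviews[i]
    npos <- series$positive_hygiene[i]
    nneg <- series$negative_hygiene[i]
    tibble::tibble(
      date = series$month[i] + (seq_len(n) %% 28),
      hygiene_polarity = c(rep("positive", npos), rep("negative", nneg),
                           rep("none", n - npos - nneg))
    )
  })
  agg <- aggregate_monthly(dplyr::bind_rows(rows),
                           window = c(min(series$month),
                                      as.Date("2023-08-31")))
  expect_equal(as.Date(agg$month), series$month)
  expect_equal(agg$total_reviews, series$total_reviews)
  expect_equal(agg$positive_hygiene, series$positive_hygiene)
  expect_equal(agg$negative_hygiene, series$negative_hygiene)
  # the June proportion: 15 negatives of 30 totals
  expect_equal(agg$negative_hygiene[6] / agg$total_reviews[6], 0.5)
})

test_that("aggregation zero-fills empty months and validates the window", {
  rv <- tibble::tibble(date = as.Date("2023-03-15") + 0:2,
                       hygiene_polarity = c("negative", "none", "positive"))
  agg <- aggregate_monthly(rv, window = c(as.Date("2023-01-01"),
                                          as.Date("2023-05-31")))
  expect_equal(nrow(agg), 5)
  expect_equal(sum(agg$total_reviews), 3)
  expect_equal(agg$total_reviews[3], 3)
  expect_error(aggregate_monthly(rv, window = c(as.Date("2023-05-01"),
                                                as.Date("2023-01-01"))),
               "window")
})

test_that("goodness-of-fit screen reproduces the worked chi-square values", {
  s <- example_series()
  pos <- chisq_gof(s$positive_hygiene, s$total_reviews)
  expect_equal(pos$dof, 7)
  # printed as 5.01; agreement at the printed precision
  expect_lt(abs(pos$statistic - 5.01), 0.01)
  expect_equal(pos$statistic,
               oracle_gof(s$positive_hygiene, s$total_reviews)$statistic)
  expect_gt(pos$p_value, 0.6)

  neg <- chisq_gof(s$negative_hygiene, s$total_reviews)
  expect_equal(neg$statistic,
               oracle_gof(s$negative_hygiene, s$total_reviews)$statistic)
  expect_lt(abs(neg$statistic - 34.56), 0.01)
  expect_lt(neg$p_value, 1e-4)
})

test_that("perfect proportionality gives a zero statistic", {
  tot <- c(50, 40, 60, 45, 55, 30, 50, 40)
  out <- chisq_gof(tot / 10, tot)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
})

test_that("statistic is homogeneous of degree one in uniform scaling", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      tot <- sample(20:60, 8)
      obs <- rbinom(8, tot, 0.15)
      if (sum(obs) == 0) obs[1] <- 1
      one <- chisq_gof(obs, tot)
      two <- chisq_gof(2 * obs, 2 * tot)
      expect_equal(two$statistic, 2 * one$statistic)
    }
  })
})

test_that("p-value decreases as the statistic grows at fixed dof", {
  s <- example_series()
  weak <- chisq_gof(s$positive_hygiene, s$total_reviews)
  strong <- chisq_gof(s$negative_hygiene, s$total_reviews)
  expect_gt(strong$statistic, weak$statistic)
  expect_lt(strong$p_value, weak$p_value)
})

test_that("verdicts separate the genuine June spike from chance", {
  s <- example_series()
  series <- tibble::tibble(month = s$month, total_reviews = s$total_reviews,
                           positive_hygiene = s$positive_hygiene,
                           negative_hygiene = s$negative_hygiene)
  neg <- temporal_verdict(series, alpha = 0.05)
  expect_identical(neg$verdict, "genuine")
  expect_equal(format(neg$spike_months, "%Y-%m"), "2023-06")

  # the positive stream from the same restaurant is chance-level
  pos_series <- dplyr::mutate(series, negative_hygiene = .data$positive_hygiene)
  pos <- temporal_verdict(pos_series, alpha = 0.05)
  expect_identical(pos$verdict, "chance")
  expect_length(pos$spike_months, 0)
  expect_gt(pos$p_value, 0.6)

  flat <- dplyr::mutate(series, negative_hygiene = .data$total_reviews %/% 10)
  expect_identical(temporal_verdict(flat)$verdict, "chance")

  none <- dplyr::mutate(series, negative_hygiene = 0L)
  out <- temporal_verdict(none)
  expect_identical(out$verdict, "chance")
  expect_equal(out$statistic, 0)
})

test_that("type-I error of the screen is calibrated under its null", {
  # null: the window total of negative reviews allocated across months in
  # proportion to review totals (the reference distribution of the
  # goodness-of-fit screen); totals as in the illustration series
  s <- example_series()
  tot <- s$total_reviews
  n_neg <- sum(s$negative_hygiene)
  withr::with_seed(101, {
    sims <- stats::rmultinom(2000, n_neg, tot / sum(tot))
    rejections <- vapply(seq_len(ncol(sims)), function(i) {
      suppressWarnings(chisq_gof(sims[, i], tot)$p_value) < 0.05
    }, logical(1))
    expect_gte(mean(rejections), 0.03)
    expect_lte(mean(rejections), 0.07)
  })
})

test_that("small expected cells warn but do not abort", {
  expect_warning(out <- chisq_gof(c(1, 0, 1), c(3, 4, 3)), "below 1")
  expect_s3_class(out, "temporal_gof")
})
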