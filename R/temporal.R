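#' Aggregate reviews into a monthly series
#'
#' Buckets reviews by calendar month over an assessment window and counts,
#' per month, the total reviews and the hygiene-positive and
#' hygiene-negative reviews. Months inside the window with no reviews appear
#' with zero counts so the temporal screen sees the full calendar.
#'
#' @param reviews Tibble with `date` (Date) and `hygiene_polarity`
#'   (`"positive"`/`"negative"`/`"none"`/`NA`) columns.
#' @param window Length-2 Date vector `c(start, end)`; defaults to the span
#'   of the data. Reviews outside the window are dropped.
#' @return A `monthly_series` tibble with columns `month` (first of month),
#'   `total_reviews`, `positive_hygiene`, `negative_hygiene`.
#' @export
aggregate_monthly <- function(reviews, window = NULL) {
  stopifnot(all(c("date", "hygiene_polarity") %in% names(reviews)))
  dates <- as.Date(reviews$date)
  if (is.null(window)) {
    if (!nrow(reviews)) stop("no reviews and no explicit window")
    window <- range(dates, na.rm = TRUE)
  }
  window <- as.Date(window)
  if (length(window) != 2L || any(is.na(window)) || window[1] > window[2]) {
    stop("window must be c(start, end) with start <= end")
  }
  keep <- !is.na(dates) & dates >= window[1] & dates <= window[2]
  df <- tibble::tibble(
    month = floor_month(dates[keep]),
    polarity = reviews$hygiene_polarity[keep]
  )
  months <- seq(floor_month(window[1]), floor_month(window[2]), by = "month")
  out <- df |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(
      total_reviews = dplyr::n(),
      positive_hygiene = sum(.data$polarity == "positive", na.rm = TRUE),
      negative_hygiene = sum(.data$polarity == "negative", na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::complete(month = months,
                    fill = list(total_reviews = 0L, positive_hygiene = 0L,
                                negative_hygiene = 0L)) |>
    dplyr::arrange(.data$month)
  class(out) <- c("monthly_series", class(out))
  out
}

floor_month <- function(d) as.Date(format(d, "%Y-%m-01"))

#' Chi-square goodness-of-fit screen for monthly counts
#'
#' Tests whether a category's monthly counts (say, negative hygiene
#' reviews) are proportional to the monthly review totals — the null of
#' "fluctuation due to chance". Expected counts are
#' `totals * sum(observed) / sum(totals)`; the statistic is the usual
#' Pearson sum over months with `months - 1` degrees of freedom and an
#' upper-tail p-value. Standardized residuals `(obs - exp) / sqrt(exp)`
#' localize which months drive a rejection.
#'
#' Expected cells below 1 trigger a small-sample warning but the
#' computation proceeds; at typical review volumes the approximation is
#' adequate for screening.
#'
#' @param observed Integer vector of per-month category counts.
#' @param totals Integer vector of per-month total reviews (all positive).
#' @return A `temporal_gof` list: `statistic`, `dof`, `p_value`,
#'   `expected`, `std_residuals`.
#' @export
#' @examples
#' chisq_gof(c(4, 7, 6, 8, 5, 3, 4, 3), c(50, 40, 60, 45, 55, 30, 50, 40))
chisq_gof <- function(observed, totals) {
  if (length(observed) != length(totals)) {
    stop("observed and totals must have the same length")
  }
  if (length(observed) < 2L) stop("need at least two months")
  if (any(observed < 0) || any(totals <= 0)) {
    stop("counts must be non-negative and totals strictly positive")
  }
  if (sum(observed) == 0) stop("category counts sum to zero")
  expected <- totals * sum(observed) / sum(totals)
  if (any(expected < 1)) {
    warning("expected count below 1 in ", sum(expected < 1),
            " month(s); chi-square approximation may be poor")
  }
  statistic <- sum((observed - expected)^2 / expected)
  dof <- length(observed) - 1L
  structure(
    list(
      statistic = statistic,
      dof = dof,
      p_value = pchisq(statistic, dof, lower.tail = FALSE),
      expected = expected,
      std_residuals = (observed - expected) / sqrt(expected)
    ),
    class = "temporal_gof"
  )
}

#' @export
print.temporal_gof <- function(x, ...) {
  cat(sprintf("chi-square GOF: X2 = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$dof, x$p_value))
  invisible(x)
}

#' Temporal verdict: chance fluctuation or genuine clustering
#'
#' Runs the goodness-of-fit screen on a monthly series' negative hygiene
#' counts against its review totals. A p-value below `alpha` means the
#' month-to-month variation in complaints cannot be explained by varying
#' review volume alone — the clustering is treated as genuine and the
#' months with standardized residual above `spike_threshold` are annotated
#' as spikes. Otherwise the fluctuation is attributed to chance and no
#' spike months are reported. A series with no negative reviews at all is a
#' chance verdict with statistic 0.
#'
#' @param series A `monthly_series` from [aggregate_monthly()].
#' @param alpha Significance level, default 0.05.
#' @param spike_threshold Standardized-residual cutoff for flagging a spike
#'   month, default 2.
#' @return A `temporal_result` list: `statistic`, `dof`, `p_value`,
#'   `verdict` (`"genuine"` or `"chance"`), `spike_months` (Date vector),
#'   `std_residuals`.
#' @export
temporal_verdict <- function(series, alpha = 0.05, spike_threshold = 2) {
  stopifnot(all(c("month", "total_reviews", "negative_hygiene")
                %in% names(series)))
  nonzero <- series$total_reviews > 0
  neg <- series$negative_hygiene[nonzero]
  tot <- series$total_reviews[nonzero]
  months <- series$month[nonzero]
  if (sum(neg) == 0 || length(neg) < 2L) {
    return(structure(
      list(statistic = 0, dof = max(length(neg) - 1L, 0L), p_value = 1,
           verdict = "chance", spike_months = as.Date(character(0)),
           std_residuals = rep(0, length(neg))),
      class = "temporal_result"
    ))
  }
  gof <- chisq_gof(neg, tot)
  genuine <- gof$p_value < alpha
  structure(
    list(
      statistic = gof$statistic,
      dof = gof$dof,
      p_value = gof$p_value,
      verdict = if (genuine) "genuine" else "chance",
      spike_months = if (genuine) {
        months[gof$std_residuals > spike_threshold]
      } else {
        as.Date(character(0))
      },
      std_residuals = gof$std_residuals
    ),
    class = "temporal_result"
  )
}

#' @export
print.temporal_result <- function(x, ...) {
  cat(sprintf("temporal screen: X2 = %.3f (df %d), p = %.4g -> %s\n",
              x$statistic, x$dof, x$p_value, x$verdict))
  if (length(x$spike_months)) {
    cat("  spike month(s):", format(x$spike_months, "%Y-%m"), "\n")
  }
  invisible(x)
}
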