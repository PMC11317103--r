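test_that("CAI worked examples and sentinels", {
  ex <- example_assessments()
  cai <- compute_cai(ex$n_negative, ex$n_positive)
  expect_equal(cai[ex$category == "BUFFET"], 3.00)
  expect_equal(cai[ex$category == "CASUAL_DINING"], 1.50)
  expect_equal(cai[ex$category == "QUICK_SERVICE"], 3.00)
  expect_equal(cai[ex$category == "FOOD_TRUCK_DHABA"], 2.00)
  expect_identical(format_cai(cai[1:2]), c("3.00", "1.50"))

  expect_equal(compute_cai(0, 5), 0)
  expect_identical(compute_cai(3, 0), Inf)
  expect_true(is.na(compute_cai(0, 0)))
  expect_error(compute_cai(-1, 2), "non-negative")
})

test_that("causality requires CAI strictly above one", {
  expect_true(causality_flag(3.00))
  expect_false(causality_flag(1.00))
  expect_false(causality_flag(0.2))
  expect_true(causality_flag(Inf))
  expect_false(causality_flag(NA_real_))
  expect_false(causality_flag(compute_cai(0, 5)))
})

test_that("CAI is invariant to uniform scaling of both counts", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      n <- sample(0:20, 1)
      p <- sample(1:20, 1)
      k <- sample(2:7, 1)
      expect_equal(compute_cai(k * n, k * p), compute_cai(n, p))
    }
  })
})

test_that("SAS is the weighted sum of sub-aspect counts", {
  ex <- example_assessments()
  counts <- function(row) {
    out <- as.integer(row[subaspect_names()])
    names(out) <- subaspect_names()
    out
  }
  casual <- counts(ex[ex$category == "CASUAL_DINING", ])
  expect_equal(compute_sas(casual), 17)
  expect_identical(grade_sas(compute_sas(casual)), "HIGHER")

  # one negative review in every sub-aspect scores the sum of the weights
  ones <- setNames(rep(1L, 8), subaspect_names())
  expect_equal(compute_sas(ones), 20)
  expect_equal(compute_sas(ones), sum(subaspect_weights()))

  expect_equal(compute_sas(setNames(integer(8), subaspect_names())), 0)
  # partial count vectors: unnamed aspects count zero
  expect_equal(compute_sas(c(PEST_CONTROL = 2)), 6)
  expect_error(compute_sas(c(BAD_NAME = 1)), "unknown")
})

test_that("alternate weight preset reproduces the other worked columns", {
  ex <- example_assessments()
  alt <- subaspect_weights("alternate")
  sas <- vapply(seq_len(nrow(ex)), function(i) {
    cnt <- as.integer(ex[i, subaspect_names()])
    names(cnt) <- subaspect_names()
    compute_sas(cnt, alt)
  }, numeric(1))
  expect_equal(sas[ex$category == "BUFFET"], 11)
  expect_equal(sas[ex$category == "QUICK_SERVICE"], 5)
  expect_equal(sas[ex$category == "FOOD_TRUCK_DHABA"], 16)
  # the presets are distinct readings, never merged
  expect_false(identical(subaspect_weights(), alt))
})

test_that("SAS increments by exactly the incremented sub-aspect's weight", {
  w <- subaspect_weights()
  base <- withr::with_seed(7,
    setNames(sample(0:4, 8, replace = TRUE), subaspect_names()))
  for (aspect in subaspect_names()) {
    bumped <- base
    bumped[aspect] <- bumped[aspect] + 1L
    expect_equal(compute_sas(bumped, w) - compute_sas(base, w),
                 unname(w[aspect]))
  }
})

test_that("risk grades cover the five bands with closed upper edges", {
  expect_identical(grade_sas(0), "LOW")
  expect_identical(grade_sas(5), "LOW")
  expect_identical(grade_sas(6), "SLIGHTLY_HIGHER")
  expect_identical(grade_sas(10), "SLIGHTLY_HIGHER")
  expect_identical(grade_sas(11), "HIGH")
  expect_identical(grade_sas(15), "HIGH")
  expect_identical(grade_sas(16), "HIGHER")
  expect_identical(grade_sas(20), "HIGHER")
  expect_identical(grade_sas(21), "HIGHEST")
  # monotone non-decreasing in the score
  grades <- grade_sas(0:40)
  levels <- c("LOW", "SLIGHTLY_HIGHER", "HIGH", "HIGHER", "HIGHEST")
  expect_true(!is.unsorted(match(grades, levels)))
})

test_that("assessment composes CAI, causality gate, SAS and grade", {
  ex <- example_assessments()
  buffet <- ex[ex$category == "BUFFET", ]
  cnt <- setNames(as.integer(buffet[subaspect_names()]), subaspect_names())
  a <- assess_restaurant("B1", buffet$n_negative, buffet$n_positive, cnt)
  expect_equal(a$cai, 3.00)
  expect_true(a$causality)
  expect_equal(a$sas, compute_sas(cnt))
  expect_identical(a$grade, "HIGH")

  # positives outnumber negatives: no causality, no grade
  b <- assess_restaurant("F1", 1, 9, cnt)
  expect_false(b$causality)
  expect_identical(b$grade, "NOT_GRADED")

  # exclusion path carries the reason and no scores
  c_ <- assess_restaurant("X1", 6, 2, cnt, excluded = TRUE,
                          exclusion_reason = "duplicate fraction 0.83 > 0.5")
  expect_true(c_$excluded)
  expect_identical(c_$grade, "NOT_GRADED")
  expect_true(is.na(c_$cai))
})
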