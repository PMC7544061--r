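test_that("quantile flags match the brute-force sort-and-count oracle", {
  # 1..100 at q = 0.75: the type-7 quantile is 75.25, so values 76..100
  # are flagged — 25 tracts by direct enumeration
  vals <- as.numeric(1:100)
  thr <- quantile(vals, 0.75, type = 7, names = FALSE)
  expect_equal(thr, 75.25)
  flags <- quantile_flag(vals, 0.75)
  expect_identical(flags, vals >= 75.25)
  expect_equal(sum(flags), sum(vals >= thr))
  expect_equal(sum(flags), 25)

  # q = 0.5 on [1,2,3,4]: median 2.5, top two flagged
  f2 <- quantile_flag(c(1, 2, 3, 4), 0.5)
  expect_identical(f2, c(FALSE, FALSE, TRUE, TRUE))

  # the maximum is always flagged
  set.seed(5)
  for (q in c(0.1, 0.5, 0.9, 0.99)) {
    v <- rnorm(50)
    expect_true(quantile_flag(v, q)[which.max(v)])
  }
  expect_error(quantile_flag(rep(3, 10), 0.75), "identical")
})

test_that("raising q never increases the number of flagged tracts", {
  set.seed(6)
  v <- rnorm(80)
  counts <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(q) sum(quantile_flag(v, q)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("priority rule matches the truth table on all 8 flag combinations", {
  # engineer a cohort where each tract realizes one combination of
  # (high_hvi, high_lst, high_feasibility)
  combos <- expand.grid(hvi_hi = c(FALSE, TRUE), lst_hi = c(FALSE, TRUE),
                        feas_hi = c(FALSE, TRUE))
  ids <- tiny_tract_ids(8)
  hvi <- tibble::tibble(tract_id = ids,
                        hvi = ifelse(combos$hvi_hi, 18L, 3L))
  lst <- tibble::tibble(tract_id = ids,
                        mean_summer_lst = ifelse(combos$lst_hi, 40, 28))
  feas <- tibble::tibble(tract_id = ids,
                         feasibility = ifelse(combos$feas_hi, "high",
                                              "low"))
  # with 4 low / 4 high values, the 0.75-quantile equals the high value,
  # so exactly the high group is flagged
  got <- prioritize_tracts(hvi, lst, feas)
  expect_identical(got$high_hvi, combos$hvi_hi)
  expect_identical(got$high_lst, combos$lst_hi)
  expect_identical(got$high_feasibility, combos$feas_hi)
  oracle <- combos$feas_hi & (combos$hvi_hi | combos$lst_hi)
  expect_identical(got$priority, oracle)
  expect_identical(got$recommendation,
                   ifelse(combos$feas_hi, "plant_trees",
                          "alternative_interventions"))
  expect_true(all(!got$priority | got$high_feasibility))
})

test_that("priority invariant holds on randomized cohorts", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 40
    ids <- tiny_tract_ids(n)
    hvi <- tibble::tibble(tract_id = ids, hvi = sample(3:18, n, TRUE))
    lst <- tibble::tibble(tract_id = ids, mean_summer_lst = rnorm(n, 33, 3))
    feas <- tibble::tibble(tract_id = ids,
                           feasibility = sample(c("high", "low"), n, TRUE))
    got <- prioritize_tracts(hvi, lst, feas)
    expect_identical(got$priority,
                     got$high_feasibility & (got$high_hvi | got$high_lst))
    expect_identical(got$recommendation == "plant_trees",
                     got$high_feasibility)
  }
})

test_that("mismatched tract sets raise a join error listing the difference", {
  ids <- tiny_tract_ids(4)
  hvi <- tibble::tibble(tract_id = ids, hvi = c(3L, 6L, 9L, 12L))
  lst <- tibble::tibble(tract_id = ids[1:3],
                        mean_summer_lst = c(30, 31, 32))
  feas <- tibble::tibble(tract_id = ids,
                         feasibility = c("high", "low", "high", "low"))
  expect_error(prioritize_tracts(hvi, lst, feas), ids[4])
})
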