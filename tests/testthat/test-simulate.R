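test_that("all generators are seed-deterministic", {
  a <- generate_tract_cohort(cohort_spec(n_tracts = 50, seed = 42))
  b <- generate_tract_cohort(cohort_spec(n_tracts = 50, seed = 42))
  expect_identical(a, b)
  c <- generate_tract_cohort(cohort_spec(n_tracts = 50, seed = 43))
  expect_false(identical(a$pct_black, c$pct_black))

  ids <- tiny_tract_ids(4)
  expect_identical(generate_landcover(ids, seed = 7),
                   generate_landcover(ids, seed = 7))
  expect_identical(generate_lst(ids, c(10, 20, 30, 40), seed = 7),
                   generate_lst(ids, c(10, 20, 30, 40), seed = 7))
})

test_that("generated artifacts pass schema validation unmodified", {
  tab <- generate_tract_cohort(cohort_spec(n_tracts = 40, seed = 2))
  expect_silent(validate_tract_table(tab))
  lc <- generate_landcover(tiny_tract_ids(5), seed = 2)
  expect_silent(validate_landcover(lc))
  lst <- generate_lst(tiny_tract_ids(5), runif(5, 0, 40), seed = 2)
  expect_true(all(is.finite(lst$mean_summer_lst)))
  geoms <- generate_tract_geometries(tiny_tract_ids(5))
  expect_s3_class(geoms, "uc_geometry")
})

test_that("land-cover generator emits the full tract x blockgroup x class grid", {
  lc <- generate_landcover(tiny_tract_ids(2), blockgroups_per_tract = 3,
                           seed = 9)
  expect_equal(nrow(lc), 2 * 3 * 5)
  per_bg <- table(lc$block_group_id)
  expect_true(all(per_bg == 5))
  expect_true(all(lc$area_sqft >= 0))
  # class shares live on the simplex: per-block-group areas are a positive
  # split of a single total
  totals <- tapply(lc$area_sqft, lc$block_group_id, sum)
  expect_true(all(totals > 0))
  expect_error(generate_landcover(character(0)), "empty")
})

test_that("the latent cohort matches its implied correlation structure", {
  spec <- cohort_spec(n_tracts = 500, noise_sd = 0.1, seed = 3)
  tab <- generate_tract_cohort(spec)
  latent <- attr(tab, "latent")
  lambda <- spec$loading_matrix
  # analytic oracle: cov = lambda lambda' + sigma^2 I, converted to
  # correlation
  cv <- lambda %*% t(lambda) + diag(spec$noise_sd^2, nrow(lambda))
  implied <- stats::cov2cor(cv)
  frob <- sqrt(sum((cor(latent) - implied)^2))
  expect_lt(frob, 0.15)
})

test_that("zero noise with one factor gives perfect rank correlation", {
  lam1 <- default_loading_matrix()[, 1, drop = FALSE]
  lam1[lam1 == 0] <- 0.7
  lam1["pct_open_undeveloped", 1] <- -0.7
  tab <- generate_tract_cohort(cohort_spec(n_tracts = 30,
                                           loading_matrix = lam1,
                                           noise_sd = 0, seed = 4))
  f <- attr(tab, "factors")[, 1]
  for (v in default_schema()$variable) {
    expect_equal(abs(cor(tab[[v]], f, method = "spearman")), 1)
  }
})

test_that("synthetic LST falls linearly with canopy and anti-correlates", {
  ids <- tiny_tract_ids(2)
  lst <- generate_lst(ids, c(0, 50), slope = 0.1, noise_sd = 0, seed = 1)
  expect_equal(lst$mean_summer_lst[1] - lst$mean_summer_lst[2], 5.0)

  ids500 <- tiny_tract_ids(500)
  set.seed(10)
  canopy <- runif(500, 0, 50)
  lst500 <- generate_lst(ids500, canopy, slope = 0.1, noise_sd = 0.2,
                         seed = 10)
  expect_lt(cor(lst500$mean_summer_lst, canopy), 0)
})

test_that("square tract geometries are closed WGS84 rings with positive area", {
  geoms <- generate_tract_geometries(tiny_tract_ids(7))
  expect_equal(nrow(geoms), 7)
  for (g in geoms$geometry) {
    ring <- g$coordinates[[1]]
    expect_equal(ring[1, ], ring[nrow(ring), ])
    expect_true(all(abs(ring[, 1]) <= 180) && all(abs(ring[, 2]) <= 90))
  }
  expect_true(all(geoms$area_sqft > 0))
})

test_that("the bundle composes reproducibly under one master seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_inputs(seed = 5, n_tracts = 20, dir = d1)
  simulate_inputs(seed = 5, n_tracts = 20, dir = d2)
  for (f in c("tracts.csv", "landcover.csv", "lst.csv", "species.csv",
              "tracts.geojson")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
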