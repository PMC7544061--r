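test_that("variable standardization centres and scales with sample SD", {
  tab <- tiny_tract_table()
  tab$pct_black <- c(10, 20, 30, 40, 50)
  std <- standardize_variables(tab)
  z <- as.matrix(std$data[, default_schema()$variable])
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  # symmetric 3-point case: [10, 20, 30] -> [-1, 0, 1] under sample SD
  small <- tab[1:3, ]
  small$pct_black <- c(10, 20, 30)
  z3 <- standardize_variables(small)$data$pct_black
  expect_equal(z3, c(-1, 0, 1))

  const <- tab
  const$pct_hispanic <- 5
  expect_error(standardize_variables(const), "pct_hispanic")
  expect_error(standardize_variables(tab[1:2, ]), "3 tracts")
})

test_that("eigendecomposition oracle: retention follows the planted rank", {
  # single dominant factor: brute-force eigenvalues of the sample
  # correlation matrix show exactly one above 1
  lam1 <- default_loading_matrix()[, 1, drop = FALSE]
  lam1[lam1 == 0] <- 0.85
  spec1 <- cohort_spec(n_tracts = 500, loading_matrix = lam1,
                       noise_sd = 0.1, seed = 11)
  tab1 <- generate_tract_cohort(spec1)
  oracle_eig <- eigen(cor(as.matrix(tab1[, default_schema()$variable])),
                      symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(oracle_eig > 1), 1)
  m1 <- fit_weighting_model(standardize_variables(tab1))
  expect_equal(ncol(m1$loadings), 1)
  expect_equal(m1$all_eigenvalues, oracle_eig, tolerance = 1e-8)

  # generator defaults plant three factors; three components come back
  tab3 <- generate_tract_cohort(cohort_spec(seed = 12))
  m3 <- fit_weighting_model(standardize_variables(tab3))
  expect_equal(ncol(m3$loadings), 3)
})

test_that("correlation-matrix eigenvalues sum to the variable count", {
  tab <- generate_tract_cohort(cohort_spec(n_tracts = 120, seed = 5))
  m <- fit_weighting_model(standardize_variables(tab))
  expect_equal(sum(m$all_eigenvalues), 13, tolerance = 1e-6)
})

test_that("varimax preserves total retained variance (communality)", {
  tab <- generate_tract_cohort(cohort_spec(seed = 8))
  m <- fit_weighting_model(standardize_variables(tab))
  expect_equal(sum(m$loadings^2), sum(m$eigenvalues), tolerance = 1e-6)
})

test_that("components are oriented toward vulnerability-increasing variables", {
  sch <- default_schema()
  inc <- sch$direction == "vulnerability_increasing"
  for (seed in c(3, 17, 29)) {
    tab <- generate_tract_cohort(cohort_spec(n_tracts = 300, seed = seed))
    m <- fit_weighting_model(standardize_variables(tab))
    w <- sweep(m$loadings, 2, m$orientation_signs, "*")
    expect_true(all(colSums(w[inc, , drop = FALSE]) >= 0))
  }
})

test_that("fixed-k retention overrides the Kaiser criterion", {
  tab <- generate_tract_cohort(cohort_spec(n_tracts = 200, seed = 21))
  m <- fit_weighting_model(standardize_variables(tab),
                           retention = "fixed", k = 5)
  expect_equal(ncol(m$loadings), 5)
  expect_error(fit_weighting_model(standardize_variables(tab),
                                   retention = "fixed", k = 99), "1..13")
})

manual_model <- function(loadings, signs = rep(1, ncol(loadings)),
                         threshold = 0) {
  structure(list(variables = rownames(loadings), loadings = loadings,
                 orientation_signs = signs, loading_threshold = threshold,
                 eigenvalues = colSums(loadings^2),
                 all_eigenvalues = colSums(loadings^2),
                 schema = default_schema(), n_tracts = NA),
            class = "uc_weighting_model")
}

test_that("component scores are the signed weighted sum of standardized values", {
  vars <- default_schema()$variable
  ones <- matrix(1, 13, 1, dimnames = list(vars, "comp1"))
  m <- manual_model(ones)
  std <- tibble::tibble(tract_id = tiny_tract_ids(3))
  for (v in vars) std[[v]] <- c(0, 1, -2)
  got <- component_scores(std, m)
  expect_equal(got$comp1, c(0, 13, -26))  # mean tract scores 0; dot products

  # loop-based dot-product oracle on arbitrary loadings and data
  set.seed(31)
  L <- matrix(rnorm(13 * 2), 13, 2, dimnames = list(vars, c("comp1",
                                                            "comp2")))
  signs <- c(1, -1)
  m2 <- manual_model(L, signs)
  z <- matrix(rnorm(6 * 13), 6, 13, dimnames = list(NULL, vars))
  std2 <- dplyr::bind_cols(tibble::tibble(tract_id = tiny_tract_ids(6)),
                           tibble::as_tibble(z))
  got2 <- component_scores(std2, m2)
  for (t in 1:6) {
    for (c in 1:2) {
      oracle <- sum(vapply(seq_along(vars), function(v) {
        L[v, c] * z[t, v] * signs[c]
      }, numeric(1)))
      expect_equal(got2[[paste0("comp", c)]][t], oracle, tolerance = 1e-12)
    }
  }
  # doubling one variable's loading doubles exactly its contribution
  L2 <- L
  L2[4, 1] <- 2 * L[4, 1]
  got3 <- component_scores(std2, manual_model(L2, signs))
  expect_equal(got3$comp1 - got2$comp1, L[4, 1] * z[, 4] * signs[1],
               tolerance = 1e-12)

  expect_error(component_scores(std[, 1:5], m), "lacks")
})

test_that("score standardization yields cohort mean 0 and SD 1 and is idempotent", {
  raw <- tibble::tibble(tract_id = tiny_tract_ids(3), comp1 = c(2, 4, 6))
  z <- standardize_scores(raw)
  expect_equal(mean(z$comp1), 0, tolerance = 1e-12)
  expect_equal(sd(z$comp1), 1, tolerance = 1e-12)
  expect_equal(standardize_scores(z)$comp1, z$comp1, tolerance = 1e-9)
  expect_error(standardize_scores(
    tibble::tibble(tract_id = tiny_tract_ids(3), comp1 = c(1, 1, 1))),
    "zero variance")
})

test_that("SD banding matches the printed extremes and the lookup oracle", {
  expect_identical(categorize_score(-2.5), 1L)
  expect_identical(categorize_score(2.5), 6L)
  # interior edges are lower-closed: z = -1 sits in [-1, 0) -> 3
  expect_identical(categorize_score(c(0, -1, 2)), c(4L, 3L, 6L))
  expect_error(categorize_score(NaN), "finite")

  # lookup oracle over a dense grid: scan the edge list directly
  lookup <- function(z) {
    edges <- c(-2, -1, 0, 1, 2)
    score <- 1L
    for (e in edges) if (z >= e) score <- score + 1L
    score
  }
  grid <- seq(-5, 5, length.out = 10000)
  got <- categorize_score(grid)
  expect_identical(got, vapply(grid, lookup, integer(1)))
  expect_true(all(diff(got) >= 0))  # monotone in z
})

test_that("the index is the integer sum of 1-6 bands within [k, 6k]", {
  expect_identical(total_hvi(rbind(c(1, 1, 1), c(6, 6, 6), c(2, 4, 5))),
                   c(3L, 18L, 11L))
  expect_error(total_hvi(rbind(c(0, 3, 3))), "1..6")
  expect_error(total_hvi(rbind(c(2.5, 3, 3))), "1..6")
})

test_that("the pipeline is deterministic and invariant to tract order", {
  tab <- generate_tract_cohort(cohort_spec(n_tracts = 150, seed = 42))
  a <- run_hvi_pipeline(tab)
  b <- run_hvi_pipeline(tab)
  expect_identical(tidy(a), tidy(b))
  k <- ncol(a$model$loadings)
  expect_true(all(tidy(a)$hvi >= k & tidy(a)$hvi <= 6 * k))

  perm <- sample(nrow(tab))
  c_fit <- run_hvi_pipeline(tab[perm, ])
  merged <- dplyr::inner_join(tidy(a)[, c("tract_id", "hvi")],
                              tidy(c_fit)[, c("tract_id", "hvi")],
                              by = "tract_id")
  expect_identical(merged$hvi.x, merged$hvi.y)
})

test_that("a tract placed above +2 SD on every component attains the maximum index", {
  # construct directly in component-score space: tract 1 dominates each
  # component by far more than 2 cohort SDs
  set.seed(7)
  n <- 60
  raw <- tibble::tibble(tract_id = tiny_tract_ids(n),
                        comp1 = c(50, rnorm(n - 1)),
                        comp2 = c(80, rnorm(n - 1)),
                        comp3 = c(60, rnorm(n - 1)))
  z <- standardize_scores(raw)
  expect_true(all(as.numeric(z[1, -1]) > 2))
  cats <- z
  for (cc in c("comp1", "comp2", "comp3")) {
    cats[[cc]] <- categorize_score(z[[cc]])
  }
  hvi <- total_hvi(cats)
  expect_equal(hvi[1], 18L)
  expect_equal(hvi[1], max(hvi))
})

test_that("per-variable score standardization reduces weights to their signs", {
  tab <- generate_tract_cohort(cohort_spec(n_tracts = 100, seed = 13))
  std <- standardize_variables(tab)
  m <- fit_weighting_model(std)
  a <- component_scores(std$data, m, score_standardization = "per_variable")
  w <- sign(sweep(m$loadings, 2, m$orientation_signs, "*"))
  oracle <- as.matrix(std$data[, m$variables]) %*% w
  expect_equal(as.matrix(a[, -1]), oracle, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("planted loadings are recovered with high Tucker congruence", {
  lambda <- default_loading_matrix()
  for (seed in c(1, 2)) {
    tab <- generate_tract_cohort(cohort_spec(seed = seed))
    m <- fit_weighting_model(standardize_variables(tab))
    expect_equal(ncol(m$loadings), 3)
    phi <- tucker_congruence(m$loadings, lambda)
    expect_true(all(phi >= 0.95))
  }
  # congruence is reflection- and scale-invariant by construction
  x <- matrix(rnorm(26), 13, 2)
  expect_equal(tucker_congruence(x, -2 * x), c(1, 1), tolerance = 1e-12)
})

test_that("tidy/glance/autoplot expose the fitted quantities", {
  tab <- generate_tract_cohort(cohort_spec(n_tracts = 100, seed = 4))
  fit <- run_hvi_pipeline(tab)
  td <- tidy(fit$model)
  expect_setequal(unique(td$variable), default_schema()$variable)
  expect_equal(nrow(td), 13 * ncol(fit$model$loadings))
  g <- glance(fit)
  expect_equal(g$n_tracts, 100)
  expect_s3_class(autoplot(fit$model), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(nrow(tidy(fit)), 100)
})
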