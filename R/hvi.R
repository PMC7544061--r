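#' Standardize tract indicators to zero mean and unit variance
#'
#' Centres and scales every schema variable across the cohort using the
#' sample standard deviation (n - 1 denominator). Principal components are
#' extracted from the correlation matrix, i.e. from exactly these
#' standardized variables, because the indicators mix incommensurate units
#' (percentages and housing units per square mile).
#'
#' @param data A validated tract table (see [validate_tract_table()]).
#' @param schema A `uc_schema`.
#' @return A list with `data` (standardized tibble), `means` and `sds`
#'   (named numeric vectors of the fitted parameters).
#' @export
standardize_variables <- function(data, schema = default_schema()) {
  assert_schema(schema)
  data <- tibble::as_tibble(data)
  if (nrow(data) < 3) {
    stop("at least 3 tracts are required to standardize (got ", nrow(data),
         ")", call. = FALSE)
  }
  vars <- schema$variable
  x <- as.matrix(data[, vars])
  means <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    stop("zero-variance variable(s): ", paste(vars[zero], collapse = ", "),
         call. = FALSE)
  }
  z <- sweep(sweep(x, 2, means, "-"), 2, sds, "/")
  out <- dplyr::bind_cols(tibble::tibble(tract_id = data$tract_id),
                          tibble::as_tibble(z))
  list(data = out, means = means, sds = sds)
}

#' Fit the rotated-PCA weighting model
#'
#' Performs principal components analysis on the cohort correlation matrix,
#' retains components by the Kaiser criterion (eigenvalue > 1) or a fixed
#' count, applies a varimax rotation (with Kaiser row normalization, the SAS
#' default) to the retained loadings, and orients each rotated component so
#' that its summed loading over vulnerability-increasing variables is
#' non-negative — so a high component score always reads as high
#' vulnerability.
#'
#' @param std A standardized tract table as returned in
#'   `standardize_variables()$data`, or the full list it returns.
#' @param schema A `uc_schema`.
#' @param retention `"kaiser"` (default) or `"fixed"`.
#' @param k Number of components when `retention = "fixed"`.
#' @param loading_threshold Loadings with absolute value below this are
#'   zeroed before scoring (default 0: full loading vectors are the
#'   weights).
#' @return An object of class `uc_weighting_model`: variables, rotated
#'   `loadings` (variables x components), pre-rotation `eigenvalues` of the
#'   retained components, `all_eigenvalues`, `orientation_signs`, fitted
#'   `variable_means`/`variable_sds`, and bookkeeping.
#' @export
fit_weighting_model <- function(std, schema = default_schema(),
                                retention = c("kaiser", "fixed"), k = NULL,
                                loading_threshold = 0) {
  assert_schema(schema)
  retention <- match.arg(retention)
  means <- sds <- NULL
  if (is.list(std) && !is.data.frame(std) && !is.null(std$data)) {
    means <- std$means
    sds <- std$sds
    std <- std$data
  }
  vars <- schema$variable
  x <- as.matrix(std[, vars])
  if (any(!is.finite(x))) stop("non-finite values in input", call. = FALSE)
  n <- nrow(x)
  if (n <= length(vars)) {
    warning("fewer tracts (", n, ") than variables (", length(vars),
            ") + 1; loadings will be unstable", call. = FALSE)
  }
  cmat <- stats::cor(x)
  eg <- eigen(cmat, symmetric = TRUE)
  eigenvalues <- eg$values
  if (retention == "kaiser") {
    k <- sum(eigenvalues > 1)
    if (k < 1) {
      stop("no eigenvalue exceeds 1; use retention = 'fixed' with an ",
           "explicit k", call. = FALSE)
    }
  } else {
    if (is.null(k) || k < 1 || k > length(vars)) {
      stop("retention = 'fixed' needs k in 1..", length(vars), call. = FALSE)
    }
  }
  # unrotated loadings: eigenvectors scaled by sqrt(eigenvalue), so that
  # squared loadings per component sum to the variance it explains
  load_raw <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eigenvalues[seq_len(k)]), k)
  if (k > 1) {
    rot <- stats::varimax(load_raw, normalize = TRUE)
    loadings <- unclass(rot$loadings)
  } else {
    loadings <- load_raw
  }
  dimnames(loadings) <- list(vars, paste0("comp", seq_len(k)))
  inc <- schema$direction == "vulnerability_increasing"
  signs <- ifelse(colSums(loadings[inc, , drop = FALSE]) >= 0, 1, -1)
  structure(list(
    variables = vars,
    loadings = loadings,
    eigenvalues = eigenvalues[seq_len(k)],
    all_eigenvalues = eigenvalues,
    orientation_signs = signs,
    loading_threshold = loading_threshold,
    variable_means = means,
    variable_sds = sds,
    schema = schema,
    n_tracts = n
  ), class = "uc_weighting_model")
}

# oriented, threshold-censored weights actually used for scoring
scoring_weights <- function(model) {
  w <- sweep(model$loadings, 2, model$orientation_signs, "*")
  if (model$loading_threshold > 0) {
    w[abs(w) < model$loading_threshold] <- 0
  }
  w
}

#' Raw component scores for each tract
#'
#' The score of tract t on component c is the weighted sum of its
#' standardized indicator values: each variable is multiplied by its rotated
#' loading (the "PCA weight") and the component's orientation sign, then
#' summed. With `score_standardization = "per_variable"` each weighted
#' variable is itself standardized across the cohort before summation —
#' algebraically that replaces the weight by its sign — an alternative
#' reading of weight-then-standardize recipes, kept behind this switch.
#'
#' @param std Standardized tract table (tibble with `tract_id` +
#'   standardized schema columns).
#' @param model A `uc_weighting_model`.
#' @param score_standardization `"sum"` (default: weighted sum, standardized
#'   later as a whole) or `"per_variable"`.
#' @return A tibble: `tract_id` plus one `comp*` column per component.
#' @export
component_scores <- function(std, model,
                             score_standardization = c("sum",
                                                       "per_variable")) {
  score_standardization <- match.arg(score_standardization)
  if (!all(model$variables %in% names(std))) {
    stop("standardized table lacks model variable(s): ",
         paste(setdiff(model$variables, names(std)), collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(std[, model$variables])
  w <- scoring_weights(model)
  if (score_standardization == "per_variable") {
    # a weighted standardized variable re-standardized across the cohort is
    # sign(weight) * z; zero weights contribute nothing
    w <- sign(w)
  }
  scores <- x %*% w
  dplyr::bind_cols(tibble::tibble(tract_id = std$tract_id),
                   tibble::as_tibble(scores))
}

#' Standardize component scores across the cohort
#'
#' Scales each component's scores to mean 0 and standard deviation 1
#' (sample SD) across tracts, the scale on which the 1-6 vulnerability bands
#' are defined.
#'
#' @param raw_scores Tibble from [component_scores()].
#' @return Tibble of the same shape with standardized `comp*` columns.
#' @export
standardize_scores <- function(raw_scores) {
  raw_scores <- tibble::as_tibble(raw_scores)
  if (nrow(raw_scores) < 3) {
    stop("at least 3 tracts are required", call. = FALSE)
  }
  comp_cols <- setdiff(names(raw_scores), "tract_id")
  for (cc in comp_cols) {
    s <- stats::sd(raw_scores[[cc]])
    if (!is.finite(s) || s <= 0) {
      stop("component '", cc, "' has zero variance across the cohort",
           call. = FALSE)
    }
    raw_scores[[cc]] <- (raw_scores[[cc]] - mean(raw_scores[[cc]])) / s
  }
  raw_scores
}

#' Band a standardized score into vulnerability categories 1-6
#'
#' Categories count standard deviations from the cohort mean: more than 2 SD
#' below the mean is the least vulnerable category (1) and more than 2 SD
#' above is the most vulnerable (6). Interior bins are half-open and
#' lower-closed, so a tract sitting exactly on an edge takes the higher
#' (more vulnerable) category: z < -2 -> 1; \[-2, -1) -> 2; \[-1, 0) -> 3;
#' \[0, 1) -> 4; \[1, 2) -> 5; z >= 2 -> 6.
#'
#' @param z Numeric vector of standardized scores.
#' @return Integer vector in 1..6.
#' @examples
#' categorize_score(c(-2.5, -1, 0, 2.5))
#' @export
categorize_score <- function(z) {
  if (anyNA(z) || any(!is.finite(z))) {
    stop("standardized scores must be finite", call. = FALSE)
  }
  as.integer(pmin(pmax(floor(z) + 4, 1), 6))
}

#' Sum categorical component scores into the overall index
#'
#' @param categorical A data frame or matrix of per-component categorical
#'   scores (integers in 1..6), one row per tract; a `tract_id` column is
#'   ignored.
#' @return Integer vector of index values, one per tract, in \[k, 6k\] for k
#'   components.
#' @export
total_hvi <- function(categorical) {
  if (is.data.frame(categorical)) {
    categorical <- as.matrix(
      categorical[, setdiff(names(categorical), "tract_id"), drop = FALSE])
  }
  if (any(categorical < 1 | categorical > 6 |
            categorical != round(categorical))) {
    stop("categorical scores must be integers in 1..6", call. = FALSE)
  }
  as.integer(rowSums(categorical))
}

#' Run the full heat-vulnerability pipeline
#'
#' Standardizes the indicators, fits the rotated-PCA weighting model,
#' computes raw and standardized component scores, bands them into 1-6
#' categories and sums them into the overall index. Entirely deterministic:
#' the same table and settings always return the same result.
#'
#' @inheritParams fit_weighting_model
#' @inheritParams component_scores
#' @param data A validated tract table.
#' @return An object of class `uc_hvi`: a list with `model` (the
#'   `uc_weighting_model`) and `scores`, a tibble with `tract_id`, raw
#'   (`raw_comp*`), standardized (`z_comp*`) and categorical (`cat_comp*`)
#'   scores, and `hvi`.
#' @export
run_hvi_pipeline <- function(data, schema = default_schema(),
                             retention = c("kaiser", "fixed"), k = NULL,
                             loading_threshold = 0,
                             score_standardization = c("sum",
                                                       "per_variable")) {
  std <- standardize_variables(data, schema)
  model <- fit_weighting_model(std, schema, retention = retention, k = k,
                               loading_threshold = loading_threshold)
  raw <- component_scores(std$data, model,
                          score_standardization = score_standardization)
  z <- standardize_scores(raw)
  comp_cols <- setdiff(names(raw), "tract_id")
  cat_df <- z
  for (cc in comp_cols) cat_df[[cc]] <- categorize_score(z[[cc]])
  scores <- tibble::tibble(tract_id = raw$tract_id)
  for (cc in comp_cols) scores[[paste0("raw_", cc)]] <- raw[[cc]]
  for (cc in comp_cols) scores[[paste0("z_", cc)]] <- z[[cc]]
  for (cc in comp_cols) scores[[paste0("cat_", cc)]] <- cat_df[[cc]]
  scores$hvi <- total_hvi(cat_df)
  structure(list(model = model, scores = scores), class = "uc_hvi")
}

#' Tucker congruence between two loading matrices
#'
#' The congruence coefficient between loading vectors x and y is their
#' cosine similarity, sum(x y) / sqrt(sum(x^2) sum(y^2)). Columns of `a` are
#' matched greedily to the columns of `b` with the highest absolute
#' congruence (reflection-invariant), the standard way to score factor
#' recovery against planted structure.
#'
#' @param a,b Numeric matrices with equal row counts.
#' @return Numeric vector: for each column of `a`, the absolute congruence
#'   with its best-matching (unused) column of `b`.
#' @export
tucker_congruence <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  phi <- abs(crossprod(a, b) /
               sqrt(outer(colSums(a^2), colSums(b^2))))
  out <- numeric(ncol(a))
  used <- logical(ncol(b))
  for (step in seq_len(min(ncol(a), ncol(b)))) {
    m <- phi
    m[, used] <- -Inf
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    out[ij[1]] <- phi[ij[1], ij[2]]
    used[ij[2]] <- TRUE
    phi[ij[1], ] <- -Inf
  }
  out
}

#' @export
print.uc_weighting_model <- function(x, ...) {
  cat("Rotated-PCA weighting model:", length(x$variables), "variables,",
      ncol(x$loadings), "retained component(s)\n")
  cat("Eigenvalues (retained):",
      paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  cat("Orientation signs:", paste(x$orientation_signs, collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.uc_hvi <- function(x, ...) {
  print(x$model)
  cat("Scored tracts:", nrow(x$scores), "; HVI range",
      min(x$scores$hvi), "-", max(x$scores$hvi), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a weighting model into a long loading table
#'
#' @param x A `uc_weighting_model`.
#' @param ... Unused.
#' @return Tibble with `variable`, `component`, `loading` (oriented),
#'   `direction`.
#' @exportS3Method generics::tidy
#' @export
tidy.uc_weighting_model <- function(x, ...) {
  w <- sweep(x$loadings, 2, x$orientation_signs, "*")
  out <- tibble::as_tibble(w)
  out$variable <- x$variables
  out <- tidyr::pivot_longer(out, -"variable", names_to = "component",
                             values_to = "loading")
  dplyr::left_join(out,
                   dplyr::rename(x$schema, variable = "variable"),
                   by = "variable")[, c("variable", "component", "loading",
                                        "direction")]
}

#' @rdname tidy.uc_weighting_model
#' @exportS3Method generics::glance
#' @export
glance.uc_weighting_model <- function(x, ...) {
  tibble::tibble(
    n_tracts = x$n_tracts,
    n_variables = length(x$variables),
    n_components = ncol(x$loadings),
    prop_variance_retained = sum(x$eigenvalues) / length(x$variables)
  )
}

#' Tidy pipeline results into the per-tract score table
#'
#' @param x A `uc_hvi` object.
#' @param ... Unused.
#' @return The `scores` tibble (raw, standardized, categorical component
#'   scores and the summed index per tract).
#' @exportS3Method generics::tidy
#' @export
tidy.uc_hvi <- function(x, ...) x$scores

#' @rdname tidy.uc_hvi
#' @exportS3Method generics::glance
#' @export
glance.uc_hvi <- function(x, ...) {
  k <- ncol(x$model$loadings)
  tibble::tibble(
    n_tracts = nrow(x$scores),
    n_components = k,
    hvi_min = min(x$scores$hvi),
    hvi_max = max(x$scores$hvi),
    hvi_floor = k,
    hvi_ceiling = 6L * k
  )
}

#' Plot rotated component loadings as a heatmap
#'
#' @param object A `uc_weighting_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.uc_weighting_model <- function(object, ...) {
  d <- tidy(object)
  d$variable <- factor(d$variable, levels = rev(object$variables))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$variable,
                                  fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading",
                  title = "Rotated component loadings (oriented)") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of the summed vulnerability index
#'
#' @param object A `uc_hvi` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.uc_hvi <- function(object, ...) {
  k <- ncol(object$model$loadings)
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$hvi)) +
    ggplot2::geom_bar(fill = "#b2182b") +
    ggplot2::scale_x_continuous(limits = c(k - 0.5, 6 * k + 0.5)) +
    ggplot2::labs(x = "Heat Vulnerability Index (sum of 1-6 component bands)",
                  y = "tracts") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
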