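# ---------------------------------------------------------------------------
# Regression machinery: saturating curves, power laws, R2, k-fold CV.
# ---------------------------------------------------------------------------

.fit_result <- function(par, se, rss, r2, converged, n, note = NA_character_) {
  structure(list(par = par, se = se, rss = rss, r_squared = r2,
                 converged = converged, n = n, note = note),
            class = "ns_fit")
}

#' @export
print.ns_fit <- function(x, ...) {
  cat("<ns_fit>", if (x$converged) "converged" else "NOT converged",
      " n =", x$n, " RSS =", signif(x$rss, 6), " R2 =", signif(x$r_squared, 6), "\n")
  est <- data.frame(estimate = x$par, se = x$se[names(x$par)])
  print(signif(est, 6))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Coefficient of determination
#'
#' `1 - RSS/TSS` against the mean-only null model. Negative values indicate
#' a predictor worse than the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return Scalar R-squared.
#' @export
#' @examples
#' r_squared(1:5, 1:5)        # 1
#' r_squared(1:5, rep(3, 5))  # 0
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  if (anyNA(observed) || anyNA(predicted)) stop("NA values in r_squared() input")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("observed values are constant; R-squared undefined")
  1 - sum((observed - predicted)^2) / tss
}

#' Fit a saturating income curve
#'
#' Fits `y = base + asymptote * x / (halfsat + x)` by nonlinear least
#' squares (Levenberg-Marquardt) with multi-start initialization of the
#' half-saturation constant at `{0.1, 1, 10} * median(x)`; the best
#' residual sum of squares wins, ties broken by the smallest half-saturation.
#' With `baseline = FALSE` the base is fixed at `offset` (0 by default, or
#' e.g. 1 for ratio curves) and only `(asymptote, halfsat)` are estimated.
#'
#' @param x Driver values (>= 0, at least 3 distinct).
#' @param y Responses.
#' @param baseline Estimate an additive baseline? Default FALSE.
#' @param offset Fixed baseline when `baseline = FALSE`.
#' @param share_constraints Constrain base to `[0, 1]` and asymptote to
#'   `[-1, 1]` (population-share curves)? Default FALSE.
#' @return An `ns_fit` with parameters `base` (if estimated), `asymptote`
#'   and `halfsat`.
#' @export
#' @examples
#' x <- seq(500, 50000, length.out = 40)
#' y <- 0.3 * x / (5000 + x)
#' fit_saturating(x, y)$par
fit_saturating <- function(x, y, baseline = FALSE, offset = 0,
                           share_constraints = FALSE) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (any(x < 0)) stop("driver values must be non-negative")
  if (length(unique(x)) < 3) stop("need at least 3 distinct driver values")
  n <- length(x)

  # degenerate: flat response
  if (stats::sd(y) < 1e-14 * max(1, abs(mean(y)))) {
    cst <- mean(y)
    if (baseline) {
      par <- c(base = cst, asymptote = 0, halfsat = NA_real_)
    } else {
      par <- c(asymptote = if (abs(cst - offset) < 1e-12) 0 else NA_real_,
               halfsat = NA_real_)
    }
    return(.fit_result(par, se = par * NA, rss = sum((y - cst)^2), r2 = NA_real_,
                       converged = TRUE, n = n,
                       note = "flat response; half-saturation unidentifiable"))
  }

  med <- stats::median(x[x > 0])
  starts_k <- c(0.1, 1, 10) * med
  ylo <- mean(y[x <= stats::quantile(x, 0.2)])
  yhi <- mean(y[x >= stats::quantile(x, 0.8)])

  best <- NULL
  for (k0 in starts_k) {
    fit <- tryCatch({
      if (baseline) {
        lower <- c(base = if (share_constraints) 0 else -Inf,
                   asymptote = if (share_constraints) -1 else -Inf,
                   halfsat = 1e-9)
        upper <- c(base = if (share_constraints) 1 else Inf,
                   asymptote = if (share_constraints) 1 else Inf,
                   halfsat = Inf)
        minpack.lm::nlsLM(
          y ~ base + asymptote * x / (halfsat + x),
          start = list(base = ylo, asymptote = yhi - ylo, halfsat = k0),
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                               ptol = 1e-14))
      } else {
        yc <- y - offset
        minpack.lm::nlsLM(
          yc ~ asymptote * x / (halfsat + x),
          start = list(asymptote = yhi - offset, halfsat = k0),
          lower = c(asymptote = if (share_constraints) -1 else -Inf, halfsat = 1e-9),
          upper = c(asymptote = if (share_constraints) 1 else Inf, halfsat = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                               ptol = 1e-14))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    k_est <- stats::coef(fit)[["halfsat"]]
    if (is.null(best) || rss < best$rss * (1 - 1e-12) ||
        (abs(rss - best$rss) <= 1e-12 * max(best$rss, 1e-300) && k_est < best$k)) {
      best <- list(fit = fit, rss = rss, k = k_est)
    }
  }
  if (is.null(best)) {
    stop("fit_saturating: no start converged (n = ", n,
         ", median x = ", signif(med, 4), ", range y = [",
         signif(min(y), 4), ", ", signif(max(y), 4), "])")
  }
  par <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))), error = function(e) par * NA)
  yhat <- stats::fitted(best$fit) + if (baseline) 0 else offset
  r2 <- tryCatch(r_squared(y, yhat), error = function(e) NA_real_)
  .fit_result(par, se, best$rss, r2, converged = TRUE, n = n)
}

#' Fit a power law by log-log ordinary least squares
#'
#' Fits `y = alpha * x^beta` as `log y = log alpha + beta log x` and
#' back-transforms the scale. Errors on any non-positive value (log
#' undefined) or when all `x` coincide (rank-deficient design).
#'
#' @param x,y Positive numeric vectors of equal length.
#' @return An `ns_fit` with parameters `alpha` and `beta`.
#' @export
#' @examples
#' fit_power_law(c(1, 2, 4), c(3, 6, 12))$par  # alpha 3, beta 1
fit_power_law <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values in power-law fit")
  if (any(x <= 0) || any(y <= 0)) {
    stop("power-law fit requires strictly positive x and y (log undefined)")
  }
  lx <- log(x)
  if (stats::sd(lx) < 1e-13) stop("degenerate design: all driver values identical")
  fit <- stats::lm(log(y) ~ lx)
  b <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))  # noiseless data: "essentially perfect fit"
  se_log <- sm$coefficients[, "Std. Error"]
  par <- c(alpha = exp(b[[1]]), beta = b[[2]])
  se <- c(alpha = exp(b[[1]]) * se_log[[1]], beta = se_log[[2]])
  yhat <- exp(stats::fitted(fit))
  .fit_result(par, se, rss = sum((y - yhat)^2),
              r2 = tryCatch(r_squared(y, yhat), error = function(e) NA_real_),
              converged = TRUE, n = length(x))
}

#' K-fold cross-validation over countries
#'
#' Partitions the country set into `k` folds of near-equal size (sizes
#' differ by at most one) using the given seed, then calls `fit_predict`
#' once per fold with the training and held-out country sets.
#' `fit_predict(train, test)` must return a data frame with columns
#' `indicator`, `observed`, `predicted` (one row per held-out observation).
#' R-squared is computed per fold and indicator, and pooled across folds.
#'
#' @param countries Character vector of country identifiers.
#' @param k Number of folds (`2 <= k <= length(countries)`).
#' @param seed Integer seed driving the fold assignment.
#' @param fit_predict Function of `(train, test)` country vectors.
#' @return A list of class `ns_cv` with elements `folds` (country-fold
#'   tibble), `per_fold` and `pooled` R-squared tibbles, and `predictions`.
#' @export
kfold_cv <- function(countries, k, seed, fit_predict) {
  countries <- unique(countries)
  n <- length(countries)
  if (k > n) stop("k (", k, ") exceeds the number of countries (", n, ")")
  if (k < 2) stop("k must be at least 2")
  fold_of <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  folds <- tibble::tibble(country = countries, fold = fold_of)

  preds <- purrr::map(seq_len(k), function(f) {
    test <- countries[fold_of == f]
    train <- countries[fold_of != f]
    out <- fit_predict(train, test)
    stopifnot(all(c("indicator", "observed", "predicted") %in% names(out)))
    dplyr::mutate(tibble::as_tibble(out), fold = f)
  }) %>% dplyr::bind_rows()

  per_fold <- preds %>%
    dplyr::group_by(.data$fold, .data$indicator) %>%
    dplyr::summarise(r2 = r_squared(.data$observed, .data$predicted),
                     n = dplyr::n(), .groups = "drop")
  pooled <- preds %>%
    dplyr::group_by(.data$indicator) %>%
    dplyr::summarise(r2 = r_squared(.data$observed, .data$predicted),
                     n = dplyr::n(), .groups = "drop")
  structure(list(folds = folds, per_fold = per_fold, pooled = pooled,
                 predictions = preds, k = k, seed = seed),
            class = "ns_cv")
}

#' @export
print.ns_cv <- function(x, ...) {
  cat("<ns_cv>", x$k, "folds, seed", x$seed, "\n")
  print(as.data.frame(x$pooled))
  invisible(x)
}
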