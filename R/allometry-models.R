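#' Fit a power-law model by log-log OLS
#'
#' Fits `y = a * x^b` as ordinary least squares of `ln y` on `ln x` (the
#' log transform linearises the power law and stabilises the variance).
#' `a = exp(intercept)`, `b = slope`. R^2 is reported on the log scale where
#' the fit takes place; RMSE is computed after back-transforming the fitted
#' values to the original units (no bias correction unless `smearing`).
#'
#' @param x,y strictly positive numeric vectors, length >= 3.
#' @param xname label of the predictor (for reports).
#' @param smearing apply Duan's smearing factor to back-transformed
#'   predictions.
#' @param cv_k optional fold count for cross-validated R^2 (`cv_k = n` gives
#'   the jackknife).
#' @param cv_seed seed for the fold shuffle.
#' @return a `power_fit`: a, b, r2, r2_back, rmse_back, cv_r2, n, xname.
#' @export
fit_power <- function(x, y, xname = deparse(substitute(x)),
                      smearing = FALSE, cv_k = NULL, cv_seed = 1L) {
  check_positive(x, "x"); check_positive(y, "y")
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  ly <- log(y); lx <- log(x)
  if (stats::var(ly) == 0) {
    fit <- list(a = y[1], b = 0, r2 = 0, r2_back = 0,
                rmse_back = 0, cv_r2 = NA_real_, smear = 1,
                n = n, xname = xname)
    class(fit) <- "power_fit"
    return(fit)
  }
  if (stats::var(lx) == 0) stop("singular design: x is constant")
  m <- stats::lm(ly ~ lx)
  smear_f <- if (smearing) mean(exp(stats::residuals(m))) else 1
  fit <- list(a = unname(exp(stats::coef(m)[1])),
              b = unname(stats::coef(m)[2]),
              r2 = summary(m)$r.squared,
              smear = smear_f, n = n, xname = xname)
  class(fit) <- "power_fit"
  pred <- predict(fit, x)
  fit$rmse_back <- sqrt(mean((pred - y)^2))
  fit$r2_back <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  fit$cv_r2 <- if (is.null(cv_k)) NA_real_ else
    cross_validate(data.frame(x = x), y,
                   function(d, yy) fit_power(d$x, yy, xname = xname,
                                             smearing = smearing),
                   function(f, d) predict(f, d$x),
                   k = cv_k, seed = cv_seed)$cv_r2
  fit
}

#' @export
predict.power_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata[[1]] else newdata
  object$smear * object$a * x^object$b
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("power fit: y = %.4f * %s^%.4f  (n = %d)\n",
              x$a, x$xname, x$b, x$n))
  cat(sprintf("  R2 (log) = %.4f   RMSE (back) = %.4f   cv R2 = %.4f\n",
              x$r2, x$rmse_back, x$cv_r2))
  invisible(x)
}

check_positive <- function(v, name) {
  if (any(!is.finite(v)) || any(v <= 0)) {
    bad <- utils::head(which(!is.finite(v) | v <= 0), 5)
    stop("non-positive ", name, " at positions ",
         paste(bad, collapse = ", "))
  }
}

#' Linear link from top-of-canopy height to basal area
#'
#' Untransformed OLS `BA = a + b * TCH`, the first stage of the daisy-chain
#' model.
#'
#' @param tch top-of-canopy heights, m.
#' @param ba basal areas, m^2 ha^-1.
#' @return a `linear_fit`: a (intercept), b (slope), r2, rmse, n.
#' @export
fit_ba_link <- function(tch, ba) {
  check_positive(tch, "tch"); check_positive(ba, "ba")
  n <- length(tch)
  if (n < 3) stop("need at least 3 observations")
  m <- stats::lm(ba ~ tch)
  fit <- list(a = unname(stats::coef(m)[1]), b = unname(stats::coef(m)[2]),
              r2 = summary(m)$r.squared,
              rmse = sqrt(mean(stats::residuals(m)^2)), n = n)
  class(fit) <- "linear_fit"
  fit
}

#' @export
predict.linear_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata[[1]] else newdata
  object$a + object$b * x
}

#' Daisy-chain model: TCH to basal area to carbon density
#'
#' Two-stage fit: the linear link `BA' = a + b TCH` ([fit_ba_link()]),
#' followed by log-log OLS of ACD on the predicted basal area and TCH,
#' `ACD = a * BA'^b1 * TCH^b2`, so carbon can be predicted from LiDAR alone.
#'
#' @param tch,ba,acd positive plot vectors, length >= 4.
#' @param cv_k,cv_seed optional k-fold cross-validation of the full chain.
#' @return a `daisy_fit`: link (`linear_fit`), a, b1, b2, r2, rmse_back,
#'   cv_r2, n.
#' @export
fit_daisy_chain <- function(tch, ba, acd, cv_k = NULL, cv_seed = 1L) {
  check_positive(acd, "acd")
  n <- length(tch)
  if (n < 4) stop("need at least 4 observations for the two-predictor fit")
  link <- fit_ba_link(tch, ba)
  bap <- predict(link, tch)
  if (any(bap <= 0))
    stop("fitted BA' is non-positive for some plots; restrict the model ",
         "domain to taller canopies before chaining")
  m <- stats::lm(log(acd) ~ log(bap) + log(tch))
  co <- stats::coef(m)
  if (any(is.na(co))) stop("singular design in the daisy-chain fit")
  fit <- list(link = link, a = unname(exp(co[1])), b1 = unname(co[2]),
              b2 = unname(co[3]), r2 = summary(m)$r.squared, n = n)
  class(fit) <- "daisy_fit"
  pred <- predict(fit, tch)
  fit$rmse_back <- sqrt(mean((pred - acd)^2))
  fit$cv_r2 <- if (is.null(cv_k)) NA_real_ else
    cross_validate(data.frame(tch = tch, ba = ba), acd,
                   function(d, yy) fit_daisy_chain(d$tch, d$ba, yy),
                   function(f, d) predict(f, d$tch),
                   k = cv_k, seed = cv_seed)$cv_r2
  fit
}

#' @export
predict.daisy_fit <- function(object, newdata, ...) {
  tch <- if (is.data.frame(newdata)) newdata$tch else newdata
  bap <- predict(object$link, tch)
  if (any(bap <= 0)) stop("predicted BA' non-positive outside fitted domain")
  object$a * bap^object$b1 * tch^object$b2
}

#' Percentile model: multiple log-log regression with backward elimination
#'
#' Starts from the full model
#' `ln ACD = b0 + b1 ln h25 + ... + b11 ln CC + eps` over the candidate
#' height-percentile, density and cover metrics, then removes the least
#' significant coefficient until every retained predictor is significant
#' (backward stepwise elimination), and refits on the survivors. Exactly
#' collinear candidates are dropped with a warning before selection.
#'
#' With `family_correction = TRUE` (the default) the per-coefficient
#' retention threshold is `alpha / m` for `m` candidates (Bonferroni), so
#' `alpha` is the family-wise rate of keeping any spurious metric. Percentile
#' metrics are strongly collinear, and uncorrected stepwise selection at the
#' per-test level retains noise predictors in roughly a third of samples —
#' family control is what makes the procedure converge on sparse models such
#' as a two-metric percentile equation.
#'
#' @param metrics data.frame of plot metrics containing (a subset of) the
#'   candidate columns h25, h50, h75, h90, h95, d25, d50, d75, d90, d95, cc;
#'   all candidate values must be strictly positive (log domain).
#' @param acd positive response vector, Mg C ha^-1.
#' @param alpha selection level (family-wise when `family_correction`).
#' @param family_correction divide `alpha` by the candidate count for the
#'   per-coefficient threshold.
#' @param cv_k,cv_seed optional k-fold cross-validation of the full
#'   select-and-fit procedure.
#' @return an `mlr_fit`: `predictors` (retained names), `coefficients`
#'   (named, incl. intercept), `sigma`, r2, rmse_back, cv_r2, n.
#' @export
fit_percentile_mlr <- function(metrics, acd, alpha = 0.05,
                               family_correction = TRUE,
                               cv_k = NULL, cv_seed = 1L) {
  check_positive(acd, "acd")
  candidates <- intersect(
    c("h25", "h50", "h75", "h90", "h95",
      "d25", "d50", "d75", "d90", "d95", "cc"), names(metrics))
  if (!length(candidates)) stop("no candidate predictor columns found")
  X <- as.data.frame(metrics)[candidates]
  bad <- vapply(X, function(v) any(!is.finite(v) | v <= 0), logical(1))
  if (any(bad)) {
    warning("dropping non-positive candidate predictors: ",
            paste(candidates[bad], collapse = ", "))
    candidates <- candidates[!bad]
    X <- X[candidates]
  }
  n <- length(acd)
  if (n <= length(candidates) + 1)
    stop("need more plots than candidate predictors")
  lX <- as.data.frame(lapply(X, log))
  ly <- log(acd)

  # drop exactly collinear candidates (aliased coefficients) up front
  full <- stats::lm(ly ~ ., data = lX)
  aliased <- names(which(is.na(stats::coef(full))))
  if (length(aliased)) {
    drop <- sub("^`|`$", "", aliased)
    warning("dropping collinear predictors: ", paste(drop, collapse = ", "))
    candidates <- setdiff(candidates, drop)
    lX <- lX[candidates]
  }

  thr <- if (family_correction) alpha / length(candidates) else alpha
  retained <- candidates
  repeat {
    m <- if (length(retained))
      stats::lm(ly ~ ., data = lX[retained]) else stats::lm(ly ~ 1)
    if (!length(retained)) break
    co <- summary(m)$coefficients
    p <- co[-1, 4]
    names(p) <- rownames(co)[-1]   # matrix indexing drops the single name
    if (all(p < thr)) break
    worst <- names(which.max(p))
    retained <- setdiff(retained, sub("^`|`$", "", worst))
  }

  fit <- list(predictors = retained,
              coefficients = stats::coef(m),
              sigma = summary(m)$sigma,
              r2 = if (length(retained)) summary(m)$r.squared else 0,
              n = n, alpha = alpha)
  class(fit) <- "mlr_fit"
  pred <- predict(fit, X)
  fit$rmse_back <- sqrt(mean((pred - acd)^2))
  fit$cv_r2 <- if (is.null(cv_k)) NA_real_ else
    cross_validate(X, acd,
                   function(d, yy)
                     fit_percentile_mlr(d, yy, alpha = alpha,
                                        family_correction = family_correction),
                   function(f, d) predict(f, d),
                   k = cv_k, seed = cv_seed)$cv_r2
  fit
}

#' @export
predict.mlr_fit <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols))
    stop("newdata lacks retained predictors: ",
         paste(missing_cols, collapse = ", "))
  eta <- rep(object$coefficients[["(Intercept)"]], nrow(newdata))
  for (p in object$predictors)
    eta <- eta + object$coefficients[[p]] * log(newdata[[p]])
  exp(eta)
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat("percentile MLR fit (log-log, backward elimination at alpha =",
      x$alpha, ")\n")
  cat("  retained:", if (length(x$predictors))
    paste(x$predictors, collapse = ", ") else "(intercept only)", "\n")
  co <- x$coefficients
  cat("  ln ACD =", sprintf("%.4f", co[["(Intercept)"]]))
  for (p in x$predictors) cat(sprintf(" + %.4f ln %s", co[[p]], p))
  cat(sprintf("\n  R2 (log) = %.4f   RMSE (back) = %.4f\n",
              x$r2, x$rmse_back))
  invisible(x)
}

#' Predict carbon density from a fitted model
#'
#' Dispatches on the fit class; for the percentile model `predictors` must
#' be a table containing the retained metric columns, for the power and
#' daisy-chain models a TCH (or other predictor) vector suffices.
#'
#' @param fit a `power_fit`, `daisy_fit` or `mlr_fit`.
#' @param predictors vector or data.frame of predictor values.
#' @return predicted ACD, Mg C ha^-1.
#' @export
predict_acd <- function(fit, predictors) {
  if (inherits(fit, "mlr_fit") && !is.data.frame(predictors))
    stop("the percentile model needs a metrics table, not a vector")
  stats::predict(fit, predictors)
}

#' Goodness of fit on held-out or training data
#'
#' R^2 on the log scale (where the models are fitted) and RMSE in
#' back-transformed response units.
#'
#' @param fit a fitted model with a `predict` method on the response scale.
#' @param newdata predictor vector/table.
#' @param y observed positive response.
#' @return list(r2, rmse_back).
#' @export
evaluate_fit <- function(fit, newdata, y) {
  check_positive(y, "y")
  pred <- stats::predict(fit, newdata)
  lp <- log(pred); ly <- log(y)
  list(r2 = 1 - sum((ly - lp)^2) / sum((ly - mean(ly))^2),
       rmse_back = sqrt(mean((pred - y)^2)))
}

#' k-fold cross-validation with pooled out-of-fold R^2
#'
#' Folds come from a seeded shuffle; each fold is predicted by a model
#' fitted on the remaining folds, and `cv_r2 = 1 - SSE/SST` is computed on
#' the pooled out-of-fold predictions (on the log scale by default,
#' matching where the models are fitted). `k = n` gives the jackknife
#' (leave-one-out).
#'
#' @param data data.frame of predictors.
#' @param y response vector.
#' @param fit_fun function(data_train, y_train) returning a fit.
#' @param predict_fun function(fit, data_test) returning response-scale
#'   predictions.
#' @param k number of folds (2..n).
#' @param seed shuffle seed.
#' @param log_scale compute the pooled R^2 on log-transformed values.
#' @return list(cv_r2, rmse_back, predictions, folds).
#' @export
cross_validate <- function(data, y, fit_fun, predict_fun, k = 10,
                           seed = 1L, log_scale = TRUE) {
  n <- length(y)
  stopifnot(k >= 2, n >= k)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  if (any(tabulate(folds, k) > n - 3))
    stop("a fold leaves fewer than 3 training points; use a smaller k")
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_fun(data[!test, , drop = FALSE], y[!test])
    pred[test] <- predict_fun(fit, data[test, , drop = FALSE])
  }
  obs <- if (log_scale) log(y) else y
  est <- if (log_scale) log(pred) else pred
  list(cv_r2 = 1 - sum((obs - est)^2) / sum((obs - mean(obs))^2),
       rmse_back = sqrt(mean((pred - y)^2)),
       predictions = pred, folds = folds)
}
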