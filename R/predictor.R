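#' Extract a serializable coefficient set from a fit
#'
#' Captures everything needed to score new sequences: the model kind, named
#' slopes, the intercept (binary) or ordinal thresholds, and free-form
#' metadata (training variant, scales, culling record, ...).
#'
#' @param fit An `"eslogit"` fit, or a plain list with fields `kind`
#'   (`"binary"`/`"ordinal"`), `coefficients` (named), and `intercept` or
#'   `thresholds` + `levels`, for coefficient sets built by hand or loaded
#'   from elsewhere.
#' @param metadata Named list stored alongside the coefficients.
#' @return Object of class `"coefficient_set"`.
#' @export
coefficient_set <- function(fit, metadata = list()) {
  if (!inherits(fit, "eslogit")) {
    stopifnot(is.list(fit), fit$kind %in% c("binary", "ordinal"))
    cf <- as.list(fit$coefficients)
    if (fit$kind == "binary") {
      stopifnot(is.numeric(fit$intercept))
      out <- list(kind = "binary", intercept = unname(fit$intercept),
                  coefficients = cf, thresholds = NULL, levels = NULL,
                  metadata = metadata)
    } else {
      th <- unlist(fit$thresholds)
      stopifnot(length(th) >= 1, all(diff(th) > 0),
                length(fit$levels) == length(th) + 1)
      out <- list(kind = "ordinal", intercept = NULL, coefficients = cf,
                  thresholds = as.list(th), levels = fit$levels,
                  metadata = metadata)
    }
    return(structure(out, class = "coefficient_set"))
  }
  if (fit$kind == "binary") {
    cf <- fit$coefficients
    out <- list(kind = "binary",
                intercept = unname(cf[["(Intercept)"]]),
                coefficients = as.list(cf[names(cf) != "(Intercept)"]),
                thresholds = NULL, levels = NULL, metadata = metadata)
  } else {
    if (any(diff(unname(fit$zeta)) <= 0))
      stop("ordinal thresholds must be strictly increasing")
    out <- list(kind = "ordinal", intercept = NULL,
                coefficients = as.list(fit$coefficients),
                thresholds = as.list(fit$zeta),
                levels = fit$levels, metadata = metadata)
  }
  structure(out, class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set> ", x$kind, ", ",
      length(x$coefficients), " coefficient(s)\n", sep = "")
  if (length(x$coefficients))
    print(signif(unlist(x$coefficients), 4))
  if (!is.null(x$intercept)) cat("intercept:", signif(x$intercept, 4), "\n")
  if (!is.null(x$thresholds))
    print(signif(unlist(x$thresholds), 4))
  invisible(x)
}

#' Write / read a coefficient set as JSON
#'
#' @param cs A [coefficient_set()].
#' @param path File path.
#' @return `read_coefficient_set()` returns the `"coefficient_set"`.
#' @export
write_coefficient_set <- function(cs, path) {
  stopifnot(inherits(cs, "coefficient_set"))
  jsonlite::write_json(unclass(cs), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_coefficient_set
#' @export
read_coefficient_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$coefficients <- lapply(x$coefficients, as.numeric)
  if (!is.null(x$thresholds)) x$thresholds <- lapply(x$thresholds, as.numeric)
  if (!is.null(x$intercept)) x$intercept <- as.numeric(x$intercept)
  if (!is.null(x$levels)) x$levels <- unlist(x$levels)
  structure(x, class = "coefficient_set")
}

## Linear predictor theta for a feature table under a coefficient set.
## Errors on any missing or NA feature; never imputes.
linear_score <- function(features, cs) {
  features <- drop_id_column(features)
  need <- names(cs$coefficients)
  missing_f <- setdiff(need, names(features))
  if (length(missing_f))
    stop("feature(s) required by the model are missing: ",
         paste(missing_f, collapse = ", "))
  X <- as.matrix(features[, need, drop = FALSE])
  if (anyNA(X)) {
    bad <- need[colSums(is.na(X)) > 0]
    stop("feature(s) contain missing values: ", paste(bad, collapse = ", "))
  }
  beta <- unlist(cs$coefficients)
  base <- if (!is.null(cs$intercept)) cs$intercept else 0
  base + drop(X %*% beta)
}

#' pES: probability of expressed and soluble (usable) protein
#'
#' Scores constructs with a fitted binary usability model:
#' `theta = intercept + sum(beta_i * feature_i)` and
#' `pES = 1 / (1 + exp(-theta))`. Every feature named by a coefficient must
#' be present and non-missing; nothing is imputed.
#'
#' @param features Data frame of sequence parameters (one row per
#'   construct; an `id` column is ignored).
#' @param coeffs A binary [coefficient_set()].
#' @param what Return the probability (default) or the linear score theta.
#' @return Numeric vector.
#' @export
pes_score <- function(features, coeffs, what = c("probability", "theta")) {
  what <- match.arg(what)
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (coeffs$kind != "binary")
    stop("pES requires a binary usability coefficient set")
  theta <- linear_score(features, coeffs)
  if (what == "theta") theta else stats::plogis(theta)
}

#' Predicted distribution over ordinal score levels
#'
#' Per-construct probabilities of each outcome level (0-5) under an ordinal
#' coefficient set: `P(Y = j) = P(Y <= j) - P(Y <= j-1)` with
#' `P(Y <= j) = plogis(t_j - theta)`.
#'
#' @param features Data frame of sequence parameters.
#' @param coeffs An ordinal [coefficient_set()].
#' @return Matrix (constructs x levels) of probabilities; rows sum to 1.
#' @export
predict_score_distribution <- function(features, coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (coeffs$kind != "ordinal")
    stop("score distributions require an ordinal coefficient set")
  theta <- linear_score(features, coeffs)
  level_probs(theta, unlist(coeffs$thresholds), coeffs$levels)
}

#' Bayesian binomial confidence interval
#'
#' Central 95% (or `level`) posterior interval for a binomial proportion
#' under a Jeffreys Beta(1/2, 1/2) prior (default) or a uniform Beta(1, 1)
#' prior: quantiles of Beta(s + a, n - s + a). By convention the lower
#' bound is 0 when no successes are observed and the upper bound 1 when all
#' trials succeed.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n >= 1`.
#' @param level Interval mass (default 0.95).
#' @param prior `"jeffreys"` or `"uniform"`.
#' @return Numeric vector `c(lower, upper)` (or a 2-column matrix for
#'   vector input).
#' @examples
#' binomial_ci(5, 10)
#' @export
binomial_ci <- function(successes, n, level = 0.95,
                        prior = c("jeffreys", "uniform")) {
  prior <- match.arg(prior)
  stopifnot(all(successes >= 0), all(successes <= n), all(n >= 1))
  a <- if (prior == "jeffreys") 0.5 else 1
  alpha <- (1 - level) / 2
  lo <- stats::qbeta(alpha, successes + a, n - successes + a)
  hi <- stats::qbeta(1 - alpha, successes + a, n - successes + a)
  lo[successes == 0] <- 0
  hi[successes == n] <- 1
  if (length(successes) == 1L) c(lower = lo, upper = hi)
  else cbind(lower = lo, upper = hi)
}

#' Calibration curve over bins of the linear score
#'
#' Bins constructs at equal intervals of `bin_width` in the linear score
#' theta (bins anchored at `origin`, empty bins omitted) and reports, per
#' bin, the observed fraction of usable proteins with a Bayesian binomial
#' confidence interval, alongside the mean model-predicted probability.
#'
#' @param theta Linear usability scores.
#' @param usable Logical outcomes.
#' @param bin_width Bin width in theta units (default 0.1).
#' @param origin Bin anchor (a bin edge falls at this value; default 0).
#' @param level Confidence level for the intervals.
#' @param prior Binomial prior, see [binomial_ci()].
#' @return Data frame: `bin_lo`, `bin_hi`, `n`, `successes`, `observed`,
#'   `predicted`, `lower`, `upper`.
#' @export
calibration_curve <- function(theta, usable, bin_width = 0.1, origin = 0,
                              level = 0.95,
                              prior = c("jeffreys", "uniform")) {
  prior <- match.arg(prior)
  stopifnot(length(theta) == length(usable), bin_width > 0)
  bin <- floor((theta - origin) / bin_width)
  grp <- sort(unique(bin))
  rows <- lapply(grp, function(b) {
    i <- bin == b
    s <- sum(usable[i])
    n <- sum(i)
    ci <- binomial_ci(s, n, level = level, prior = prior)
    data.frame(bin_lo = origin + b * bin_width,
               bin_hi = origin + (b + 1) * bin_width,
               n = n, successes = s, observed = s / n,
               predicted = mean(stats::plogis(theta[i])),
               lower = ci[[1]], upper = ci[[2]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cutoff trade-off table for target selection
#'
#' For each pES cutoff, the fraction of the pool kept (`pES > cutoff`) and
#' the relative increase in the usable-protein yield among kept targets:
#' `100 * (usable rate among kept / overall usable rate - 1)`. A cutoff
#' keeping no records is flagged undefined (`NA`).
#'
#' @param pes pES scores.
#' @param usable Logical outcomes.
#' @param cutoffs Cutoff values (default the study's 0.3, 0.4, 0.5).
#' @return Data frame: `cutoff`, `kept_n`, `kept_fraction`,
#'   `usable_rate_kept`, `usable_rate_overall`, `yield_increase_pct`.
#' @export
cutoff_tradeoff <- function(pes, usable, cutoffs = c(0.3, 0.4, 0.5)) {
  stopifnot(length(pes) == length(usable))
  overall <- mean(usable)
  rows <- lapply(cutoffs, function(ct) {
    keep <- pes > ct
    n <- sum(keep)
    if (n == 0L)
      return(data.frame(cutoff = ct, kept_n = 0L, kept_fraction = 0,
                        usable_rate_kept = NA_real_,
                        usable_rate_overall = overall,
                        yield_increase_pct = NA_real_))
    rate <- mean(usable[keep])
    data.frame(cutoff = ct, kept_n = n, kept_fraction = n / length(pes),
               usable_rate_kept = rate, usable_rate_overall = overall,
               yield_increase_pct = 100 * (rate / overall - 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
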