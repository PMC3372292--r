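#' Binary and proportional-odds ordinal logistic regression
#'
#' Maximum-likelihood logistic regression in the parameterization used
#' throughout the package. For a binary outcome, `Pr(Y = 1) =
#' exp(theta)/(1 + exp(theta))` with `theta` the linear predictor (intercept
#' plus slopes). For an ordinal outcome with levels `l_1 < ... < l_J`, the
#' cumulative-logit (proportional-odds) model `P(Y <= l_j) =
#' exp(t_j - theta)/(1 + exp(t_j - theta))` with strictly increasing
#' thresholds `t_j` and no intercept in `theta`; larger `theta` shifts
#' probability mass toward higher outcome levels.
#'
#' Fitting is Newton-Raphson with step-halving on the exact log-likelihood,
#' using the analytic gradient and observed-information Hessian, converging
#' at gradient norm below `tol`; if a Newton iterate produces non-monotone
#' thresholds the model is refit by quasi-Newton (BFGS) on a reparameterized
#' scale (first threshold plus log-increments) and polished. Standard errors
#' come from the observed information matrix at the optimum.
#'
#' @param formula Model formula, e.g. `E ~ gravy + fracnumcharge`.
#' @param data Data frame holding the outcome and predictors.
#' @param kind `"binary"`, `"ordinal"`, or `"auto"` (binary iff the outcome
#'   takes exactly two values).
#' @param ... Passed on to [fit_binary_logit()] or [fit_ordinal_logit()].
#' @return An object of class `"eslogit"`; see [fit_ordinal_logit()] for its
#'   fields.
#' @seealso [fit_binary_logit()], [fit_ordinal_logit()], [wald_test()],
#'   [lr_test()]
#' @examples
#' d <- data.frame(x = rnorm(100))
#' d$y <- rbinom(100, 1, plogis(d$x))
#' fit <- eslogit(y ~ x, d, kind = "binary")
#' coef(fit)
#' @export
eslogit <- function(formula, data, kind = c("auto", "binary", "ordinal"),
                    ...) {
  kind <- match.arg(kind)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (kind == "auto")
    kind <- if (length(unique(y)) == 2L) "binary" else "ordinal"
  fit <- if (kind == "binary") fit_binary_logit(X, y, ...)
         else fit_ordinal_logit(X, y, ...)
  fit$call <- match.call()
  fit
}

#' Fit a binary logistic regression by maximum likelihood
#'
#' @param x Numeric predictor matrix (no intercept column; may be `NULL` or
#'   zero-column for an intercept-only model).
#' @param y Binary outcome: logical, 0/1 numeric, or two-level factor.
#' @param tol Convergence tolerance on the gradient norm.
#' @param maxit Maximum Newton iterations.
#' @return An `"eslogit"` object; `coef()` returns `(Intercept)` plus slopes.
#' @examples
#' fit_binary_logit(NULL, c(rep(1, 3), rep(0, 7)))  # intercept = log(3/7)
#' @export
fit_binary_logit <- function(x, y, tol = 1e-8, maxit = 200L) {
  y <- as_binary(y)
  x <- as_predictor_matrix(x, length(y))
  keep <- stats::complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  if (n < 1L) stop("no complete observations")
  if (!all(c(0, 1) %in% y))
    stop("binary fit requires at least one observation of each outcome class")
  check_rank(x, intercept = TRUE)

  Xb <- cbind("(Intercept)" = 1, x)
  p <- ncol(Xb)
  xscale <- c(1, if (ncol(x) > 0) apply(x, 2, stats::sd))
  beta <- numeric(p)
  beta[1] <- stats::qlogis(mean(y))
  nll <- function(b) {
    th <- drop(Xb %*% b)
    -sum(y * th - log1p(exp(th)))
  }
  cur <- nll(beta)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    th <- drop(Xb %*% beta)
    mu <- stats::plogis(th)
    g <- drop(crossprod(Xb, y - mu))          # gradient of log-lik
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    if (it > maxit) break
    w <- mu * (1 - mu)
    info <- crossprod(Xb, Xb * w)
    step <- tryCatch(solve(info, g), error = function(e) g / max(diag(info), 1))
    lam <- 1
    for (h in 1:40) {
      new <- beta + lam * step
      v <- nll(new)
      if (is.finite(v) && v <= cur + 1e-12) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    cur <- nll(beta)
    ## divergence flagged on the standardized scale so legitimately large
    ## slopes on small-scale fraction predictors do not trip the check
    if (any(abs(beta * xscale) > 50))
      stop("complete separation detected: standardized coefficient ",
           "magnitude exceeded 50; the maximum-likelihood estimate does ",
           "not exist")
  }
  th <- drop(Xb %*% beta)
  mu <- stats::plogis(th)
  if (all(abs(y - mu) < 1e-6))
    stop("complete separation detected: fitted probabilities are all 0 or 1; ",
         "the maximum-likelihood estimate does not exist")
  info <- crossprod(Xb, Xb * (mu * (1 - mu)))
  finish_fit(kind = "binary", coefficients = stats::setNames(drop(beta), colnames(Xb)),
             zeta = NULL, info = info, loglik = -cur, n = n,
             converged = converged, iterations = it,
             grad_norm = sqrt(sum(drop(crossprod(Xb, y - mu))^2)),
             levels = c(0, 1), x = x, y = y)
}

#' Fit a proportional-odds ordinal logistic regression by maximum likelihood
#'
#' Cumulative-logit model `P(Y <= l_j) = plogis(t_j - x'beta)`. Outcome
#' levels absent from the data are dropped with a warning. See [eslogit()]
#' for the algorithm.
#'
#' @param x Numeric predictor matrix (no intercept; may be `NULL`).
#' @param y Ordinal outcome: ordered factor, factor, or numeric with at
#'   least two observed levels.
#' @param tol Convergence tolerance on the gradient norm.
#' @param maxit Maximum Newton iterations.
#' @return An object of class `"eslogit"` with fields `coefficients`
#'   (slopes), `zeta` (thresholds `t_j`, strictly increasing), `se`, `vcov`,
#'   `loglik`, `aic`, `n`, `levels`, `converged`, `iterations`.
#' @export
fit_ordinal_logit <- function(x, y, tol = 1e-8, maxit = 200L) {
  lev <- if (is.factor(y)) levels(y) else sort(unique(y[!is.na(y)]))
  yi0 <- if (is.factor(y)) as.character(y) else y
  x <- as_predictor_matrix(x, length(y))
  keep <- stats::complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]
  yidx <- match(yi0[keep], lev)
  n <- length(yidx)
  if (n < 1L) stop("no complete observations")
  obs <- tabulate(yidx, nbins = length(lev))
  if (any(obs == 0)) {
    warning("outcome level(s) ", paste(lev[obs == 0], collapse = ", "),
            " not observed; dropped")
    lev <- lev[obs > 0]
    yidx <- match(yi0[keep], lev)
  }
  J <- length(lev)
  if (J < 2L) stop("ordinal fit requires at least two observed outcome levels")
  check_rank(x, intercept = TRUE)
  p <- ncol(x)

  cum <- cumsum(tabulate(yidx, J))[-J] / n
  pscale <- c(if (p > 0) apply(x, 2, stats::sd), rep(1, J - 1))
  par <- c(numeric(p), stats::qlogis(cum))
  ng <- function(par) ologit_nll_grad(par, x, yidx, J, p)

  cur <- ng(par)
  converged <- FALSE
  it <- 0L
  fallback <- FALSE
  repeat {
    it <- it + 1L
    if (sqrt(sum(cur$grad^2)) < tol) { converged <- TRUE; break }
    if (it > maxit) break
    info <- ologit_info(par, x, yidx, J, p)
    step <- tryCatch(solve(info, cur$grad), error = function(e) NULL)
    if (is.null(step)) { fallback <- TRUE; break }
    lam <- 1
    ok <- FALSE
    for (h in 1:40) {
      new <- par + lam * step
      tnew <- new[p + seq_len(J - 1)]
      if (J == 2L || all(diff(tnew) > 0)) {
        v <- ng(new)
        if (is.finite(v$nll) && v$nll <= cur$nll + 1e-12) { ok <- TRUE; break }
      }
      lam <- lam / 2
    }
    if (!ok) { fallback <- TRUE; break }
    par <- par + lam * step
    cur <- ng(par)
    if (any(abs(par * pscale) > 50))
      stop("complete separation detected: standardized parameter ",
           "magnitude exceeded 50; the maximum-likelihood estimate does ",
           "not exist")
  }

  if (fallback && !converged) {
    ## reparameterize thresholds as (t_1, log increments) and BFGS
    to_z <- function(par) {
      t <- par[p + seq_len(J - 1)]
      c(par[seq_len(p)], t[1], if (J > 2) log(diff(t)))
    }
    from_z <- function(z) {
      t1 <- z[p + 1]
      t <- if (J > 2) t1 + c(0, cumsum(exp(z[p + 1 + seq_len(J - 2)]))) else t1
      c(z[seq_len(p)], t)
    }
    fn <- function(z) ng(from_z(z))$nll
    gr <- function(z) {
      par <- from_z(z)
      g <- ng(par)$grad               # gradient of nll? (see ologit_nll_grad)
      gt <- -g[p + seq_len(J - 1)]    # d nll / d t
      gz <- numeric(length(z))
      gz[seq_len(p)] <- -g[seq_len(p)]
      gz[p + 1] <- sum(gt)
      if (J > 2) for (k in seq_len(J - 2))
        gz[p + 1 + k] <- sum(gt[(k + 1):(J - 1)]) * exp(z[p + 1 + k])
      gz
    }
    opt <- stats::optim(to_z(par), fn, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    par <- from_z(opt$par)
    cur <- ng(par)
    ## Newton polish from the BFGS solution
    for (k in 1:25) {
      if (sqrt(sum(cur$grad^2)) < tol) { converged <- TRUE; break }
      info <- ologit_info(par, x, yidx, J, p)
      step <- tryCatch(solve(info, cur$grad), error = function(e) NULL)
      if (is.null(step)) break
      new <- par + step
      tnew <- new[p + seq_len(J - 1)]
      if (J > 2L && any(diff(tnew) <= 0)) break
      v <- ng(new)
      if (!is.finite(v$nll) || v$nll > cur$nll + 1e-10) break
      par <- new; cur <- v
    }
    converged <- converged || sqrt(sum(cur$grad^2)) < tol
  }

  if (all(ologit_pi(par, x, yidx, J, p) > 1 - 1e-6))
    stop("complete separation detected: fitted category probabilities are ",
         "all 1; the maximum-likelihood estimate does not exist")
  info <- ologit_info(par, x, yidx, J, p)
  cf <- stats::setNames(par[seq_len(p)], colnames(x))
  zt <- stats::setNames(par[p + seq_len(J - 1)],
                        paste0("t_", lev[seq_len(J - 1)]))
  finish_fit(kind = "ordinal", coefficients = cf, zeta = zt, info = info,
             loglik = -cur$nll, n = n, converged = converged,
             iterations = it, grad_norm = sqrt(sum(cur$grad^2)),
             levels = lev, x = x, y = lev[yidx])
}

## Negative log-likelihood and gradient (of the LOG-LIKELIHOOD, so Newton
## ascends; nll reported for line search) of the proportional-odds model.
## par = c(beta[p], t[J-1]); yidx in 1..J.
ologit_nll_grad <- function(par, x, yidx, J, p) {
  beta <- par[seq_len(p)]
  t <- par[p + seq_len(J - 1)]
  n <- length(yidx)
  eta <- if (p > 0) drop(x %*% beta) else numeric(n)
  top <- yidx == J
  bot <- yidx == 1L
  i1 <- which(!top); i0 <- which(!bot)
  F1 <- rep(1, n); F0 <- f1 <- f0 <- numeric(n)
  F1[i1] <- stats::plogis(t[yidx[i1]] - eta[i1])
  F0[i0] <- stats::plogis(t[yidx[i0] - 1L] - eta[i0])
  pi <- F1 - F0
  if (any(pi <= 0)) return(list(nll = Inf, grad = rep(NA_real_, length(par))))
  f1[i1] <- F1[i1] * (1 - F1[i1])
  f0[i0] <- F0[i0] * (1 - F0[i0])
  u <- f1 / pi
  v <- -f0 / pi
  deta <- -(f1 - f0) / pi
  gbeta <- if (p > 0) drop(crossprod(x, deta)) else numeric(0)
  gt <- numeric(J - 1)
  su <- rowsum(u[!top], yidx[!top])
  gt[as.integer(rownames(su))] <- su[, 1]
  if (any(!bot)) {
    sv <- rowsum(v[!bot], yidx[!bot] - 1L)
    ii <- as.integer(rownames(sv))
    gt[ii] <- gt[ii] + sv[, 1]
  }
  list(nll = -sum(log(pi)), grad = c(gbeta, gt))
}

## Probability of each observation's own category at the given parameters.
ologit_pi <- function(par, x, yidx, J, p) {
  beta <- par[seq_len(p)]
  t <- par[p + seq_len(J - 1)]
  n <- length(yidx)
  eta <- if (p > 0) drop(x %*% beta) else numeric(n)
  top <- yidx == J
  bot <- yidx == 1L
  i1 <- which(!top); i0 <- which(!bot)
  F1 <- rep(1, n); F0 <- numeric(n)
  F1[i1] <- stats::plogis(t[yidx[i1]] - eta[i1])
  F0[i0] <- stats::plogis(t[yidx[i0] - 1L] - eta[i0])
  F1 - F0
}

## Observed information matrix (negative Hessian of the log-likelihood).
ologit_info <- function(par, x, yidx, J, p) {
  beta <- par[seq_len(p)]
  t <- par[p + seq_len(J - 1)]
  n <- length(yidx)
  eta <- if (p > 0) drop(x %*% beta) else numeric(n)
  top <- yidx == J
  bot <- yidx == 1L
  i1 <- which(!top); i0 <- which(!bot)
  F1 <- rep(1, n); F0 <- f1 <- f0 <- numeric(n)
  F1[i1] <- stats::plogis(t[yidx[i1]] - eta[i1])
  F0[i0] <- stats::plogis(t[yidx[i0] - 1L] - eta[i0])
  pi <- F1 - F0
  f1[i1] <- F1[i1] * (1 - F1[i1])
  f0[i0] <- F0[i0] * (1 - F0[i0])
  f1p <- f1 * (1 - 2 * F1)
  f0p <- f0 * (1 - 2 * F0)
  Aaa <- f1p / pi - (f1 / pi)^2
  Abb <- -f0p / pi - (f0 / pi)^2
  Aab <- f1 * f0 / pi^2
  q <- J - 1L
  H <- matrix(0, p + q, p + q)
  if (p > 0) {
    w <- Aaa + 2 * Aab + Abb
    H[seq_len(p), seq_len(p)] <- crossprod(x, x * w)
  }
  ## threshold block (tridiagonal)
  dj <- numeric(q); oj <- numeric(max(q - 1L, 0L))
  sA <- rowsum(Aaa[!top], yidx[!top])
  dj[as.integer(rownames(sA))] <- sA[, 1]
  if (any(!bot)) {
    sB <- rowsum(Abb[!bot], yidx[!bot] - 1L)
    ii <- as.integer(rownames(sB))
    dj[ii] <- dj[ii] + sB[, 1]
  }
  mid <- !top & !bot                 # obs linking t_{y-1} and t_y
  if (any(mid) && q > 1L) {
    sO <- rowsum(Aab[mid], yidx[mid] - 1L)   # pairs (t_{y-1}, t_y)
    oj[as.integer(rownames(sO))] <- sO[, 1]
  }
  for (k in seq_len(q)) {
    H[p + k, p + k] <- dj[k]
    if (k < q) {
      H[p + k, p + k + 1] <- oj[k]
      H[p + k + 1, p + k] <- oj[k]
    }
  }
  ## cross terms beta x t
  if (p > 0) {
    ca <- Aaa + Aab                  # weight on t_{y} side
    cb <- Abb + Aab                  # weight on t_{y-1} side
    for (k in seq_len(q)) {
      s <- numeric(p)
      ik <- which(yidx == k & !top)  # y = k contributes via a to t_k
      if (length(ik)) s <- s + colSums(x[ik, , drop = FALSE] * ca[ik])
      ik2 <- which(yidx == k + 1L)   # y = k+1 contributes via b to t_k
      if (length(ik2)) s <- s + colSums(x[ik2, , drop = FALSE] * cb[ik2])
      H[seq_len(p), p + k] <- -s
      H[p + k, seq_len(p)] <- -s
    }
  }
  -H
}

as_binary <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("binary outcome must have exactly two levels")
    return(as.integer(y) - 1L)
  }
  if (is.logical(y)) return(as.integer(y))
  y <- as.numeric(y)
  if (!all(y[!is.na(y)] %in% c(0, 1)))
    stop("binary outcome must be 0/1, logical, or a two-level factor")
  y
}

as_predictor_matrix <- function(x, n) {
  if (is.null(x)) return(matrix(numeric(0), nrow = n, ncol = 0))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  x
}

check_rank <- function(x, intercept = TRUE) {
  if (ncol(x) == 0L) return(invisible(TRUE))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant (zero-variance) predictor(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  Xf <- if (intercept) cbind(1, x) else x
  qr_ <- qr(Xf)
  if (qr_$rank < ncol(Xf)) {
    drop_idx <- qr_$pivot[(qr_$rank + 1):ncol(Xf)]
    nm <- colnames(Xf)[drop_idx]
    nm <- nm[nzchar(nm)]
    stop("rank-deficient predictor matrix; collinear column(s): ",
         paste(nm, collapse = ", "))
  }
  invisible(TRUE)
}

finish_fit <- function(kind, coefficients, zeta, info, loglik, n, converged,
                       iterations, grad_norm, levels, x, y) {
  k <- length(coefficients) + length(zeta)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc)) {
    warning("observed information is singular; standard errors unavailable")
    vc <- matrix(NA_real_, k, k)
  }
  nm <- c(names(coefficients), names(zeta))
  dimnames(vc) <- list(nm, nm)
  se <- sqrt(pmax(diag(vc), 0))
  structure(list(kind = kind, coefficients = coefficients, zeta = zeta,
                 se = stats::setNames(se, nm), vcov = vc,
                 loglik = loglik, aic = 2 * k - 2 * loglik, df = k,
                 n = n, converged = converged, iterations = iterations,
                 grad_norm = grad_norm, levels = levels,
                 x = x, y = y),
            class = "eslogit")
}

#' @export
coef.eslogit <- function(object, ...) object$coefficients

#' @export
vcov.eslogit <- function(object, ...) object$vcov

#' @export
logLik.eslogit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")
}

#' @export
nobs.eslogit <- function(object, ...) object$n

#' Predicted probabilities, linear predictor, or modal class
#'
#' @param object An `"eslogit"` fit.
#' @param newdata Predictor matrix or data frame with the fit's columns;
#'   the training matrix when omitted.
#' @param type `"prob"` (binary: `Pr(Y = 1)`; ordinal: matrix of per-level
#'   probabilities summing to 1), `"link"` (the linear predictor `theta`),
#'   or `"class"` (modal level).
#' @param ... Unused.
#' @export
predict.eslogit <- function(object, newdata = NULL,
                            type = c("prob", "link", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$x else {
    nd <- if (is.data.frame(newdata)) as.matrix(newdata[, names(object$coefficients)[
      names(object$coefficients) != "(Intercept)"], drop = FALSE]) else newdata
    as_predictor_matrix(nd, NROW(newdata))
  }
  cf <- object$coefficients
  if (object$kind == "binary") {
    slopes <- cf[names(cf) != "(Intercept)"]
    theta <- cf[["(Intercept)"]] +
      (if (length(slopes)) drop(X[, names(slopes), drop = FALSE] %*% slopes) else 0)
    if (type == "link") return(theta)
    pr <- stats::plogis(theta)
    if (type == "prob") return(pr)
    return(as.integer(pr > 0.5))
  }
  theta <- if (length(cf)) drop(X[, names(cf), drop = FALSE] %*% cf) else
    numeric(NROW(X))
  if (type == "link") return(theta)
  probs <- level_probs(theta, object$zeta, object$levels)
  if (type == "prob") return(probs)
  object$levels[max.col(probs)]
}

## n x J matrix of P(Y = level) under the cumulative-logit model.
level_probs <- function(theta, zeta, levels) {
  J <- length(levels)
  cum <- vapply(unname(zeta), function(t) stats::plogis(t - theta),
                numeric(length(theta)))
  cum <- matrix(cum, nrow = length(theta))
  cum <- cbind(cum, 1)
  probs <- cum - cbind(0, cum[, -J, drop = FALSE])
  colnames(probs) <- as.character(levels)
  probs
}

#' @export
print.eslogit <- function(x, ...) {
  cat("<eslogit> ", x$kind, " logistic regression, n = ", x$n, "\n", sep = "")
  if (length(x$coefficients)) {
    cat("Coefficients:\n")
    print(signif(x$coefficients, 5))
  } else cat("(no predictors)\n")
  if (!is.null(x$zeta)) {
    cat("Thresholds:\n")
    print(signif(x$zeta, 5))
  }
  cat("logLik ", formatC(x$loglik, format = "f", digits = 3),
      "  AIC ", formatC(x$aic, format = "f", digits = 3),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' @export
summary.eslogit <- function(object, ...) {
  est <- c(object$coefficients, object$zeta)
  se <- object$se
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = p)
  structure(list(kind = object$kind, table = tab, loglik = object$loglik,
                 aic = object$aic, n = object$n,
                 converged = object$converged),
            class = "summary.eslogit")
}

#' @export
print.summary.eslogit <- function(x, ...) {
  cat(x$kind, " logistic regression, n = ", x$n, "\n", sep = "")
  stats::printCoefmat(x$table, P.values = TRUE, has.Pvalue = TRUE)
  cat("logLik ", formatC(x$loglik, format = "f", digits = 3),
      "  AIC ", formatC(x$aic, format = "f", digits = 3),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' Simulate outcomes from a fitted model
#'
#' Draws outcome vectors from the fitted binary or cumulative-logit model at
#' the training predictor values (or `newdata`).
#'
#' @param object An `"eslogit"` fit.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional integer seed.
#' @param newdata Optional predictor matrix.
#' @param ... Unused.
#' @return Data frame with `nsim` columns.
#' @export
simulate.eslogit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object, newdata = newdata, type = "prob")
  out <- if (object$kind == "binary") {
    replicate(nsim, stats::rbinom(length(pr), 1, pr), simplify = FALSE)
  } else {
    cum <- t(apply(pr, 1, cumsum))
    replicate(nsim, {
      u <- stats::runif(nrow(pr))
      object$levels[rowSums(u > cum) + 1L]
    }, simplify = FALSE)
  }
  stats::setNames(as.data.frame(out), paste0("sim_", seq_len(nsim)))
}

#' Wald test for a single parameter
#'
#' `Z = estimate / SE` with a two-sided p-value from the standard normal.
#'
#' @param fit An `"eslogit"` fit.
#' @param parameter Name of a coefficient (or threshold).
#' @return List with `statistic` (Z), `df` (`NA`), `p.value`.
#' @export
wald_test <- function(fit, parameter) {
  stopifnot(inherits(fit, "eslogit"))
  est <- c(fit$coefficients, fit$zeta)
  if (!parameter %in% names(est))
    stop("parameter '", parameter, "' not in fit")
  se <- fit$se[[parameter]]
  if (!is.finite(se) || se <= 0)
    stop("degenerate fit: standard error for '", parameter,
         "' is zero or non-finite")
  z <- est[[parameter]] / se
  structure(list(statistic = z, df = NA_integer_,
                 p.value = min(2 * stats::pnorm(-abs(z)), 1),
                 log10_p = (log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10),
                 parameter = parameter),
            class = "eslogit_test")
}

#' Likelihood-ratio test of nested fits
#'
#' `statistic = 2 (logLik_full - logLik_nested)` referred to a chi-squared
#' distribution with degrees of freedom equal to the parameter-count
#' difference.
#'
#' @param full,nested `"eslogit"` fits on the same observations with the
#'   nested model's predictors a subset of the full model's.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
lr_test <- function(full, nested) {
  stopifnot(inherits(full, "eslogit"), inherits(nested, "eslogit"))
  if (full$kind != nested$kind)
    stop("non-nested models: different outcome kinds")
  if (full$n != nested$n)
    stop("non-nested models: different numbers of observations")
  if (!all(names(nested$coefficients) %in% names(full$coefficients)))
    stop("non-nested models: nested predictors are not a subset")
  stat <- 2 * (full$loglik - nested$loglik)
  df <- full$df - nested$df
  if (df < 0) stop("non-nested models: fewer parameters in the full model")
  if (stat < -1e-6)
    warning("negative LR statistic (", format(stat),
            "); check convergence of the full fit")
  stat <- max(stat, 0)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p.value = min(max(p, 0), 1),
                 log10_p = if (df == 0) 0 else
                   stats::pchisq(stat, df, lower.tail = FALSE, log.p = TRUE) / log(10)),
            class = "eslogit_test")
}

#' @export
print.eslogit_test <- function(x, ...) {
  if (is.na(x$df))
    cat("Wald test", if (!is.null(x$parameter)) paste0(" (", x$parameter, ")"),
        ": Z = ", format(x$statistic), ", p = ", format(x$p.value), "\n", sep = "")
  else
    cat("LR test: chi2 = ", format(x$statistic), ", df = ", x$df,
        ", p = ", format(x$p.value), "\n", sep = "")
  invisible(x)
}
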