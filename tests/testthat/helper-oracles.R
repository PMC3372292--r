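# Independent oracles used by the tests. These are deliberately written
# without touching the package's fitting internals: direct likelihood
# formulas evaluated by refining grid search, a brute-force pH grid for the
# isoelectric point, and a numeric-integration Beta quantile.

# Negative log-likelihood of a binary logit with params c(intercept, slope).
oracle_bin_nll <- function(par, x, y) {
  th <- par[1] + par[2] * x
  sum(log1p(exp(th))) - sum(y * th)
}

# Negative log-likelihood of a cumulative-logit model with J levels;
# par = c(slope, t_1 .. t_{J-1}); y takes levels 0 .. J-1.
oracle_ord_nll <- function(par, x, y, J) {
  t <- par[-1]
  if (length(t) > 1 && any(diff(t) <= 0)) return(Inf)
  eta <- par[1] * x
  cum <- cbind(0, vapply(t, function(tt) plogis(tt - eta),
                         numeric(length(x))), 1)
  yi <- y + 1L                      # column of the level
  pr <- cum[cbind(seq_along(y), yi + 1L)] - cum[cbind(seq_along(y), yi)]
  if (any(pr <= 0)) return(Inf)
  -sum(log(pr))
}

# Refining grid search: minimize fn over a box, zooming 6 times by a factor
# of 10 around the best node (21 nodes per dimension). For the concave
# likelihoods here the optimum log-likelihood is located to ~1e-7.
oracle_grid_min <- function(fn, lower, upper, zooms = 6L, nodes = 21L) {
  k <- length(lower)
  best_par <- (lower + upper) / 2
  best_val <- Inf
  for (z in seq_len(zooms)) {
    grids <- lapply(seq_len(k), function(j) seq(lower[j], upper[j],
                                                length.out = nodes))
    pts <- as.matrix(do.call(expand.grid, grids))
    vals <- apply(pts, 1, fn)
    i <- which.min(vals)
    if (vals[i] < best_val) {
      best_val <- vals[i]
      best_par <- pts[i, ]
    }
    span <- (upper - lower) / (nodes - 1)
    lower <- best_par - 1.5 * span
    upper <- best_par + 1.5 * span
  }
  list(par = best_par, value = best_val)
}

# Brute-force pH grid for the isoelectric point: coarse 1e-3 grid over
# [0, 14], then a 1e-5 grid in the bracketing window (equivalent to the
# full 1e-5 grid because the charge curve is strictly decreasing).
oracle_pi <- function(seq_str, pka = pesol::bjellqvist_pka) {
  counts <- table(strsplit(seq_str, "")[[1]])
  groups <- data.frame(
    group = c("Cterm", "D", "E", "C", "Y", "Nterm", "H", "K", "R"),
    n = c(1, counts["D"], counts["E"], counts["C"], counts["Y"], 1,
          counts["H"], counts["K"], counts["R"]))
  groups$n[is.na(groups$n)] <- 0
  charge <- function(ph) {
    z <- 0
    for (i in seq_len(nrow(pka))) {
      g <- pka$group[i]
      n <- groups$n[match(g, groups$group)]
      if (is.na(n) || n == 0) next
      z <- z + if (pka$sign[i] > 0) n / (1 + 10^(ph - pka$pka[i]))
               else -n / (1 + 10^(pka$pka[i] - ph))
    }
    z
  }
  coarse <- seq(0, 14, by = 1e-3)
  zc <- vapply(coarse, charge, 0)
  i <- which.min(abs(zc))
  fine <- seq(max(0, coarse[i] - 2e-3), min(14, coarse[i] + 2e-3), by = 1e-5)
  zf <- vapply(fine, charge, 0)
  fine[which.min(abs(zf))]
}

# Beta quantile by numeric integration of the density plus root finding,
# independent of qbeta.
oracle_beta_quantile <- function(p, shape1, shape2) {
  cdf <- function(x) integrate(function(u) dbeta(u, shape1, shape2), 0, x,
                               rel.tol = 1e-10)$value
  uniroot(function(x) cdf(x) - p, c(1e-12, 1 - 1e-12), tol = 1e-10)$root
}

# Simulate ordinal outcomes (levels 0..J-1) from the cumulative-logit model
# -- plain data generation for recovery/type-I studies.
sim_ordinal <- function(theta, thresholds) {
  cum <- vapply(thresholds, function(t) plogis(t - theta),
                numeric(length(theta)))
  cum <- matrix(cum, nrow = length(theta))
  u <- runif(length(theta))
  as.integer(rowSums(u > cum))
}

# Small random peptide.
random_peptide <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                             "H", "I", "K", "L", "M", "N",
                                             "P", "Q", "R", "S", "T", "V",
                                             "W", "Y")) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Fixture suite for the grid-search oracle equivalence checks: small
# (n <= 15) one-predictor datasets without separation.
oracle_fixtures <- function() {
  list(
    list(kind = "binary",
         x = c(-1.2, -0.8, -0.5, -0.1, 0.2, 0.4, 0.9, 1.3, 1.7, 2.1),
         y = c(0, 0, 1, 0, 0, 1, 1, 0, 1, 1)),
    list(kind = "binary",
         x = c(-2, -1.5, -1, -0.5, 0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5),
         y = c(0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 1, 1)),
    list(kind = "binary",
         x = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.1, 1.3, 1.5),
         y = c(1, 0, 1, 1, 0, 0, 1, 1)),
    list(kind = "binary",
         x = c(-3, -2, -1, 0, 1, 2, 3, 4, 5, -4, 2.5, -1.5, 0.5, 1.5, -0.5),
         y = c(1, 0, 0, 1, 1, 0, 1, 1, 1, 0, 0, 1, 0, 1, 1)),
    list(kind = "ordinal",
         x = c(-1.5, -1, -0.6, -0.2, 0.1, 0.5, 0.9, 1.4, 1.8, 2.2),
         y = c(0, 1, 0, 2, 1, 0, 2, 1, 2, 2)),
    list(kind = "ordinal",
         x = c(-2, -1.4, -0.9, -0.3, 0, 0.4, 0.8, 1.1, 1.6, 2, 2.4, 2.9),
         y = c(0, 0, 1, 0, 2, 1, 1, 2, 0, 2, 2, 1)),
    list(kind = "ordinal",
         x = c(0.2, 0.5, 0.9, 1.4, 1.9, 2.3, 2.8, 3.3, 3.7),
         y = c(1, 0, 2, 1, 0, 2, 2, 1, 2)),
    list(kind = "ordinal",
         x = c(-1, -0.7, -0.4, -0.1, 0.3, 0.6, 1, 1.3, 1.7, 2, 2.3, 2.7,
               3, 3.3, 3.7),
         y = c(0, 1, 0, 1, 2, 0, 1, 2, 1, 2, 0, 2, 2, 1, 2)))
}
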