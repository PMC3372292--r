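#' Usability of a construct
#'
#' A construct is "usable" (worth scaling up for purification) when the
#' product of its expression level and solubility score exceeds 11, i.e. is
#' 12 or higher on integer scores. A missing S (recorded only when E > 0)
#' means not usable.
#'
#' @param E,S Integer scores 0-5 (`S` may be `NA`).
#' @return Logical vector.
#' @examples
#' usability(3, 4)        # TRUE  (product 12)
#' usability(2, 5)        # FALSE (product 10)
#' usability(0, NA)       # FALSE
#' @export
usability <- function(E, S) {
  prod <- E * ifelse(is.na(S), 0, S)
  !is.na(E) & prod > 11
}

#' Aggregate replicate clone scores for each construct
#'
#' Combines the (E, S) scores observed in replicate expression trials of the
#' same construct into one outcome pair per construct, by one of the study's
#' strategies: `"max-each"` takes componentwise maxima (the primary rule,
#' motivated by experimental errors lowering scores); `"blind-average"`
#' takes arithmetic means (S averaged over clones with S recorded);
#' `"max-exs"` takes the (E, S) pair of the replicate with the highest E*S
#' product (ties broken by clone order); `"consistent"` keeps a construct
#' only if all replicates agree exactly on both E and S.
#'
#' @param outcomes Data frame with columns `id`, `clone_id`, `E`, `S`
#'   (`S` may be `NA` where `E` is 0).
#' @param strategy Aggregation strategy.
#' @return Data frame with one row per retained construct: `id`, `E`, `S`,
#'   `usable` (E*S > 11; for `"blind-average"` computed on the averaged
#'   values). Construct order follows first appearance in `outcomes`.
#' @examples
#' reps <- data.frame(id = "p1", clone_id = c("c1", "c2"),
#'                    E = c(3, 4), S = c(2, 1))
#' aggregate_clone_scores(reps, "max-each")  # E = 4, S = 2
#' aggregate_clone_scores(reps, "max-exs")   # E = 3, S = 2 (6 > 4)
#' @export
aggregate_clone_scores <- function(outcomes,
                                   strategy = c("max-each", "blind-average",
                                                "max-exs", "consistent")) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(outcomes),
            all(c("id", "E", "S") %in% names(outcomes)))
  if (nrow(outcomes) == 0L) stop("empty replicate list")
  ids <- unique(outcomes$id)
  grp <- split(seq_len(nrow(outcomes)), factor(outcomes$id, levels = ids))
  E <- outcomes$E; S <- outcomes$S
  agg <- function(i) {
    switch(strategy,
      "max-each" = {
        s <- if (all(is.na(S[i]))) NA_real_ else max(S[i], na.rm = TRUE)
        c(max(E[i]), s)
      },
      "blind-average" = {
        s <- if (all(is.na(S[i]))) NA_real_ else mean(S[i], na.rm = TRUE)
        c(mean(E[i]), s)
      },
      "max-exs" = {
        prod <- E[i] * ifelse(is.na(S[i]), 0, S[i])
        k <- i[which.max(prod)]          # which.max keeps the first tie
        c(E[k], S[k])
      },
      "consistent" = {
        sameE <- length(unique(E[i])) == 1L
        sameS <- length(unique(S[i])) == 1L   # NA == NA counts as consistent
        if (sameE && sameS) c(E[i[1]], S[i[1]]) else c(NA_real_, NA_real_)
      })
  }
  m <- vapply(grp, agg, numeric(2))
  out <- data.frame(id = ids, E = m[1, ], S = m[2, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (strategy == "consistent") out <- out[!is.na(out$E), , drop = FALSE]
  out$usable <- usability(out$E, out$S)
  rownames(out) <- NULL
  out
}

#' Keep one construct per target
#'
#' For dataset variants with multiple constructs of the same target
#' protein, retains the single construct with the highest E*S product
#' (ties broken by the first id in order).
#'
#' @param aggregated Aggregated outcome table (`id`, `E`, `S`, ...).
#' @param target Target identifier per row.
#' @return The aggregated table restricted to one row per target.
#' @export
select_one_construct <- function(aggregated, target) {
  stopifnot(nrow(aggregated) == length(target))
  prod <- aggregated$E * ifelse(is.na(aggregated$S), 0, aggregated$S)
  keep <- unlist(lapply(split(seq_len(nrow(aggregated)),
                              factor(target, levels = unique(target))),
                        function(i) i[which.max(prod[i])]),
                 use.names = FALSE)
  out <- aggregated[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Round averaged scores half-up to integer levels
#'
#' Blind-average aggregation yields non-integer scores; cumulative-logit
#' fits need discrete levels, so averaged scores are rounded half-up
#' (2.5 -> 3) before ordinal modeling.
#'
#' @param x Numeric scores.
#' @return Integer vector (`NA` preserved).
#' @export
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests (default 72, the core parameter count).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 72)  # 0.00069 to two significant figures
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 72) {
  stopifnot(alpha > 0, n_tests >= 1)
  alpha / n_tests
}

#' Single-regression screen of sequence parameters
#'
#' Fits one single-predictor regression per parameter against the outcome:
#' proportional-odds ordinal regressions for the E and S scores, binary
#' logistic regression for usability. Reports, per parameter, the slope, its
#' Wald p-value, the signed `-log10(p)` (negative log p times the sign of
#' the slope) and the predictive value (slope times the parameter's standard
#' deviation in the screened subset, a scale-normalized effect size), plus a
#' Bonferroni significance flag at `alpha / n_tests`.
#'
#' Rows with a missing outcome are excluded listwise (so passing S scores
#' with `NA` where E = 0 restricts the S screen to expressed proteins, as in
#' the study design). Constant or all-`NA` parameters are flagged and
#' excluded from the fits.
#'
#' @param features Data frame of parameters (an `id` column, if present, is
#'   ignored).
#' @param y Outcome vector aligned with `features` rows (integer scores for
#'   ordinal kinds, logical/0-1 for `"usability-binary"`).
#' @param kind `"E-ordinal"`, `"S-ordinal"` or `"usability-binary"` (sets
#'   the regression family; E and S are equivalent here, the split exists
#'   for provenance).
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @param n_tests Bonferroni denominator; defaults to the number of screened
#'   (non-excluded) parameters.
#' @return Data frame of class `"es_screen"`: `parameter`, `slope`, `se`,
#'   `p`, `signed_log_p`, `predictive_value`, `significant`, `note`.
#' @export
single_screen <- function(features, y,
                          kind = c("E-ordinal", "S-ordinal",
                                   "usability-binary"),
                          alpha = 0.05, n_tests = NULL) {
  kind <- match.arg(kind)
  features <- drop_id_column(features)
  keep <- !is.na(y)
  features <- features[keep, , drop = FALSE]
  y <- y[keep]
  params <- names(features)
  usable_col <- vapply(params, function(p) {
    v <- features[[p]]
    any(!is.na(v)) && stats::sd(v, na.rm = TRUE) > 0
  }, logical(1))
  n_scr <- if (is.null(n_tests)) sum(usable_col) else n_tests
  thr <- bonferroni_threshold(alpha, n_scr)

  rows <- lapply(params, function(pn) {
    if (!usable_col[[pn]])
      return(data.frame(parameter = pn, slope = NA_real_, se = NA_real_,
                        p = NA_real_, signed_log_p = NA_real_,
                        predictive_value = NA_real_, significant = FALSE,
                        note = "constant or missing",
                        stringsAsFactors = FALSE))
    v <- features[[pn]]
    ok <- !is.na(v)
    x <- matrix(v[ok], ncol = 1, dimnames = list(NULL, pn))
    fit <- if (kind == "usability-binary") fit_binary_logit(x, y[ok])
           else fit_ordinal_logit(x, y[ok])
    w <- wald_test(fit, pn)
    slope <- fit$coefficients[[pn]]
    data.frame(parameter = pn, slope = slope, se = fit$se[[pn]],
               p = w$p.value,
               signed_log_p = -w$log10_p * sign(slope),
               predictive_value = slope * stats::sd(v[ok]),
               significant = w$log10_p < log10(thr),
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "kind") <- kind
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- n_scr
  attr(out, "bonferroni") <- thr
  class(out) <- c("es_screen", "data.frame")
  out
}

drop_id_column <- function(features) {
  if (is.matrix(features)) features <- as.data.frame(features)
  features[, setdiff(names(features), "id"), drop = FALSE]
}

#' Choose between total and exposure-split amino-acid fractions
#'
#' For each amino acid, the buried and exposed fractions replace the total
#' fraction only when the two split variables have opposite-signed slopes in
#' the single-regression screen and both are significant at the Bonferroni
#' threshold; otherwise the total fraction is retained. Selection is done
#' independently per outcome.
#'
#' @param screens An `"es_screen"` table containing rows for the total (`a`
#'   ... `y`), buried (`ab` ... `yb`) and exposed (`ae` ... `ye`) fractions.
#' @param threshold Significance threshold (defaults to the screen's
#'   Bonferroni threshold).
#' @return Character vector of retained variable names (per amino acid,
#'   either the total name or the two split names).
#' @export
select_exposure_variables <- function(screens, threshold = NULL) {
  if (is.null(threshold)) threshold <- attr(screens, "bonferroni")
  stopifnot(!is.null(threshold))
  sc <- screens
  get <- function(p) {
    i <- match(p, sc$parameter)
    if (is.na(i)) stop("missing screen for parameter '", p, "'")
    sc[i, ]
  }
  out <- character(0)
  for (a in tolower(AA_ALPHABET)) {
    rb <- get(paste0(a, "b")); re <- get(paste0(a, "e"))
    split_ok <- !is.na(rb$slope) && !is.na(re$slope) &&
      sign(rb$slope) != sign(re$slope) &&
      !is.na(rb$p) && !is.na(re$p) &&
      rb$p < threshold && re$p < threshold
    out <- c(out, if (split_ok) c(paste0(a, "b"), paste0(a, "e")) else {
      get(a)  # ensure the total screen exists
      a
    })
  }
  out
}

#' Choose between whole and fractional charge variables
#'
#' For each of the three charge-variable pairs (numcharge/fracnumcharge,
#' netcharge/fracnetcharge, absnetcharge/fracabsnetcharge) the more
#' significant (smaller p) member is kept; ties keep the fractional
#' (length-normalized) version. A member excluded from the screen (constant)
#' cedes to the other.
#'
#' @param screens An `"es_screen"` table containing the six charge rows.
#' @return Character vector of three retained variable names.
#' @export
select_charge_variables <- function(screens) {
  pairs <- list(c("numcharge", "fracnumcharge"),
                c("netcharge", "fracnetcharge"),
                c("absnetcharge", "fracabsnetcharge"))
  vapply(pairs, function(pr) {
    i <- match(pr, screens$parameter)
    if (anyNA(i)) stop("missing screen for parameter(s): ",
                       paste(pr[is.na(i)], collapse = ", "))
    pw <- screens$p[i[1]]; pf <- screens$p[i[2]]
    if (is.na(pw)) return(pr[2])
    if (is.na(pf)) return(pr[1])
    if (pw < pf) pr[1] else pr[2]    # tie -> fractional
  }, character(1))
}

#' Cull the screened parameter set to stepwise candidates
#'
#' Applies the two redundancy rules (exposure split and whole-vs-fractional
#' charge, see [select_exposure_variables()] and
#' [select_charge_variables()]) and then drops every variable not
#' significant at the Bonferroni-adjusted threshold, yielding the candidate
#' pool for stepwise model building.
#'
#' @param screens An `"es_screen"` table over the full core parameter set.
#' @return List with `candidates` (character vector, in screen order),
#'   `retained` (post-redundancy, pre-Bonferroni set) and `threshold`.
#' @export
cull_screen <- function(screens) {
  thr <- attr(screens, "bonferroni")
  aa_vars <- select_exposure_variables(screens, thr)
  charge_vars <- select_charge_variables(screens)
  other <- intersect(c("gravy", "sce", "esce", "diso", "length", "pi"),
                     screens$parameter)
  retained <- intersect(screens$parameter, c(aa_vars, charge_vars, other))
  keep <- screens$parameter %in% retained & screens$significant
  list(candidates = screens$parameter[keep], retained = retained,
       threshold = thr)
}

#' Stepwise forward/reverse variable selection
#'
#' Builds a multiple regression by iterating: add the out-of-model candidate
#' with the smallest Wald p-value if it is below `p_add` (0.049); then
#' remove the in-model variable with the largest Wald p-value if it is at or
#' above `p_remove` (0.05). Ties at addition break lexicographically.
#' Terminates when neither action applies, or with a warning on an
#' add/remove cycle. Candidates are expected to be pre-culled to the
#' Bonferroni-significant set (see [cull_screen()]).
#'
#' @param features Data frame of parameters.
#' @param y Outcome vector (rows with `NA` are dropped listwise).
#' @param kind As in [single_screen()]: ordinal for E/S, binary for
#'   usability.
#' @param candidates Character vector of candidate variable names.
#' @param p_add Wald p-value required to enter (default 0.049).
#' @param p_remove Wald p-value forcing removal (default 0.05).
#' @param max_steps Safety cap on add/remove iterations.
#' @return List with `fit` (the final `"eslogit"`), `selected` (variables in
#'   the final model, in entry order) and `trace` (data frame of actions).
#' @export
stepwise_fit <- function(features, y,
                         kind = c("E-ordinal", "S-ordinal",
                                  "usability-binary"),
                         candidates, p_add = 0.049, p_remove = 0.05,
                         max_steps = 100L) {
  kind <- match.arg(kind)
  features <- drop_id_column(features)
  missing_cand <- setdiff(candidates, names(features))
  if (length(missing_cand))
    stop("candidate variable(s) not in features: ",
         paste(missing_cand, collapse = ", "))
  keep <- !is.na(y) & stats::complete.cases(features[, candidates, drop = FALSE])
  features <- features[keep, , drop = FALSE]
  y <- y[keep]

  fit_on <- function(vars) {
    x <- if (length(vars)) as.matrix(features[, vars, drop = FALSE]) else NULL
    if (kind == "usability-binary") fit_binary_logit(x, y)
    else fit_ordinal_logit(x, y)
  }
  wald_p <- function(fit, var) wald_test(fit, var)$p.value

  selected <- character(0)
  trace <- list()
  seen <- character(0)
  cur_fit <- fit_on(selected)
  for (step in seq_len(max_steps)) {
    acted <- FALSE
    ## addition
    pool <- sort(setdiff(candidates, selected))  # lexicographic tie-break
    if (length(pool)) {
      pvals <- vapply(pool, function(v) {
        f <- tryCatch(fit_on(c(selected, v)), error = function(e) NULL)
        if (is.null(f)) NA_real_ else wald_p(f, v)
      }, numeric(1))
      if (any(!is.na(pvals)) && min(pvals, na.rm = TRUE) < p_add) {
        v <- pool[which.min(pvals)]
        selected <- c(selected, v)
        cur_fit <- fit_on(selected)
        trace[[length(trace) + 1L]] <-
          data.frame(step = step, action = "add", variable = v,
                     p = min(pvals, na.rm = TRUE),
                     stringsAsFactors = FALSE)
        acted <- TRUE
      }
    }
    ## removal
    if (length(selected)) {
      pvals <- vapply(selected, function(v) wald_p(cur_fit, v), numeric(1))
      if (max(pvals) >= p_remove) {
        v <- selected[which.max(pvals)]
        selected <- setdiff(selected, v)
        cur_fit <- fit_on(selected)
        trace[[length(trace) + 1L]] <-
          data.frame(step = step, action = "remove", variable = v,
                     p = max(pvals), stringsAsFactors = FALSE)
        acted <- TRUE
      }
    }
    if (!acted) break
    sig <- paste(sort(selected), collapse = "|")
    if (sig %in% seen) {
      warning("stepwise selection cycled; terminating with current model")
      break
    }
    seen <- c(seen, sig)
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), action = character(0),
               variable = character(0), p = numeric(0))
  list(fit = cur_fit, selected = selected, trace = trace)
}

#' AIC-based pruning of a stepwise model
#'
#' Each variable in the model is removed in turn (in input order); a
#' variable is discarded if the refit without it has strictly lower AIC.
#' Passes repeat until no variable is dropped, so the final AIC is at most
#' the input model's.
#'
#' @inheritParams stepwise_fit
#' @param selected Variables of the current model.
#' @return List with `fit`, `selected`, `dropped`.
#' @export
aic_prune <- function(features, y,
                      kind = c("E-ordinal", "S-ordinal", "usability-binary"),
                      selected) {
  kind <- match.arg(kind)
  features <- drop_id_column(features)
  keep <- !is.na(y) &
    stats::complete.cases(features[, selected, drop = FALSE])
  features <- features[keep, , drop = FALSE]
  y <- y[keep]
  fit_on <- function(vars) {
    x <- if (length(vars)) as.matrix(features[, vars, drop = FALSE]) else NULL
    if (kind == "usability-binary") fit_binary_logit(x, y)
    else fit_ordinal_logit(x, y)
  }
  cur_fit <- fit_on(selected)
  dropped <- character(0)
  repeat {
    changed <- FALSE
    for (v in selected) {
      f <- fit_on(setdiff(selected, v))
      if (f$aic < cur_fit$aic) {
        selected <- setdiff(selected, v)
        cur_fit <- f
        dropped <- c(dropped, v)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(fit = cur_fit, selected = selected, dropped = dropped)
}

#' Paired rare/common codon regressions
#'
#' For each of Arg, Ile, Leu and Pro, fits one two-predictor regression in
#' which the fractions of the amino acid encoded by rare codons and by
#' common codons enter independently but simultaneously, separating codon
#' effects from amino-acid effects. Reports a screen row for each fraction
#' (slope, Wald p, signed -log10 p, predictive value). A constant fraction
#' (e.g. no rare codons in the cohort) is excluded and the other fitted
#' alone.
#'
#' @inheritParams single_screen
#' @param features Data frame containing the codon-split columns `r_rare`,
#'   `r_common`, ..., `p_common` (from [feature_table()] with CDS input).
#' @return An `"es_screen"`-style data frame with a row per fitted fraction
#'   and an `amino_acid` column.
#' @export
paired_rare_common_screen <- function(features, y,
                                      kind = c("E-ordinal", "S-ordinal",
                                               "usability-binary"),
                                      alpha = 0.05, n_tests = 8) {
  kind <- match.arg(kind)
  features <- drop_id_column(features)
  keep <- !is.na(y)
  features <- features[keep, , drop = FALSE]
  y <- y[keep]
  thr <- bonferroni_threshold(alpha, n_tests)
  rows <- list()
  for (a in c("r", "i", "l", "p")) {
    vars <- paste0(a, c("_rare", "_common"))
    if (!all(vars %in% names(features)))
      stop("codon-split columns missing for '", a,
           "'; compute features with a CDS")
    vals <- features[, vars, drop = FALSE]
    nonconst <- vapply(vars, function(v) stats::sd(vals[[v]]) > 0, logical(1))
    use <- vars[nonconst]
    if (length(use) == 0L) next
    x <- as.matrix(vals[, use, drop = FALSE])
    fit <- if (kind == "usability-binary") fit_binary_logit(x, y)
           else fit_ordinal_logit(x, y)
    for (v in vars) {
      if (v %in% use) {
        w <- wald_test(fit, v)
        slope <- fit$coefficients[[v]]
        rows[[v]] <- data.frame(
          amino_acid = toupper(a), parameter = v, slope = slope,
          se = fit$se[[v]], p = w$p.value,
          signed_log_p = -w$log10_p * sign(slope),
          predictive_value = slope * stats::sd(vals[[v]]),
          significant = w$log10_p < log10(thr), note = "",
          stringsAsFactors = FALSE)
      } else {
        rows[[v]] <- data.frame(
          amino_acid = toupper(a), parameter = v, slope = NA_real_,
          se = NA_real_, p = NA_real_, signed_log_p = NA_real_,
          predictive_value = NA_real_, significant = FALSE,
          note = "constant; excluded", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "kind") <- kind
  attr(out, "bonferroni") <- thr
  class(out) <- c("es_screen", "data.frame")
  out
}

#' Permissive vs enhancing screens at the score extremes
#'
#' Splits an ordinal score's influence into its two boundary effects:
#' "permissive" factors act on the low boundary (score 0 vs any expression,
#' a binary regression on the indicator `score > 0`) and "enhancing" factors
#' on the high boundary (score 5 vs less, indicator `score == 5`). A side
#' whose extreme class is empty errors with `strict = TRUE` (default when
#' both sides fail); otherwise it is returned as `NULL` with a warning so
#' the other side can proceed.
#'
#' @param features Data frame of parameters.
#' @param score Integer score vector (0-5; `NA` dropped listwise).
#' @param alpha,n_tests Bonferroni settings passed to [single_screen()].
#' @param top Highest score value (default 5).
#' @return List with elements `permissive` and `enhancing`, each an
#'   `"es_screen"` table or `NULL`.
#' @export
permissive_enhancing_screen <- function(features, score, alpha = 0.05,
                                        n_tests = NULL, top = 5) {
  features <- drop_id_column(features)
  keep <- !is.na(score)
  features <- features[keep, , drop = FALSE]
  score <- score[keep]
  run_side <- function(y, label) {
    if (length(unique(y)) < 2L) {
      warning(label, " screen unavailable: extreme class empty")
      return(NULL)
    }
    single_screen(features, as.integer(y), kind = "usability-binary",
                  alpha = alpha, n_tests = n_tests)
  }
  perm <- run_side(score > 0, "permissive")
  enh <- run_side(score == top, "enhancing")
  if (is.null(perm) && is.null(enh))
    stop("both extreme classes are empty; no screen possible")
  list(permissive = perm, enhancing = enh)
}

#' Run the full model-building pipeline for one outcome
#'
#' Chains the study's analysis procedure: single-regression screen of all
#' supplied parameters, redundancy culling (exposure splits, charge pairs),
#' Bonferroni drop, stepwise forward/reverse selection, and AIC pruning.
#' Returns every intermediate product plus a serializable coefficient set.
#'
#' @param features Data frame with an `id` column and the core parameters.
#' @param y Outcome vector aligned with `features` rows.
#' @param kind `"E-ordinal"`, `"S-ordinal"` or `"usability-binary"`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param p_add,p_remove Stepwise cutoffs (defaults 0.049 / 0.05).
#' @param n_tests Optional Bonferroni denominator override.
#' @param metadata Optional list stored in the coefficient set's metadata.
#' @return List of class `"es_pipeline"`: `screen`, `cull`, `stepwise`,
#'   `pruned`, `fit`, `selected`, `coefficient_set`, `provenance`.
#' @export
run_model_pipeline <- function(features, y,
                               kind = c("E-ordinal", "S-ordinal",
                                        "usability-binary"),
                               alpha = 0.05, p_add = 0.049, p_remove = 0.05,
                               n_tests = NULL, metadata = list()) {
  kind <- match.arg(kind)
  screen <- single_screen(features, y, kind = kind, alpha = alpha,
                          n_tests = n_tests)
  cull <- cull_screen(screen)
  sw <- stepwise_fit(features, y, kind = kind, candidates = cull$candidates,
                     p_add = p_add, p_remove = p_remove)
  pr <- aic_prune(features, y, kind = kind, selected = sw$selected)
  prov <- list(package_version = as.character(utils::packageVersion("pesol")),
               kind = kind, alpha = alpha,
               bonferroni_threshold = attr(screen, "bonferroni"),
               n_tests = attr(screen, "n_tests"),
               p_add = p_add, p_remove = p_remove)
  cs <- coefficient_set(pr$fit, metadata = c(prov, metadata))
  structure(list(screen = screen, cull = cull, stepwise = sw, pruned = pr,
                 fit = pr$fit, selected = pr$selected,
                 coefficient_set = cs, provenance = prov),
            class = "es_pipeline")
}

#' @export
print.es_pipeline <- function(x, ...) {
  cat("<es_pipeline> ", x$provenance$kind, "\n", sep = "")
  cat("  screened ", nrow(x$screen), " parameters, Bonferroni threshold ",
      signif(x$provenance$bonferroni_threshold, 3), "\n", sep = "")
  cat("  candidates after culling: ",
      paste(x$cull$candidates, collapse = ", "), "\n", sep = "")
  cat("  final model: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)",
      "  [AIC ", formatC(x$fit$aic, format = "f", digits = 2), "]\n", sep = "")
  invisible(x)
}
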