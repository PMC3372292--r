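## Average SwissProt-like amino-acid background frequencies used as the
## generator's base composition.
BASE_COMPOSITION <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0661, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292
)

## TOP-IDP-style per-residue disorder propensities used by the baseline
## annotator (positive = disorder-promoting).
DISORDER_PROPENSITY <- c(
  A =  0.060, C =  0.020, D =  0.192, E =  0.736, F = -0.697,
  G =  0.166, H =  0.303, I = -0.486, K =  0.586, L = -0.326,
  M = -0.397, N =  0.007, P =  0.987, Q =  0.318, R =  0.180,
  S =  0.341, T =  0.059, V = -0.121, W = -0.884, Y = -0.510
)

#' Configuration for the synthetic cohort generator
#'
#' Describes the statistical world the generator emulates: a high-throughput
#' E. coli expression screen in which each construct receives integer
#' expression (E) and solubility (S) scores 0-5 from replicate clone trials,
#' with bimodal score distributions, a strong positive E-S coupling, S
#' unrecorded when E = 0, ~25% of constructs showing clone discrepancies,
#' and a 4:1 analysis/test split. Outcomes are drawn from the same
#' cumulative-logit family the analysis fits (so parameter recovery is
#' well-posed); an optional latent-normal mode provides a misspecified
#' variant for robustness checks.
#'
#' @param n Number of constructs.
#' @param seed Integer seed; fully determines the cohort.
#' @param length_meanlog,length_sdlog,length_range Lognormal sequence-length
#'   distribution (mean about 200 residues) clipped to `length_range`.
#' @param base_composition Mean amino-acid frequencies.
#' @param dirichlet_concentration Per-construct composition is drawn from a
#'   Dirichlet with this concentration around `base_composition` (larger =
#'   less between-construct variation).
#' @param coef_E Named true coefficients on the (cohort-centered) feature
#'   scale for the E latent score.
#' @param thresholds_E Strictly increasing thresholds `t_0 < ... < t_4` of
#'   the E cumulative-logit model.
#' @param coef_S,thresholds_S Same for the S model.
#' @param coupling Weight of (E - mean E) added to the S latent scale,
#'   inducing the positive E-S correlation.
#' @param clones Clones per construct (integer, >= 1).
#' @param discrepancy_rate Target fraction of constructs whose clones
#'   disagree (default 0.25).
#' @param rare_codon_usage Per-amino-acid probability that a residue is
#'   encoded by a rare codon (Arg, Ile, Leu, Pro).
#' @param with_cds Generate coding sequences (needed for codon splits)?
#' @param train_fraction Per-construct Bernoulli probability of landing in
#'   the analysis (training) set; default 0.8 for the 4:1 split.
#' @param outcome_link `"logistic"` (the model family the pipeline fits) or
#'   `"latent-normal"` (misspecified thresholded-Gaussian outcomes with a
#'   variance-matched latent scale).
#' @param buried_fraction Fraction of residues the baseline annotator labels
#'   buried (most hydrophobic first; default 0.45).
#' @param disorder_window,disorder_threshold Baseline disorder annotator:
#'   window width for the smoothed disorder propensity and the cutoff above
#'   which residues are labeled disordered.
#' @param scales A [scale_config()].
#' @return Object of class `"generator_config"`.
#' @export
generator_config <- function(n = 9644,
                             seed = NULL,
                             length_meanlog = log(185),
                             length_sdlog = 0.35,
                             length_range = c(50, 600),
                             base_composition = BASE_COMPOSITION,
                             dirichlet_concentration = 80,
                             coef_E = c(fracnumcharge = 15, gravy = -1,
                                        r = -20),
                             thresholds_E = stats::qlogis(c(0.30, 0.38, 0.45,
                                                            0.52, 0.65)),
                             coef_S = c(fracnumcharge = 15, gravy = -0.8,
                                        r = -20),
                             thresholds_S = stats::qlogis(c(0.18, 0.26, 0.33,
                                                            0.40, 0.55)),
                             coupling = 0.8,
                             clones = 2L,
                             discrepancy_rate = 0.25,
                             rare_codon_usage = c(R = 0.25, I = 0.15,
                                                  L = 0.10, P = 0.20),
                             with_cds = TRUE,
                             train_fraction = 0.8,
                             outcome_link = c("logistic", "latent-normal"),
                             buried_fraction = 0.45,
                             disorder_window = 11L,
                             disorder_threshold = 0.26,
                             scales = scale_config()) {
  outcome_link <- match.arg(outcome_link)
  bad <- character(0)
  if (!(is.numeric(n) && length(n) == 1 && n >= 1)) bad <- c(bad, "n")
  if (!is.null(seed) && !(is.numeric(seed) && length(seed) == 1))
    bad <- c(bad, "seed")
  if (!(length(length_range) == 2 && length_range[1] >= 1 &&
        length_range[1] < length_range[2])) bad <- c(bad, "length_range")
  if (!(is.numeric(base_composition) &&
        setequal(names(base_composition), AA_ALPHABET) &&
        all(base_composition > 0))) bad <- c(bad, "base_composition")
  if (!(dirichlet_concentration > 0)) bad <- c(bad, "dirichlet_concentration")
  if (!(length(thresholds_E) >= 1 && all(diff(thresholds_E) > 0)))
    bad <- c(bad, "thresholds_E")
  if (!(length(thresholds_S) >= 1 && all(diff(thresholds_S) > 0)))
    bad <- c(bad, "thresholds_S")
  if (!(discrepancy_rate >= 0 && discrepancy_rate <= 1))
    bad <- c(bad, "discrepancy_rate")
  if (!(all(rare_codon_usage >= 0) && all(rare_codon_usage <= 1)))
    bad <- c(bad, "rare_codon_usage")
  if (!(train_fraction >= 0 && train_fraction <= 1))
    bad <- c(bad, "train_fraction")
  if (!(clones >= 1)) bad <- c(bad, "clones")
  if (!(buried_fraction >= 0 && buried_fraction <= 1))
    bad <- c(bad, "buried_fraction")
  if (length(bad))
    stop("invalid generator configuration field(s): ",
         paste(bad, collapse = ", "))
  structure(list(
    n = as.integer(n), seed = seed, length_meanlog = length_meanlog,
    length_sdlog = length_sdlog, length_range = length_range,
    base_composition = base_composition[AA_ALPHABET],
    dirichlet_concentration = dirichlet_concentration,
    coef_E = coef_E, thresholds_E = thresholds_E,
    coef_S = coef_S, thresholds_S = thresholds_S, coupling = coupling,
    clones = as.integer(clones), discrepancy_rate = discrepancy_rate,
    rare_codon_usage = rare_codon_usage, with_cds = with_cds,
    train_fraction = train_fraction, outcome_link = outcome_link,
    buried_fraction = buried_fraction,
    disorder_window = as.integer(disorder_window),
    disorder_threshold = disorder_threshold, scales = scales),
    class = "generator_config")
}

#' Generate a synthetic expression/solubility cohort
#'
#' Draws a cohort of protein constructs with sequences, baseline
#' exposure/disorder annotations, optional coding sequences, clone-level
#' E/S outcomes from the configured cumulative-logit models (S coupled to
#' E, unrecorded when E = 0), clone discrepancies, and a 4:1 analysis/test
#' split. The true latent parameters are returned in a `truth` record that
#' analysis stages must never read.
#'
#' @param config A [generator_config()].
#' @return Object of class `"es_cohort"`: named character vectors `aa`,
#'   `exposure`, `disorder`, `cds` (keyed by construct id), the computed
#'   `features` table, clone-level `outcomes` (`id`, `clone_id`, `E`, `S`),
#'   `split` (`id`, `set`), and `truth`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  ids <- sprintf("sim%05d", seq_len(n))

  lens <- pmin(pmax(round(stats::rlnorm(n, config$length_meanlog,
                                        config$length_sdlog)),
                    config$length_range[1]), config$length_range[2])

  ## per-construct composition: Dirichlet around the base frequencies
  alpha <- config$dirichlet_concentration * config$base_composition
  gam <- matrix(stats::rgamma(n * 20L, shape = rep(alpha, each = n)),
                nrow = n)
  comp <- gam / rowSums(gam)

  ## residues drawn by inverse CDF against each construct's composition,
  ## vectorized across the whole cohort
  idx <- rep.int(seq_len(n), lens)
  u <- stats::runif(length(idx))
  code <- integer(length(u))
  acc <- numeric(length(u))
  for (j in seq_len(20L)) {
    acc <- acc + comp[idx, j]
    code <- code + (u > acc)
  }
  resv <- AA_ALPHABET[pmin.int(code + 1L, 20L)]
  ends <- cumsum(lens); starts <- ends - lens + 1L
  aa <- stats::setNames(substring(paste0(resv, collapse = ""), starts, ends),
                        ids)

  ann <- annotate_baseline(aa, scales = config$scales,
                           buried_fraction = config$buried_fraction,
                           window = config$disorder_window,
                           threshold = config$disorder_threshold,
                           .residues = resv, .idx = idx, .lens = lens)

  cds <- NULL
  if (config$with_cds)
    cds <- sample_cds(resv, idx, ids, config$rare_codon_usage, config$scales)

  features <- feature_table(aa, exposure = ann$exposure,
                            disorder = ann$disorder, cds = cds,
                            scales = config$scales)

  theta_E <- latent_score(features, config$coef_E)
  E <- draw_ordinal(theta_E, config$thresholds_E, config$outcome_link)
  theta_S <- latent_score(features, config$coef_S) +
    config$coupling * (E - mean(E))
  S <- draw_ordinal(theta_S, config$thresholds_S, config$outcome_link)
  S[E == 0] <- NA_integer_

  base <- data.frame(id = rep(ids, each = config$clones),
                     clone_id = rep(paste0("c", seq_len(config$clones)), n),
                     E = rep(E, each = config$clones),
                     S = rep(S, each = config$clones),
                     stringsAsFactors = FALSE)
  outcomes <- inject_clone_discrepancy(base, config$discrepancy_rate)

  split <- data.frame(id = ids,
                      set = ifelse(stats::runif(n) < config$train_fraction,
                                   "analysis", "test"),
                      stringsAsFactors = FALSE)

  truth <- list(config = config[setdiff(names(config), "scales")],
                theta_E = stats::setNames(theta_E, ids),
                theta_S = stats::setNames(theta_S, ids),
                E = stats::setNames(E, ids), S = stats::setNames(S, ids),
                package_version = as.character(utils::packageVersion("pesol")),
                rare_codons = config$scales$rare_codons)

  structure(list(id = ids, aa = aa, exposure = ann$exposure,
                 disorder = ann$disorder, cds = cds, features = features,
                 outcomes = outcomes, split = split, truth = truth),
            class = "es_cohort")
}

## theta = sum over named coefficients of beta * (feature - cohort mean).
latent_score <- function(features, coefs) {
  if (length(coefs) == 0) return(numeric(nrow(features)))
  miss <- setdiff(names(coefs), names(features))
  if (length(miss))
    stop("true-coefficient name(s) not among features: ",
         paste(miss, collapse = ", "))
  X <- as.matrix(features[, names(coefs), drop = FALSE])
  Xc <- sweep(X, 2, colMeans(X))
  drop(Xc %*% coefs)
}

## Draw ordinal levels 0..J from the cumulative model. Under the logistic
## link this is exactly the proportional-odds model the pipeline fits; the
## latent-normal option replaces the logistic latent noise with a Gaussian
## of matched variance (a misspecified world for robustness tests).
draw_ordinal <- function(theta, thresholds, link = "logistic") {
  n <- length(theta)
  tm <- matrix(thresholds, n, length(thresholds), byrow = TRUE)
  if (link == "logistic") {
    cum <- stats::plogis(tm - theta)
  } else {
    cum <- stats::pnorm((tm - theta) / (pi / sqrt(3)))
  }
  u <- stats::runif(n)
  as.integer(rowSums(u > cum))
}

#' Inject clone-to-clone score discrepancies
#'
#' Emulates the ~25% of constructs for which replicate clones disagreed.
#' Clone scores are only ever degraded (one point subtracted from E or S of
#' one clone), mirroring the rationale that experimental errors lower
#' scores, so no clone exceeds the construct's generative value. Constructs
#' whose scores cannot be lowered (E = 0 with S unrecorded) or with a single
#' clone are ineligible; the discrepant set is a Binomial(n, rate)-sized
#' random sample of eligible constructs, so the realized discrepant fraction
#' matches `rate` up to sampling error.
#'
#' @param outcomes Clone-level data frame (`id`, `clone_id`, `E`, `S`) in
#'   which all clones of a construct agree.
#' @param rate Target discrepant fraction of constructs.
#' @return The outcome data frame with discrepancies applied; a clone whose
#'   E is degraded to 0 has its S set to `NA` (not recorded).
#' @export
inject_clone_discrepancy <- function(outcomes, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(outcomes)
  ids <- unique(outcomes$id)
  n <- length(ids)
  first <- match(ids, outcomes$id)
  nclones <- tabulate(match(outcomes$id, ids), nbins = n)
  E0 <- outcomes$E[first]; S0 <- outcomes$S[first]
  eligible <- nclones >= 2L & (E0 > 0 | (!is.na(S0) & S0 > 0))
  m <- min(stats::rbinom(1, n, rate), sum(eligible))
  pick <- which(eligible)[sample.int(sum(eligible), m)]
  rows_by_id <- split(seq_len(nrow(outcomes)), factor(outcomes$id, levels = ids))
  for (i in pick) {
    rows <- rows_by_id[[i]]
    r <- rows[sample.int(length(rows) - 1L, 1L) + 1L]  # never the first clone
    canE <- outcomes$E[r] > 0
    canS <- !is.na(outcomes$S[r]) && outcomes$S[r] > 0
    what <- if (canE && canS) sample(c("E", "S"), 1) else if (canE) "E" else "S"
    if (what == "E") {
      outcomes$E[r] <- outcomes$E[r] - 1L
      if (outcomes$E[r] == 0L) outcomes$S[r] <- NA_integer_
    } else {
      outcomes$S[r] <- outcomes$S[r] - 1L
    }
  }
  outcomes
}

#' Baseline exposure and disorder annotator
#'
#' A deterministic stand-in for the neural surface-exposure and disorder
#' predictors whose outputs are inputs to the real analysis. Burial: each
#' residue's hydropathy is smoothed over an 9-residue window (burial is a
#' property of local context, so charged residues inside hydrophobic
#' stretches can be buried and hydrophobic residues in polar context
#' exposed) and the ~45% of residues with the highest smoothed hydropathy
#' in each sequence are labeled buried, ties broken by position. Disorder:
#' residues whose windowed mean disorder propensity exceeds a threshold are
#' labeled disordered. Intended for testing and simulation, not as a
#' substitute for real structure predictions.
#'
#' @param aa Named character vector of amino-acid sequences.
#' @param scales A [scale_config()] (hydropathy scale for burial ranking).
#' @param buried_fraction Fraction labeled buried.
#' @param window,threshold Disorder smoothing window and cutoff.
#' @param burial_window Hydropathy smoothing window for burial.
#' @param .residues,.idx,.lens Internal pre-split inputs.
#' @return List of named character vectors `exposure` (`B`/`E` strings) and
#'   `disorder` (`O`/`D` strings).
#' @export
annotate_baseline <- function(aa, scales = scale_config(),
                              buried_fraction = 0.45, window = 11L,
                              threshold = 0.26, burial_window = 9L,
                              .residues = NULL, .idx = NULL, .lens = NULL) {
  if (is.null(.residues)) {
    chars <- strsplit(toupper(aa), "", fixed = TRUE)
    .lens <- lengths(chars)
    .idx <- rep.int(seq_along(aa), .lens)
    .residues <- unlist(chars, use.names = FALSE)
  }
  n <- length(aa)
  N <- length(.residues)

  ## windowed mean of v within each sequence; ends (where the window runs
  ## off the sequence) fall back to `fallback`
  smooth_by_seq <- function(v, w, fallback) {
    pos <- seq_len(N) + (.idx - 1L) * w   # leave w NAs between sequences
    padded <- rep(NA_real_, N + n * w)
    padded[pos] <- v
    sm <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[pos]
    sm[is.na(sm)] <- fallback[is.na(sm)]
    sm
  }

  kdv <- scales$hydropathy[.residues]
  kdv[is.na(kdv)] <- 0
  kds <- smooth_by_seq(kdv, as.integer(burial_window), kdv)

  ## burial: within each sequence, rank by smoothed hydropathy (stable)
  o <- order(.idx, kds, method = "radix")
  start <- cumsum(c(0L, .lens[-n]))
  pos_in_seq <- seq_along(o) - start[.idx[o]]
  nb <- floor(buried_fraction * .lens)
  buried_sorted <- pos_in_seq > (.lens[.idx[o]] - nb[.idx[o]])
  buried <- logical(N)
  buried[o] <- buried_sorted
  expo <- c("E", "B")[buried + 1L]

  prop <- DISORDER_PROPENSITY[.residues]
  prop[is.na(prop)] <- 0
  sm_res <- smooth_by_seq(prop, as.integer(window),
                          rep(-Inf, N))    # sequence ends -> ordered
  dis <- c("O", "D")[(sm_res > threshold) + 1L]

  ids <- names(aa)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  ends <- cumsum(.lens)
  starts <- ends - .lens + 1L
  big_e <- paste0(expo, collapse = "")
  big_d <- paste0(dis, collapse = "")
  list(exposure = stats::setNames(substring(big_e, starts, ends), ids),
       disorder = stats::setNames(substring(big_d, starts, ends), ids))
}

## Sample an in-frame CDS per construct with configured rare-codon usage.
sample_cds <- function(resv, idx, ids, rare_usage, scales) {
  sets <- codon_sets(scales)
  codons <- character(length(resv))
  for (a in AA_ALPHABET) {
    at <- which(resv == a)
    if (!length(at)) next
    s <- sets[[a]]
    if (length(s$rare) > 0 && !is.na(rare_usage[a]) && rare_usage[a] > 0) {
      is_rare <- stats::runif(length(at)) < rare_usage[a]
      codons[at[is_rare]] <- sample(s$rare, sum(is_rare), replace = TRUE)
      codons[at[!is_rare]] <- sample(s$common, sum(!is_rare), replace = TRUE)
    } else {
      all_c <- c(s$rare, s$common)
      codons[at] <- sample(all_c, length(at), replace = TRUE)
    }
  }
  lens <- tabulate(idx, nbins = length(ids))
  ends <- 3L * cumsum(lens); starts <- ends - 3L * lens + 1L
  stats::setNames(substring(paste0(codons, collapse = ""), starts, ends), ids)
}

#' @export
print.es_cohort <- function(x, ...) {
  cat("<es_cohort> ", length(x$id), " constructs, ",
      nrow(x$outcomes), " clone trials",
      if (!is.null(x$cds)) ", with CDS", "\n", sep = "")
  tab <- aggregate_clone_scores(x$outcomes, "max-each")
  cat("  E distribution: ",
      paste(sprintf("%d:%d", 0:5, tabulate(factor(tab$E, levels = 0:5))),
            collapse = " "), "\n", sep = "")
  cat("  usable (E*S > 11): ", sum(tab$usable), " (",
      round(100 * mean(tab$usable), 1), "%)\n", sep = "")
  invisible(x)
}
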