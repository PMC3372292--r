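#' Fractional amino-acid composition of a construct
#'
#' Count of each standard residue divided by total chain length. Residues
#' outside the 20-letter alphabet (X, U, B, Z, ...) are counted in the chain
#' length but contribute to no fraction, with a warning.
#'
#' @param record A [protein_record()].
#' @return Named numeric vector of length 20 (names are one-letter codes).
#' @examples
#' amino_acid_fractions(protein_record("p", "AAK"))[c("A", "K")]
#' @export
amino_acid_fractions <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  chars <- ann_chars(record$aa_seq)
  n <- length(chars)
  code <- match(chars, AA_ALPHABET)
  if (anyNA(code))
    warning("record '", record$id, "': ", sum(is.na(code)),
            " nonstandard residue(s) counted in chain length only")
  counts <- tabulate(code, nbins = 20L)
  stats::setNames(counts / n, AA_ALPHABET)
}

#' Buried/exposed split of amino-acid fractions
#'
#' Splits each residue fraction by the per-residue exposure annotation.
#' Both the buried and the exposed fraction use total chain length as the
#' denominator, so `buried + exposed` equals the total fraction for every
#' amino acid.
#'
#' @param record A [protein_record()] with an exposure annotation.
#' @return List with named numeric vectors `buried` and `exposed`.
#' @export
exposure_split_fractions <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  if (is.null(record$exposure))
    stop("annotation required: record '", record$id, "' has no exposure labels")
  chars <- ann_chars(record$aa_seq)
  expo <- ann_chars(record$exposure)
  n <- length(chars)
  code <- match(chars, AA_ALPHABET)
  ok <- !is.na(code)
  b <- tabulate(code[ok & expo == "B"], nbins = 20L)
  e <- tabulate(code[ok & expo == "E"], nbins = 20L)
  list(buried = stats::setNames(b / n, AA_ALPHABET),
       exposed = stats::setNames(e / n, AA_ALPHABET))
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of per-residue hydropathy values under the configured
#' scale (Kyte-Doolittle by default).
#'
#' @param record A [protein_record()].
#' @param scales A [scale_config()].
#' @param on_missing What to do with residues absent from the scale:
#'   `"fail"` (default) or `"skip"` (exclude from the mean, with a warning).
#' @return Mean hydropathy (numeric scalar).
#' @examples
#' gravy(protein_record("p", "AILV"))  # 3.575 on the Kyte-Doolittle scale
#' @export
gravy <- function(record, scales = scale_config(),
                  on_missing = c("fail", "skip")) {
  on_missing <- match.arg(on_missing)
  mean_scale_value(record, scales$hydropathy, on_missing, "hydropathy")
}

#' Mean side-chain conformational entropy
#'
#' Mean of the configured side-chain entropy values over all residues
#' (`exposed_only = FALSE`, the `sce` parameter) or over residues predicted
#' surface-exposed only (`exposed_only = TRUE`, the `esce` parameter). Note
#' the `esce` denominator is the number of exposed residues, unlike the
#' exposure-split fractions which use chain length.
#'
#' @inheritParams gravy
#' @param exposed_only Restrict the mean to exposed residues (requires an
#'   exposure annotation).
#' @return Mean side-chain entropy; `NA` (with a warning) if `exposed_only`
#'   and no residue is predicted exposed.
#' @export
sidechain_entropy <- function(record, scales = scale_config(),
                              exposed_only = FALSE,
                              on_missing = c("fail", "skip")) {
  on_missing <- match.arg(on_missing)
  if (!exposed_only)
    return(mean_scale_value(record, scales$sce, on_missing, "sce"))
  if (is.null(record$exposure))
    stop("annotation required: record '", record$id, "' has no exposure labels")
  chars <- ann_chars(record$aa_seq)
  expo <- ann_chars(record$exposure)
  keep <- expo == "E"
  if (!any(keep)) {
    warning("record '", record$id, "': no exposed residues; esce undefined")
    return(NA_real_)
  }
  sub <- protein_record(record$id, paste0(chars[keep], collapse = ""))
  mean_scale_value(sub, scales$sce, on_missing, "sce")
}

mean_scale_value <- function(record, scale, on_missing, what) {
  stopifnot(inherits(record, "protein_record"))
  chars <- ann_chars(record$aa_seq)
  vals <- scale[chars]
  if (anyNA(vals)) {
    if (on_missing == "fail")
      stop("record '", record$id, "': residue '",
           chars[which(is.na(vals))[1]], "' missing from ", what, " scale")
    warning("record '", record$id, "': ", sum(is.na(vals)),
            " residue(s) missing from ", what, " scale skipped")
    vals <- vals[!is.na(vals)]
  }
  mean(vals)
}

#' Electrostatic charge metrics
#'
#' Counts and chain-length-normalized fractions built from the charged
#' residues Arg, Lys, Asp, Glu: number of charged residues (R+K+D+E), net
#' charge (R+K-D-E), absolute net charge, and their fractional versions.
#'
#' @param record A [protein_record()].
#' @return Named numeric vector: `numcharge`, `netcharge`, `absnetcharge`,
#'   `fracnumcharge`, `fracnetcharge`, `fracabsnetcharge`.
#' @examples
#' charge_metrics(protein_record("p", "RRKDA"))
#' @export
charge_metrics <- function(record) {
  fr <- suppressWarnings(amino_acid_fractions(record))
  n <- nchar(record$aa_seq)
  cnt <- fr * n
  num <- cnt[["R"]] + cnt[["K"]] + cnt[["D"]] + cnt[["E"]]
  net <- cnt[["R"]] + cnt[["K"]] - cnt[["D"]] - cnt[["E"]]
  c(numcharge = num, netcharge = net, absnetcharge = abs(net),
    fracnumcharge = num / n, fracnetcharge = net / n,
    fracabsnetcharge = abs(net) / n)
}

#' Henderson-Hasselbalch net charge at a given pH
#'
#' Net charge of the construct at pH `ph`, summing the configured ionizable
#' side chains (D, E, C, Y, H, K, R by default) plus one free N- and one
#' C-terminus. Strictly decreasing in pH.
#'
#' @param record A [protein_record()].
#' @param ph pH value(s).
#' @param scales A [scale_config()].
#' @return Net charge (same length as `ph`).
#' @export
net_charge <- function(record, ph, scales = scale_config()) {
  counts <- ionizable_counts_matrix(record$aa_seq, scales)
  as.numeric(charge_at_ph(counts, ph, scales$pka))
}

#' Isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the construct is
#' zero, found by bisection on \[0, 14\] to a tolerance of 1e-4 pH units.
#' Uses the Bjellqvist-style pKa table of the configuration.
#'
#' @param record A [protein_record()].
#' @param scales A [scale_config()].
#' @return Isoelectric point (numeric scalar).
#' @examples
#' isoelectric_point(protein_record("p", "DDKK"))
#' @export
isoelectric_point <- function(record, scales = scale_config()) {
  counts <- ionizable_counts_matrix(record$aa_seq, scales)
  as.numeric(pi_bisect(counts, scales$pka))
}

#' Fraction of residues predicted disordered
#'
#' @param record A [protein_record()] with a disorder annotation.
#' @return Fraction in \[0, 1\].
#' @export
disorder_fraction <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  if (is.null(record$disorder))
    stop("annotation required: record '", record$id, "' has no disorder labels")
  d <- ann_chars(record$disorder)
  mean(d == "D")
}

#' Rare- vs common-codon split of Arg, Ile, Leu, Pro fractions
#'
#' For each of the four amino acids encoded in part by E. coli rare codons,
#' splits the residue fraction into the part encoded by rare codons and the
#' part encoded by common codons, using the configured rare-codon sets.
#' Denominator is total chain length, so `rare + common` equals the total
#' fraction of the amino acid.
#'
#' @param record A [protein_record()] with a CDS.
#' @param scales A [scale_config()].
#' @return Matrix with rows R, I, L, P and columns `rare`, `common`.
#' @export
rare_codon_split <- function(record, scales = scale_config()) {
  stopifnot(inherits(record, "protein_record"))
  if (is.null(record$cds))
    stop("record '", record$id, "' has no CDS; rare-codon split unavailable")
  n <- nchar(record$aa_seq)
  codons <- substring(record$cds, seq(1, 3 * n, by = 3), seq(3, 3 * n, by = 3))
  aas <- ann_chars(record$aa_seq)
  out <- matrix(0, nrow = 4, ncol = 2,
                dimnames = list(c("R", "I", "L", "P"), c("rare", "common")))
  for (aa in rownames(out)) {
    at <- aas == aa
    rare <- at & codons %in% scales$rare_codons[[aa]]
    out[aa, "rare"] <- sum(rare) / n
    out[aa, "common"] <- (sum(at) - sum(rare)) / n
  }
  out
}

#' Compute the full named parameter vector for one construct
#'
#' Evaluates all 72 core sequence parameters (20 total residue fractions,
#' 20 buried and 20 exposed fractions, and the 12 compound parameters:
#' gravy, sce, esce, numcharge, netcharge, absnetcharge, fracnumcharge,
#' fracnetcharge, fracabsnetcharge, diso, length, pi), plus the eight
#' rare/common codon-split fractions when a CDS is present. Parameters whose
#' annotation is missing are returned as `NA` and listed in the `"absent"`
#' attribute rather than silently set to zero.
#'
#' @param record A [protein_record()].
#' @param scales A [scale_config()].
#' @return Named numeric vector with attribute `"absent"`.
#' @export
compute_feature_vector <- function(record, scales = scale_config()) {
  tab <- feature_table(aa = stats::setNames(record$aa_seq, record$id),
                       exposure = if (!is.null(record$exposure))
                         stats::setNames(record$exposure, record$id),
                       disorder = if (!is.null(record$disorder))
                         stats::setNames(record$disorder, record$id),
                       cds = if (!is.null(record$cds))
                         stats::setNames(record$cds, record$id),
                       scales = scales)
  v <- unlist(tab[1, -1, drop = TRUE])
  structure(v, absent = names(v)[is.na(v)])
}

#' Compute the parameter table for a cohort of constructs
#'
#' Vectorized evaluation of all sequence parameters for many constructs at
#' once; the workhorse behind [compute_feature_vector()] and the synthetic
#' cohort generator. Input sequences and annotations are named character
#' vectors keyed by construct id.
#'
#' @param aa Named character vector of amino-acid sequences.
#' @param exposure Optional named character vector of `B`/`E` strings.
#' @param disorder Optional named character vector of `O`/`D` strings.
#' @param cds Optional named character vector of coding sequences (validated
#'   against `aa` under the standard genetic code).
#' @param scales A [scale_config()].
#' @return Data frame: column `id` then one column per parameter. Exposure-
#'   or disorder-dependent columns are `NA` when the annotation is absent;
#'   codon-split columns are present only when `cds` is given.
#' @export
feature_table <- function(aa, exposure = NULL, disorder = NULL, cds = NULL,
                          scales = scale_config()) {
  stopifnot(is.character(aa), length(aa) >= 1L)
  if (is.null(names(aa))) names(aa) <- paste0("seq", seq_along(aa))
  aa <- toupper(aa)
  if (any(!nzchar(aa))) stop("invalid input: empty amino-acid sequence")
  n_rec <- length(aa)
  chars <- strsplit(aa, "", fixed = TRUE)
  lens <- lengths(chars)
  idx <- rep.int(seq_len(n_rec), lens)
  res <- unlist(chars, use.names = FALSE)
  code <- match(res, AA_ALPHABET)
  std <- !is.na(code)
  if (!all(std)) {
    bad_ids <- unique(names(aa)[idx[!std]])
    warning(length(bad_ids), " record(s) contain nonstandard residues ",
            "(counted in chain length only): ",
            paste(utils::head(bad_ids, 5), collapse = ", "),
            if (length(bad_ids) > 5) ", ...")
  }

  counts <- count_matrix(idx[std], code[std], n_rec)
  frac <- counts / lens
  colnames(frac) <- tolower(AA_ALPHABET)

  kd <- scales$hydropathy[AA_ALPHABET]
  sc <- scales$sce[AA_ALPHABET]
  n_std <- rowSums(counts)
  gravy_v <- as.numeric(counts %*% kd) / n_std
  sce_v <- as.numeric(counts %*% sc) / n_std

  cnt <- function(a) counts[, match(a, AA_ALPHABET)]
  num <- cnt("R") + cnt("K") + cnt("D") + cnt("E")
  net <- cnt("R") + cnt("K") - cnt("D") - cnt("E")

  pi_v <- pi_bisect(ionizable_counts(counts), scales$pka)

  out <- data.frame(id = names(aa), frac, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)

  bur <- exp_ <- matrix(NA_real_, n_rec, 20,
                        dimnames = list(NULL, NULL))
  esce_v <- rep(NA_real_, n_rec)
  if (!is.null(exposure)) {
    exposure <- exposure[names(aa)]
    if (anyNA(exposure)) stop("exposure annotation missing for some ids")
    ech <- strsplit(unname(exposure), "", fixed = TRUE)
    if (!all(lengths(ech) == lens))
      stop("exposure annotation length mismatch for id '",
           names(aa)[which(lengths(ech) != lens)[1]], "'")
    ev <- unlist(ech, use.names = FALSE)
    bsel <- std & ev == "B"
    esel <- std & ev == "E"
    bur <- count_matrix(idx[bsel], code[bsel], n_rec) / lens
    exp_ <- count_matrix(idx[esel], code[esel], n_rec) / lens
    n_exp <- rowsum_by(as.numeric(esel), idx, n_rec)
    s_exp <- rowsum_by(ifelse(esel, sc[code], 0), idx, n_rec)
    esce_v <- ifelse(n_exp > 0, s_exp / n_exp, NA_real_)
    if (any(n_exp == 0))
      warning(sum(n_exp == 0), " record(s) have no exposed residues; ",
              "esce set to NA")
  }
  colnames(bur) <- paste0(tolower(AA_ALPHABET), "b")
  colnames(exp_) <- paste0(tolower(AA_ALPHABET), "e")
  out <- cbind(out, as.data.frame(bur), as.data.frame(exp_))

  diso_v <- rep(NA_real_, n_rec)
  if (!is.null(disorder)) {
    disorder <- disorder[names(aa)]
    if (anyNA(disorder)) stop("disorder annotation missing for some ids")
    dch <- strsplit(unname(disorder), "", fixed = TRUE)
    if (!all(lengths(dch) == lens))
      stop("disorder annotation length mismatch for id '",
           names(aa)[which(lengths(dch) != lens)[1]], "'")
    dv <- unlist(dch, use.names = FALSE)
    diso_v <- rowsum_by(as.numeric(dv == "D"), idx, n_rec) / lens
  }

  out$gravy <- gravy_v
  out$sce <- sce_v
  out$esce <- esce_v
  out$numcharge <- num
  out$netcharge <- net
  out$absnetcharge <- abs(net)
  out$fracnumcharge <- num / lens
  out$fracnetcharge <- net / lens
  out$fracabsnetcharge <- abs(net) / lens
  out$diso <- diso_v
  out$length <- as.numeric(lens)
  out$pi <- pi_v

  if (!is.null(cds)) {
    cds <- toupper(cds[names(aa)])
    if (anyNA(cds)) stop("CDS missing for some ids")
    out <- cbind(out, codon_split_table(aa, cds, lens, idx, res, scales))
  }
  out
}

## Per-record counts of the 20 standard residues from a subset of residue
## positions. idx: record index per position; code: alphabet index.
count_matrix <- function(idx, code, n_rec) {
  matrix(tabulate((idx - 1L) * 20L + code, nbins = n_rec * 20L),
         nrow = n_rec, byrow = TRUE)
}

## Sum of x by record index, returning a length-n_rec vector (0 for absent).
rowsum_by <- function(x, idx, n_rec) {
  out <- numeric(n_rec)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

## Counts of ionizable groups per record: columns Cterm, D, E, C, Y, Nterm,
## H, K, R (termini always 1).
ionizable_counts <- function(counts) {
  g <- cbind(Cterm = 1, D = counts[, 3], E = counts[, 4], C = counts[, 2],
             Y = counts[, 20], Nterm = 1, H = counts[, 7], K = counts[, 9],
             R = counts[, 15])
  g
}

ionizable_counts_matrix <- function(aa_seq, scales) {
  chars <- strsplit(toupper(aa_seq), "", fixed = TRUE)[[1]]
  code <- match(chars, AA_ALPHABET)
  counts <- matrix(tabulate(code[!is.na(code)], nbins = 20L), nrow = 1)
  ionizable_counts(counts)
}

## Net charge at pH for a matrix of ionizable-group counts. Groups absent
## from the configured pKa table are ignored.
charge_at_ph <- function(gcounts, ph, pka) {
  gcounts <- gcounts[, colnames(gcounts) %in% pka$group, drop = FALSE]
  ord <- match(colnames(gcounts), pka$group)
  pk <- pka$pka[ord]
  sg <- pka$sign[ord]
  z <- matrix(0, nrow(gcounts), length(ph))
  for (j in seq_along(pk)) {
    frac <- if (sg[j] > 0) 1 / (1 + 10^(outer(rep(1, nrow(gcounts)), ph) - pk[j]))
            else -1 / (1 + 10^(pk[j] - outer(rep(1, nrow(gcounts)), ph)))
    z <- z + gcounts[, j] * frac
  }
  z
}

## Vectorized bisection for the isoelectric point over [0, 14]; the charge
## curve is strictly decreasing in pH so the root is unique and bracketed.
pi_bisect <- function(gcounts, pka, iter = 26L) {
  n <- nrow(gcounts)
  lo <- rep(0, n); hi <- rep(14, n)
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    z <- charge_at_mid(gcounts, mid, pka)
    pos <- z > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

## Charge at a per-record pH vector (one pH per record).
charge_at_mid <- function(gcounts, ph, pka) {
  gcounts <- gcounts[, colnames(gcounts) %in% pka$group, drop = FALSE]
  ord <- match(colnames(gcounts), pka$group)
  pk <- pka$pka[ord]
  sg <- pka$sign[ord]
  z <- numeric(nrow(gcounts))
  for (j in seq_along(pk)) {
    frac <- if (sg[j] > 0) 1 / (1 + 10^(ph - pk[j]))
            else -1 / (1 + 10^(pk[j] - ph))
    z <- z + gcounts[, j] * frac
  }
  z
}

## Rare/common codon-split fractions for R, I, L, P across a cohort.
codon_split_table <- function(aa, cds, lens, idx, res, scales) {
  n_rec <- length(aa)
  gc <- genetic_code_table()
  starts <- lapply(lens, function(l) seq(1, 3 * l, by = 3))
  codons <- unlist(mapply(function(s, st) substring(s, st, st + 2),
                          cds, starts, SIMPLIFY = FALSE), use.names = FALSE)
  tr <- unname(gc[codons])
  bad <- which(is.na(tr) | tr != res)
  if (length(bad) > 0) {
    i <- bad[1]
    pos <- i - match(idx[i], idx) + 1L
    stop("CDS/translation mismatch for '", names(aa)[idx[i]], "': codon ",
         pos, " ('", codons[i], "') translates to ",
         ifelse(is.na(tr[i]), "?", tr[i]), ", sequence has ", res[i])
  }
  cols <- list()
  for (a in c("R", "I", "L", "P")) {
    at <- res == a
    rare <- at & codons %in% scales$rare_codons[[a]]
    r <- rowsum_by(as.numeric(rare), idx, n_rec) / lens
    tot <- rowsum_by(as.numeric(at), idx, n_rec) / lens
    cols[[paste0(tolower(a), "_rare")]] <- r
    cols[[paste0(tolower(a), "_common")]] <- tot - r
  }
  as.data.frame(cols)
}

#' Names of the 72 core sequence parameters
#'
#' The 20 total residue fractions, 20 buried fractions, 20 exposed fractions
#' and 12 compound parameters, in the canonical column order of
#' [feature_table()].
#'
#' @return Character vector of length 72.
#' @export
core_parameter_names <- function() {
  c(tolower(AA_ALPHABET),
    paste0(tolower(AA_ALPHABET), "b"),
    paste0(tolower(AA_ALPHABET), "e"),
    "gravy", "sce", "esce", "numcharge", "netcharge", "absnetcharge",
    "fracnumcharge", "fracnetcharge", "fracabsnetcharge",
    "diso", "length", "pi")
}
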