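#' @keywords internal
"_PACKAGE"

## Standard 20-letter amino-acid alphabet, alphabetical by one-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used for GRAVY (grand average of hydropathy).
#' Positive values are hydrophobic, negative hydrophilic.
#'
#' @format Named numeric vector over the 20 standard amino acids.
#' @export
kd_hydropathy <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

#' Side-chain conformational entropy scale
#'
#' Default per-residue side-chain conformational entropies (cal mol^-1 K^-1)
#' used for the mean side-chain entropy (sce) and mean exposed side-chain
#' entropy (esce) parameters. Values follow published Monte Carlo / rotamer
#' conformational-entropy estimates; long flexible charged side chains (Lys,
#' Arg, Glu, Gln, Met) carry the largest entropies, while Ala, Gly and Pro
#' carry none. The scale is a convention, not a measurement on this dataset;
#' replace it via [scale_config()] if a different entropy table is preferred.
#'
#' @format Named numeric vector over the 20 standard amino acids.
#' @export
creamer_sce <- c(
  A = 0.00, C = 3.55, D = 2.00, E = 3.53, F = 1.40,
  G = 0.00, H = 3.44, I = 1.74, K = 5.86, L = 1.63,
  M = 4.55, N = 3.29, P = 0.00, Q = 5.02, R = 7.11,
  S = 3.68, T = 3.31, V = 0.12, W = 2.74, Y = 2.78
)

#' Bjellqvist-style pKa table for isoelectric-point calculation
#'
#' Ionizable-group pKa values in the style of the ExPASy pI tool: side chains
#' of Asp, Glu, Cys, Tyr, His, Lys, Arg plus the free N- and C-termini.
#' `sign` is +1 for groups that are positively charged when protonated
#' (bases: His, Lys, Arg, N-terminus) and -1 for acids.
#'
#' @format Data frame with columns `group`, `pka`, `sign`.
#' @export
bjellqvist_pka <- data.frame(
  group = c("Cterm", "D", "E", "C", "Y", "Nterm", "H", "K", "R"),
  pka   = c(3.55,   4.05, 4.45, 9.00, 10.00, 7.50,  5.98, 10.00, 12.00),
  sign  = c(-1,     -1,   -1,   -1,   -1,    +1,    +1,   +1,    +1),
  stringsAsFactors = FALSE
)

#' Default E. coli rare-codon sets
#'
#' Codons decoded inefficiently in E. coli for the four amino acids commonly
#' considered to be encoded in part by expression-reducing rare codons:
#' Arg (AGA, AGG, CGA, CGG), Ile (ATA), Leu (CTA), Pro (CCC). Used to split
#' the Arg/Ile/Leu/Pro fractions into rare-codon-encoded and
#' common-codon-encoded components. Fully configurable via [scale_config()];
#' the set in force is recorded in output metadata.
#'
#' @format Named list of character vectors of codons, names are one-letter
#'   amino-acid codes.
#' @export
ecoli_rare_codons <- list(
  R = c("AGA", "AGG", "CGA", "CGG"),
  I = "ATA",
  L = "CTA",
  P = "CCC"
)

#' Assemble a scale configuration
#'
#' Bundles the lookup tables used by the sequence-parameter calculators:
#' hydropathy scale (GRAVY), side-chain entropy scale (sce/esce), pKa table
#' (isoelectric point) and rare-codon sets (codon-usage splits). Each
#' component is validated: the hydropathy and entropy scales must cover all
#' 20 standard residues, and every rare codon must actually encode its
#' amino acid under the standard genetic code.
#'
#' @param hydropathy Named numeric vector, amino acid -> hydropathy.
#' @param sce Named numeric vector, amino acid -> side-chain entropy.
#' @param pka Data frame with columns `group`, `pka`, `sign` (see
#'   [bjellqvist_pka]).
#' @param rare_codons Named list, amino acid -> character vector of codons.
#' @return An object of class `"scale_config"`.
#' @examples
#' sc <- scale_config()
#' sc$hydropathy[["I"]]
#' @export
scale_config <- function(hydropathy = kd_hydropathy,
                         sce = creamer_sce,
                         pka = bjellqvist_pka,
                         rare_codons = ecoli_rare_codons) {
  stopifnot(is.numeric(hydropathy), is.numeric(sce))
  miss_h <- setdiff(AA_ALPHABET, names(hydropathy))
  if (length(miss_h) > 0)
    stop("hydropathy scale is missing residues: ", paste(miss_h, collapse = ", "))
  miss_s <- setdiff(AA_ALPHABET, names(sce))
  if (length(miss_s) > 0)
    stop("sce scale is missing residues: ", paste(miss_s, collapse = ", "))
  if (!is.data.frame(pka) || !all(c("group", "pka", "sign") %in% names(pka)))
    stop("pka must be a data frame with columns group, pka, sign")
  if (!all(c("Nterm", "Cterm") %in% pka$group))
    stop("pka table must include Nterm and Cterm groups")
  if (!all(pka$sign %in% c(-1, 1)))
    stop("pka sign column must be +1 or -1")
  if (!is.list(rare_codons) || is.null(names(rare_codons)))
    stop("rare_codons must be a named list of codon vectors")
  gc <- genetic_code_table()
  for (aa in names(rare_codons)) {
    cods <- toupper(rare_codons[[aa]])
    bad <- cods[gc[cods] != aa]
    if (any(is.na(gc[cods])))
      stop("unknown codon(s) in rare set for ", aa, ": ",
           paste(cods[is.na(gc[cods])], collapse = ", "))
    if (length(bad) > 0)
      stop("rare codon(s) ", paste(bad, collapse = ", "),
           " do not encode amino acid ", aa)
    rare_codons[[aa]] <- cods
  }
  structure(list(hydropathy = hydropathy, sce = sce, pka = pka,
                 rare_codons = rare_codons),
            class = "scale_config")
}

## Standard genetic code as a named vector codon -> one-letter amino acid
## ("*" for stop), taken from Biostrings.
genetic_code_table <- function() {
  Biostrings::GENETIC_CODE
}

## Codon sets per amino acid (stops excluded), split into rare/common using
## the configured rare sets.
codon_sets <- function(scales) {
  gc <- genetic_code_table()
  gc <- gc[gc != "*"]
  all_sets <- split(names(gc), gc)
  rare <- scales$rare_codons
  lapply(stats::setNames(names(all_sets), names(all_sets)), function(aa) {
    cods <- all_sets[[aa]]
    r <- intersect(cods, rare[[aa]])
    list(rare = r, common = setdiff(cods, r))
  })
}

#' @export
print.scale_config <- function(x, ...) {
  cat("Scale configuration\n")
  cat("  hydropathy: ", length(x$hydropathy), " residues (GRAVY)\n", sep = "")
  cat("  sce:        ", length(x$sce), " residues (side-chain entropy)\n", sep = "")
  cat("  pKa groups: ", paste(x$pka$group, collapse = ", "), "\n", sep = "")
  cat("  rare codons:",
      paste(vapply(names(x$rare_codons),
                   function(a) paste0(a, "={", paste(x$rare_codons[[a]], collapse = ","), "}"),
                   ""), collapse = " "), "\n")
  invisible(x)
}
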