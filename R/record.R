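#' Construct a protein record
#'
#' One expression construct: identifier, amino-acid sequence, optional
#' in-frame coding sequence, and optional per-residue annotations for
#' predicted surface exposure and backbone disorder. Sequences are analyzed
#' as supplied; purification tags should be removed by the caller before
#' constructing the record.
#'
#' @param id Construct identifier (single string).
#' @param aa_seq Amino-acid sequence (one-letter codes; upper-cased on input).
#' @param cds Optional coding DNA sequence, length `3 * nchar(aa_seq)`, no
#'   stop codon; must translate to `aa_seq` under the standard genetic code.
#' @param exposure Optional per-residue exposure labels: a character vector of
#'   `"B"`/`"E"` (or `"buried"`/`"exposed"`) of length `nchar(aa_seq)`, or a
#'   single string of `B`/`E` letters.
#' @param disorder Optional per-residue disorder labels: `"O"`/`"D"` (or
#'   `"ordered"`/`"disordered"`), same conventions as `exposure`.
#' @return An object of class `"protein_record"`.
#' @examples
#' protein_record("p1", "MKLV")
#' @export
protein_record <- function(id, aa_seq, cds = NULL, exposure = NULL,
                           disorder = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L)
  aa_seq <- toupper(aa_seq)
  n <- nchar(aa_seq)
  if (n < 1L) stop("invalid input: empty amino-acid sequence for '", id, "'")

  if (!is.null(exposure))
    exposure <- normalize_labels(exposure, n, c(buried = "B", exposed = "E"),
                                 "exposure", id)
  if (!is.null(disorder))
    disorder <- normalize_labels(disorder, n, c(ordered = "O", disordered = "D"),
                                 "disorder", id)
  if (!is.null(cds)) {
    cds <- toupper(cds)
    if (nchar(cds) != 3L * n)
      stop("CDS for '", id, "' has length ", nchar(cds),
           ", expected ", 3L * n)
    check_translation(cds, aa_seq, id)
  }
  structure(list(id = id, aa_seq = aa_seq, cds = cds,
                 exposure = exposure, disorder = disorder),
            class = "protein_record")
}

## Normalize annotation input (vector of labels/words or one string) to a
## single string of one-letter codes of length n.
normalize_labels <- function(x, n, map, what, id) {
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L)
    x <- strsplit(x, "", fixed = TRUE)[[1]]
  x <- as.character(x)
  lx <- tolower(x)
  out <- character(length(x))
  codes <- unname(map)
  for (i in seq_along(map)) {
    out[lx == names(map)[i] | toupper(x) == map[[i]]] <- map[[i]]
  }
  bad <- which(!out %in% codes)
  if (length(bad) > 0)
    stop("invalid ", what, " label '", x[bad[1]], "' at position ", bad[1],
         " for '", id, "'")
  if (length(out) != n)
    stop(what, " annotation for '", id, "' has length ", length(out),
         ", expected ", n)
  paste0(out, collapse = "")
}

## Verify that cds translates to aa_seq; report the first discordant codon.
check_translation <- function(cds, aa_seq, id) {
  gc <- genetic_code_table()
  codons <- substring(cds, seq(1, nchar(cds), by = 3),
                      seq(3, nchar(cds), by = 3))
  tr <- unname(gc[codons])
  aas <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  if (anyNA(tr)) {
    i <- which(is.na(tr))[1]
    stop("CDS/translation mismatch for '", id, "': unrecognized codon '",
         codons[i], "' at codon position ", i)
  }
  bad <- which(tr != aas)
  if (length(bad) > 0) {
    i <- bad[1]
    stop("CDS/translation mismatch for '", id, "': codon ", i, " ('",
         codons[i], "') translates to ", tr[i], ", sequence has ", aas[i])
  }
  invisible(TRUE)
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", nchar(x$aa_seq), " aa",
      if (!is.null(x$cds)) ", CDS",
      if (!is.null(x$exposure)) ", exposure",
      if (!is.null(x$disorder)) ", disorder", ")\n", sep = "")
  invisible(x)
}

## Split an annotation string into a character vector, or NULL.
ann_chars <- function(s) {
  if (is.null(s)) NULL else strsplit(s, "", fixed = TRUE)[[1]]
}
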