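#' Read a FASTA file of protein or coding sequences
#'
#' Sequences are upper-cased; identifiers are the first whitespace-delimited
#' token of each header and must be unique and non-empty.
#'
#' @param path FASTA file.
#' @param type `"AA"` (default) or `"DNA"`.
#' @return Named character vector of sequences, input order preserved.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file '", path, "'")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("empty record id in '", path, "'")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s) in '", path, "': ",
         paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id '", ids[!nzchar(seqs)][1], "' in '", path, "'")
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a clone-level outcome table
#'
#' TSV with columns `id`, `clone_id`, `E`, `S`. E and S must be integers
#' 0-5; S may be blank (unrecorded) only where E = 0.
#'
#' @param path TSV file.
#' @return Data frame with columns `id`, `clone_id`, `E`, `S` (`S` is `NA`
#'   where unrecorded).
#' @export
read_outcomes <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("id", "clone_id", "E", "S")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("outcome table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  parse_score <- function(x, what) {
    blank <- is.na(x) | x == ""
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!blank & (is.na(v) | v != round(v) | v < 0 | v > 5))
    if (length(bad))
      stop("invalid ", what, " value '", x[bad[1]], "' at row ", bad[1],
           " of '", path, "' (integer 0-5 required)")
    v[blank] <- NA
    as.integer(v)
  }
  E <- parse_score(tab$E, "E")
  S <- parse_score(tab$S, "S")
  badE <- which(is.na(E))
  if (length(badE))
    stop("missing E value at row ", badE[1], " of '", path, "'")
  bad <- which(is.na(S) & E > 0)
  if (length(bad))
    stop("S unrecorded at row ", bad[1], " of '", path,
         "' although E > 0; S is only unrecorded when E = 0")
  data.frame(id = tab$id, clone_id = tab$clone_id, E = E, S = S,
             stringsAsFactors = FALSE)
}

#' Write a clone-level outcome table
#'
#' @param outcomes Data frame (`id`, `clone_id`, `E`, `S`).
#' @param path Output TSV path.
#' @export
write_outcomes <- function(outcomes, path) {
  out <- outcomes
  out$S <- ifelse(is.na(out$S), "", as.character(out$S))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-residue annotations
#'
#' TSV with columns `id`, `position` (1-based), `exposure` (`B`/`E`) and
#' `disorder` (`O`/`D`). Positions must cover 1..length contiguously for
#' each construct.
#'
#' @param path TSV file.
#' @return List of named character vectors `exposure` and `disorder`
#'   (one label string per construct).
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "position", "exposure", "disorder")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.integer(tab$position))
  if (anyNA(pos))
    stop("non-integer position at row ", which(is.na(pos))[1],
         " of '", path, "'")
  if (!all(tab$exposure %in% c("B", "E")))
    stop("invalid exposure label at row ",
         which(!tab$exposure %in% c("B", "E"))[1], " of '", path, "'")
  if (!all(tab$disorder %in% c("O", "D")))
    stop("invalid disorder label at row ",
         which(!tab$disorder %in% c("O", "D"))[1], " of '", path, "'")
  ids <- unique(tab$id)
  grp <- split(seq_len(nrow(tab)), factor(tab$id, levels = ids))
  expo <- diso <- character(length(ids))
  for (k in seq_along(ids)) {
    i <- grp[[k]][order(pos[grp[[k]]])]
    p <- pos[i]
    if (!identical(p, seq_along(p)))
      stop("positions for id '", ids[k], "' in '", path,
           "' do not cover 1..", length(p), " contiguously")
    expo[k] <- paste0(tab$exposure[i], collapse = "")
    diso[k] <- paste0(tab$disorder[i], collapse = "")
  }
  list(exposure = stats::setNames(expo, ids),
       disorder = stats::setNames(diso, ids))
}

#' Write per-residue annotations
#'
#' @param exposure,disorder Named character vectors of label strings.
#' @param path Output TSV path.
#' @export
write_annotations <- function(exposure, disorder, path) {
  stopifnot(identical(names(exposure), names(disorder)))
  lens <- nchar(exposure)
  tab <- data.frame(
    id = rep(names(exposure), lens),
    position = unlist(lapply(lens, seq_len), use.names = FALSE),
    exposure = unlist(strsplit(unname(exposure), "", fixed = TRUE),
                      use.names = FALSE),
    disorder = unlist(strsplit(unname(disorder), "", fixed = TRUE),
                      use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a feature table as TSV
#'
#' @param features Data frame from [feature_table()].
#' @param path TSV path.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Export a synthetic cohort to plain-text files
#'
#' Writes `proteins.fasta`, `cds.fasta` (when present), `annotations.tsv`,
#' `outcomes.tsv`, `split.tsv` and `truth.json` under `dir`. The truth
#' record (latent parameters) is serialized for audit only; analysis stages
#' read everything except `truth.json`.
#'
#' @param cohort An `"es_cohort"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "es_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wrap <- function(expr, file) {
    tryCatch(expr, error = function(e)
      stop("failed writing '", file, "': ", conditionMessage(e)))
  }
  wrap(write_fasta(cohort$aa, file.path(dir, "proteins.fasta"), "AA"),
       file.path(dir, "proteins.fasta"))
  if (!is.null(cohort$cds))
    wrap(write_fasta(cohort$cds, file.path(dir, "cds.fasta"), "DNA"),
         file.path(dir, "cds.fasta"))
  wrap(write_annotations(cohort$exposure, cohort$disorder,
                         file.path(dir, "annotations.tsv")),
       file.path(dir, "annotations.tsv"))
  wrap(write_outcomes(cohort$outcomes, file.path(dir, "outcomes.tsv")),
       file.path(dir, "outcomes.tsv"))
  wrap(utils::write.table(cohort$split, file.path(dir, "split.tsv"),
                          sep = "\t", quote = FALSE, row.names = FALSE),
       file.path(dir, "split.tsv"))
  truth <- cohort$truth
  truth$config$scales <- NULL
  wrap(jsonlite::write_json(truth, file.path(dir, "truth.json"),
                            auto_unbox = TRUE, digits = NA, null = "null"),
       file.path(dir, "truth.json"))
  invisible(dir)
}

#' Import a cohort from files written by [export_cohort()]
#'
#' Reads the sequence, annotation, outcome and split files (never
#' `truth.json`) and recomputes the feature table, yielding an in-memory
#' cohort equivalent to the exported one for all analysis purposes.
#'
#' @param dir Directory holding the cohort files.
#' @param scales A [scale_config()].
#' @param features Recompute the feature table (default `TRUE`)?
#' @return An `"es_cohort"` (with `truth = NULL`).
#' @export
read_cohort <- function(dir, scales = scale_config(), features = TRUE) {
  aa <- read_fasta(file.path(dir, "proteins.fasta"), "AA")
  cds_path <- file.path(dir, "cds.fasta")
  cds <- if (file.exists(cds_path)) read_fasta(cds_path, "DNA") else NULL
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  outcomes <- read_outcomes(file.path(dir, "outcomes.tsv"))
  split <- utils::read.delim(file.path(dir, "split.tsv"),
                             stringsAsFactors = FALSE)
  ids <- names(aa)
  feats <- if (features)
    feature_table(aa, exposure = ann$exposure[ids],
                  disorder = ann$disorder[ids],
                  cds = if (!is.null(cds)) cds[ids], scales = scales)
  else NULL
  structure(list(id = ids, aa = aa, exposure = ann$exposure[ids],
                 disorder = ann$disorder[ids], cds = cds,
                 features = feats, outcomes = outcomes, split = split,
                 truth = NULL),
            class = "es_cohort")
}
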