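# Reference-anchored MSA parsing, identity filtering and conservation scoring.

.GAP <- "-"

#' Construct an alignment set
#'
#' A reference-anchored multiple sequence alignment: the reference's aligned
#' sequence plus zero or more homolog rows of equal length, all in reference
#' coordinates (insertion columns relative to the reference already removed).
#'
#' @param reference_id Identifier of the reference sequence.
#' @param reference_aligned Aligned reference string over the 20 letters and
#'   `-`.
#' @param homologs Named character vector of aligned homolog strings (may be
#'   empty).
#' @return An object of class `alignment_set`.
#' @export
alignment_set <- function(reference_id, reference_aligned, homologs = character()) {
  stopifnot(is.character(reference_id), length(reference_id) == 1L,
            is.character(reference_aligned), length(reference_aligned) == 1L,
            is.character(homologs))
  reference_aligned <- toupper(reference_aligned)
  homologs <- toupper(homologs)
  widths <- nchar(homologs)
  if (length(homologs) && any(widths != nchar(reference_aligned)))
    stop("ragged alignment: homolog rows differ in length from the reference",
         call. = FALSE)
  if (!grepl("[A-Z]", reference_aligned))
    stop("reference row contains no residues", call. = FALSE)
  if (is.null(names(homologs)) && length(homologs))
    names(homologs) <- paste0("hom", seq_along(homologs))
  structure(list(reference_id = reference_id,
                 reference_aligned = reference_aligned,
                 homologs = homologs),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("Alignment set: reference '", x$reference_id, "' (",
      nchar(gsub("-", "", x$reference_aligned)), " residues, ",
      nchar(x$reference_aligned), " columns), ",
      length(x$homologs), " homolog(s)\n", sep = "")
  invisible(x)
}

#' @export
length.alignment_set <- function(x) length(x$homologs)

# strip a3m insertion states: lowercase letters are insertions relative to the
# reference profile and do not exist in reference coordinates; '.' is a gap
.a3m_normalize <- function(s) {
  s <- gsub("[a-z]", "", s)
  gsub("\\.", "-", s)
}

.read_fasta_lines <- function(lines) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records found", call. = FALSE)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  from <- hdr + 1L
  to <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (from[i] > to[i]) return("")
    paste(gsub("\\s", "", lines[from[i]:to[i]]), collapse = "")
  }, character(1L))
  stats::setNames(seqs, ids)
}

#' Parse a multiple sequence alignment
#'
#' Reads an alignment in A3M, CLUSTAL or aligned-FASTA format into an
#' [alignment_set]. For A3M, lowercase letters (insertions relative to the
#' reference profile) are removed and `.` is treated as a gap, so every
#' retained column maps to a reference alignment position. The first sequence
#' is taken as the reference unless `reference` names another record.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"a3m"`, `"clustal"`, `"fasta"` (aligned
#'   FASTA). `"auto"` uses the file extension (`.a3m`, `.aln`/`.clustal`,
#'   otherwise FASTA).
#' @param reference Optional identifier of the reference record.
#' @return An [alignment_set].
#' @export
parse_alignment <- function(path, format = c("auto", "a3m", "clustal", "fasta"),
                            reference = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub("^.*\\.", "", path))
    format <- switch(ext, a3m = "a3m", aln = "clustal", clustal = "clustal",
                     "fasta")
  }
  seqs <- switch(format,
    a3m = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[!grepl("^#", lines)]
      .a3m_normalize(.read_fasta_lines(lines))
    },
    clustal = {
      aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
      as.character(Biostrings::unmasked(aln))
    },
    fasta = {
      as.character(Biostrings::readAAStringSet(path))
    })
  if (!length(seqs)) stop("empty alignment file: ", path, call. = FALSE)
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment in '", path,
         "': rows differ in length after insertion removal", call. = FALSE)
  ref_i <- 1L
  if (!is.null(reference)) {
    ref_i <- match(reference, names(seqs))
    if (is.na(ref_i))
      stop("reference '", reference, "' not found in alignment", call. = FALSE)
  }
  alignment_set(names(seqs)[ref_i], seqs[[ref_i]], seqs[-ref_i])
}

#' Percent identity of a homolog to the reference
#'
#' Counts the columns where the homolog letter equals the reference letter
#' (both non-gap, case-insensitive) and divides by the full aligned length of
#' the reference, gap columns included.
#'
#' @param homolog_aligned,reference_aligned Equal-length aligned strings.
#' @return Identity in `[0, 1]`.
#' @examples
#' percent_identity("AG-R", "AG-R")  # 3 matches / 4 columns = 0.75
#' @export
percent_identity <- function(homolog_aligned, reference_aligned) {
  if (nchar(homolog_aligned) != nchar(reference_aligned))
    stop("aligned strings differ in length", call. = FALSE)
  h <- strsplit(toupper(homolog_aligned), "")[[1]]
  r <- strsplit(toupper(reference_aligned), "")[[1]]
  n <- sum(h == r & h != .GAP & r != .GAP)
  n / length(r)
}

#' Filter homologs by minimum identity to the reference
#'
#' Retains exactly the homologs whose [percent_identity()] to the reference is
#' at least `min_identity` (inclusive, per "at least 20% identity"); order is
#' preserved and the reference is untouched.
#'
#' @param a An [alignment_set].
#' @param min_identity Identity threshold in `[0, 1]` (default 0.20).
#' @return The filtered [alignment_set].
#' @export
filter_homologs <- function(a, min_identity = 0.20) {
  stopifnot(inherits(a, "alignment_set"))
  if (!length(a$homologs)) return(a)
  pid <- vapply(a$homologs, percent_identity, numeric(1L),
                reference_aligned = a$reference_aligned)
  a$homologs <- a$homologs[pid >= min_identity]
  a
}

#' Per-position conservation scores from an alignment
#'
#' For every reference residue (non-gap reference column, renumbered 1..L over
#' reference residues) counts the homologs whose letter matches the reference
#' letter (`n_match`) and the homologs with any non-gap letter (`n_nongap`),
#' and reports the conservation score `cs = n_match / n_nongap`. The reference
#' itself is excluded from both counts. All-gap columns yield a missing score
#' (absence of evidence, not zero). The alignment is assumed to be identity-
#' filtered already; this is not re-checked.
#'
#' @param a An [alignment_set].
#' @param include_reference Count the reference row itself in both totals
#'   (default `FALSE`).
#' @return A `conservation_track` data frame with columns `protein_id`,
#'   `position`, `wt_aa`, `cs`, `n_match`, `n_nongap`.
#' @export
conservation_scores <- function(a, include_reference = FALSE) {
  stopifnot(inherits(a, "alignment_set"))
  ref <- strsplit(a$reference_aligned, "")[[1]]
  keep <- ref != .GAP
  ref_res <- ref[keep]
  nh <- length(a$homologs)
  if (nh == 0L) {
    warning("alignment for '", a$reference_id,
            "' has no homologs; conservation scores are missing")
    n_match <- n_nongap <- integer(length(ref_res))
  } else {
    H <- do.call(rbind, strsplit(unname(a$homologs), ""))[, keep, drop = FALSE]
    n_match <- colSums(H == rep(ref_res, each = nh))
    n_nongap <- colSums(H != .GAP)
  }
  if (include_reference) {
    n_match <- n_match + 1L
    n_nongap <- n_nongap + 1L
  }
  cs <- ifelse(n_nongap > 0L, n_match / n_nongap, NA_real_)
  out <- data.frame(protein_id = a$reference_id,
                    position = seq_along(ref_res),
                    wt_aa = ref_res,
                    cs = cs,
                    n_match = as.integer(n_match),
                    n_nongap = as.integer(n_nongap),
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_track", "data.frame")
  out
}

#' Write / read a conservation track as TSV
#'
#' @param track A `conservation_track` from [conservation_scores()].
#' @param path File path.
#' @return `write_conservation` returns `path` invisibly; `read_conservation`
#'   the track data frame.
#' @export
write_conservation <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_conservation
#' @export
read_conservation <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("conservation_track", "data.frame")
  out
}
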