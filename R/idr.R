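# Disordered-region extraction, phase-separation classification and the
# dataset-construction filters. All intervals are 1-based and inclusive
# (UniProt convention), deliberately not BED half-open.

#' Extract disordered regions from a pLDDT track
#'
#' Maximal runs of residues with pLDDT at or below the disorder threshold.
#' There is no minimum run length; a single boundary residue at exactly the
#' threshold is a one-residue region.
#'
#' @param plddt Complete numeric per-residue pLDDT vector.
#' @param threshold Disorder threshold (default 70; disordered iff
#'   `plddt <= threshold`).
#' @param protein_id Optional identifier carried into the output.
#' @return Data frame with columns `protein_id`, `start`, `end`,
#'   `functional_class` (initialised `"unassigned"`), sorted and disjoint.
#' @examples
#' extract_idrs(c(90, 90, 60, 60, 90))
#' @export
extract_idrs <- function(plddt, threshold = 70, protein_id = NA_character_) {
  if (!length(plddt)) {
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), functional_class = character(),
                      stringsAsFactors = FALSE))
  }
  if (anyNA(plddt))
    stop("missing pLDDT value(s) at position(s) ",
         paste(utils::head(which(is.na(plddt)), 5L), collapse = ", "),
         call. = FALSE)
  iv <- .runs(which(plddt <= threshold))
  data.frame(protein_id = rep(protein_id, nrow(iv)),
             start = as.integer(iv[, 1L]), end = as.integer(iv[, 2L]),
             functional_class = rep("unassigned", nrow(iv)),
             stringsAsFactors = FALSE)
}

# overlap length of two 1-based inclusive intervals
.overlap_len <- function(a_start, a_end, b_start, b_end) {
  max(0L, min(a_end, b_end) - max(a_start, b_start) + 1L)
}

#' Classify a disordered region against phase-separation segments
#'
#' For each experimentally annotated phase-separation segment, the coverage is
#' the fraction of the segment's residues that fall inside the disordered
#' region. The region is `"driving"` when its maximum coverage exceeds 0.5
#' (it constitutes over half of some segment), `"participating"` when it
#' overlaps a segment but never beyond half (coverage exactly 0.5 is
#' participating), and `"non_participating"` when it overlaps no segment
#' (including when no segments exist for the protein).
#'
#' @param idr Either a `c(start, end)` pair or a one-row data frame with
#'   `start`/`end` columns (1-based inclusive).
#' @param segments Data frame of segments with `start`, `end` columns (rows
#'   may be zero).
#' @param driving_coverage Coverage above which a region is driving
#'   (default 0.5, strict).
#' @return One of `"driving"`, `"participating"`, `"non_participating"`.
#' @examples
#' classify_idr(c(90, 160), data.frame(start = 100, end = 200))  # driving
#' @export
classify_idr <- function(idr, segments, driving_coverage = 0.5) {
  if (is.data.frame(idr)) idr <- c(idr$start[1L], idr$end[1L])
  if (is.null(segments) || nrow(segments) == 0L) return("non_participating")
  cov <- vapply(seq_len(nrow(segments)), function(k) {
    seg_len <- segments$end[k] - segments$start[k] + 1L
    .overlap_len(idr[1L], idr[2L], segments$start[k], segments$end[k]) / seg_len
  }, numeric(1L))
  m <- max(cov)
  if (m > driving_coverage) "driving"
  else if (m > 0) "participating"
  else "non_participating"
}

#' Classify every disordered region of a protein
#'
#' @param idrs Data frame from [extract_idrs()].
#' @param segments Phase-separation segments for the same protein.
#' @param driving_coverage Passed to [classify_idr()].
#' @return `idrs` with `functional_class` filled in.
#' @export
classify_idrs <- function(idrs, segments, driving_coverage = 0.5) {
  if (nrow(idrs))
    idrs$functional_class <- vapply(seq_len(nrow(idrs)), function(k)
      classify_idr(c(idrs$start[k], idrs$end[k]), segments, driving_coverage),
      character(1L))
  idrs
}

#' Disorder-fraction dataset filter
#'
#' A protein passes when at least `min_fraction` of its residues are
#' disordered (pLDDT at or below the threshold); the comparison is inclusive.
#'
#' @param plddt Complete per-residue pLDDT vector.
#' @param min_fraction Minimum disordered fraction (default 0.10).
#' @param threshold Disorder threshold (default 70).
#' @return `TRUE` or `FALSE`.
#' @export
disorder_fraction_filter <- function(plddt, min_fraction = 0.10,
                                     threshold = 70) {
  if (!length(plddt)) stop("empty pLDDT track", call. = FALSE)
  if (anyNA(plddt)) stop("missing pLDDT values", call. = FALSE)
  mean(plddt <= threshold) >= min_fraction
}

# identity of a global alignment: unit match, zero mismatch, linear gap cost 1;
# identity = matches / alignment length (PID1)
.pairwise_identity <- function(seq_a, seq_b) {
  submat <- diag(1, 20L)
  dimnames(submat) <- list(AA_ALPHABET, AA_ALPHABET)
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = submat,
                                       gapOpening = 0, gapExtension = 1)
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Greedy sequence-redundancy filter
#'
#' One pass over the proteins in input order: a protein is retained unless its
#' pairwise identity with an already-retained protein exceeds `max_identity`.
#' Identity is matches over the alignment length of a global alignment with
#' unit match score, zero mismatch score and a linear gap cost of 1.
#'
#' @param ids Character vector of protein identifiers.
#' @param sequences Character vector of sequences, parallel to `ids`.
#' @param max_identity Redundancy threshold (default 0.50, strict: identity
#'   must exceed it for removal).
#' @return Character vector of retained identifiers, in input order.
#' @export
redundancy_filter <- function(ids, sequences, max_identity = 0.50) {
  stopifnot(length(ids) == length(sequences), length(ids) >= 1L)
  kept <- 1L
  for (k in seq_along(ids)[-1L]) {
    redundant <- any(vapply(kept, function(j)
      .pairwise_identity(sequences[k], sequences[j]) > max_identity,
      logical(1L)))
    if (!redundant) kept <- c(kept, k)
  }
  ids[kept]
}

#' Read / write phase-separation segment tables
#'
#' TSV with columns `protein_id`, `start`, `end`, `note`; coordinates 1-based
#' inclusive.
#'
#' @param path File path.
#' @param segments Data frame of segments.
#' @return `read_ps_segments` returns the data frame; `write_ps_segments`
#'   returns `path` invisibly.
#' @export
read_ps_segments <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("protein_id", "start", "end"), names(tab))
  if (length(miss))
    stop("PS segment table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tab$start > tab$end))
    stop("PS segment with start > end", call. = FALSE)
  if (is.null(tab$note)) tab$note <- ""
  tab[, c("protein_id", "start", "end", "note")]
}

#' @rdname read_ps_segments
#' @export
write_ps_segments <- function(segments, path) {
  if (is.null(segments$note)) segments$note <- ""
  utils::write.table(segments[, c("protein_id", "start", "end", "note")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write classified disordered regions as TSV
#'
#' @param idrs Data frame from [classify_idrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_idrs <- function(idrs, path) {
  utils::write.table(idrs[, c("protein_id", "start", "end", "functional_class")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
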