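# Bidirectional greedy identification of low-entropy (conserved) motifs.

# Running-mean comparisons against the threshold carry a small absolute guard:
# sums like 0.4 + 0.3 + 0.4 + 0.9 give 2.0 + 2e-16 in floating point and a
# true mean of exactly 0.5 must not register as a breach.
.MEAN_TOL <- 1e-9

# mean of scores[i:j] > thr (breach), tolerance-guarded
.breaches <- function(total, len, thr) total - thr * len > .MEAN_TOL * len

#' Directional greedy scan for low-score segments
#'
#' One pass of the motif search from a chosen terminus. Starting at the given
#' end, the scan locates the next anchor residue whose score is at or below
#' `threshold`, then appends residues toward the opposite terminus while the
#' running segment mean stays at or below the threshold. On the first breach
#' at residue j, the segment up to j-1 is emitted and the search resumes at j;
#' a segment that reaches the terminus without breaching is emitted open.
#'
#' @param scores Numeric vector of per-residue scores (finite).
#' @param threshold Segment-mean threshold (default 0.5).
#' @param direction `"forward"` (N- to C-terminus) or `"backward"`.
#' @return List of integer vectors, each a contiguous run of 1-based
#'   positions, in scan order.
#' @examples
#' scan_directional(c(0.9, 0.4, 0.3, 0.4, 0.9, 0.9), 0.5, "forward")
#' @export
scan_directional <- function(scores, threshold = 0.5,
                             direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (!length(scores)) return(list())
  if (!is.numeric(scores) || !all(is.finite(scores)))
    stop("scores must be finite numeric values", call. = FALSE)
  L <- length(scores)
  s <- if (direction == "forward") scores else rev(scores)
  segs <- list()
  i <- 1L
  while (i <= L) {
    if (s[i] > threshold + .MEAN_TOL) { i <- i + 1L; next }
    total <- s[i]
    j <- i + 1L
    while (j <= L && !.breaches(total + s[j], j - i + 1L, threshold)) {
      total <- total + s[j]
      j <- j + 1L
    }
    segs[[length(segs) + 1L]] <- i:(j - 1L)
    i <- j  # resume at the breaching residue (or past the end)
  }
  if (direction == "backward")
    segs <- lapply(segs, function(x) sort(L + 1L - x))
  segs
}

# contiguous runs of a sorted integer vector -> 2-column matrix (start, end)
.runs <- function(pos) {
  if (!length(pos)) return(matrix(integer(), ncol = 2L,
                                  dimnames = list(NULL, c("start", "end"))))
  brk <- which(diff(pos) != 1L)
  cbind(start = pos[c(1L, brk + 1L)], end = pos[c(brk, length(pos))])
}

#' Intersect forward and backward candidate segments
#'
#' Takes the residue-level intersection of the union of forward-scan positions
#' with the union of backward-scan positions, re-extracts contiguous runs, and
#' drops runs whose mean score exceeds the threshold (a subsegment of a
#' below-threshold segment carries no mean guarantee), so every reported
#' interval honours the motif definition.
#'
#' @param fwd,bwd Lists of integer position vectors from [scan_directional()].
#' @param scores The score vector the scans were run on.
#' @param threshold Segment-mean threshold (default 0.5).
#' @return Integer matrix with columns `start`, `end` (1-based inclusive),
#'   disjoint and sorted.
#' @export
intersect_candidates <- function(fwd, bwd, scores, threshold = 0.5) {
  common <- sort(intersect(unlist(fwd), unlist(bwd)))
  iv <- .runs(common)
  if (!nrow(iv)) return(iv)
  keep <- vapply(seq_len(nrow(iv)), function(k) {
    len <- iv[k, 2L] - iv[k, 1L] + 1L
    !.breaches(sum(scores[iv[k, 1L]:iv[k, 2L]]), len, threshold)
  }, logical(1L))
  iv[keep, , drop = FALSE]
}

#' Merge motifs in close sequence proximity
#'
#' Two adjacent motifs are mergeable when the later one starts within `gap`
#' residues of the earlier one's end and the mean score over the spanning
#' segment (both motifs plus intervening residues) is strictly below the
#' threshold; the pair is then replaced by the span. Among all currently
#' mergeable adjacent pairs, the pair with the smallest spanning mean is
#' merged first, and merging repeats until no pair qualifies (a merged
#' interval may merge again with its neighbours). This best-first order is
#' independent of the end of the sequence the motifs were scanned from, so
#' the result mirrors correctly under sequence reversal.
#'
#' @param motifs Integer matrix with columns `start`, `end`, disjoint, sorted.
#' @param scores Score vector.
#' @param gap Maximum separation `start(B) - end(A)` for a merge attempt
#'   (default 8).
#' @param threshold Span-mean threshold (default 0.5, strict).
#' @return Interval matrix of the same shape.
#' @export
merge_motifs <- function(motifs, scores, gap = 8L, threshold = 0.5) {
  if (!nrow(motifs)) return(motifs)
  if (is.unsorted(motifs[, 1L]) ||
      any(motifs[-1L, 1L] <= motifs[-nrow(motifs), 2L]))
    stop("motif intervals must be disjoint and sorted", call. = FALSE)
  out <- motifs
  span_mean <- function(a, b)  # mean over [start(A), end(B)]
    mean(scores[out[a, 1L]:out[b, 2L]])
  repeat {
    if (nrow(out) < 2L) break
    k <- seq_len(nrow(out) - 1L)
    ok <- out[k + 1L, 1L] - out[k, 2L] <= gap
    means <- rep(NA_real_, length(k))
    means[ok] <- vapply(k[ok], function(a) span_mean(a, a + 1L), numeric(1L))
    lens <- out[k + 1L, 2L] - out[k, 1L] + 1L
    ok <- ok & !is.na(means) &
      (means - threshold) * lens < -.MEAN_TOL * lens
    if (!any(ok)) break
    best <- which(ok)[which.min(means[ok])]
    out[best, 2L] <- out[best + 1L, 2L]
    out <- out[-(best + 1L), , drop = FALSE]
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Identify conserved motifs in a score track
#'
#' Full motif search: forward and backward greedy scans, residue-level
#' intersection of the two candidate sets, proximity merging, and a minimum
#' length filter. Motifs are contiguous residue stretches whose average score
#' is at or below the threshold; the bidirectional intersection trims terminal
#' residues that satisfy the running-mean criterion only by riding on an
#' adjacent low-scoring core.
#'
#' @param x A `residue_track` from [score_protein()] or a bare numeric score
#'   vector.
#' @param threshold Mean-score threshold defining a motif (default 0.5).
#' @param gap Proximity-merge gap in residues (default 8).
#' @param min_len Minimum reported motif length (default 4).
#' @param region Optional `c(start, end)` interval (1-based inclusive)
#'   restricting the scan, e.g. to one disordered region.
#' @return A `motif_set` data frame with columns `protein_id`, `start`, `end`,
#'   `length`, `sequence`, `mean_esm2`, `sticker_fraction`; motifs disjoint
#'   and sorted.
#' @examples
#' find_motifs(c(0.9, 0.4, 0.3, 0.4, 0.9, 0.9), min_len = 1)
#' @export
find_motifs <- function(x, threshold = 0.5, gap = 8L, min_len = 4L,
                        region = NULL) {
  if (inherits(x, "residue_track") || is.data.frame(x)) {
    scores <- x$esm2_score
    aa <- x$wt_aa
    pid <- x$protein_id[1L]
  } else {
    scores <- x
    aa <- NULL
    pid <- NA_character_
  }
  L <- length(scores)
  offset <- 0L
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2L || region[1L] < 1L || region[2L] > L ||
        region[1L] > region[2L])
      stop("region [", region[1L], ", ", region[2L],
           "] is out of bounds for a track of length ", L, call. = FALSE)
    offset <- region[1L] - 1L
    scores_scan <- scores[region[1L]:region[2L]]
  } else {
    scores_scan <- scores
  }
  iv <- matrix(integer(), ncol = 2L)
  if (length(scores_scan)) {
    fwd <- scan_directional(scores_scan, threshold, "forward")
    bwd <- scan_directional(scores_scan, threshold, "backward")
    iv <- intersect_candidates(fwd, bwd, scores_scan, threshold)
    if (nrow(iv)) iv <- merge_motifs(iv, scores_scan, gap, threshold)
    if (nrow(iv)) iv <- iv[iv[, 2L] - iv[, 1L] + 1L >= min_len, , drop = FALSE]
  }
  res <- data.frame(protein_id = rep(pid, nrow(iv)),
                    start = iv[, 1L] + offset,
                    end = iv[, 2L] + offset,
                    stringsAsFactors = FALSE)
  res$length <- res$end - res$start + 1L
  res$sequence <- if (is.null(aa)) rep(NA_character_, nrow(res)) else
    vapply(seq_len(nrow(res)), function(k)
      paste(aa[res$start[k]:res$end[k]], collapse = ""), character(1L))
  res$mean_esm2 <- vapply(seq_len(nrow(res)), function(k)
    mean(scores[res$start[k]:res$end[k]]), numeric(1L))
  res$sticker_fraction <- ifelse(is.na(res$sequence), NA_real_,
                                 vapply(res$sequence, function(s)
                                   if (is.na(s)) NA_real_ else sticker_fraction(s),
                                   numeric(1L), USE.NAMES = FALSE))
  class(res) <- c("motif_set", "data.frame")
  res
}

#' Fraction of conserved residues covered by motifs, per amino acid
#'
#' For each amino-acid letter, among the residues of that letter with score at
#' or below `conserved_max`, the fraction lying inside any motif interval.
#' Letters with no conserved residues get a missing value (absence of
#' evidence), not 0.
#'
#' @param track A `residue_track`.
#' @param motifs A `motif_set` produced from the same track.
#' @param conserved_max Conserved-class score bound (default 0.5).
#' @return Data frame with columns `wt_aa`, `n_conserved`, `n_in_motif`,
#'   `fraction`, one row per letter of [AA_ALPHABET].
#' @export
motif_membership <- function(track, motifs, conserved_max = 0.5) {
  in_motif <- rep(FALSE, nrow(track))
  if (nrow(motifs)) {
    same <- is.na(motifs$protein_id[1L]) |
      motifs$protein_id == track$protein_id[1L]
    for (k in which(same))
      in_motif[track$position >= motifs$start[k] &
               track$position <= motifs$end[k]] <- TRUE
  }
  cons <- track$esm2_score <= conserved_max
  out <- do.call(rbind, lapply(AA_ALPHABET, function(a) {
    sel <- cons & track$wt_aa == a
    n <- sum(sel)
    data.frame(wt_aa = a, n_conserved = n, n_in_motif = sum(sel & in_motif),
               fraction = if (n > 0L) sum(sel & in_motif) / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Sticker fraction of a motif sequence
#'
#' Proportion of sticker residues (Y, F, W, R, K, Q) in a sequence.
#'
#' @param motif_sequence Nonempty amino-acid string.
#' @return Fraction in `[0, 1]`.
#' @examples
#' sticker_fraction("GYG")  # 1/3
#' @export
sticker_fraction <- function(motif_sequence) {
  if (!is.character(motif_sequence) || length(motif_sequence) != 1L ||
      !nzchar(motif_sequence))
    stop("motif sequence must be a nonempty string", call. = FALSE)
  aa <- strsplit(toupper(motif_sequence), "")[[1]]
  mean(aa %in% STICKER_RESIDUES)
}

#' Write a motif set as CSV
#'
#' @param motifs A `motif_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  utils::write.csv(as.data.frame(motifs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
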