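# Group-level statistics: Mann-Whitney comparisons with significance tiers,
# class fractions, phase-separation localization probability, per-amino-acid
# LLR profiles, tolerance/conservation correlation and profile clustering.

#' Significance tier of a p-value
#'
#' Strict thresholds: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `†` (marginal) p < 0.10, `n.s.` p >= 0.10.
#'
#' @param p P-value in `[0, 1]`.
#' @return Tier label string.
#' @export
significance_tier <- function(p) {
  stopifnot(is.finite(p), p >= 0, p <= 1)
  if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else if (p < 0.10) "†"
  else "n.s."
}

# U statistic of group a vs b (rank-sum form, ties by midranks)
.mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact two-sided p by full enumeration of group-label assignments; valid
# with ties (U computed on midranks of the pooled sample either way)
.mw_exact_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  mu <- na * nb / 2
  obs_dev <- abs(.mw_u(a, b) - mu)
  idx <- utils::combn(na + nb, na)
  devs <- apply(idx, 2L, function(sel)
    abs(.mw_u(pooled[sel], pooled[-sel]) - mu))
  mean(devs >= obs_dev - 1e-12)
}

#' Two-sided Mann-Whitney U comparison with significance tier
#'
#' Rank-sum test of the null hypothesis that the two groups have equal
#' medians. When the combined sample size is at most `exact_limit`, the
#' two-sided p-value is computed exactly by enumerating all group-label
#' assignments (valid in the presence of ties); otherwise the tie-corrected
#' normal approximation of [stats::wilcox.test()] (with continuity
#' correction) is used. The reported tier follows [significance_tier()].
#'
#' @param a,b Numeric samples (nonempty).
#' @param group_a,group_b Labels carried into the result.
#' @param exact_limit Combined-size cutoff for exact enumeration (default 12).
#' @return An object of class `group_comparison`: list with `group_a`,
#'   `group_b`, `n_a`, `n_b`, `u_statistic`, `p_value`, `significance`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, group_a = "a", group_b = "b",
                         exact_limit = 12L) {
  if (!length(a) || !length(b))
    stop("both groups must be nonempty", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite", call. = FALSE)
  u <- .mw_u(a, b)
  p <- if (length(a) + length(b) <= exact_limit) {
    .mw_exact_p(a, b)
  } else {
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)$p.value
  }
  p <- min(1, p)
  structure(list(group_a = group_a, group_b = group_b,
                 n_a = length(a), n_b = length(b),
                 u_statistic = u, p_value = p,
                 significance = significance_tier(p)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: %s (n=%d) vs %s (n=%d), U = %g, p = %.4g [%s]\n",
              x$group_a, x$n_a, x$group_b, x$n_b,
              x$u_statistic, x$p_value, x$significance))
  invisible(x)
}

#' Fraction of residues in a tolerance class
#'
#' Among residues passing the structural-order filter, the fraction carrying
#' the requested tolerance class. Returns `NA` when no residue passes the
#' filter.
#'
#' @param track A `residue_track` (or row-bound set of tracks).
#' @param tolerance_class `"conserved"`, `"intermediate"` or `"flexible"`.
#' @param order_filter Optional `"ordered"` or `"disordered"`; `NULL` keeps
#'   all residues.
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
fraction_by_class <- function(track, tolerance_class,
                              order_filter = NULL) {
  sel <- rep(TRUE, nrow(track))
  if (!is.null(order_filter)) {
    if (anyNA(track$order_class))
      stop("track has residues without order class; ",
           "provide pLDDT before order-filtered statistics", call. = FALSE)
    sel <- track$order_class == order_filter
  }
  if (!any(sel)) return(NA_real_)
  mean(track$tolerance_class[sel] == tolerance_class)
}

#' Probability of conserved residues lying in phase-separating regions
#'
#' For one protein: the fraction of its conserved residues (score at or below
#' `conserved_max`) that fall inside disordered regions classified as driving
#' or participating. The complement `1 - p` is the probability of conserved
#' residues lying outside phase-separating regions.
#'
#' @param track The protein's `residue_track`.
#' @param idrs Classified disordered regions for the same protein
#'   ([classify_idrs()]).
#' @param conserved_max Conserved-class bound (default 0.5).
#' @return `p` in `[0, 1]`, or `NA` when the protein has no conserved
#'   residues.
#' @export
ps_localization_probability <- function(track, idrs, conserved_max = 0.5) {
  cons <- track$esm2_score <= conserved_max
  if (!any(cons)) return(NA_real_)
  ps <- idrs[idrs$functional_class %in% c("driving", "participating"), ,
             drop = FALSE]
  inside <- rep(FALSE, nrow(track))
  for (k in seq_len(nrow(ps)))
    inside[track$position >= ps$start[k] & track$position <= ps$end[k]] <- TRUE
  sum(cons & inside) / sum(cons)
}

#' Per-amino-acid mean LLR profiles
#'
#' For each amino-acid letter, averages the 20-element LLR vectors of all
#' contributing residues element-wise and records the mean entropy score,
#' mean conservation score and residue count. The residue population is
#' selected by `residue_filter` (e.g. restrict to driving-IDR residues).
#'
#' @param tracks A `residue_track` or list of them.
#' @param matrices An [llr_matrix] or list of them, named or carrying matching
#'   `protein_id`s.
#' @param conservation Optional `conservation_track` or list of them.
#' @param residue_filter Optional function taking one track and returning a
#'   logical vector selecting residues; default keeps all.
#' @return An `aa_profile_set` data frame: one row per letter with columns
#'   `wt_aa`, `llr.A` .. `llr.Y`, `mean_esm2`, `mean_cs`, `n_residues`,
#'   `cluster` (`NA` until [cluster_aa_profiles()]). Letters with no
#'   contributing residues have `n_residues` 0 and missing means.
#' @export
aa_profiles <- function(tracks, matrices, conservation = NULL,
                        residue_filter = NULL) {
  if (inherits(tracks, "residue_track")) tracks <- list(tracks)
  if (inherits(matrices, "llr_matrix")) matrices <- list(matrices)
  names(matrices) <- vapply(matrices, `[[`, character(1L), "protein_id")
  if (!is.null(conservation) && inherits(conservation, "conservation_track"))
    conservation <- list(conservation)
  cons_ids <- if (is.null(conservation)) character() else
    vapply(conservation, function(x) x$protein_id[1L], character(1L))
  parts <- lapply(tracks, function(tr) {
    pid <- tr$protein_id[1L]
    m <- matrices[[pid]]
    if (is.null(m))
      stop("no LLR matrix for protein '", pid, "'", call. = FALSE)
    keep <- if (is.null(residue_filter)) rep(TRUE, nrow(tr)) else
      residue_filter(tr)
    cs <- rep(NA_real_, nrow(tr))
    ci <- match(pid, cons_ids)
    if (!is.na(ci))
      cs[conservation[[ci]]$position] <- conservation[[ci]]$cs
    list(aa = tr$wt_aa[keep], llr = m$llr[tr$position[keep], , drop = FALSE],
         esm2 = tr$esm2_score[keep], cs = cs[keep])
  })
  aa <- unlist(lapply(parts, `[[`, "aa"))
  llr <- do.call(rbind, lapply(parts, `[[`, "llr"))
  esm2 <- unlist(lapply(parts, `[[`, "esm2"))
  cs <- unlist(lapply(parts, `[[`, "cs"))
  out <- do.call(rbind, lapply(AA_ALPHABET, function(letter) {
    sel <- aa == letter
    n <- sum(sel)
    prof <- if (n > 0L) colMeans(llr[sel, , drop = FALSE]) else
      rep(NA_real_, 20L)
    row <- data.frame(wt_aa = letter, stringsAsFactors = FALSE)
    row[paste0("llr.", AA_ALPHABET)] <- as.list(prof)
    row$mean_esm2 <- if (n > 0L) mean(esm2[sel]) else NA_real_
    row$mean_cs <- if (n > 0L && any(!is.na(cs[sel])))
      mean(cs[sel], na.rm = TRUE) else NA_real_
    row$n_residues <- n
    row$cluster <- NA_integer_
    row
  }))
  class(out) <- c("aa_profile_set", "data.frame")
  out
}

#' Correlation between mean tolerance and mean conservation across amino acids
#'
#' Pearson correlation of `(mean_esm2, mean_cs)` over the amino-acid letters,
#' excluding letters listed in `exclude` (methionine by default: its frequent
#' initiator position confounds mutational-effect prediction) and letters with
#' no contributing residues.
#'
#' @param profiles An `aa_profile_set` from [aa_profiles()].
#' @param exclude Letters to exclude (default `"M"`).
#' @return Pearson `r`.
#' @export
esm2_cs_correlation <- function(profiles, exclude = "M") {
  sel <- !(profiles$wt_aa %in% exclude) & profiles$n_residues > 0L &
    is.finite(profiles$mean_esm2) & is.finite(profiles$mean_cs)
  x <- profiles$mean_esm2[sel]
  y <- profiles$mean_cs[sel]
  if (length(x) < 3L)
    stop("need at least 3 amino-acid letters with defined means, have ",
         length(x), call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in the profile means",
         call. = FALSE)
  stats::cor(x, y)
}

#' Cluster amino acids by their mean LLR profiles
#'
#' Embeds the 20 per-letter mean LLR vectors into two dimensions and applies
#' average-linkage hierarchical clustering, cutting the tree at `n_clusters`.
#' The default embedding is the first two principal components (deterministic);
#' any function mapping a 20 x 20 matrix to a 20 x 2 matrix may be plugged in
#' (e.g. a nonlinear neighbour-graph embedding with a fixed seed). Cluster
#' labels are ordered by ascending cluster-mean entropy score, so group 1 is
#' the most mutation-constrained.
#'
#' @param profiles An `aa_profile_set` with all 20 letters populated.
#' @param n_clusters Number of clusters (default 5).
#' @param embed_fn Optional embedding function (matrix in, `n x 2` matrix
#'   out).
#' @return `profiles` with the `cluster` column filled (integer 1..k) and an
#'   attribute `"embedding"` holding the 2-D coordinates.
#' @export
cluster_aa_profiles <- function(profiles, n_clusters = 5L, embed_fn = NULL) {
  missing_aa <- profiles$wt_aa[profiles$n_residues == 0L |
                                 !is.finite(profiles$mean_esm2)]
  if (length(missing_aa))
    stop("cannot cluster: no residues for letter(s) ",
         paste(missing_aa, collapse = ", "), call. = FALSE)
  X <- as.matrix(profiles[, paste0("llr.", AA_ALPHABET)])
  rownames(X) <- profiles$wt_aa
  emb <- if (is.null(embed_fn)) {
    stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  } else {
    embed_fn(X)
  }
  if (n_clusters == 1L) {
    raw <- rep(1L, nrow(X))
  } else if (n_clusters >= nrow(X)) {
    raw <- seq_len(nrow(X))
  } else {
    hc <- stats::hclust(stats::dist(emb), method = "average")
    raw <- stats::cutree(hc, k = n_clusters)
  }
  # relabel so that cluster 1 has the lowest (most conserved) mean score
  means <- tapply(profiles$mean_esm2, raw, mean)
  remap <- stats::setNames(rank(means, ties.method = "first"), names(means))
  profiles$cluster <- as.integer(remap[as.character(raw)])
  attr(profiles, "embedding") <- emb
  profiles
}

#' Write group comparisons / amino-acid profiles
#'
#' @param comparisons List of `group_comparison` objects or a data frame.
#' @param profiles An `aa_profile_set`.
#' @param path Output path (TSV for comparisons, CSV for profiles).
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(comparisons, path) {
  if (!is.data.frame(comparisons))
    comparisons <- do.call(rbind, lapply(comparisons, function(x)
      data.frame(group_a = x$group_a, group_b = x$group_b,
                 n_a = x$n_a, n_b = x$n_b, U = x$u_statistic,
                 p = x$p_value, tier = x$significance,
                 stringsAsFactors = FALSE)))
  utils::write.table(comparisons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_comparisons
#' @export
write_aa_profiles <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
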