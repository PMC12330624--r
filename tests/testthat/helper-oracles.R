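# Independent oracles used across test files. Each is written directly from
# the published definition, separately from the package implementation.

# two-pass entropy of the softmax of the 20 LLR entries, no max-shift
oracle_entropy <- function(llr) {
  z <- sum(exp(llr))
  p <- exp(llr) / z
  -sum(p * log(p))
}

# per-column conservation counting loop
oracle_conservation <- function(ref_aligned, homologs) {
  ref <- strsplit(ref_aligned, "")[[1]]
  hs <- strsplit(homologs, "")
  res <- NULL
  pos <- 0L
  for (col in seq_along(ref)) {
    if (ref[col] == "-") next
    pos <- pos + 1L
    n_match <- 0L
    n_nongap <- 0L
    for (h in hs) {
      if (h[col] != "-") {
        n_nongap <- n_nongap + 1L
        if (h[col] == ref[col]) n_match <- n_match + 1L
      }
    }
    res <- rbind(res, data.frame(
      position = pos, wt_aa = ref[col],
      cs = if (n_nongap > 0) n_match / n_nongap else NA_real_,
      n_match = n_match, n_nongap = n_nongap))
  }
  res
}

# greedy directional scan written from the procedure prose: anchor at the
# next residue at or below the threshold, append residues until the segment
# mean exceeds it, record, restart at the breaching residue
oracle_scan <- function(scores, thr) {
  segs <- list()
  i <- 1L
  L <- length(scores)
  while (i <= L) {
    if (scores[i] <= thr + 1e-9) {
      seg <- i
      j <- i + 1L
      while (j <= L && mean(scores[c(seg, j)]) <= thr + 1e-9) {
        seg <- c(seg, j)
        j <- j + 1L
      }
      segs[[length(segs) + 1L]] <- seg
      i <- j
    } else {
      i <- i + 1L
    }
  }
  segs
}

# exact two-sided Mann-Whitney p by bitmask enumeration of label assignments
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  mu <- na * length(b) / 2
  obs <- abs(u_of(a, b) - mu)
  devs <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) != na) next
    devs <- c(devs, abs(u_of(pooled[sel], pooled[-sel]) - mu))
  }
  mean(devs >= obs - 1e-12)
}

# residue-level Jaccard similarity between two interval sets
jaccard_intervals <- function(a, b) {
  pos_a <- if (is.null(a) || nrow(a) == 0) integer() else
    unlist(lapply(seq_len(nrow(a)), function(k) a[k, 1]:a[k, 2]))
  pos_b <- if (is.null(b) || nrow(b) == 0) integer() else
    unlist(lapply(seq_len(nrow(b)), function(k) b[k, 1]:b[k, 2]))
  if (!length(pos_a) && !length(pos_b)) return(1)
  length(intersect(pos_a, pos_b)) / length(union(pos_a, pos_b))
}

# small aa_profile_set builder for statistics tests
make_profiles <- function(mean_esm2, mean_cs = NULL, llr = NULL, n = 1L) {
  out <- data.frame(wt_aa = AA_ALPHABET, stringsAsFactors = FALSE)
  if (is.null(llr)) llr <- matrix(0, 20, 20)
  colnames(llr) <- paste0("llr.", AA_ALPHABET)
  out <- cbind(out, as.data.frame(llr))
  out$mean_esm2 <- mean_esm2
  out$mean_cs <- if (is.null(mean_cs)) NA_real_ else mean_cs
  out$n_residues <- rep(n, length.out = 20L)
  out$cluster <- NA_integer_
  class(out) <- c("aa_profile_set", "data.frame")
  out
}
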