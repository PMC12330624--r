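# Bidirectional greedy motif identification.

test_that("directional scans reproduce the hand-traced example", {
  s <- c(0.9, 0.4, 0.3, 0.4, 0.9, 0.9)
  # forward: anchor at 2, means 0.4, 0.35, 0.3667, 0.5 (not a breach),
  # then 0.58 breaches when residue 6 joins
  expect_equal(scan_directional(s, 0.5, "forward"), list(2:5))
  # backward: anchor at 4, extension reaches the N-terminus at mean 0.5
  expect_equal(scan_directional(s, 0.5, "backward"), list(1:4))
  expect_equal(scan_directional(rep(0.9, 6), 0.5, "forward"), list())
  expect_equal(scan_directional(numeric(0), 0.5, "forward"), list())
  expect_error(scan_directional(c(0.1, NA), 0.5, "forward"), "finite")
})

test_that("candidate intersection keeps the shared core", {
  s <- c(0.9, 0.4, 0.3, 0.4, 0.9, 0.9)
  iv <- intersect_candidates(list(2:5), list(1:4), s)
  expect_equal(unname(iv), matrix(c(2L, 4L), 1))

  iv2 <- intersect_candidates(list(1:6), list(1:6), rep(0.1, 6))
  expect_equal(unname(iv2), matrix(c(1L, 6L), 1))

  expect_equal(nrow(intersect_candidates(list(1:2), list(5:6), rep(0.1, 6))),
               0L)
})

test_that("proximity merging follows the spanning-mean rule", {
  s <- c(0, 0, 2, 0, 0)
  pre <- rbind(c(1L, 2L), c(4L, 5L))
  # gap 4 - 2 = 2 <= 8 and span mean 2/5 = 0.4 < 0.5: merge
  expect_equal(unname(merge_motifs(pre, s)), matrix(c(1L, 5L), 1))

  s2 <- c(0.1, 0.1, 0.1, 2.9, 2.9, 0.1, 0.1, 0.1)
  pre2 <- rbind(c(1L, 3L), c(6L, 8L))
  # gap 3 <= 8 but span mean 6.7/8 = 0.8375: no merge
  expect_equal(unname(merge_motifs(pre2, s2)), unname(pre2))

  single <- rbind(c(2L, 4L))
  expect_equal(unname(merge_motifs(single, rep(0.1, 5))), unname(single))

  expect_error(merge_motifs(rbind(c(1L, 4L), c(3L, 6L)), rep(0.1, 6)),
               "disjoint")
})

test_that("find_motifs composes scan, intersection, merge and length filter", {
  s <- c(0.9, 0.4, 0.3, 0.4, 0.9, 0.9)
  m <- find_motifs(s, min_len = 1)
  expect_equal(m$start, 2L)
  expect_equal(m$end, 4L)
  expect_equal(m$mean_esm2, mean(c(0.4, 0.3, 0.4)), tolerance = 1e-12)
  expect_equal(nrow(find_motifs(s, min_len = 4)), 0L)

  m2 <- find_motifs(rep(0.1, 6))
  expect_equal(c(m2$start, m2$end), c(1L, 6L))

  # the spike-merge trace, end to end
  m3 <- find_motifs(c(0, 0, 2, 0, 0), min_len = 1)
  expect_equal(c(m3$start, m3$end), c(1L, 5L))
})

test_that("region-restricted scans stay inside the region and map back", {
  s <- c(0.1, 0.1, 0.9, 0.1, 0.1, 0.1, 0.9)
  m <- find_motifs(s, min_len = 1, region = c(4, 7))
  expect_equal(c(m$start, m$end), c(4L, 6L))
  expect_error(find_motifs(s, region = c(5, 9)), "out of bounds")
})

test_that("every reported motif honours the definition", {
  set.seed(31)
  for (i in 1:200) {
    L <- sample(5:50, 1)
    s <- stats::runif(L, 0, 1)
    m <- find_motifs(s, min_len = 1)
    if (!nrow(m)) next
    expect_true(all(m$mean_esm2 <= 0.5 + 1e-9))
    expect_true(all(m$length >= 1))
    expect_true(!is.unsorted(m$start))
    if (nrow(m) > 1) expect_true(all(m$start[-1] > m$end[-nrow(m)]))
    expect_true(all(m$start >= 1 & m$end <= L))
  }
})

test_that("anchors of directional candidates score at or below the threshold", {
  set.seed(32)
  for (i in 1:200) {
    s <- stats::runif(sample(5:50, 1), 0, 1)
    fwd <- scan_directional(s, 0.5, "forward")
    bwd <- scan_directional(s, 0.5, "backward")
    for (seg in fwd) expect_lte(s[seg[1]], 0.5 + 1e-9)
    for (seg in bwd) expect_lte(s[seg[length(seg)]], 0.5 + 1e-9)
  }
})

test_that("reversing the sequence mirrors the motif set", {
  set.seed(33)
  for (i in 1:1000) {
    L <- sample(2:50, 1)
    s <- stats::runif(L, 0, 1)
    m <- find_motifs(s, min_len = 1)
    mr <- find_motifs(rev(s), min_len = 1)
    mirrored <- data.frame(start = L + 1L - mr$end, end = L + 1L - mr$start)
    mirrored <- mirrored[order(mirrored$start), , drop = FALSE]
    expect_equal(m$start, mirrored$start)
    expect_equal(m$end, mirrored$end)
  }
})

test_that("the directional scan agrees with a naive prose implementation", {
  set.seed(34)
  for (i in 1:1000) {
    L <- sample(1:50, 1)
    s <- stats::runif(L, 0, 1)
    expect_identical(scan_directional(s, 0.5, "forward"), oracle_scan(s, 0.5))
    got_bwd <- scan_directional(s, 0.5, "backward")
    want_bwd <- lapply(oracle_scan(rev(s), 0.5), function(seg)
      sort(L + 1L - seg))
    expect_identical(got_bwd[order(vapply(got_bwd, min, 1L))],
                     want_bwd[order(vapply(want_bwd, min, 1L))])
  }
})

test_that("find_motifs is a fixed point on its own output pattern", {
  # outside value 50 makes any non-motif residue breach every running mean
  # at these lengths, so the reported pattern must reproduce itself exactly
  set.seed(35)
  for (i in 1:50) {
    s <- stats::runif(sample(10:50, 1), 0, 1)
    m <- find_motifs(s, min_len = 1)
    s2 <- rep(50, length(s))
    for (k in seq_len(nrow(m))) s2[m$start[k]:m$end[k]] <- 0
    m2 <- find_motifs(s2, min_len = 1)
    expect_equal(m2$start, m$start)
    expect_equal(m2$end, m$end)
  }
})

test_that("motif membership is counted per amino acid among conserved residues", {
  m <- llr_matrix("p1", "GAGAAG", matrix(0, 6, 20))
  tr <- score_protein(m)
  tr$esm2_score <- c(0.1, 0.2, 0.1, 0.9, 0.3, 0.2)
  motifs <- data.frame(protein_id = "p1", start = 1L, end = 3L)
  mm <- motif_membership(tr, motifs)
  # conserved G at 1, 3, 6: two of three inside; conserved A at 2, 5: one of two
  expect_equal(mm$fraction[mm$wt_aa == "G"], 2 / 3)
  expect_equal(mm$fraction[mm$wt_aa == "A"], 1 / 2)
  expect_true(is.na(mm$fraction[mm$wt_aa == "W"]))
})

test_that("sticker fractions count Y, F, W, R, K, Q", {
  expect_equal(sticker_fraction("GYG"), 1 / 3)
  expect_equal(sticker_fraction("YFWRKQ"), 1)
  expect_equal(sticker_fraction("GAPS"), 0)
  expect_error(sticker_fraction(""), "nonempty")
})

test_that("planted motifs are recovered at high residue-level Jaccard", {
  cfg <- sim_config(n_homologs = 0L, n_motifs_per_protein = 2)
  jac <- vapply(1:20, function(seed) {
    set.seed(seed)
    p <- simulate_protein(cfg, "p", group = "driver", motif_multiplier = 1)
    tr <- score_protein(p$llr, p$plddt)
    idrs <- extract_idrs(p$plddt, protein_id = "p")
    rec <- do.call(rbind, lapply(seq_len(nrow(idrs)), function(k)
      find_motifs(tr, region = c(idrs$start[k], idrs$end[k]))))
    jaccard_intervals(p$truth$motifs,
                      if (is.null(rec)) NULL else
                        cbind(rec$start, rec$end))
  }, numeric(1))
  expect_gte(mean(jac), 0.8)
})
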