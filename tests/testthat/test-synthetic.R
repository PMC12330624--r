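# The synthetic-protein generator: determinism, planted score structure,
# conservation coupling and file round-trips.

test_that("the same seed and configuration reproduce the dataset exactly", {
  cfg <- sim_config(n_homologs = 20L, length_range = c(240L, 280L), seed = 61)
  spec <- data.frame(group = c("background", "driver"), n = c(1L, 1L),
                     multiplier = c(0.5, 2))
  d1 <- simulate_dataset(cfg, spec)
  d2 <- simulate_dataset(cfg, spec)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(lapply(d1$proteins, `[[`, "sequence"),
                   lapply(d2$proteins, `[[`, "sequence"))
  expect_identical(lapply(d1$proteins, function(p) p$llr$llr),
                   lapply(d2$proteins, function(p) p$llr$llr))
  expect_identical(lapply(d1$proteins, function(p) p$msa$homologs),
                   lapply(d2$proteins, function(p) p$msa$homologs))
})

test_that("planted sites separate cleanly in entropy score", {
  cfg <- sim_config(n_homologs = 0L, n_motifs_per_protein = 3)
  n_cons <- 0L; cons_ok <- 0L
  n_bg <- 0L; bg_ok <- 0L
  seed <- 62
  while (n_cons < 1000L || n_bg < 1000L) {
    seed <- seed + 1L
    set.seed(seed)
    p <- simulate_protein(cfg, "p", group = "driver")
    sc <- score_protein(p$llr, p$plddt)
    in_motif <- rep(FALSE, nchar(p$sequence))
    for (k in seq_len(nrow(p$truth$motifs)))
      in_motif[p$truth$motifs[k, 1]:p$truth$motifs[k, 2]] <- TRUE
    dis <- sc$order_class == "disordered"
    n_cons <- n_cons + sum(in_motif)
    cons_ok <- cons_ok + sum(sc$esm2_score[in_motif] <= 0.5)
    n_bg <- n_bg + sum(dis & !in_motif)
    bg_ok <- bg_ok + sum(sc$esm2_score[dis & !in_motif] >= 2.0)
  }
  expect_gt(cons_ok / n_cons, 0.99)
  expect_gt(bg_ok / n_bg, 0.99)
})

test_that("motif-site entropy matches the two-level softmax closed form", {
  # all non-WT LLRs at exactly -8: p_wt = 1/(1+19 e^-8), 19 equal tails
  cfg <- sim_config(n_homologs = 0L, motif_nonwt_llr_sd = 0,
                    n_motifs_per_protein = 3)
  set.seed(63)
  p <- simulate_protein(cfg, "p", group = "driver")
  stopifnot(nrow(p$truth$motifs) >= 1)
  sc <- score_protein(p$llr)
  sites <- unlist(lapply(seq_len(nrow(p$truth$motifs)), function(k)
    p$truth$motifs[k, 1]:p$truth$motifs[k, 2]))
  pw <- 1 / (1 + 19 * exp(-8))
  q <- exp(-8) / (1 + 19 * exp(-8))
  h_closed <- -(pw * log(pw) + 19 * q * log(q))
  expect_equal(unname(sc$esm2_score[sites]),
               rep(h_closed, length(sites)), tolerance = 1e-9)
})

test_that("homolog sampling converges to the softmax wild-type weight per site", {
  cfg <- sim_config(length_range = c(240L, 280L), indel_rate = 0,
                    n_motifs_per_protein = 4, seed = 64)
  set.seed(64)
  p <- simulate_protein(cfg, "p", group = "driver")
  stopifnot(nrow(p$truth$motifs) >= 1)
  cs <- conservation_scores(p$msa)
  # per-site |empirical - softmax weight| within 3 binomial standard errors,
  # allowing the usual few-percent of 3-sigma excursions
  se <- sqrt(p$truth$p_wt * (1 - p$truth$p_wt) / length(p$msa$homologs))
  dev_ok <- abs(cs$cs - p$truth$p_wt) <= 3 * se + 1e-9
  expect_gt(mean(dev_ok), 0.98)
  # and the planted-conserved sites agree with the closed form on average
  sites <- unlist(lapply(seq_len(nrow(p$truth$motifs)), function(k)
    p$truth$motifs[k, 1]:p$truth$motifs[k, 2]))
  emp <- cs$cs[sites]
  expect_lt(abs(mean(emp) - mean(p$truth$p_wt[sites])),
            3 * stats::sd(emp) / sqrt(length(emp)) + 1e-6)
})

test_that("a zero-motif configuration yields no recovered motifs in almost all seeds", {
  cfg <- sim_config(n_homologs = 0L, n_motifs_per_protein = 0,
                    length_range = c(120L, 160L))
  empty <- vapply(1:100, function(seed) {
    set.seed(seed)
    p <- simulate_protein(cfg, "p", group = "background",
                          motif_multiplier = 0)
    tr <- score_protein(p$llr, p$plddt)
    idrs <- extract_idrs(p$plddt, protein_id = "p")
    rec <- do.call(rbind, lapply(seq_len(nrow(idrs)), function(k)
      find_motifs(tr, region = c(idrs$start[k], idrs$end[k]))))
    is.null(rec) || nrow(rec) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("truth intervals lie inside disordered runs and WT entries are zero", {
  cfg <- sim_config(n_homologs = 0L, n_motifs_per_protein = 3)
  for (seed in 65:69) {
    set.seed(seed)
    p <- simulate_protein(cfg, "p", group = "driver")
    for (k in seq_len(nrow(p$truth$motifs)))
      expect_true(all(p$plddt[p$truth$motifs[k, 1]:p$truth$motifs[k, 2]] <= 70))
    wt <- match(strsplit(p$sequence, "")[[1]], AA_ALPHABET)
    expect_true(all(p$llr$llr[cbind(seq_along(wt), wt)] == 0))
    # planted motifs respect the minimum separation
    if (nrow(p$truth$motifs) > 1) {
      gaps <- p$truth$motifs[-1, 1] - p$truth$motifs[-nrow(p$truth$motifs), 2]
      expect_true(all(gaps > 12))
    }
  }
})

test_that("an unplaceable motif demand raises a generation error", {
  cfg <- sim_config(n_homologs = 0L, n_motifs_per_protein = 500,
                    length_range = c(120L, 140L), motif_overflow = "error")
  set.seed(70)
  expect_error(simulate_protein(cfg, "p", group = "driver"),
               "capacity")
})

test_that("written datasets round-trip through every parser without warnings", {
  cfg <- sim_config(n_homologs = 15L, length_range = c(240L, 280L), seed = 71)
  spec <- data.frame(group = c("client", "driver"), n = c(1L, 1L),
                     multiplier = c(1, 2))
  ds <- simulate_dataset(cfg, spec)
  dir <- withr::local_tempdir()
  expect_no_warning(write_dataset(ds, dir))
  expect_no_warning({
    mats <- read_llr_table(file.path(dir, "llr.tsv"))
    plddt <- read_plddt(file.path(dir, "plddt.tsv"))
    segs <- read_ps_segments(file.path(dir, "ps_segments.tsv"))
    msas <- lapply(names(ds$proteins), function(id)
      parse_alignment(file.path(dir, "msa", paste0(id, ".a3m"))))
  })
  id <- names(ds$proteins)[1]
  expect_equal(mats[[id]]$sequence, ds$proteins[[id]]$sequence)
  expect_equal(unname(mats[[id]]$llr), unname(ds$proteins[[id]]$llr$llr),
               tolerance = 1e-9)
  expect_equal(plddt$plddt[plddt$protein_id == id],
               ds$proteins[[id]]$plddt, tolerance = 1e-9)
  expect_equal(unname(msas[[1]]$homologs),
               unname(ds$proteins[[id]]$msa$homologs))
  # truth manifest is valid JSON keyed by protein
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_setequal(names(truth), names(ds$proteins))
})
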