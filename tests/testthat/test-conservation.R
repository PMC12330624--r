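# MSA parsing, percent-identity filtering and conservation scoring.

write_a3m <- function(records, path) {
  con <- file(path, "w")
  for (id in names(records)) {
    writeLines(paste0(">", id), con)
    writeLines(records[[id]], con)
  }
  close(con)
  path
}

test_that("A3M lowercase insertions are removed and '.' is a gap", {
  f <- withr::local_tempfile(fileext = ".a3m")
  write_a3m(c(ref = "AGR", hom1 = "Ak-R", hom2 = "A.R"), f)
  a <- parse_alignment(f, format = "a3m")
  expect_equal(a$reference_id, "ref")
  expect_equal(a$reference_aligned, "AGR")
  expect_equal(unname(a$homologs), c("A-R", "A-R"))
})

test_that("block-wrapped CLUSTAL alignments are concatenated to full rows", {
  f <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "ref             AGRKL",
               "hom1            AGRK-",
               "                **** ",
               "",
               "ref             MNP",
               "hom1            MN-",
               "                ** "), f)
  a <- parse_alignment(f, format = "clustal")
  expect_equal(a$reference_aligned, "AGRKLMNP")
  expect_equal(unname(a$homologs), "AGRK-MN-")
})

test_that("aligned FASTA parses and ragged alignments are rejected", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_a3m(c(ref = "AG-R", hom1 = "AGKR"), f)
  a <- parse_alignment(f, format = "fasta")
  expect_equal(a$reference_aligned, "AG-R")

  f2 <- withr::local_tempfile(fileext = ".a3m")
  write_a3m(c(ref = "AGR", hom1 = "AGRK"), f2)
  expect_error(parse_alignment(f2, format = "a3m"), "ragged")

  f3 <- withr::local_tempfile(fileext = ".a3m")
  writeLines(character(), f3)
  expect_error(parse_alignment(f3, format = "a3m"), "FASTA|empty")
})

test_that("percent identity counts matches over the full aligned length", {
  ref <- "AGRKLMNPQW"
  hom <- "AGRKLM----"   # 6 matches over 10 columns
  expect_equal(percent_identity(hom, ref), 0.6)
  # gap columns of the reference still count in the denominator
  expect_equal(percent_identity("AG-R", "AG-R"), 0.75)
  expect_equal(percent_identity("----", "AGRK"), 0)
  expect_error(percent_identity("AG", "AGR"), "length")
})

test_that("the identity filter is inclusive at the published 20% boundary", {
  ref <- paste(rep("A", 100), collapse = "")
  at20 <- paste(c(rep("A", 20), rep("G", 80)), collapse = "")
  below <- paste(c(rep("A", 19), rep("G", 81)), collapse = "")
  a <- alignment_set("ref", ref, c(keep = at20, drop = below))
  flt <- filter_homologs(a, min_identity = 0.20)
  expect_equal(names(flt$homologs), "keep")

  ident <- alignment_set("ref", ref, c(h1 = ref, h2 = ref))
  expect_equal(length(filter_homologs(ident)$homologs), 2L)
  empty <- alignment_set("ref", ref, character())
  expect_equal(length(filter_homologs(empty)$homologs), 0L)
})

test_that("conservation scores follow the per-column counting rule", {
  # worked column: ref A over homologs {A, A, A, G, -}
  a <- alignment_set("ref", "A", c(h1 = "A", h2 = "A", h3 = "A",
                                   h4 = "G", h5 = "-"))
  cs <- conservation_scores(a)
  expect_equal(cs$cs, 0.75)
  expect_equal(cs$n_match, 3L)
  expect_equal(cs$n_nongap, 4L)

  all_gap <- alignment_set("ref", "A", c(h1 = "-", h2 = "-"))
  expect_true(is.na(conservation_scores(all_gap)$cs))

  perfect <- alignment_set("ref", "A", c(h1 = "A", h2 = "A"))
  expect_equal(conservation_scores(perfect)$cs, 1)

  none <- alignment_set("ref", "AG", character())
  expect_warning(cs0 <- conservation_scores(none), "no homologs")
  expect_true(all(is.na(cs0$cs)))
})

test_that("reference-gap columns are dropped and positions renumbered", {
  a <- alignment_set("ref", "A-G", c(h1 = "AKG", h2 = "A-G"))
  cs <- conservation_scores(a)
  expect_equal(cs$position, 1:2)
  expect_equal(cs$wt_aa, c("A", "G"))
  expect_equal(cs$cs, c(1, 1))
})

test_that("conservation scoring matches a naive per-column oracle exactly", {
  set.seed(21)
  letters20 <- c(AA_ALPHABET, "-")
  for (i in 1:100) {
    ncol <- 30L
    ref <- paste(sample(c(AA_ALPHABET, "-"), ncol, replace = TRUE,
                        prob = c(rep(1, 20), 3)), collapse = "")
    if (!grepl("[A-Z]", ref)) next
    homs <- vapply(1:12, function(h)
      paste(sample(letters20, ncol, replace = TRUE), collapse = ""),
      character(1))
    names(homs) <- paste0("h", 1:12)
    got <- conservation_scores(alignment_set("ref", ref, homs))
    want <- oracle_conservation(ref, homs)
    expect_identical(got$n_match, as.integer(want$n_match))
    expect_identical(got$n_nongap, as.integer(want$n_nongap))
    expect_equal(got$cs, want$cs)
  }
})

test_that("a homolog matching the reference everywhere never lowers any score", {
  set.seed(22)
  for (i in 1:20) {
    ref <- paste(sample(AA_ALPHABET, 25, replace = TRUE), collapse = "")
    homs <- vapply(1:8, function(h)
      paste(sample(c(AA_ALPHABET, "-"), 25, replace = TRUE), collapse = ""),
      character(1))
    names(homs) <- paste0("h", 1:8)
    a <- alignment_set("ref", ref, homs)
    before <- conservation_scores(a)$cs
    a$homologs <- c(a$homologs, perfect = ref)
    after <- conservation_scores(a)$cs
    expect_true(all(after >= before - 1e-12, na.rm = TRUE))
  }
})

test_that("softmax-sampled homologs reproduce the closed-form conservation", {
  # at a planted conserved site with every non-WT LLR at exactly -8, the
  # wild-type softmax weight is 1/(1 + 19 e^-8); the empirical match
  # frequency over 200 homologs must sit within 3 standard errors
  cfg <- sim_config(length_range = c(240L, 300L), motif_nonwt_llr_sd = 0,
                    n_motifs_per_protein = 4, seed = 23)
  set.seed(23)
  p <- simulate_protein(cfg, "drv", group = "driver", motif_multiplier = 1)
  cs <- conservation_scores(p$msa)
  stopifnot(nrow(p$truth$motifs) >= 1)
  sites <- unlist(lapply(seq_len(nrow(p$truth$motifs)), function(k)
    p$truth$motifs[k, 1]:p$truth$motifs[k, 2]))
  p_closed <- 1 / (1 + 19 * exp(-8))
  emp <- cs$cs[sites]
  se <- stats::sd(emp) / sqrt(length(emp))
  expect_lt(abs(mean(emp) - p_closed), 3 * se + 1e-6)
})
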