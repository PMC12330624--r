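# Per-residue mutational-tolerance scoring from language-model LLR matrices.

#' Canonical amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes in alphabetical order. This fixed order
#' is the column order of every LLR matrix and LLR table in the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Sticker residues
#'
#' Residues treated as condensate "stickers" (strong, specific interactions)
#' in the stickers-and-spacers framework: Y, F, W, R, K and Q.
#'
#' @format Character vector of length 6.
#' @export
STICKER_RESIDUES <- c("Y", "F", "W", "R", "K", "Q")

# tolerance for checking that the wild-type LLR entry is zero
.WT_TOL <- 1e-9

#' Construct an LLR matrix object
#'
#' Bundles a protein sequence with its per-residue log-likelihood-ratio (LLR)
#' matrix: one 20-element row per residue, column k holding the LLR of mutating
#' that residue to alphabet letter k (natural-log scale). The wild-type letter's
#' own entry is the ratio of the wild type to itself and must be 0.
#'
#' @param protein_id Single identifier string.
#' @param sequence Amino-acid string over the 20 canonical letters.
#' @param llr Numeric matrix, `nchar(sequence)` rows by 20 columns in
#'   [AA_ALPHABET] order (column names, if present, are checked).
#' @return An object of class `llr_matrix`: a list with elements `protein_id`,
#'   `sequence`, and `llr` (matrix with residue rownames `pos.aa`).
#' @examples
#' m <- llr_matrix("prot1", "AG", rbind(c(0, rep(-2, 19)), rep(0, 20)))
#' m
#' @export
llr_matrix <- function(protein_id, sequence, llr) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% AA_ALPHABET)
  if (length(bad))
    stop("nonstandard residue(s) '", paste(unique(aa[bad]), collapse = "','"),
         "' at position(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         " in protein '", protein_id, "'", call. = FALSE)
  llr <- as.matrix(llr)
  if (ncol(llr) != 20L)
    stop("LLR matrix must have 20 columns, got ", ncol(llr), call. = FALSE)
  if (nrow(llr) != length(aa))
    stop("LLR matrix has ", nrow(llr), " rows but sequence has ",
         length(aa), " residues", call. = FALSE)
  if (!all(is.finite(llr)))
    stop("LLR matrix contains non-finite values", call. = FALSE)
  if (!is.null(colnames(llr)) && !identical(colnames(llr), AA_ALPHABET))
    stop("LLR columns must be in canonical order ",
         paste(AA_ALPHABET, collapse = ""), call. = FALSE)
  colnames(llr) <- AA_ALPHABET
  wt_idx <- match(aa, AA_ALPHABET)
  wt_val <- llr[cbind(seq_along(aa), wt_idx)]
  off <- which(abs(wt_val) > .WT_TOL)
  if (length(off))
    stop("wild-type LLR entry is not 0 at position(s) ",
         paste(utils::head(off, 5L), collapse = ", "),
         " of protein '", protein_id, "'", call. = FALSE)
  llr[cbind(seq_along(aa), wt_idx)] <- 0
  rownames(llr) <- paste0(seq_along(aa), ".", aa)
  structure(list(protein_id = protein_id,
                 sequence = paste(aa, collapse = ""),
                 llr = llr),
            class = "llr_matrix")
}

#' @export
print.llr_matrix <- function(x, ...) {
  cat("LLR matrix for protein '", x$protein_id, "': ",
      nrow(x$llr), " residues x 20 mutant states\n", sep = "")
  invisible(x)
}

#' @export
length.llr_matrix <- function(x) nrow(x$llr)

# entropy of the softmax of v; max-shifted for numerical stability
.softmax_entropy <- function(v) {
  w <- exp(v - max(v))
  p <- w / sum(w)
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Entropy score of a 20-element LLR vector
#'
#' Condenses a residue's 20 mutant log-likelihood ratios into a single
#' mutational-tolerance value: the Shannon entropy (nats) of the softmax
#' distribution over the 20 LLR entries,
#' \deqn{S = -\sum_i p_i \log p_i, \quad p_i = e^{LLR_i} / \sum_j e^{LLR_j}.}
#' Low values indicate mutational constraint (few permissible substitutions),
#' high values mutational flexibility; the maximum, \eqn{\ln 20 \approx 2.996},
#' is attained by the uniform landscape. The score is invariant to adding a
#' constant to all entries and to permuting them.
#'
#' @param llr Numeric vector of length 20 (finite).
#' @return Entropy in nats, in `[0, log(20)]`.
#' @examples
#' esm2_score(rep(0, 20))            # log(20)
#' esm2_score(c(0, rep(-50, 19)))    # ~0: only the wild type tolerated
#' @export
esm2_score <- function(llr) {
  if (!is.numeric(llr))
    stop("`llr` must be numeric", call. = FALSE)
  if (length(llr) != 20L)
    stop("`llr` must have length 20, got ", length(llr), call. = FALSE)
  if (!all(is.finite(llr)))
    stop("`llr` contains non-finite values", call. = FALSE)
  .softmax_entropy(llr)
}

# row-wise entropy scores of an L x 20 matrix (validated upstream)
.esm2_score_rows <- function(m) apply(m, 1L, .softmax_entropy)

#' Score every residue of a protein and classify it
#'
#' Computes the per-residue entropy score from an LLR matrix and, when a pLDDT
#' track is supplied, classifies each residue by structural order
#' (disordered iff pLDDT <= `plddt_disorder`) and by mutational tolerance
#' (conserved iff score <= `conserved_max`, flexible iff score >=
#' `flexible_min`, intermediate otherwise).
#'
#' @param m An [llr_matrix].
#' @param plddt Optional numeric vector of per-residue pLDDT values in
#'   `[0, 100]`, same length as the sequence. When absent, `order_class` is
#'   `NA` and order-dependent downstream steps will reject the protein.
#' @param plddt_disorder Disorder threshold on pLDDT (default 70).
#' @param conserved_max Upper score bound for the conserved class (default 0.5).
#' @param flexible_min Lower score bound for the flexible class (default 2.0).
#' @return A `residue_track`: a data frame with columns `protein_id`,
#'   `position` (1-based), `wt_aa`, `esm2_score`, `plddt`, `order_class`
#'   (`"ordered"`/`"disordered"`/`NA`) and `tolerance_class`
#'   (`"conserved"`/`"intermediate"`/`"flexible"`).
#' @export
score_protein <- function(m, plddt = NULL, plddt_disorder = 70,
                          conserved_max = 0.5, flexible_min = 2.0) {
  stopifnot(inherits(m, "llr_matrix"))
  L <- nrow(m$llr)
  if (!is.null(plddt)) {
    if (length(plddt) != L)
      stop("pLDDT track length (", length(plddt),
           ") does not match LLR matrix length (", L,
           ") for protein '", m$protein_id, "'", call. = FALSE)
    if (any(!is.finite(plddt) | plddt < 0 | plddt > 100))
      stop("pLDDT values must be finite and in [0, 100] for protein '",
           m$protein_id, "'", call. = FALSE)
  }
  score <- .esm2_score_rows(m$llr)
  order_class <- if (is.null(plddt)) rep(NA_character_, L) else
    ifelse(plddt <= plddt_disorder, "disordered", "ordered")
  tol <- ifelse(score <= conserved_max, "conserved",
                ifelse(score >= flexible_min, "flexible", "intermediate"))
  out <- data.frame(protein_id = m$protein_id,
                    position = seq_len(L),
                    wt_aa = strsplit(m$sequence, "")[[1]],
                    esm2_score = score,
                    plddt = if (is.null(plddt)) NA_real_ else plddt,
                    order_class = order_class,
                    tolerance_class = tol,
                    stringsAsFactors = FALSE)
  class(out) <- c("residue_track", "data.frame")
  out
}

#' Read per-residue LLR tables
#'
#' Reads a TSV with header columns `protein_id`, `position` (1-based),
#' `wt_aa`, then the 20 alphabet columns in canonical order. Positions of each
#' protein must be contiguous from 1 and the wild-type column entry of each row
#' must be 0 (within 1e-9); violations signal a table following a different
#' convention and raise a format error.
#'
#' @param path Path to the TSV file.
#' @return A single [llr_matrix] when the file holds one protein, otherwise a
#'   named list of them.
#' @seealso [write_llr_table()]
#' @export
read_llr_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein_id", "position", "wt_aa", AA_ALPHABET)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("LLR table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(split(tab, tab$protein_id), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    if (!identical(as.integer(d$position), seq_len(nrow(d))))
      stop("positions of protein '", d$protein_id[1L],
           "' are not contiguous from 1", call. = FALSE)
    wt_idx <- match(toupper(d$wt_aa), AA_ALPHABET)
    if (anyNA(wt_idx))
      stop("nonstandard wt_aa in protein '", d$protein_id[1L], "'",
           call. = FALSE)
    m <- as.matrix(d[, AA_ALPHABET])
    wt_val <- m[cbind(seq_len(nrow(m)), wt_idx)]
    off <- which(abs(wt_val) > .WT_TOL)
    if (length(off))
      stop("wild-type LLR entry differs from 0 at position ", d$position[off[1L]],
           " of protein '", d$protein_id[1L],
           "'; the table's WT convention differs", call. = FALSE)
    llr_matrix(d$protein_id[1L], paste(toupper(d$wt_aa), collapse = ""), m)
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Write per-residue LLR tables
#'
#' Inverse of [read_llr_table()]: `read_llr_table(write_llr_table(x, path))`
#' reproduces `x`.
#'
#' @param x An [llr_matrix] or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_llr_table <- function(x, path) {
  if (inherits(x, "llr_matrix")) x <- list(x)
  rows <- lapply(x, function(m) {
    d <- data.frame(protein_id = m$protein_id,
                    position = seq_len(nrow(m$llr)),
                    wt_aa = strsplit(m$sequence, "")[[1]],
                    stringsAsFactors = FALSE)
    cbind(d, as.data.frame(m$llr, row.names = FALSE))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a residue track as TSV
#'
#' @param track A `residue_track` data frame from [score_protein()].
#' @param path File path.
#' @return `write_track` returns `path` invisibly; `read_track` returns the
#'   track data frame.
#' @export
write_track <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("residue_track", "data.frame")
  out
}

#' Read a per-residue pLDDT track
#'
#' Two input conventions are supported: a TSV with columns `protein_id`,
#' `position`, `plddt`; or an AlphaFold-convention coordinate (PDB) file in
#' which the per-residue confidence occupies the B-factor field (the first
#' atom of each residue is read, via the bio3d package).
#'
#' @param path File path.
#' @param format `"auto"` (detect PDB by ATOM/HEADER records), `"tsv"` or
#'   `"pdb"`.
#' @param protein_id Identifier used for PDB input (defaults to the file's
#'   base name).
#' @return Data frame with columns `protein_id`, `position`, `plddt`.
#' @export
read_plddt <- function(path, format = c("auto", "tsv", "pdb"),
                       protein_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    head_lines <- readLines(path, n = 10L, warn = FALSE)
    format <- if (any(grepl("^(ATOM|HETATM|HEADER|MODEL)", head_lines)))
      "pdb" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("protein_id", "position", "plddt"), names(tab))
    if (length(miss))
      stop("pLDDT table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    return(tab[, c("protein_id", "position", "plddt")])
  }
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading pLDDT from coordinate files requires the 'bio3d' package",
         call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  first <- atoms[!duplicated(paste(atoms$chain, atoms$resno)), , drop = FALSE]
  data.frame(protein_id = if (is.null(protein_id))
               sub("\\.[^.]*$", "", basename(path)) else protein_id,
             position = seq_len(nrow(first)),
             plddt = first$b,
             stringsAsFactors = FALSE)
}
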