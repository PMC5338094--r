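# Shared fixtures and independent oracles, all built in code at test time.

write_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# random unrooted binary tree with positive branch lengths and its additive
# distance matrix
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) runif(k, 0.1, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, dm = stats::cophenetic(tr))
}

# brute-force regex scan for spacer+PAM sites on one strand (oracle for
# find_spacer_sites); returns 0-based spacer starts in this strand's frame
regex_spacer_starts <- function(seq, spacer_length, pam) {
  pat <- paste0("(?=[ACGT]{", spacer_length, "}",
                gsub("N", "[ACGT]", pam), ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

revcomp_chr <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Biostrings global-alignment score with the same scoring convention as
# align_read (gap of length L costs gap_open + L * gap_extend)
biostrings_score <- function(read, reference, match = 1, mismatch = -1,
                             gap_open = 4, gap_extend = 1) {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- match
  mat["N", ] <- mat[, "N"] <- mismatch
  Biostrings::pairwiseAlignment(read, reference, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = gap_open,
                                gapExtension = gap_extend,
                                scoreOnly = TRUE)
}

# toy two-species alignment tibble from explicit sequences
aln_tbl <- function(seqs, species = NULL, paralog = NULL) {
  tibble::tibble(id = names(seqs),
                 species = species %||% rep("sp", length(seqs)),
                 paralog = paralog %||% names(seqs),
                 seq = unname(seqs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# delete k bases at 0-based offset `cut`
apply_del <- function(seq, cut, k) {
  paste0(substr(seq, 1, cut), substr(seq, cut + k + 1, nchar(seq)))
}
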