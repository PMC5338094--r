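#' Scan a sequence for SpCas9 spacer sites
#'
#' Finds every position, on both strands, where a `spacer_length`-nt window
#' is immediately followed by a PAM match (default NGG; N matches any base).
#' Positions are 0-based starts of the spacer's footprint on the forward
#' strand; for minus-strand hits the reported `spacer` is the protospacer
#' read off the minus strand.
#'
#' @param seq Nucleotide sequence (string or one-row tibble with `seq`).
#' @param spacer_length Spacer length in nt; 19 and 20 are the common SpCas9
#'   choices.
#' @param pam PAM pattern; `N` is a wildcard.
#' @return A tibble with columns `position`, `strand`, `spacer`, `pam`.
#'   Empty if the sequence is shorter than spacer + PAM.
#' @export
find_spacer_sites <- function(seq, spacer_length = 19L, pam = "NGG") {
  if (is.data.frame(seq)) seq <- seq$seq[1]
  seq <- toupper(seq)
  stopifnot(spacer_length >= 17, spacer_length <= 23)
  fwd <- scan_strand(seq, spacer_length, pam)
  rev <- scan_strand(revcomp(seq), spacer_length, pam)
  L <- nchar(seq)
  out <- dplyr::bind_rows(
    if (nrow(fwd)) dplyr::mutate(fwd, strand = "+"),
    if (nrow(rev)) dplyr::mutate(rev, strand = "-",
                                 position = L - .data$position - spacer_length)
  )
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(position = integer(), strand = character(),
                  spacer = character(), pam = character()))
  }
  dplyr::arrange(out[, c("position", "strand", "spacer", "pam")],
                 .data$position, .data$strand)
}

scan_strand <- function(seq, spacer_length, pam) {
  L <- nchar(seq)
  pl <- nchar(pam)
  if (L < spacer_length + pl) {
    return(tibble(position = integer(), spacer = character(), pam = character()))
  }
  starts <- seq_len(L - spacer_length - pl + 1L)   # 1-based spacer starts
  pam_seq <- substring(seq, starts + spacer_length, starts + spacer_length + pl - 1L)
  pam_chars <- strsplit(pam, "")[[1]]
  hit <- rep(TRUE, length(starts))
  for (k in seq_len(pl)) {
    if (pam_chars[k] == "N") next
    hit <- hit & substring(pam_seq, k, k) == pam_chars[k]
  }
  if (!any(hit)) {
    return(tibble(position = integer(), spacer = character(), pam = character()))
  }
  tibble(position = starts[hit] - 1L,
         spacer = substring(seq, starts[hit], starts[hit] + spacer_length - 1L),
         pam = pam_seq[hit])
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Global pairwise alignment of a read against an amplicon reference
#'
#' Needleman–Wunsch alignment with affine gaps (Gotoh recursion). Scoring:
#' match +1, mismatch -1 (N never matches), a gap of length L costs
#' `gap_open + L * gap_extend`. Traceback ties are broken deterministically,
#' preferring a match/mismatch column over a deletion (gap in the read) over
#' an insertion (gap in the reference).
#'
#' @param read,reference Nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (penalties
#'   given as positive numbers).
#' @return An object of class `pairwise_alignment`: list with `read_aln`,
#'   `ref_aln` (equal-length gapped strings) and `score`.
#' @export
align_read <- function(read, reference, match = 1, mismatch = -1,
                       gap_open = 4, gap_extend = 1) {
  if (!nzchar(read)) abort("empty read")
  if (!nzchar(reference)) abort("empty reference")
  a <- strsplit(toupper(read), "")[[1]]       # rows (read)
  b <- strsplit(toupper(reference), "")[[1]]  # cols (reference)
  n <- length(a); m <- length(b)
  go <- gap_open + gap_extend   # cost of the first base of a gap
  ge <- gap_extend
  NEG <- -1e15
  # M: a_i aligned to b_j; X: gap in reference (read base consumed);
  # Y: gap in read (reference base consumed). 1-based R indices = 0-based + 1.
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (m >= 1) Y[1, 2:(m + 1)] <- -(go + ge * (0:(m - 1)))
  for (i in 2:(n + 1)) {
    prevM <- M[i - 1, ]; prevX <- X[i - 1, ]; prevY <- Y[i - 1, ]
    s <- ifelse(b == a[i - 1] & a[i - 1] != "N", match, mismatch)
    M[i, 2:(m + 1)] <- pmax(prevM, prevX, prevY)[1:m] + s
    X[i, ] <- pmax(pmax(prevM, prevY) - go, prevX - ge)
    # Y along the row: Y[i,j] = max(C[j-1] - go, Y[i,j-1] - ge), C = max(M, X).
    # With T[j] = Y[i,j] + j*ge this is a running maximum:
    # T[j] = max(C[j-1] - go + j*ge, T[j-1]).
    Cg <- pmax(M[i, ], X[i, ]) - go
    E <- Cg[1:m] + ge * (2:(m + 1))
    Y[i, 2:(m + 1)] <- cummax(E) - ge * (2:(m + 1))
    Y[i, 1] <- NEG
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback; ties broken preferring match/mismatch > deletion > insertion
  eps <- 1e-9
  state <- if (M[n + 1, m + 1] > score - eps) "M"
           else if (Y[n + 1, m + 1] > score - eps) "Y" else "X"
  i <- n + 1L; j <- m + 1L
  ra <- character(n + m); rb <- character(n + m)
  k <- n + m
  pick <- function(vals, target) {
    # vals named M/Y/X in preference order
    nm <- names(vals)[abs(vals - target) < eps]
    if (length(nm) == 0) names(vals)[which.max(vals)] else nm[1]
  }
  while (i > 1L || j > 1L) {
    if (state == "M") {
      sc <- if (b[j - 1L] == a[i - 1L] && a[i - 1L] != "N") match else mismatch
      ra[k] <- a[i - 1L]; rb[k] <- b[j - 1L]; k <- k - 1L
      state <- pick(c(M = M[i - 1L, j - 1L], Y = Y[i - 1L, j - 1L],
                      X = X[i - 1L, j - 1L]), M[i, j] - sc)
      i <- i - 1L; j <- j - 1L
    } else if (state == "Y") {
      ra[k] <- "-"; rb[k] <- b[j - 1L]; k <- k - 1L
      state <- pick(c(M = M[i, j - 1L] - go, Y = Y[i, j - 1L] - ge,
                      X = X[i, j - 1L] - go), Y[i, j])
      j <- j - 1L
    } else {
      ra[k] <- a[i - 1L]; rb[k] <- "-"; k <- k - 1L
      state <- pick(c(M = M[i - 1L, j] - go, Y = Y[i - 1L, j] - go,
                      X = X[i - 1L, j] - ge), X[i, j])
      i <- i - 1L
    }
  }
  structure(list(read_aln = paste(ra[(k + 1L):(n + m)], collapse = ""),
                 ref_aln = paste(rb[(k + 1L):(n + m)], collapse = ""),
                 score = score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment (score", x$score, ")\n")
  cat(" read:", x$read_aln, "\n")
  cat("  ref:", x$ref_aln, "\n")
  invisible(x)
}

#' Call the net indel of an aligned read around a cut site
#'
#' Sums inserted minus deleted bases whose reference anchor lies within
#' `cut_site` ± `window` and classifies the read by the reading-frame
#' consequence of the net length: `unedited` (0), `in_frame` (multiple of
#' 3) or `frameshift` (otherwise). A read whose aligned bases do not reach
#' the window is flagged uncallable.
#'
#' @param alignment A `pairwise_alignment` from [align_read()].
#' @param cut_site 0-based cut offset on the reference.
#' @param window Bases on each side of the cut considered part of the edit
#'   site.
#' @return A one-row tibble: `net_indel`, `classification`, `callable`.
#' @export
call_indel <- function(alignment, cut_site, window = 20L) {
  stopifnot(inherits(alignment, "pairwise_alignment"), window >= 1)
  ra <- strsplit(alignment$read_aln, "")[[1]]
  rb <- strsplit(alignment$ref_aln, "")[[1]]
  ref_pos <- cumsum(rb != "-") - 1L     # 0-based ref position of each column
  lo <- cut_site - window
  hi <- cut_site + window               # half-open [lo, hi)
  in_win <- ref_pos >= lo & ref_pos < hi
  n_del <- sum(in_win & rb != "-" & ra == "-")
  # insertions anchor at the reference position of the next reference base
  ins_cols <- which(rb == "-")
  ins_anchor <- ref_pos[ins_cols] + 1L
  n_ins <- sum(ins_anchor >= lo & ins_anchor < hi)
  covered <- ra != "-" & rb != "-"
  callable <- any(covered & in_win) || n_del > 0 || n_ins > 0
  net <- as.integer(n_ins - n_del)
  tibble(net_indel = net,
         classification = if (!callable) NA_character_
                          else if (net == 0L) "unedited"
                          else if (net %% 3L == 0L) "in_frame"
                          else "frameshift",
         callable = callable)
}

#' Call indels for a table of amplicon reads
#'
#' Aligns each read globally to the reference and calls its net indel at the
#' cut site.
#'
#' @param reads Tibble with columns `id` and `seq` (e.g. from
#'   [simulate_amplicon_reads()] or [read_fasta()]).
#' @param reference Reference amplicon (string or one-row tibble).
#' @param cut_site 0-based cut offset.
#' @param window Window half-width around the cut.
#' @return A tibble with one row per read: `id`, `net_indel`,
#'   `classification`, `callable`.
#' @export
call_indels <- function(reads, reference, cut_site, window = 20L) {
  if (is.data.frame(reference)) reference <- reference$seq[1]
  calls <- purrr::map(reads$seq, function(s) {
    call_indel(align_read(s, reference), cut_site, window)
  })
  dplyr::bind_cols(tibble(id = reads$id), dplyr::bind_rows(calls))
}

#' Summarize a clone's amplicon reads into edit-class counts
#'
#' Counts unedited, in-frame and frameshift reads at the cut site and
#' classifies the clone as `low` or `high` by whether the frameshift
#' fraction reaches `frameshift_threshold` — the programmatic version of
#' sorting single-cell clones into low- and high-frameshift classes.
#'
#' @inheritParams call_indels
#' @param frameshift_threshold Fraction of frameshift reads at or above
#'   which the clone is classed `high`.
#' @param clone_id Identifier carried into the summary.
#' @return A one-row tibble: `clone_id`, `n_reads`, `n_unedited`,
#'   `n_in_frame`, `n_frameshift`, `n_uncallable`, `frameshift_fraction`,
#'   `clone_class`.
#' @export
summarize_clone <- function(reads, reference, cut_site, window = 20L,
                            frameshift_threshold = 0.5, clone_id = "clone") {
  stopifnot(frameshift_threshold > 0, frameshift_threshold < 1)
  calls <- call_indels(reads, reference, cut_site, window)
  ok <- calls[calls$callable, ]
  if (nrow(ok) == 0) abort("no callable reads")
  n <- nrow(ok)
  n_fs <- sum(ok$classification == "frameshift")
  frac <- n_fs / n
  tibble(clone_id = clone_id,
         n_reads = n,
         n_unedited = sum(ok$classification == "unedited"),
         n_in_frame = sum(ok$classification == "in_frame"),
         n_frameshift = n_fs,
         n_uncallable = sum(!calls$callable),
         frameshift_fraction = frac,
         clone_class = if (frac >= frameshift_threshold) "high" else "low")
}
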