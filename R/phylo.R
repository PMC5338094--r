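#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or an ambiguity code are
#' excluded (pairwise deletion). Over the remaining sites, P is the
#' transition fraction (A<->G, C<->T) and Q the transversion fraction, and
#'
#'   d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)
#'
#' @param seq1,seq2 Equal-length aligned DNA strings.
#' @return A one-row tibble with columns `d`, `P`, `Q`, `sites_used`.
#' @examples
#' # 10 transitions among 100 sites: d = -ln(0.8)/2
#' a <- strrep("A", 100)
#' b <- paste0(strrep("G", 10), strrep("A", 90))
#' k2p_distance(a, b)
#' @export
k2p_distance <- function(seq1, seq2) {
  x <- encode_dna(seq1)
  y <- encode_dna(seq2)
  if (length(x) != length(y)) abort("sequences must be aligned to equal length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0) abort("no comparable sites after pairwise deletion")
  xo <- x[ok]; yo <- y[ok]
  diff <- xo != yo
  ts <- diff & abs(xo - yo) == 2L   # A(1)<->G(3), C(2)<->T(4)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort("K2P distance saturated (substitution fractions too large)")
  }
  tibble(d = -0.5 * log(w1) - 0.25 * log(w2), P = P, Q = Q, sites_used = n)
}

# A=1 C=2 G=3 T=4; gaps and ambiguity codes become NA (pairwise deletion).
encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  unname(c(A = 1L, C = 2L, G = 3L, T = 4L)[chars])
}

#' Pairwise distance matrix under K2P or p-distance
#'
#' Computes all pairwise distances of an alignment with pairwise deletion.
#' `model = "k2p"` is the nucleotide default; `model = "p"` is the plain
#' mismatch proportion, usable for protein alignments where no nucleotide
#' substitution model applies.
#'
#' @param aln Alignment tibble with columns `id` and `seq` (equal lengths),
#'   e.g. from [read_fasta()] or [simulate_gene_family()].
#' @param model `"k2p"` or `"p"`.
#' @return An object of class `k2p_dist`: a list with `labels`, matrices
#'   `d`, `P`, `Q` (NA for `model = "p"`) and `sites_used`.
#' @export
distance_matrix <- function(aln, model = c("k2p", "p")) {
  model <- match.arg(model)
  stopifnot(nrow(aln) >= 3, all(c("id", "seq") %in% names(aln)))
  if (length(unique(nchar(aln$seq))) != 1) {
    abort("alignment sequences must have equal length")
  }
  n <- nrow(aln)
  labels <- aln$id
  if (model == "k2p") {
    enc <- lapply(aln$seq, encode_dna)
  } else {
    enc <- lapply(aln$seq, encode_protein)
  }
  d <- P <- Q <- matrix(0, n, n, dimnames = list(labels, labels))
  sites <- matrix(nchar(aln$seq[1]), n, n, dimnames = list(labels, labels))
  saturated <- character()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(enc[[i]]) & !is.na(enc[[j]])
      m <- sum(ok)
      if (m == 0) abort(paste0("no comparable sites for pair ",
                               labels[i], " / ", labels[j]))
      xo <- enc[[i]][ok]; yo <- enc[[j]][ok]
      diffs <- xo != yo
      if (model == "k2p") {
        ts <- diffs & abs(xo - yo) == 2L
        p <- sum(ts) / m; q <- sum(diffs & !ts) / m
        if (1 - 2 * p - q <= 0 || 1 - 2 * q <= 0) {
          saturated <- c(saturated, paste0(labels[i], "/", labels[j]))
          next
        }
        dij <- -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q)
        P[i, j] <- P[j, i] <- p
        Q[i, j] <- Q[j, i] <- q
      } else {
        dij <- sum(diffs) / m
        P[i, j] <- P[j, i] <- NA_real_
        Q[i, j] <- Q[j, i] <- NA_real_
      }
      d[i, j] <- d[j, i] <- dij
      sites[i, j] <- sites[j, i] <- m
    }
  }
  if (length(saturated) > 0) {
    abort(paste0("K2P distance saturated for pair(s): ",
                 paste(saturated, collapse = ", ")))
  }
  structure(list(labels = labels, d = d, P = P, Q = Q, sites_used = sites),
            class = "k2p_dist")
}

encode_protein <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  out <- match(chars, aa)
  out
}

#' @export
as.matrix.k2p_dist <- function(x, ...) x$d

#' @export
print.k2p_dist <- function(x, ...) {
  cat("Pairwise distance matrix over", length(x$labels), "sequences\n")
  print(round(x$d, 4))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration on the Q-criterion. On an additive
#' distance matrix the returned tree's path lengths reproduce the input
#' distances exactly. Two determinism/robustness rules are applied: ties in
#' the Q-criterion are broken by the lexicographically smallest pair of
#' cluster labels, and a negative branch-length estimate is clamped to zero
#' with its length transferred to the sibling branch so path lengths through
#' the join are preserved. A matrix with all distances zero yields a star
#' tree (no resolved internal branch).
#'
#' @param dm A `k2p_dist` object, `dist`, or symmetric numeric matrix with
#'   dimnames.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  d <- dm_to_matrix(dm)
  n <- nrow(d)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  labels <- rownames(d)
  if (all(d == 0)) {
    nwk <- paste0("(", paste0(labels, ":0", collapse = ","), ");")
    return(ape::read.tree(text = nwk))
  }
  # each active cluster carries a growing Newick fragment and a
  # representative label (its lexicographically smallest tip) for tie-breaks
  frag <- labels
  rep_lab <- labels
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      pr <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_frag <- paste0("(", frag[i], ":", fmt_bl(vi), ",",
                       frag[j], ":", fmt_bl(vj), ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
    d <- d2
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- paste0("(", frag[1], ":", fmt_bl(v[1]), ",",
                frag[2], ":", fmt_bl(v[2]), ",",
                frag[3], ":", fmt_bl(v[3]), ");")
  ape::read.tree(text = nwk)
}

fmt_bl <- function(x) sprintf("%.15g", x)

dm_to_matrix <- function(dm) {
  if (inherits(dm, "k2p_dist")) return(dm$d)
  if (inherits(dm, "dist")) return(as.matrix(dm))
  if (is.matrix(dm)) {
    if (is.null(rownames(dm))) {
      rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
    }
    return(dm)
  }
  abort("dm must be a k2p_dist, dist, or matrix")
}

# Canonical string form of every non-trivial bipartition of an unrooted tree:
# each internal edge splits the tips in two; the side not containing the
# first label (in `all_labels` order) is sorted and pasted.
bipartitions <- function(tree, all_labels) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- vapply(pp, function(idx) {
    s <- labs[idx]
    if (all_labels[1] %in% s) s <- setdiff(all_labels, s)
    if (length(s) < 2 || length(s) > length(all_labels) - 2) return(NA_character_)
    paste(sort(s), collapse = "|")
  }, character(1))
  out
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and scores every internal branch of the original tree by
#' the percentage of replicates whose tree contains the same bipartition.
#' A replicate whose resampled distance matrix is saturated or degenerate is
#' skipped (with a warning) and excluded from the denominator.
#'
#' @param aln Alignment tibble (`id`, `seq`).
#' @param n_replicates Number of bootstrap replicates (500 is the customary
#'   figure-quality default).
#' @param seed Optional integer seed; the same seed reproduces the supports
#'   bit for bit.
#' @param model Distance model passed to [distance_matrix()].
#' @return The original NJ [ape::phylo] tree with integer percentage
#'   supports in `node.label` (empty for the unresolvable basal node) and
#'   attributes `n_used` / `n_skipped`.
#' @export
bootstrap_support <- function(aln, n_replicates = 500L, seed = NULL,
                              model = "k2p") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_replicates >= 1)
  dm <- distance_matrix(aln, model = model)
  tree <- nj_tree(dm)
  all_labels <- sort(aln$id)
  orig_bip <- bipartitions(tree, all_labels)
  counts <- integer(length(orig_bip))
  L <- nchar(aln$seq[1])
  seq_chars <- do.call(rbind, strsplit(aln$seq, ""))
  n_used <- 0L
  n_skipped <- 0L
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- tibble(id = aln$id,
                      seq = apply(seq_chars[, cols, drop = FALSE], 1,
                                  paste, collapse = ""))
    rep_tree <- tryCatch(nj_tree(distance_matrix(rep_aln, model = model)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) {
      n_skipped <- n_skipped + 1L
      next
    }
    n_used <- n_used + 1L
    rep_bip <- bipartitions(rep_tree, all_labels)
    counts <- counts + (orig_bip %in% rep_bip[!is.na(rep_bip)])
  }
  if (n_skipped > 0) {
    warn(paste0(n_skipped, " bootstrap replicate(s) skipped (saturated distances)"))
  }
  if (n_used == 0) abort("all bootstrap replicates failed")
  supports <- ifelse(is.na(orig_bip), "",
                     as.character(as.integer(round(100 * counts / n_used))))
  tree$node.label <- supports
  attr(tree, "n_used") <- n_used
  attr(tree, "n_skipped") <- n_skipped
  tree
}

#' Concerted-evolution statistic of a two-species gene family
#'
#' Under concerted evolution (e.g. frequent interlocus gene conversion),
#' duplicated copies are homogenized within each species, so paralogs within
#' a species are more similar to each other than to their counterparts in
#' the other species. This statistic captures that as the ratio of the mean
#' within-species paralog distance W to the mean between-species distance B:
#' W/B < 1 indicates within-species clustering (concerted evolution),
#' W/B > 1 orthologous clustering. A per-species monophyly flag from the NJ
#' tree's bipartitions records whether each species' copies form a clade.
#'
#' @param aln Alignment tibble with columns `id`, `species`, `paralog`,
#'   `seq` (e.g. from [simulate_gene_family()]), or a `k2p_dist` plus
#'   explicit `species` labels.
#' @param species Optional character vector of species labels, one per
#'   sequence, when `aln` is a distance object.
#' @param model Distance model passed to [distance_matrix()].
#' @return An object of class `concerted_stat`; see [tidy.concerted_stat()]
#'   and [glance.concerted_stat()].
#' @export
concerted_stat <- function(aln, species = NULL, model = "k2p") {
  if (inherits(aln, "k2p_dist")) {
    dm <- aln
    if (is.null(species) || length(species) != length(dm$labels)) {
      abort("species labels (one per sequence) required with a distance input")
    }
  } else {
    stopifnot(all(c("id", "species", "seq") %in% names(aln)))
    dm <- distance_matrix(aln, model = model)
    species <- aln$species
  }
  if (length(unique(species)) < 2) abort("need at least 2 species")
  d <- dm$d
  n <- nrow(d)
  same <- outer(species, species, `==`)
  ut <- upper.tri(d)
  within <- d[ut & same]
  between <- d[ut & !same]
  if (length(within) == 0) abort("no within-species pairs: every species has a single copy")
  W <- mean(within)
  B <- mean(between)
  tree <- nj_tree(dm)
  all_labels <- sort(dm$labels)
  bip <- bipartitions(tree, all_labels)
  mono <- vapply(unique(species), function(s) {
    tips <- dm$labels[species == s]
    if (length(tips) <= 1 || length(tips) >= n - 1) return(TRUE)
    canon <- if (all_labels[1] %in% tips) {
      paste(sort(setdiff(all_labels, tips)), collapse = "|")
    } else {
      paste(sort(tips), collapse = "|")
    }
    canon %in% bip
  }, logical(1))
  structure(
    list(W = W, B = B, ratio = if (B > 0) W / B else NA_real_,
         n_within_pairs = length(within), n_between_pairs = length(between),
         monophyly = mono, species = species, tree = tree, dm = dm),
    class = "concerted_stat")
}

#' @export
print.concerted_stat <- function(x, ...) {
  cat("Concerted-evolution statistic\n")
  cat("  mean within-species distance  W =", format(x$W, digits = 4),
      " (", x$n_within_pairs, "pairs )\n")
  cat("  mean between-species distance B =", format(x$B, digits = 4),
      " (", x$n_between_pairs, "pairs )\n")
  cat("  ratio W/B =", format(x$ratio, digits = 4),
      if (!is.na(x$ratio) && x$ratio < 1) " (within-species clustering)" else "", "\n")
  cat("  species monophyly:",
      paste(names(x$monophyly), x$monophyly, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-species detail of a concerted-evolution statistic
#' @param x A `concerted_stat` object.
#' @param ... Unused.
#' @return A tibble with one row per species: `species`, `n_copies`,
#'   `mean_within_distance`, `monophyletic`.
#' @method tidy concerted_stat
#' @export
tidy.concerted_stat <- function(x, ...) {
  d <- x$dm$d
  ut <- upper.tri(d)
  purrr::map_dfr(unique(x$species), function(s) {
    sel <- x$species == s
    within <- d[ut & outer(sel, sel, `&`)]
    tibble(species = s, n_copies = sum(sel),
           mean_within_distance = if (length(within)) mean(within) else NA_real_,
           monophyletic = unname(x$monophyly[s]))
  })
}

#' One-row summary of a concerted-evolution statistic
#' @param x A `concerted_stat` object.
#' @param ... Unused.
#' @return A one-row tibble: `W`, `B`, `ratio`, `all_species_monophyletic`,
#'   `n_within_pairs`, `n_between_pairs`.
#' @method glance concerted_stat
#' @export
glance.concerted_stat <- function(x, ...) {
  tibble(W = x$W, B = x$B, ratio = x$ratio,
         all_species_monophyletic = all(x$monophyly),
         n_within_pairs = x$n_within_pairs,
         n_between_pairs = x$n_between_pairs)
}
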