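#' Simulate two-channel ddPCR droplet counts
#'
#' Emulates a droplet digital PCR plate read: template molecules are loaded
#' into droplets under Poisson statistics, so the number of positive droplets
#' in a channel is Binomial(`n_droplets`, 1 - exp(-lambda)). The target
#' channel's mean occupancy is tied to the reference channel's through the
#' true copy number: lambda_target = `reference_lambda` * `true_cn` /
#' `reference_copies`.
#'
#' @param true_cn True copies per diploid genome; a scalar, or one value per
#'   sample.
#' @param n_samples Number of samples (wells).
#' @param n_droplets Droplets generated per channel.
#' @param reference_lambda Mean reference molecules per droplet.
#' @param reference_copies Copies of the reference gene per diploid genome.
#' @param population Population label(s), recycled over samples.
#' @param seed Optional integer seed.
#' @return A tibble with columns `sample_id`, `population`, `channel`,
#'   `positives`, `total` — the same layout [read_droplet_csv()] returns.
#' @examples
#' simulate_droplets(true_cn = 7.5, n_samples = 3, seed = 1)
#' @export
simulate_droplets <- function(true_cn, n_samples = 1L, n_droplets = 20000L,
                              reference_lambda = 0.2, reference_copies = 2L,
                              population = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(true_cn >= 0), reference_lambda > 0, n_droplets >= 1)
  cn <- rep_len(true_cn, n_samples)
  pop <- rep_len(population, n_samples)
  lam_t <- reference_lambda * cn / reference_copies
  p_t <- 1 - exp(-lam_t)
  p_r <- 1 - exp(-reference_lambda)
  if (any(p_t >= 1 - 1e-12) || p_r >= 1 - 1e-12) {
    abort("channel saturated: implied positive fraction is ~1; lower reference_lambda")
  }
  tibble(
    sample_id = rep(sprintf("s%03d", seq_len(n_samples)), each = 2L),
    population = rep(pop, each = 2L),
    channel = rep(c("target", "reference"), times = n_samples),
    positives = as.vector(rbind(rbinom(n_samples, n_droplets, p_t),
                                rbinom(n_samples, n_droplets, p_r))),
    total = n_droplets
  )
}

#' Simulate Poisson read depth over a genome with a collapsed multi-copy locus
#'
#' Models the read-depth footprint of a segmentally duplicated family on a
#' reference that carries fewer copies than the genome: all reads from the
#' family pile onto the represented locus, so depth at base i is
#' Poisson(`coverage` * m_i / 2), where m_i is the number of haploid copies
#' mapping there (2 in the diploid background, a region's `multiplicity`
#' inside it).
#'
#' @param genome_length Length of the simulated contig in bases.
#' @param coverage Mean diploid background depth.
#' @param regions Optional tibble of collapsed loci with columns `contig`,
#'   `start`, `end` (0-based half-open), `label`, `multiplicity` (total
#'   haploid copies mapping to that locus).
#' @param contig Contig name.
#' @param seed Optional integer seed.
#' @return A list with `track` (tibble `contig`, `pos`, `depth`) and
#'   `regions` (the region tibble, possibly empty).
#' @export
simulate_depth_track <- function(genome_length = 50000L, coverage = 30,
                                 regions = NULL, contig = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(genome_length >= 1, coverage >= 0)
  mult <- rep(2, genome_length)
  if (is.null(regions)) {
    regions <- tibble(contig = character(), start = integer(), end = integer(),
                      label = character(), multiplicity = numeric())
  } else {
    validate_regions(regions)
    stopifnot(all(regions$multiplicity >= 0),
              all(regions$start >= 0), all(regions$end <= genome_length))
    for (i in seq_len(nrow(regions))) {
      mult[(regions$start[i] + 1L):regions$end[i]] <- regions$multiplicity[i]
    }
  }
  track <- tibble(contig = contig,
                  pos = seq_len(genome_length) - 1L,
                  depth = rpois(genome_length, coverage * mult / 2))
  list(track = track, regions = as_tibble(regions))
}

NUC <- c("A", "C", "G", "T")
TS_OF <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
TV1_OF <- c(2L, 1L, 2L, 1L)
TV2_OF <- c(4L, 3L, 4L, 3L)

# One pulse of K2P evolution: x is an integer vector over 1..4, d the branch
# length in expected substitutions/site, kappa the transition/transversion
# rate ratio. Multiple hits are implicit in the transition probabilities.
evolve_k2p <- function(x, d, kappa) {
  if (d <= 0) return(x)
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.5 - 0.5 * exp(-4 * bt)   # both transversions together
  u <- runif(length(x))
  out <- x
  i <- u < p_ts
  out[i] <- TS_OF[x[i]]
  j <- u >= p_ts & u < p_ts + p_tv / 2
  out[j] <- TV1_OF[x[j]]
  k <- u >= p_ts + p_tv / 2 & u < p_ts + p_tv
  out[k] <- TV2_OF[x[k]]
  out
}

#' Simulate a two-species gene family with optional gene conversion
#'
#' Evolves a gene family along a fixed history: an ancestral gene duplicates
#' into `n_paralogs` copies at `duplication_depth` (time units before
#' present), each paralog lineage then splits into two species at
#' `speciation_depth`, and all branches accumulate substitutions under a
#' Kimura two-parameter process (`subst_rate` expected substitutions per site
#' per time unit, transition/transversion ratio `kappa`). After speciation,
#' each terminal lineage receives a Poisson(`gene_conversion_rate`) number of
#' gene-conversion events, each overwriting a uniformly placed tract
#' (`conversion_tract_fraction` of the alignment) with the homologous tract
#' of a random within-species paralog. High conversion rates homogenize
#' paralogs within species — the concerted-evolution signature.
#'
#' @param n_paralogs Paralogs per species.
#' @param root_length Alignment length in sites.
#' @param subst_rate Substitutions per site per time unit.
#' @param kappa Transition/transversion rate ratio.
#' @param duplication_depth,speciation_depth Times before present; the
#'   duplication must precede the speciation.
#' @param gene_conversion_rate Expected conversion events per terminal
#'   lineage.
#' @param conversion_tract_fraction Tract length as a fraction of the
#'   alignment, in (0, 1].
#' @param species Two species labels.
#' @param seed Optional integer seed.
#' @return An alignment tibble with columns `id`, `species`, `paralog`,
#'   `seq` (equal-length DNA strings).
#' @export
simulate_gene_family <- function(n_paralogs = 4L, root_length = 1000L,
                                 subst_rate = 0.01, kappa = 2,
                                 duplication_depth = 3, speciation_depth = 1,
                                 gene_conversion_rate = 0,
                                 conversion_tract_fraction = 0.2,
                                 species = c("speciesA", "speciesB"),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_paralogs >= 2, root_length >= 1, subst_rate >= 0, kappa > 0,
            duplication_depth > speciation_depth, speciation_depth > 0,
            gene_conversion_rate >= 0, length(species) == 2,
            conversion_tract_fraction > 0, conversion_tract_fraction <= 1)
  root <- sample.int(4L, root_length, replace = TRUE)
  par_anc <- lapply(seq_len(n_paralogs), function(p) {
    evolve_k2p(root, subst_rate * (duplication_depth - speciation_depth), kappa)
  })
  tips <- list()
  for (s in species) {
    for (p in seq_len(n_paralogs)) {
      tips[[paste(s, p, sep = ".")]] <-
        evolve_k2p(par_anc[[p]], subst_rate * speciation_depth, kappa)
    }
  }
  # post-speciation gene conversion, applied within each species
  tract <- max(1L, round(conversion_tract_fraction * root_length))
  for (s in species) {
    n_ev <- rpois(n_paralogs, gene_conversion_rate)
    events <- rep(seq_len(n_paralogs), n_ev)
    if (length(events) > 1) events <- sample(events)
    for (recip in events) {
      donor <- sample(setdiff(seq_len(n_paralogs), recip), 1L)
      start <- sample.int(root_length - tract + 1L, 1L)
      idx <- start:(start + tract - 1L)
      key_r <- paste(s, recip, sep = ".")
      key_d <- paste(s, donor, sep = ".")
      tips[[key_r]][idx] <- tips[[key_d]][idx]
    }
  }
  tibble(
    id = names(tips),
    species = rep(species, each = n_paralogs),
    paralog = rep(paste0("P", seq_len(n_paralogs)), times = 2L),
    seq = vapply(tips, function(x) paste(NUC[x], collapse = ""), character(1),
                 USE.NAMES = FALSE)
  )
}

#' Simulate CRISPR-edited amplicon reads
#'
#' Each read is the reference unchanged with probability `unedited_fraction`;
#' otherwise it carries a single indel at the cut site, with signed length
#' drawn from `indel_spectrum` (negative = deletion, positive = insertion of
#' random bases). Optionally adds uniform substitution errors.
#'
#' @param reference Reference amplicon sequence (string or one-row tibble
#'   with a `seq` column).
#' @param cut_site 0-based offset of the nuclease cut within the reference;
#'   deletions remove bases starting at this offset, insertions are placed
#'   before it.
#' @param n_reads Number of reads.
#' @param indel_spectrum Named numeric vector of probabilities, names being
#'   signed indel lengths (e.g. `c("-3" = 0.4, "1" = 0.6)`); together with
#'   `unedited_fraction` these must sum to 1.
#' @param unedited_fraction Fraction of unedited reads.
#' @param error_rate Per-base substitution error rate (default 0).
#' @param seed Optional integer seed.
#' @return A tibble with columns `id`, `seq`, and ground truth `true_indel`
#'   (signed net length, 0 if unedited) and `true_class` (`unedited`,
#'   `in_frame`, `frameshift`).
#' @export
simulate_amplicon_reads <- function(reference, cut_site, n_reads = 1000L,
                                    indel_spectrum = c("-1" = 1),
                                    unedited_fraction = 0, error_rate = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(reference)) reference <- reference$seq[1]
  L <- nchar(reference)
  stopifnot(cut_site >= 0, cut_site < L, n_reads >= 1,
            unedited_fraction >= 0, unedited_fraction <= 1)
  lens <- as.integer(names(indel_spectrum))
  probs <- as.numeric(indel_spectrum)
  if (abs(sum(probs) + unedited_fraction - 1) > 1e-8) {
    abort("indel_spectrum probabilities plus unedited_fraction must sum to 1")
  }
  if (any(lens == 0)) abort("indel length 0 is not an edit; use unedited_fraction")
  if (any(-lens > L - cut_site)) abort("deletion longer than reference downstream of cut")
  edited <- runif(n_reads) >= unedited_fraction
  indel <- integer(n_reads)
  if (any(edited)) {
    indel[edited] <- sample(lens, sum(edited), replace = TRUE, prob = probs)
  }
  seqs <- vapply(indel, function(d) apply_indel(reference, cut_site, d), character(1))
  if (error_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      x <- strsplit(s, "")[[1]]
      hit <- which(runif(length(x)) < error_rate)
      for (i in hit) x[i] <- sample(setdiff(NUC, x[i]), 1L)
      paste(x, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  tibble(
    id = sprintf("read%05d", seq_len(n_reads)),
    seq = seqs,
    true_indel = indel,
    true_class = dplyr::case_when(indel == 0 ~ "unedited",
                                  indel %% 3 == 0 ~ "in_frame",
                                  TRUE ~ "frameshift")
  )
}

apply_indel <- function(reference, cut_site, d) {
  if (d == 0) return(reference)
  left <- substr(reference, 1L, cut_site)           # bases before the cut
  right <- substr(reference, cut_site + 1L, nchar(reference))
  if (d < 0) {
    paste0(left, substr(right, -d + 1L, nchar(right)))
  } else {
    paste0(left, paste(sample(NUC, d, replace = TRUE), collapse = ""), right)
  }
}
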