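#' Read a FASTA file into a tibble of sequence records
#'
#' One row per record: `id` (first whitespace-delimited token of the header),
#' `description` (remainder of the header, possibly empty), `seq` (uppercased,
#' gaps preserved) and `alphabet` (`"dna"` or `"protein"`, guessed from the
#' residue composition).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `seq`, `alphabet`.
#'   An empty file yields a zero-row tibble.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(id = character(), description = character(),
                  seq = character(), alphabet = character()))
  }
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) abort("malformed FASTA: line 1 is not a header")
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S+", "", headers))
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  # records with no sequence lines are missing from `seqs`
  seq_full <- setNames(character(length(ids)), as.character(seq_len(length(ids))))
  seq_full[names(seqs)] <- seqs
  empty <- !nzchar(seq_full)
  if (any(empty)) {
    abort(paste0("empty sequence for record(s): ",
                 paste(ids[empty], collapse = ", ")))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  tibble(id = ids, description = desc, seq = unname(seq_full),
         alphabet = vapply(seq_full, guess_alphabet, character(1), USE.NAMES = FALSE))
}

guess_alphabet <- function(seq) {
  res <- strsplit(gsub("-", "", seq), "")[[1]]
  # ambiguity codes overlap amino-acid letters, so classify by composition
  if (mean(res %in% c("A", "C", "G", "T", "U", "N")) > 0.9) "dna" else "protein"
}

#' Write sequence records to FASTA
#'
#' @param records Tibble with columns `id`, `seq` and optionally `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  hdr <- paste0(">", records$id, ifelse(nzchar(desc), paste0(" ", desc), ""))
  body <- purrr::map2(records$seq, hdr, function(s, h) {
    c(h, substring(s, seq(1, nchar(s), width),
                   pmin(seq(1, nchar(s), width) + width - 1L, nchar(s))))
  })
  readr::write_lines(unlist(body), path)
  invisible(path)
}

#' Read a samtools-depth-style TSV into a per-base depth table
#'
#' Input columns are contig, 1-based position, integer depth (no header), the
#' dialect `samtools depth` emits. Positions absent from the file inside a
#' contig's observed span are filled in with depth 0, matching the tool's
#' default of omitting zero-depth sites. All positions in the returned table
#' are 0-based.
#'
#' @param path Path to a 3-column TSV.
#' @return A tibble with columns `contig`, `pos` (0-based), `depth`, one row
#'   per base of each contig's observed span.
#' @export
read_depth_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("contig", "pos", "depth"),
                         col_types = "cdd", progress = FALSE)
  if (nrow(raw) == 0L) {
    return(tibble(contig = character(), pos = integer(), depth = integer()))
  }
  bad <- which(raw$depth %% 1 != 0 | raw$depth < 0 | is.na(raw$depth) |
                 is.na(raw$pos) | raw$pos %% 1 != 0)
  if (length(bad) > 0) {
    abort(paste0("non-integer or negative depth/position at data line ", bad[1]))
  }
  raw |>
    dplyr::group_split(.data$contig) |>
    purrr::map_dfr(function(g) {
      lo <- min(g$pos)
      hi <- max(g$pos)
      d <- integer(hi - lo + 1L)
      d[g$pos - lo + 1L] <- as.integer(g$depth)
      tibble(contig = g$contig[1],
             pos = as.integer(seq(lo, hi) - 1L),
             depth = d)
    })
}

#' Write a depth table as samtools-depth-style TSV
#'
#' Inverse of [read_depth_tsv()] for gap-free tracks: positions are written
#' 1-based; zero-depth rows are kept so the round trip is exact.
#'
#' @param track Tibble with columns `contig`, `pos` (0-based), `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(track, path) {
  readr::write_tsv(dplyr::transmute(track, .data$contig,
                                    pos = .data$pos + 1L, .data$depth),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a ddPCR droplet-count CSV
#'
#' Expected columns: `sample_id`, `population`, `channel` (one of `target`,
#' `reference`), `positives`, `total`. Validates that counts are consistent
#' and that every sample carries both channels.
#'
#' @param path Path to a CSV with a header row.
#' @return A validated tibble of droplet counts.
#' @export
read_droplet_csv <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    sample_id = "c", population = "c", channel = "c",
    positives = "d", total = "d"), progress = FALSE)
  validate_droplet_table(tbl)
}

validate_droplet_table <- function(tbl) {
  need <- c("sample_id", "population", "channel", "positives", "total")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) abort(paste0("missing droplet column(s): ", paste(miss, collapse = ", ")))
  if (!all(tbl$channel %in% c("target", "reference"))) {
    abort("channel must be 'target' or 'reference'")
  }
  bad <- which(tbl$positives > tbl$total)
  if (length(bad)) abort(paste0("positives > total at row ", bad[1]))
  if (any(tbl$total <= 0)) abort("total droplets must be > 0")
  if (any(tbl$positives < 0)) abort("positives must be >= 0")
  chan_n <- dplyr::count(tbl, .data$sample_id, .data$channel)
  per_sample <- dplyr::count(chan_n, .data$sample_id)
  if (any(per_sample$n != 2L)) {
    abort(paste0("sample(s) missing a channel: ",
                 paste(per_sample$sample_id[per_sample$n != 2L], collapse = ", ")))
  }
  as_tibble(tbl)
}

#' Read a BED file of labeled regions
#'
#' BED coordinates are already 0-based half-open, the package's internal
#' convention, so they pass through unchanged.
#'
#' @param path Path to a 4-column BED (contig, start, end, label).
#' @return A tibble with columns `contig`, `start`, `end`, `label`.
#' @export
read_bed <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("contig", "start", "end", "label"),
                         col_types = "ciic", progress = FALSE)
  validate_regions(tbl)
}

validate_regions <- function(regions) {
  if (any(regions$start >= regions$end)) abort("region start must be < end")
  dup <- unique(regions$label[duplicated(regions$label)])
  if (length(dup)) abort(paste0("duplicate region label(s): ", paste(dup, collapse = ", ")))
  as_tibble(regions)
}

#' Write a BED file of labeled regions
#' @param regions Tibble with columns `contig`, `start`, `end`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(regions[, c("contig", "start", "end", "label")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are emitted to full precision; integer bootstrap supports
#' stored as node labels are written as internal-node labels.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

# Average residue masses (Da) of the 20 standard amino acids; adding one
# water (18.0153 Da) per chain gives the conventional predicted MW used to
# compare with SDS-PAGE estimates.
AVERAGE_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

WATER_MASS <- 18.0153

#' Predicted molecular weight of a protein
#'
#' Sum of average (not monoisotopic) residue masses plus one water, the
#' convention behind predicted-vs-gel molecular weights. Only the 20 standard
#' uppercase residues are accepted; anything else (including lowercase and
#' selenocysteine) raises an error naming the offending character and
#' position, rather than silently returning a wrong mass.
#'
#' @param seq A protein sequence string (or a one-row tibble with a `seq`
#'   column, as returned by [read_fasta()]).
#' @return Mass in Daltons.
#' @examples
#' protein_molecular_weight("G")  # 75.07
#' @export
protein_molecular_weight <- function(seq) {
  if (is.data.frame(seq)) seq <- seq$seq[1]
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) abort("empty protein sequence")
  res <- strsplit(seq, "")[[1]]
  unknown <- which(!res %in% names(AVERAGE_RESIDUE_MASS))
  if (length(unknown)) {
    abort(paste0("unknown residue '", res[unknown[1]], "' at position ", unknown[1]))
  }
  sum(AVERAGE_RESIDUE_MASS[res]) + WATER_MASS
}
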