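#' Mean read depth over labeled regions
#'
#' Arithmetic mean of per-base depth over each region's full span; bases the
#' track does not cover count as depth 0, so a region half outside the track
#' is averaged over its whole length.
#'
#' @param track Depth tibble with columns `contig`, `pos` (0-based), `depth`.
#' @param regions Region tibble (`contig`, `start`, `end`, `label`,
#'   0-based half-open).
#' @return A tibble with columns `label` and `mean_depth`.
#' @export
region_mean_depth <- function(track, regions) {
  validate_regions(regions)
  means <- purrr::pmap_dbl(
    regions[, c("contig", "start", "end", "label")],
    function(contig, start, end, label) {
      hit <- track$contig == contig & track$pos >= start & track$pos < end
      if (!any(hit)) abort(paste0("region '", label, "' does not overlap the track"))
      sum(track$depth[hit]) / (end - start)
    })
  tibble(label = regions$label, mean_depth = means)
}

#' Overall background depth of a genome
#'
#' The diploid baseline used to normalize copy-number estimates: the mean
#' (or median) per-base depth over background regions. By default the
#' background is every track base outside `exclude_regions` (typically the
#' paralog-homologous loci themselves).
#'
#' @param track Depth tibble.
#' @param background_regions Optional region tibble restricting the
#'   background; bases not covered by the track count as 0.
#' @param exclude_regions Optional region tibble removed from the default
#'   whole-track background.
#' @param stat `"mean"` (default) or `"median"`.
#' @return A single number.
#' @export
background_depth <- function(track, background_regions = NULL,
                             exclude_regions = NULL,
                             stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!is.null(background_regions)) {
    validate_regions(background_regions)
    depths <- unlist(purrr::pmap(
      background_regions[, c("contig", "start", "end")],
      function(contig, start, end) {
        d <- numeric(end - start)
        hit <- track$contig == contig & track$pos >= start & track$pos < end
        d[track$pos[hit] - start + 1L] <- track$depth[hit]
        d
      }))
  } else {
    keep <- rep(TRUE, nrow(track))
    if (!is.null(exclude_regions)) {
      for (i in seq_len(nrow(exclude_regions))) {
        keep <- keep & !(track$contig == exclude_regions$contig[i] &
                           track$pos >= exclude_regions$start[i] &
                           track$pos < exclude_regions$end[i])
      }
    }
    depths <- track$depth[keep]
  }
  if (length(depths) == 0) abort("empty background: no bases to average")
  if (stat == "mean") mean(depths) else stats::median(depths)
}

#' Total copy number of a gene family from read depth
#'
#' Implements the collapsed-locus estimator for segmentally duplicated
#' families: reads from every copy in the genome map onto the
#' paralog-homologous reference loci, so summing the mean depth over those
#' loci and normalizing by the genome's overall depth gives the total copy
#' number, scaled so that a single-copy locus at background depth scores the
#' ploidy (2 for a diploid):
#'
#'   cn = ploidy * sum_regions mean_depth(region) / background_depth
#'
#' @param track Depth tibble for one genome.
#' @param paralog_regions Region tibble of paralog-homologous loci.
#' @param background_regions Optional explicit background regions; default is
#'   everything outside `paralog_regions`.
#' @param genome_id Identifier carried into the result.
#' @param ploidy Scaling constant (2 for diploid genomes; overridable for
#'   haploid assemblies).
#' @param stat Background statistic, `"mean"` or `"median"`.
#' @return An object of class `depth_cn`; see [tidy.depth_cn()] and
#'   [glance.depth_cn()].
#' @export
estimate_total_cn <- function(track, paralog_regions, background_regions = NULL,
                              genome_id = "genome", ploidy = 2,
                              stat = c("mean", "median")) {
  region_depths <- region_mean_depth(track, paralog_regions)
  bg <- background_depth(track, background_regions,
                         exclude_regions = paralog_regions, stat = stat)
  if (bg == 0) abort("background depth is 0: copy number undefined")
  structure(
    list(genome_id = genome_id,
         region_depths = region_depths,
         background_depth = bg,
         ploidy = ploidy,
         estimated_total_cn = ploidy * sum(region_depths$mean_depth) / bg),
    class = "depth_cn")
}

#' @export
print.depth_cn <- function(x, ...) {
  cat("Read-depth copy-number estimate for", x$genome_id, "\n")
  cat("  background depth:", format(x$background_depth, digits = 4), "\n")
  cat("  regions:", nrow(x$region_depths),
      " summed mean depth:", format(sum(x$region_depths$mean_depth), digits = 4), "\n")
  cat("  estimated total copy number:",
      format(x$estimated_total_cn, digits = 4), "\n")
  invisible(x)
}

#' Per-region detail of a read-depth copy-number estimate
#' @param x A `depth_cn` object.
#' @param ... Unused.
#' @return A tibble with one row per paralog-homologous region: `genome_id`,
#'   `label`, `mean_depth`, `normalized_cn` (the region's own contribution,
#'   ploidy * mean/background).
#' @method tidy depth_cn
#' @export
tidy.depth_cn <- function(x, ...) {
  dplyr::mutate(x$region_depths,
                genome_id = x$genome_id,
                normalized_cn = x$ploidy * .data$mean_depth / x$background_depth,
                .before = 1)
}

#' One-row summary of a read-depth copy-number estimate
#' @param x A `depth_cn` object.
#' @param ... Unused.
#' @return A one-row tibble: `genome_id`, `n_regions`, `background_depth`,
#'   `estimated_total_cn`.
#' @method glance depth_cn
#' @export
glance.depth_cn <- function(x, ...) {
  tibble(genome_id = x$genome_id, n_regions = nrow(x$region_depths),
         background_depth = x$background_depth,
         estimated_total_cn = x$estimated_total_cn)
}

#' Cohort table of copy-number estimates across genomes
#'
#' @param results A list of `depth_cn` objects (one per genome).
#' @return A tibble `genome_id`, `estimated_total_cn`, sorted by genome id.
#' @export
cohort_table <- function(results) {
  if (length(results) == 0) abort("no results to tabulate")
  purrr::map_dfr(results, glance) |>
    dplyr::select("genome_id", "estimated_total_cn") |>
    dplyr::arrange(.data$genome_id)
}

#' Plot a depth track with region annotations
#'
#' @param track Depth tibble.
#' @param regions Optional region tibble shaded behind the depth line.
#' @return A ggplot object.
#' @export
plot_depth_track <- function(track, regions = NULL) {
  p <- ggplot2::ggplot(track, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_step(color = "grey30", linewidth = 0.3) +
    ggplot2::labs(x = "position (0-based)", y = "read depth") +
    ggplot2::facet_wrap(~contig, ncol = 1, scales = "free_x") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "firebrick")
  }
  p
}
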