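#' Poisson concentration estimate from droplet counts
#'
#' In digital PCR, template molecules partition into droplets under Poisson
#' statistics, so the mean number of molecules per droplet is recovered from
#' the positive fraction p as lambda = -ln(1 - p). A 95% Wilson score
#' interval on p (well behaved near p = 0) is transformed through the same
#' map to give the confidence bounds.
#'
#' @param positives Number of positive droplets (vectorized).
#' @param total Total droplets read.
#' @param conf_level Confidence level for the interval.
#' @return A tibble with columns `positives`, `total`, `lambda`, `ci_low`,
#'   `ci_high`.
#' @examples
#' estimate_lambda(500000, 1000000)  # lambda = ln 2
#' @export
estimate_lambda <- function(positives, total, conf_level = 0.95) {
  if (any(total <= 0)) abort("total droplets must be > 0")
  if (any(positives < 0) || any(positives > total)) {
    abort("positives must lie in [0, total]")
  }
  if (any(positives == total)) {
    abort("all droplets positive: channel saturated, lambda undefined")
  }
  p <- positives / total
  ci <- wilson_interval(positives, total, conf_level)
  tibble(positives = positives, total = total,
         lambda = -log(1 - p),
         ci_low = -log(1 - ci$low),
         ci_high = -log(1 - pmin(ci$high, 1 - 1e-15)))
}

wilson_interval <- function(x, n, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(center - half, 0), high = pmin(center + half, 1))
}

#' Copy number from target and reference channel concentrations
#'
#' The copy number per diploid genome is the concentration ratio scaled by
#' the reference gene's copy number: cn = `reference_copies` * lambda_target
#' / lambda_reference. Droplet volume cancels in the ratio, so no volume
#' parameter is needed. Confidence bounds propagate conservatively as the
#' ratio of the channel bounds.
#'
#' @param target,reference One-row tibbles from [estimate_lambda()] (or
#'   multi-row, matched by position).
#' @param reference_copies Copies of the reference gene per diploid genome
#'   (2 for a standard autosomal single-copy gene such as EIF2C1).
#' @return A tibble with columns `cn`, `ci_low`, `ci_high`.
#' @export
estimate_copy_number <- function(target, reference, reference_copies = 2L) {
  if (any(reference$lambda == 0)) {
    abort("no reference signal (lambda_reference = 0)")
  }
  tibble(cn = reference_copies * target$lambda / reference$lambda,
         ci_low = reference_copies * target$ci_low / reference$ci_high,
         ci_high = reference_copies * target$ci_high /
           pmax(reference$ci_low, .Machine$double.xmin))
}

#' Per-sample copy numbers from a droplet-count table
#'
#' Pipeline form of [estimate_lambda()] + [estimate_copy_number()]: takes the
#' two-channel droplet table (as read by [read_droplet_csv()] or produced by
#' [simulate_droplets()]) and returns one copy-number estimate per sample.
#'
#' @param droplets Tibble with columns `sample_id`, `population`, `channel`,
#'   `positives`, `total`.
#' @param reference_copies Reference gene copies per diploid genome.
#' @return A tibble with columns `sample_id`, `population`,
#'   `lambda_target`, `lambda_reference`, `cn`, `ci_low`, `ci_high`.
#' @examples
#' simulate_droplets(7.5, n_samples = 2, seed = 1) |> ddpcr_copy_number()
#' @export
ddpcr_copy_number <- function(droplets, reference_copies = 2L) {
  droplets <- validate_droplet_table(droplets)
  wide <- droplets |>
    tidyr::pivot_wider(id_cols = c("sample_id", "population"),
                       names_from = "channel",
                       values_from = c("positives", "total"))
  lt <- estimate_lambda(wide$positives_target, wide$total_target)
  lr <- estimate_lambda(wide$positives_reference, wide$total_reference)
  est <- estimate_copy_number(lt, lr, reference_copies)
  tibble(sample_id = wide$sample_id, population = wide$population,
         lambda_target = lt$lambda, lambda_reference = lr$lambda,
         cn = est$cn, ci_low = est$ci_low, ci_high = est$ci_high)
}

#' Bin copy-number estimates into number classes
#'
#' Counts estimates in half-open bins \[c - w/2, c + w/2) whose centers are
#' integer multiples of the bin width, the binning used to display
#' population copy-number histograms.
#'
#' @param estimates Tibble with a `cn` column (e.g. from
#'   [ddpcr_copy_number()]), or a numeric vector.
#' @param bin_width Bin width (default 0.5 copies).
#' @return A tibble with columns `bin_center` and `count`; total count equals
#'   the number of estimates. Has class `cn_bins` for [autoplot.cn_bins()].
#' @export
bin_copy_numbers <- function(estimates, bin_width = 0.5) {
  if (bin_width <= 0) abort("bin_width must be > 0")
  cn <- if (is.data.frame(estimates)) estimates$cn else estimates
  if (length(cn) == 0) abort("no estimates to bin")
  centers <- bin_width * floor(cn / bin_width + 0.5)
  out <- dplyr::count(tibble(bin_center = centers), .data$bin_center,
                      name = "count")
  attr(out, "bin_width") <- bin_width
  class(out) <- c("cn_bins", class(out))
  out
}

#' Histogram of binned copy numbers
#'
#' @param object A `cn_bins` tibble from [bin_copy_numbers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cn_bins
#' @export
autoplot.cn_bins <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.9,
                      fill = "steelblue") +
    ggplot2::labs(x = "copies per diploid genome", y = "individuals") +
    ggplot2::theme_minimal()
}

#' Per-population summary of copy-number estimates
#'
#' Sample mean and (n-1) standard deviation per population, with a pooled
#' row across all samples appended. For a population with a single sample
#' the standard deviation is reported as `NA`.
#'
#' @param estimates Tibble with `population` and `cn` columns.
#' @return A tibble with columns `population`, `n`, `mean`, `sd`; the last
#'   row is the pooled summary labeled `"(pooled)"`.
#' @export
population_summary <- function(estimates) {
  if (nrow(estimates) == 0) abort("no estimates to summarize")
  per_pop <- estimates |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$cn),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$cn), NA_real_),
                     .groups = "drop")
  pooled <- tibble(population = "(pooled)", n = nrow(estimates),
                   mean = mean(estimates$cn),
                   sd = ifelse(nrow(estimates) > 1, stats::sd(estimates$cn),
                               NA_real_))
  dplyr::bind_rows(per_pop, pooled)
}
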