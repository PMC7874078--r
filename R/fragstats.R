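# Fragment-size distribution and FFT periodicity.
#
# ATAC-seq libraries show a sub-nucleosomal mode (<150 bp, nucleosome-free
# regions) plus modes at integer multiples of the inter-nucleosome spacing
# (~190-200 bp).  The spacing is estimated as the dominant period of the
# detrended 1-bp fragment-length histogram.

#' Fragment-length histogram at 1-bp resolution
#'
#' @param fragments Fragment `GRanges` (or an integer vector of lengths).
#' @param max_length Longest length tracked (bp). Default 1000.
#' @return A `length_histogram`: `counts` indexed by length `1..max_length`,
#'   plus `max_length` and `n_excluded` (fragments longer than `max_length`).
#' @export
length_histogram <- function(fragments, max_length = 1000) {
  if (max_length < 1) stop("max_length must be >= 1")
  lens <- if (is(fragments, "GRanges")) width(fragments)
          else as.integer(fragments)
  if (length(lens) == 0) warning("no fragments; histogram is empty")
  n_long <- sum(lens > max_length)
  if (n_long > 0)
    warning(sprintf("%d fragments longer than %d bp excluded", n_long,
                    max_length))
  counts <- tabulate(lens[lens >= 1 & lens <= max_length], nbins = max_length)
  structure(list(counts = counts, max_length = as.integer(max_length),
                 n_excluded = n_long),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("fragment-length histogram: %d fragments, 1..%d bp\n",
              sum(x$counts), x$max_length))
  invisible(x)
}

#' Write a histogram as TSV (length, count)
#' @param hist A `length_histogram`.
#' @param path Output TSV.
#' @export
write_length_histogram <- function(hist, path) {
  write.table(data.frame(length = seq_along(hist$counts),
                         count = hist$counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# centered moving average with edge shrinkage (window truncated at the ends)
.moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Estimate nucleosome periodicity of the fragment-length histogram by FFT
#'
#' The histogram, restricted to lengths of at least the search band's lower
#' edge (the nucleosome ladder lives above the sub-nucleosomal mode), is
#' detrended by subtracting a centered moving average, tapered with a Hann
#' window to suppress spectral leakage, zero-mean adjusted, zero-padded
#' eight-fold to a power of two for a fine frequency grid, and Fourier
#' transformed.  The period is `1/f*` where `f*` maximizes spectral power
#' among frequencies whose period falls in `search_band`, refined by
#' parabolic interpolation over the three bins around the maximum.
#' `has_signal` is FALSE when the maximal band power is below 4x the median
#' band power (or the spectrum is identically zero).
#'
#' @param hist A `length_histogram`.
#' @param search_band Numeric length-2, period search band in bp.
#'   Default `c(100, 400)`, bracketing the ~190-200 bp nucleosome spacing.
#' @param detrend_window Odd moving-average width (bp), >= 3. Default 51.
#' @return A `period_estimate`: `period` (bp), `search_band`,
#'   `power_spectrum` (data.frame frequency, period_bp, power), `has_signal`.
#' @export
estimate_period_fft <- function(hist, search_band = c(100, 400),
                                detrend_window = 51) {
  stopifnot(inherits(hist, "length_histogram"))
  if (length(search_band) != 2 || search_band[1] <= 2 ||
      search_band[2] <= search_band[1])
    stop("search_band must be increasing and within (2, max_length)")
  if (search_band[2] > hist$max_length)
    stop("histogram shorter than search band maximum")
  if (detrend_window < 3 || detrend_window %% 2 == 0)
    stop("detrend_window must be odd and >= 3")
  fit_min <- max(1L, floor(search_band[1]))
  x <- as.numeric(hist$counts[fit_min:hist$max_length])
  detr <- x - .moving_average(x, detrend_window)
  n <- length(detr)
  detr <- detr * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  detr <- detr - mean(detr)            # exact zero at f = 0
  nfft <- 2^ceiling(log2(8 * n))
  padded <- c(detr, numeric(nfft - n))
  spec <- fft(padded)
  k <- 0:(nfft %/% 2)
  freq <- k / nfft                     # cycles per bp
  power <- Mod(spec[k + 1])^2
  period <- ifelse(freq > 0, 1 / freq, Inf)
  in_band <- period >= search_band[1] & period <= search_band[2]
  if (!any(in_band)) stop("search band contains no spectral bins")
  band_power <- power[in_band]
  imax_band <- which.max(band_power)
  imax <- which(in_band)[imax_band]
  has_signal <- max(band_power) > 0 &&
    max(band_power) >= 4 * stats::median(band_power)
  # parabolic refinement on the power spectrum around the peak bin
  k_star <- k[imax]
  if (imax > 1 && imax < length(power)) {
    p1 <- power[imax - 1]; p2 <- power[imax]; p3 <- power[imax + 1]
    denom <- p1 - 2 * p2 + p3
    delta <- if (abs(denom) > 0) 0.5 * (p1 - p3) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    k_star <- k[imax] + delta
  }
  est <- if (k_star > 0) nfft / k_star else Inf
  structure(list(
    period = est,
    search_band = search_band,
    power_spectrum = data.frame(frequency = freq, period_bp = period,
                                power = power),
    has_signal = has_signal
  ), class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  cat(sprintf("estimated period: %.1f bp (band %g-%g bp, signal: %s)\n",
              x$period, x$search_band[1], x$search_band[2],
              ifelse(x$has_signal, "yes", "no")))
  invisible(x)
}

#' Write the band-limited power spectrum as TSV (period_bp, power)
#' @param estimate A `period_estimate`.
#' @param path Output TSV.
#' @export
write_period_spectrum <- function(estimate, path) {
  sp <- estimate$power_spectrum
  keep <- sp$period_bp >= estimate$search_band[1] &
          sp$period_bp <= estimate$search_band[2]
  write.table(sp[keep, c("period_bp", "power")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot the fragment-size distribution
#' @param hist A `length_histogram`.
#' @param path Optional PNG path; plots to the active device when NULL.
#' @export
plot_fragment_sizes <- function(hist, path = NULL) {
  if (!is.null(path)) { grDevices::png(path, 900, 500); on.exit(grDevices::dev.off()) }
  graphics::plot(seq_along(hist$counts), hist$counts, type = "h",
                 xlab = "fragment length (bp)", ylab = "fragments",
                 main = "Fragment-size distribution")
  invisible(hist)
}

#' Plot the period power spectrum
#' @param estimate A `period_estimate`.
#' @param path Optional PNG path.
#' @export
plot_period_spectrum <- function(estimate, path = NULL) {
  if (!is.null(path)) { grDevices::png(path, 900, 500); on.exit(grDevices::dev.off()) }
  sp <- estimate$power_spectrum
  keep <- is.finite(sp$period_bp) &
    sp$period_bp >= estimate$search_band[1] &
    sp$period_bp <= estimate$search_band[2]
  graphics::plot(sp$period_bp[keep], sp$power[keep], type = "l",
                 xlab = "period (bp)", ylab = "power",
                 main = sprintf("FFT period estimate: %.0f bp", estimate$period))
  graphics::abline(v = estimate$period, lty = 2)
  invisible(estimate)
}
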