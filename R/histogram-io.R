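#' Construct a normalized histogram table
#'
#' @param values per-bin densities (1/Angstrom, >= 0); renormalized so
#'   that `sum(values) * binWidth == 1` unless already normalized
#' @param binWidth bin width Delta-r (Angstrom); bin n is centred at
#'   `n * binWidth`
#' @return a [HistogramTable]
#' @examples
#' h <- histogramTable(dnorm(1:60, mean = 30, sd = 3), binWidth = 1)
#' sum(histValues(h)) * binWidth(h)
#' @export
histogramTable <- function(values, binWidth = 1) {
  if (any(values < 0)) stop("histogram values must be >= 0")
  total <- sum(values) * binWidth
  if (total <= 0) stop("histogram has zero total mass; not normalizable")
  new("HistogramTable", values = values / total, binWidth = binWidth)
}

#' Read a target distance histogram from a two-column text table
#'
#' Expects whitespace-delimited `bin_center value` rows (comments with
#' `#`).  Bin centres must lie on the `n * binWidth` grid; bins missing
#' from the file are filled with zero and the table is renormalized so
#' that \eqn{\sum_n h(n)\,\Delta r = 1}, the convention under which
#' target distributions and ensemble histograms are compared.
#'
#' @param path path to the table
#' @param binWidth bin width Delta-r (Angstrom)
#' @param nBins number of bins (grid is `1:nBins * binWidth`)
#' @return a [HistogramTable]
#' @seealso [writeHistogramTable()], [smoothedHistogram()]
#' @export
readHistogramTable <- function(path, binWidth = 1, nBins = 60L) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("center", "value"))
  if (nrow(tab) == 0L) stop("empty histogram table: ", path)
  if (any(tab$value < 0))
    stop("negative histogram value in ", path)
  idx <- tab$center / binWidth
  if (any(abs(idx - round(idx)) > 1e-6))
    stop("bin centers not on the n*binWidth grid in ", path)
  idx <- as.integer(round(idx))
  if (any(idx < 1L | idx > nBins))
    stop("bin center outside the 1..nBins grid in ", path)
  values <- numeric(nBins)
  values[idx] <- tab$value
  histogramTable(values, binWidth)
}

#' Write a histogram table as two-column text
#'
#' @param h a [HistogramTable]
#' @param path output path
#' @param comment optional comment line written after `#`
#' @return `path`, invisibly
#' @export
writeHistogramTable <- function(h, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines("# bin_center_A  density_per_A", con)
  writeLines(sprintf("%10.4f %14.8g", binCenters(h), histValues(h)), con)
  invisible(path)
}
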