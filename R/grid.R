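#' Masked human-population grid
#'
#' Container for a gridded population-count raster: a numeric matrix of
#' people per cell, a logical mask of cells belonging to the study region
#' (e.g. sub-Saharan Africa), and the nominal cell area in km^2 used to
#' convert density thresholds to per-cell count thresholds.
#'
#' @param values Numeric matrix of per-cell population counts.
#' @param mask Logical matrix of the same shape; `TRUE` cells are in the
#'   study region. Defaults to all finite, non-NA cells.
#' @param cell_area Cell area in km^2 (default 21, the nominal resolution
#'   of the 2.5 arc-minute gridded population product near the equator).
#' @param xllcorner,yllcorner,cellsize Optional georeferencing for ESRI
#'   ASCII round-trips.
#' @return An object of class `population_grid`.
#' @export
population_grid <- function(values, mask = NULL, cell_area = 21,
                            xllcorner = 0, yllcorner = 0, cellsize = 1) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(values), dim(mask))) {
    abort("mask and values must have identical shape")
  }
  mask <- mask & !is.na(values)
  if (any(values[mask] < 0)) {
    abort("negative population counts on masked cells")
  }
  structure(list(values = values, mask = mask, cell_area = cell_area,
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize),
            class = "population_grid")
}

#' @export
print.population_grid <- function(x, ...) {
  cat(sprintf(paste0("<population_grid: %d x %d cells, %d masked-in, ",
                     "cell area %g km^2>\n"),
              nrow(x$values), ncol(x$values), sum(x$mask), x$cell_area))
  invisible(x)
}

n_masked <- function(g) sum(g$mask)

#' Read or write an ESRI ASCII raster grid
#'
#' `read_ascii_grid()` parses the standard ESRI ASCII format (header lines
#' `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, optional
#' `NODATA_value`, then `nrows` rows of values, top row first); NODATA
#' cells are excluded from the mask. `write_ascii_grid()` writes the same
#' format so that a read/write round-trip preserves values and header.
#'
#' @param path File path.
#' @param cell_area Cell area in km^2 attached to the grid (default 21).
#' @return `read_ascii_grid()` returns a [population_grid];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, cell_area = 21) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    abort(paste0("ESRI ASCII header incomplete; need ",
                 paste(setdiff(need, names(hdr)), collapse = ", ")))
  }
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != hdr$ncols * hdr$nrows) {
    abort(sprintf("grid body has %d values, header promises %d x %d",
                  length(body), hdr$nrows, hdr$ncols))
  }
  values <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  mask <- matrix(TRUE, hdr$nrows, hdr$ncols)
  if (!is.null(hdr$nodata_value)) {
    mask <- values != hdr$nodata_value
    values[!mask] <- NA_real_
  }
  population_grid(values, mask, cell_area = cell_area,
                  xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner,
                  cellsize = hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @param g A [population_grid].
#' @param nodata NODATA marker written for unmasked cells (default -9999).
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "population_grid"))
  vals <- g$values
  vals[!g$mask] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(vals)),
           sprintf("nrows %d", nrow(vals)),
           sprintf("xllcorner %.10g", g$xllcorner),
           sprintf("yllcorner %.10g", g$yllcorner),
           sprintf("cellsize %.10g", g$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(vals, 1, function(r) paste(format(r, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Split grid cells at a population-density threshold
#'
#' Divides the masked cells into a high-density group (count strictly above
#' `threshold_density * cell_area`) and a low-density group (the rest);
#' cells exactly at the threshold count as low.
#'
#' @param g A [population_grid].
#' @param threshold_density Threshold in people per km^2 (default 100).
#' @return A one-row tibble: `threshold_density`, `threshold_count`
#'   (people per cell), `n_high`, `n_low`, `n_masked`.
#' @export
density_split <- function(g, threshold_density = 100) {
  stopifnot(inherits(g, "population_grid"))
  if (!is.numeric(threshold_density) || threshold_density <= 0) {
    abort("threshold_density must be positive")
  }
  if (n_masked(g) == 0) abort("empty mask")
  threshold_count <- threshold_density * g$cell_area
  counts <- g$values[g$mask]
  n_high <- sum(counts > threshold_count)
  tibble::tibble(threshold_density = threshold_density,
                 threshold_count = threshold_count,
                 n_high = n_high, n_low = length(counts) - n_high,
                 n_masked = length(counts))
}

#' Exact probability that all invasion sites fall in the high-density group
#'
#' Under the null hypothesis that invasion localities are placed
#' independently and uniformly over the masked cells, the probability that
#' all `k` sites land in the high-density group is
#' \eqn{(n_{high}/n_{total})^k}. The without-replacement (hypergeometric)
#' analogue and, when only `k_in_high < k` sites are in the high group, the
#' binomial upper tail \eqn{P(X \ge k_{in\_high})} are reported alongside.
#'
#' @param n_high Number of high-density cells.
#' @param n_total Total number of masked cells.
#' @param k Number of invasion sites.
#' @param k_in_high Number of sites observed in the high group (default
#'   `k`).
#' @return A one-row tibble: `n_high`, `n_total`, `k`, `k_in_high`,
#'   `p_exact` (independent uniform placement), `p_hypergeom`
#'   (without replacement) and `p_binom_tail`.
#' @examples
#' split_probability(n_high = 76391, n_total = 988224, k = 6)
#' @export
split_probability <- function(n_high, n_total, k, k_in_high = k) {
  if (n_total <= 0) abort("n_total must be positive")
  if (n_high < 0 || n_high > n_total) abort("need 0 <= n_high <= n_total")
  if (k < 0 || k_in_high < 0 || k_in_high > k) {
    abort("need 0 <= k_in_high <= k")
  }
  pr <- n_high / n_total
  # primary definition: all k sites independently, uniformly placed land in
  # the high group; when k_in_high < k the binomial tail is the usable answer
  p_exact <- if (k_in_high == k) pr^k else NA_real_
  p_hyper <- if (k_in_high == k) {
    if (k > n_high) 0 else prod((n_high - seq_len(k) + 1) /
                                  (n_total - seq_len(k) + 1))
  } else {
    NA_real_
  }
  p_binom_tail <- sum(stats::dbinom(k_in_high:k, k, pr))
  tibble::tibble(n_high = n_high, n_total = n_total, k = k,
                 k_in_high = k_in_high, p_exact = p_exact,
                 p_hypergeom = p_hyper, p_binom_tail = p_binom_tail)
}

#' Validate invasion sites against a grid
#'
#' @param g A [population_grid].
#' @param sites A data frame with columns `locality`, `row`, `col` (1-based
#'   cell indices). Records falling in the same cell are collapsed to one
#'   site (one locality, one cell).
#' @return A deduplicated sites tibble.
#' @export
validate_sites <- function(g, sites) {
  sites <- tibble::as_tibble(sites)
  if (!all(c("locality", "row", "col") %in% names(sites))) {
    abort("sites need columns locality, row, col")
  }
  off <- sites$row < 1 | sites$row > nrow(g$values) |
    sites$col < 1 | sites$col > ncol(g$values)
  if (any(off)) {
    abort(paste0("site(s) outside the grid: ",
                 paste(sites$locality[off], collapse = ", ")))
  }
  offmask <- !g$mask[cbind(sites$row, sites$col)]
  if (any(offmask)) {
    abort(paste0("site(s) on unmasked cells: ",
                 paste(sites$locality[offmask], collapse = ", ")))
  }
  dplyr::distinct(sites, .data$row, .data$col, .keep_all = TRUE)
}
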