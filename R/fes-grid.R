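#' Free-energy surface on a regular grid
#'
#' A `fes_grid` holds free energies F (kcal/mol) on a regular 1D or 2D
#' binning of collective-variable space, together with a visited mask:
#' bins never visited by the estimator carry `NA`, not an imputed value.
#' Visited free energies are anchored so their minimum is zero (the
#' convention used when reading depths off a surface).
#'
#' @param breaks list of bin-edge vectors, one per axis.
#' @param values numeric vector (1D) or matrix (2D) of free energies;
#'   `NA` marks unvisited bins.
#' @param labels CV names, one per axis.
#' @param units per-axis units (`"A"` or `"rad"`).
#' @param temperature temperature (K) at which F was estimated.
#' @param counts optional occupancy counts per bin.
#' @param anchor shift visited values so `min(F) == 0` (default TRUE).
#' @return Object of class `fes_grid`.
#' @export
fes_grid <- function(breaks, values, labels, units = rep("A", length(breaks)),
                     temperature = 300, counts = NULL, anchor = TRUE) {
  d <- length(breaks)
  stopifnot(d %in% 1:2, length(labels) == d, length(units) == d)
  breaks <- lapply(breaks, function(b) {
    b <- as.numeric(b)
    if (length(b) < 2L || is.unsorted(b, strictly = TRUE))
      stop_param("bin edges must be strictly increasing")
    b
  })
  nb <- vapply(breaks, function(b) length(b) - 1L, integer(1))
  if (d == 1L) {
    values <- as.numeric(values)
    if (length(values) != nb[1]) stop_param("values length does not match bins")
  } else {
    values <- as.matrix(values)
    if (!identical(dim(values), as.integer(nb)))
      stop_param("values dimensions do not match bins")
  }
  visited <- is.finite(values)
  if (anchor && any(visited)) values <- values - min(values[visited])
  if (!is.null(counts)) {
    if (length(counts) != length(values)) stop_param("counts shape mismatch")
  }
  structure(list(dim = d, labels = labels, units = units, breaks = breaks,
                 values = values, visited = visited, counts = counts,
                 temperature = temperature),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  nb <- vapply(x$breaks, function(b) length(b) - 1L, integer(1))
  cat(sprintf("Free-energy surface on %s bins along %s; %d/%d bins visited\n",
              paste(nb, collapse = " x "), paste(x$labels, collapse = ", "),
              sum(x$visited), length(x$visited)))
  if (any(x$visited))
    cat(sprintf("  F range over visited bins: [0, %.3f] kcal/mol at T = %g K\n",
                max(x$values[x$visited]), x$temperature))
  invisible(x)
}

#' Bin centers of a free-energy grid
#' @param fes a [fes_grid()].
#' @return list of numeric vectors of bin centers, one per axis.
#' @export
fes_centers <- function(fes) {
  lapply(fes$breaks, function(b) (b[-1] + b[-length(b)]) / 2)
}

fes_bin_widths <- function(fes) {
  lapply(fes$breaks, diff)
}
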