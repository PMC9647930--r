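#' Spatial gradient magnitude of a per-neuron field
#'
#' Maps a per-neuron scalar field onto the electrode lattice and computes the
#' finite-difference gradient: central differences at interior electrodes,
#' one-sided at the edges, with the lattice pitch as spacing. Returns the
#' per-neuron gradient magnitude `sqrt(gx^2 + gy^2)` in field-units per um.
#'
#' @param values numeric vector, one value per neuron
#' @param geom a [NetworkGeometry-class]
#' @return numeric vector of gradient magnitudes, one per neuron
#' @examples
#' g <- buildGeometry(1, nExc = 13, nInh = 7, gridShape = c(5, 4))
#' all(spatialGradient(rep(3, 20), g) == 0)  # constant field
#' @export
spatialGradient <- function(values, geom) {
  stopifnot(is(geom, "NetworkGeometry"))
  pos <- positions(geom)
  if (length(values) != nrow(pos))
    stop("need one value per neuron (", nrow(pos), "), got ", length(values))
  nc <- geom@gridShape[1]
  nr <- geom@gridShape[2]
  h <- geom@pitch
  col <- round(pos[, 1] / h) + 1L
  row <- round(pos[, 2] / h) + 1L
  fld <- matrix(NA_real_, nr, nc)
  fld[cbind(row, col)] <- values

  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  if (nc > 1) {
    gx[, 1] <- (fld[, 2] - fld[, 1]) / h
    gx[, nc] <- (fld[, nc] - fld[, nc - 1]) / h
    if (nc > 2)
      gx[, 2:(nc - 1)] <- (fld[, 3:nc] - fld[, 1:(nc - 2)]) / (2 * h)
  }
  if (nr > 1) {
    gy[1, ] <- (fld[2, ] - fld[1, ]) / h
    gy[nr, ] <- (fld[nr, ] - fld[nr - 1, ]) / h
    if (nr > 2)
      gy[2:(nr - 1), ] <- (fld[3:nr, ] - fld[1:(nr - 2), ]) / (2 * h)
  }
  mag <- sqrt(gx^2 + gy^2)
  mag[cbind(row, col)]
}

#' Six summary statistics of a per-neuron field and its spatial gradient
#'
#' The recurring summary block: mean, maximum and standard deviation of the
#' field, and mean, maximum and standard deviation of its spatial-gradient
#' magnitude.
#'
#' @param values per-neuron scalars
#' @param geom a [NetworkGeometry-class]
#' @param prefix name prefix for the returned vector
#' @return named numeric vector of length 6:
#'   `<prefix>_mean, _max, _sd, _grad_mean, _grad_max, _grad_sd`
#' @export
fieldSummary <- function(values, geom, prefix) {
  grad <- spatialGradient(values, geom)
  out <- c(mean(values), max(values), stats::sd(values),
           mean(grad), max(grad), stats::sd(grad))
  names(out) <- paste0(prefix, c("_mean", "_max", "_sd",
                                 "_grad_mean", "_grad_max", "_grad_sd"))
  out
}

#' Firing-rate features
#'
#' Per-neuron firing rate (spikes per second over the recording) summarized
#' as: maximum rate, maximum of the rate's spatial-gradient magnitude, mean
#' rate, and mean gradient magnitude.
#'
#' @param result a [SimulationResult-class]
#' @return named numeric vector of length 4
#' @export
frequencyFeatures <- function(result) {
  rates <- firingRates(result)
  grad <- spatialGradient(rates, geometry(result))
  c(freq_max = max(rates), freq_grad_max = max(grad),
    freq_mean = mean(rates), freq_grad_mean = mean(grad))
}
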