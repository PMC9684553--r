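# Iterative retrieval of the sample thickness map (z-map) and the
# mu_s(E0)*rho map from a single STXM transmission map.

#' Derive a thickness map from an STXM transmission map
#'
#' Beer-Lambert inversion made identifiable by the method's priors: the
#' average density, the maximum expected thickness, and the admissible
#' ranges of both. The most absorbing pixel(s) are assigned `h_max`, fixing
#' a globally constant initial `mu_s(E0) rho`; every other thickness
#' follows by inversion. Each iteration then flags pixels whose thickness
#' changes too abruptly relative to the sample-average rate of change (the
#' mean over footprint pixels of the maximum absolute thickness difference
#' to any of the 8 nearest neighbours, background counting as zero
#' thickness), replaces the flagged thicknesses with the neighbour mean and
#' recomputes their `mu_s rho` from the transmission, so
#' `exp(-mu_rho * z)` reproduces the input exactly at every iteration. The
#' recomputed `mu_s rho` is confined to the admissible density band
#' (`rho_range` around the average): without this physical bound the
#' neighbour-mean replacement erodes every sample edge indefinitely,
#' because a rim pixel is always abrupt with respect to the empty
#' background. Flags are processed simultaneously from a frozen snapshot
#' per iteration; iteration stops early once no pixel moves.
#'
#' @param stxm transmission matrix in (0, 1].
#' @param rho_avg average sample density in g/cm^3 (carried in the state;
#'   splitting `mu_rho` into `mu_s * rho` downstream uses it).
#' @param h_max maximum expected sample thickness in um.
#' @param n_iter maximum number of iterations.
#' @param rho_range admissible fractional deviation of the local density
#'   (hence of `mu_s rho`) from the average.
#' @param neighborhood 4 or 8 nearest neighbours.
#' @param background_threshold pixels with transmission above this are
#'   empty (thickness 0) and excluded from all statistics.
#' @return Object of class `zmap_state`: `z` (um), `mu_rho` (um^-1),
#'   `footprint` (logical), `rho_avg`, `h_max`, `iterations`, `converged`.
#' @export
derive_zmap <- function(stxm, rho_avg, h_max, n_iter = 1000,
                        rho_range = 0.10, neighborhood = 8,
                        background_threshold = 0.999) {
  if (h_max <= 0) stop("h_max must be positive")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (any(stxm <= 0 | stxm > 1)) stop("stxm values must be in (0, 1]")
  ny <- nrow(stxm); nx <- ncol(stxm)
  fp <- stxm <= background_threshold
  if (!any(fp)) {
    warning("all-background STXM: zero thickness map")
    return(structure(list(z = matrix(0, ny, nx), mu_rho = matrix(0, ny, nx),
                          footprint = fp, rho_avg = rho_avg, h_max = h_max,
                          iterations = 0L, converged = TRUE),
                     class = "zmap_state"))
  }
  A <- -log(stxm)                       # absorbance, mu_rho * z
  tmin <- min(stxm[fp])
  mr0 <- -log(tmin) / h_max             # initial constant mu_s rho (um^-1)
  mr_lo <- mr0 * (1 - rho_range)
  mr_hi <- mr0 * (1 + rho_range)
  z <- matrix(0, ny, nx)
  z[fp] <- A[fp] / mr0
  z[abs(stxm - tmin) <= 1e-9 & fp] <- h_max
  mu_rho <- matrix(0, ny, nx)
  mu_rho[fp] <- A[fp] / z[fp]

  offs <- if (neighborhood == 8)
    cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1), dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(di = c(-1, 0, 0, 1), dj = c(0, -1, 1, 0))

  # out-of-map neighbours are unknown (NA), in-map background counts as zero
  shift <- function(m, di, dj) {
    out <- matrix(NA_real_, ny, nx)
    si <- seq_len(ny) - di; sj <- seq_len(nx) - dj
    keep_i <- si >= 1 & si <= ny; keep_j <- sj >= 1 & sj <= nx
    out[keep_i, keep_j] <- m[si[keep_i], sj[keep_j]]
    out
  }

  it <- 0L; converged <- FALSE
  for (it in seq_len(n_iter)) {
    maxdiff <- matrix(0, ny, nx)
    nbsum <- matrix(0, ny, nx)
    nbn <- matrix(0, ny, nx)
    for (r in seq_len(nrow(offs))) {
      nb <- shift(z, offs[r, 1], offs[r, 2])
      ok <- !is.na(nb)
      maxdiff[ok] <- pmax(maxdiff[ok], abs(z - nb)[ok])
      nbsum[ok] <- nbsum[ok] + nb[ok]
      nbn <- nbn + ok
    }
    thr <- mean(maxdiff[fp])
    flag <- fp & (maxdiff > thr) & (nbn > 0)
    if (!any(flag)) { converged <- TRUE; break }
    znew <- nbsum[flag] / nbn[flag]
    # admissible-density clamp, and never above h_max
    znew <- pmin(pmax(znew, A[flag] / mr_hi), pmin(A[flag] / mr_lo, h_max))
    if (max(abs(z[flag] - znew)) < 1e-12) { converged <- TRUE; break }
    z[flag] <- znew
    mu_rho[flag] <- A[flag] / z[flag]
  }
  structure(list(z = z, mu_rho = mu_rho, footprint = fp, rho_avg = rho_avg,
                 h_max = h_max, iterations = it, converged = converged),
            class = "zmap_state")
}
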