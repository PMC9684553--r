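# Shared fixtures: small grids built in code, and a cache so expensive
# pipeline runs are shared between acceptance criteria.

make_slab <- function(ny = 8, nx = 8, nz = 6, t = 3, density = 1.25,
                      fractions = lovo_fractions(), voxel = 1) {
  voxel_grid(c(ny, nx, nz), voxel,
             thickness = matrix(t, ny, nx),
             density = density, fractions = as.list(fractions))
}

# pseudo-element constants with flat attenuation tables (mu in cm^2/g)
flat_tables <- function(mus, tau_frac = NULL, lines = NULL) {
  tabs <- lapply(mus, function(m)
    cbind(E = c(100, 3000), mu = c(m, m)))
  fr <- if (is.null(tau_frac)) setNames(rep(1, length(mus)), names(mus))
    else tau_frac
  xrf_constants(mu_tables = tabs, tau_fraction = fr,
                lines = if (is.null(lines)) xrf_constants()$lines else lines)
}

.pipeline_cache <- new.env(parent = emptyenv())

cached_pipeline <- function(key, ...) {
  if (is.null(.pipeline_cache[[key]]))
    .pipeline_cache[[key]] <- suppressWarnings(run_pipeline(...))
  .pipeline_cache[[key]]
}

# independent fine-step line integral of att2d over a column grid
brute_path_depth <- function(p0, p1, zbot, ztop, att, vox, step = 0.01) {
  d <- p1 - p0
  L <- sqrt(sum(d^2))
  n <- ceiling(L / step)
  u <- (seq_len(n) - 0.5) / n
  depth <- 0
  ny <- nrow(zbot); nx <- ncol(zbot)
  for (k in seq_len(n)) {
    q <- p0 + u[k] * d
    j <- floor(q[1] / vox) + 1
    i <- floor(q[2] / vox) + 1
    if (i < 1 || i > ny || j < 1 || j > nx) next
    if (q[3] >= zbot[i, j] && q[3] <= ztop[i, j])
      depth <- depth + att[i, j] * L / n
  }
  depth
}
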