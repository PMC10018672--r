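# Independent oracles, written against the bare definitions and kept free
# of the package's production code paths.

# Pure-R local gamma by brute force: loop over every lattice offset within
# the search sphere, trilinear interpolation written out longhand. Only
# usable on tiny grids.
r_gamma_oracle <- function(ref, ev, dose_tol_pct, dta, exclusion_fraction = 0.1,
                           step, radius) {
  dm <- dim(ref$values)
  sp <- ref$spacing
  dmax <- max(ref$values)
  cutoff <- exclusion_fraction * dmax
  nmax <- floor(radius / step + 1e-9)
  offs <- expand.grid(a = -nmax:nmax, b = -nmax:nmax, c = -nmax:nmax)
  offs <- offs[offs$a^2 + offs$b^2 + offs$c^2 <= (radius / step)^2 + 1e-9, ]
  interp <- function(p) {
    f <- floor(p); w <- p - f
    lo <- f; hi <- ifelse(w < 1e-12, f, f + 1)
    w[w < 1e-12] <- 0
    if (any(lo < 1) || any(hi > dm)) return(NA_real_)
    v <- 0
    for (ci in 0:1) for (cj in 0:1) for (ck in 0:1) {
      ii <- if (ci == 0) lo[1] else hi[1]
      jj <- if (cj == 0) lo[2] else hi[2]
      kk <- if (ck == 0) lo[3] else hi[3]
      wt <- (if (ci == 0) 1 - w[1] else w[1]) *
            (if (cj == 0) 1 - w[2] else w[2]) *
            (if (ck == 0) 1 - w[3] else w[3])
      v <- v + wt * ev$values[ii, jj, kk]
    }
    v
  }
  g <- array(NA_real_, dim = dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    dr <- ref$values[i, j, k]
    if (dr < cutoff) next
    tol <- dose_tol_pct / 100 * dr
    if (tol <= 0) next
    best <- Inf
    for (m in seq_len(nrow(offs))) {
      o_mm <- c(offs$a[m], offs$b[m], offs$c[m]) * step
      de <- interp(c(i, j, k) + o_mm / sp)
      if (is.na(de)) next
      g2 <- sum(o_mm^2) / dta^2 + ((de - dr) / tol)^2
      if (g2 < best) best <- g2
    }
    g[i, j, k] <- sqrt(best)
  }
  g
}

# Step-function DVH oracle: dose to the hottest v_cc cm^3 read off the raw
# sorted voxel list with no interpolation.
dvh_step_oracle <- function(doses, voxel_cc, v_cc) {
  d <- sort(doses, decreasing = TRUE)
  k <- ceiling(v_cc / voxel_cc - 1e-12)
  d[min(max(k, 1), length(d))]
}

# index-arithmetic oracle for a pure integer-voxel translation (pull-back:
# output voxel x takes input value at x + shift)
shift_volume_oracle <- function(values, shift, fill = 0) {
  dm <- dim(values)
  out <- array(fill, dim = dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    src <- c(i, j, k) + shift
    if (all(src >= 1) && all(src <= dm))
      out[i, j, k] <- values[src[1], src[2], src[3]]
  }
  out
}
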