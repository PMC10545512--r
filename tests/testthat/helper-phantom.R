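# Shared fixtures: phantom specs at two working resolutions and a few
# hand-built slices for rule tests. Everything is generated in code.

# routine resolution used by the screening tests (fast)
small_spec <- function(seed, withIntensities = FALSE) {
  randomPhantomSpec(seed, nSlices = 12L, grid = c(84L, 84L),
                    spacingMm = c(2, 2, 8), withIntensities = withIntensities)
}

# high-resolution spec used for volumetry and papillary accounting
fine_spec <- function(seed, withIntensities = FALSE) {
  randomPhantomSpec(seed, nSlices = 48L, grid = c(160L, 160L),
                    spacingMm = c(1, 1, 2), withIntensities = withIntensities)
}

# a stack with an annular myocardium around a circular LV blood pool on
# each of `n_slices` identical slices; optionally an RV arc
ring_stack <- function(n_slices = 1L, size = 40L, r_lv = 8, wall = 4,
                       rv = FALSE, gap_cols = NULL, phase = "ED") {
  ctr <- (size + 1) / 2
  xy <- expand.grid(row = seq_len(size), col = seq_len(size))
  rho <- sqrt((xy$row - ctr)^2 + (xy$col - ctr)^2)
  sl <- matrix(0L, size, size)
  sl[rho < r_lv + wall] <- 2L
  sl[rho < r_lv] <- 1L
  if (rv) {
    phi <- atan2(xy$row - ctr, xy$col - ctr)
    m <- rho >= r_lv + wall & rho < r_lv + wall + 4 & abs(abs(phi) - pi) < 0.8
    sl[matrix(m, size, size)] <- 3L
  }
  if (!is.null(gap_cols)) {
    # punch a wedge through the myocardium on the +col side
    for (rr in seq_len(size)) for (cc in gap_cols)
      if (sl[rr, cc] == 2L && rr >= ctr - 1 && rr <= ctr + 1) sl[rr, cc] <- 0L
  }
  v <- array(0L, c(n_slices, size, size))
  for (k in seq_len(n_slices)) v[k, , ] <- sl
  LabelStack(v, c(1, 1), 10, phase)
}

# brute-force flood-fill oracle: partition the TRUE cells of a 2D mask
# into 8-connected components, implemented independently of the package
flood_oracle_2d <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      r <- (i - 1L) %% nrow(mask) + 1L
      c <- (i - 1L) %/% nrow(mask) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if ((dr | dc) && rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask)) {
          j <- (cc - 1L) * nrow(mask) + rr
          if (mask[j] && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
        }
      }
    }
  }
  lab
}

# component partition as a canonical set-of-sets (sorted index vectors)
canon_components <- function(comps) {
  out <- lapply(comps, function(cp) sort(cp$indices))
  out[order(vapply(out, min, numeric(1)))]
}
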