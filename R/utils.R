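# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# voxel volume in mL
.voxel_ml <- function(stack) {
  prod(stack@inPlaneSpacing) * stack@sliceSpacing / 1000
}

# resolve a label given by name or code to its integer code
.label_code <- function(stack, label) {
  lm <- stack@labelMap
  if (is.character(label)) {
    if (!label %in% names(lm)) stop(sprintf("label '%s' not in vocabulary", label))
    return(unname(lm[label]))
  }
  label <- as.integer(label)
  if (!label %in% lm) stop(sprintf("label %d not in vocabulary", label))
  label
}

# per-slice voxel counts of a label code
.slice_counts <- function(stack, code) {
  v <- stack@voxels
  d <- dim(v)
  counts <- integer(d[1])
  m <- v == code
  if (any(m)) counts <- tabulate(arrayInd(which(m), d)[, 1], nbins = d[1])
  counts
}

# in-plane polar coordinates of voxel centres, origin at the grid centre.
# Returns list(rho, phi) of (rows x cols) matrices; phi in (-pi, pi],
# phi = 0 along +col, phi = pi along -col (where the RV crescent sits).
.plane_polar <- function(rows, cols, sp_row, sp_col) {
  y <- ((seq_len(rows) - 0.5) - rows / 2) * sp_row
  x <- ((seq_len(cols) - 0.5) - cols / 2) * sp_col
  ym <- matrix(y, rows, cols)
  xm <- matrix(x, rows, cols, byrow = TRUE)
  list(rho = sqrt(xm^2 + ym^2), phi = atan2(ym, xm), x = xm, y = ym)
}

# absolute angular distance between phi and a reference angle
.ang_dist <- function(phi, ref) {
  d <- (phi - ref) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# slice-centre long-axis coordinates (mm), slice 1 = base at z in (0, ds)
.slice_z <- function(n_slices, ds) (seq_len(n_slices) - 0.5) * ds
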