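#' Construct a 2-D hexagonally packed lattice of building blocks
#'
#' Blocks are placed on a triangular (hexagonally packed) lattice:
#' `n_rows` rows of `n_cols` blocks, odd rows offset horizontally by
#' `spacing/2`, row pitch `spacing * sqrt(3)/2`. All nearest-neighbour
#' pairs at distance `spacing` are bonded, giving every interior block of
#' a defect-free lattice exactly 6 bonds. Velocities start at zero.
#'
#' The system is stored with the origin at the lower-left block; x is the
#' loading (horizontal) direction, y the transverse one. Identifiers are
#' contiguous integers starting at 1.
#'
#' @param n_cols,n_rows lattice dimensions in blocks (>= 1).
#' @param spacing nearest-neighbour distance, nm; default 9.17 nm, the
#'   pristine equilibrium block size.
#' @param species initial species of all blocks (`"P"` or `"D"`).
#' @param mass block mass in atomic mass units; default 1e6 amu, the
#'   order-of-magnitude mass of a 10x10x10-unit-cell hydroxyapatite prism
#'   plus one collagen triple-helix.
#' @param boundary `"clamped"` (displacement-controlled grips on the
#'   leftmost and rightmost block columns, free top/bottom surfaces) or
#'   `"periodic_x"` (periodic along x, free top/bottom).
#' @return an object of class `lattice_system`: a list with matrices
#'   `positions` and `velocities` (n x 2, nm and nm/ps), integer vector
#'   `species` (1 = pristine, 2 = damaged), `mass`, bond matrix `bonds`
#'   (m x 2 block ids), per-block `col`/`row` indices, logical `clamped`,
#'   a `boundary` spec, `applied_strain`, `time` (ps) and `spacing`.
#' @examples
#' sys <- build_hexagonal_lattice(3, 3)
#' nrow(sys$positions)  # 9 blocks
#' nrow(sys$bonds)      # 16 bonds
#' @export
build_hexagonal_lattice <- function(n_cols, n_rows, spacing = 9.17,
                                    species = "P", mass = 1e6,
                                    boundary = c("clamped", "periodic_x")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(n_cols) || !is.numeric(n_rows) || n_cols < 1 || n_rows < 1)
    stop("lattice dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(spacing) || spacing <= 0)
    stop("spacing must be positive", call. = FALSE)
  if (!is.numeric(mass) || mass <= 0)
    stop("mass must be positive", call. = FALSE)
  n_cols <- as.integer(n_cols); n_rows <- as.integer(n_rows)
  sp <- as_species(species)
  stopifnot(length(sp) == 1)

  col <- rep(seq_len(n_cols), times = n_rows)
  row <- rep(seq_len(n_rows), each = n_cols)
  x <- (col - 1) * spacing + ((row - 1) %% 2) * spacing / 2
  y <- (row - 1) * spacing * sqrt(3) / 2
  n <- n_cols * n_rows

  bonds <- .hex_bonds(n_cols, n_rows, periodic_x = (boundary == "periodic_x"))

  sys <- structure(list(
    positions = cbind(x = x, y = y),
    velocities = matrix(0, n, 2, dimnames = list(NULL, c("x", "y"))),
    species = rep(sp, n),
    mass = rep(as.numeric(mass), n),
    bonds = bonds,
    col = col, row = row,
    clamped = rep(FALSE, n),
    boundary = list(mode = boundary,
                    clamped_cols = if (boundary == "clamped") c(1L, n_cols) else integer(0),
                    box_lx = if (boundary == "periodic_x") n_cols * spacing else NA_real_),
    applied_strain = 0,
    time = 0,
    spacing = spacing,
    n_cols = n_cols, n_rows = n_rows,
    notch = NULL
  ), class = "lattice_system")
  sys
}

# Nearest-neighbour bond list of the offset triangular lattice.
# Row parity decides which two blocks of the adjacent row are neighbours.
.hex_bonds <- function(n_cols, n_rows, periodic_x = FALSE) {
  id <- function(i, j) (j - 1L) * n_cols + i   # i = col, j = row, 1-based
  from <- integer(0); to <- integer(0)
  add <- function(a, b) { from <<- c(from, a); to <<- c(to, b) }
  if (n_cols >= 2) {
    for (j in seq_len(n_rows)) add(id(seq_len(n_cols - 1L), j), id(seq.int(2L, n_cols), j))
    if (periodic_x) for (j in seq_len(n_rows)) add(id(n_cols, j), id(1L, j))
  }
  if (n_rows >= 2) {
    for (j in seq_len(n_rows - 1L)) {
      if ((j - 1L) %% 2L == 0L) {     # even row (0-based) -> offset row above
        add(id(seq_len(n_cols), j), id(seq_len(n_cols), j + 1L))
        if (n_cols >= 2) add(id(seq.int(2L, n_cols), j), id(seq_len(n_cols - 1L), j + 1L))
        if (periodic_x) add(id(1L, j), id(n_cols, j + 1L))
      } else {                        # offset row -> aligned row above
        add(id(seq_len(n_cols), j), id(seq_len(n_cols), j + 1L))
        if (n_cols >= 2) add(id(seq_len(n_cols - 1L), j), id(seq.int(2L, n_cols), j + 1L))
        if (periodic_x) add(id(n_cols, j), id(1L, j + 1L))
      }
    }
  }
  b <- cbind(pmin(from, to), pmax(from, to))
  b <- unique(b[order(b[, 1], b[, 2]), , drop = FALSE])
  storage.mode(b) <- "integer"
  colnames(b) <- c("i", "j")
  b
}

#' @export
print.lattice_system <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("lattice_system: %d blocks (%d x %d grid), %d bonds\n",
              n, x$n_cols, x$n_rows, nrow(x$bonds)))
  cat(sprintf("  species: %d pristine, %d damaged; boundary: %s; clamped blocks: %d\n",
              sum(x$species == 1L), sum(x$species == 2L),
              x$boundary$mode, sum(x$clamped)))
  cat(sprintf("  applied strain: %.4g; time: %.4g ps\n", x$applied_strain, x$time))
  if (!is.null(x$notch))
    cat(sprintf("  notch: %d cols x %d rows centred on column %d (top surface)\n",
                x$notch$width_blocks, x$notch$depth_rows, x$notch$center_col))
  invisible(x)
}

#' Current bond lengths
#'
#' @param system a [lattice_system].
#' @return numeric vector of centre-to-centre bond lengths (nm), one per
#'   row of `system$bonds` (minimum-image along x for periodic systems).
#' @export
bond_lengths <- function(system) {
  stopifnot(inherits(system, "lattice_system"))
  if (nrow(system$bonds) == 0L) return(numeric(0))
  d <- system$positions[system$bonds[, 2], , drop = FALSE] -
       system$positions[system$bonds[, 1], , drop = FALSE]
  if (identical(system$boundary$mode, "periodic_x")) {
    lx <- system$boundary$box_lx
    d[, 1] <- d[, 1] - lx * round(d[, 1] / lx)
  }
  sqrt(rowSums(d^2))
}

#' Cut a rectangular notch into the top surface
#'
#' Removes a `width_blocks` x `depth_rows` patch of blocks centred on
#' `center_col` at the top (free) surface, together with all their bonds,
#' to seed crack initiation at a pre-existing imperfection. Remaining
#' identifiers are re-indexed contiguously; the notch specification is
#' recorded on the returned system.
#'
#' @param system a [lattice_system].
#' @param center_col column index the notch is centred on.
#' @param width_blocks notch width in blocks (0 = no notch).
#' @param depth_rows notch depth in rows.
#' @return the notched [lattice_system].
#' @export
insert_notch <- function(system, center_col, width_blocks = 4L, depth_rows = 2L) {
  stopifnot(inherits(system, "lattice_system"))
  width_blocks <- as.integer(width_blocks); depth_rows <- as.integer(depth_rows)
  center_col <- as.integer(center_col)
  if (width_blocks < 0 || depth_rows < 0) stop("notch dimensions must be >= 0", call. = FALSE)
  if (width_blocks == 0L || depth_rows == 0L) return(system)
  cols <- center_col + seq_len(width_blocks) - 1L - (width_blocks - 1L) %/% 2L
  rows <- system$n_rows - seq_len(depth_rows) + 1L
  if (min(cols) < 1L || max(cols) > system$n_cols || min(rows) < 1L)
    stop("notch exceeds lattice bounds", call. = FALSE)
  drop <- which(system$col %in% cols & system$row %in% rows)
  if (!length(drop)) return(system)
  keep <- setdiff(seq_len(nrow(system$positions)), drop)
  remap <- integer(nrow(system$positions)); remap[keep] <- seq_along(keep)

  b <- system$bonds
  b_keep <- b[, 1] %in% keep & b[, 2] %in% keep
  b <- b[b_keep, , drop = FALSE]
  b[] <- remap[b]

  system$positions <- system$positions[keep, , drop = FALSE]
  system$velocities <- system$velocities[keep, , drop = FALSE]
  system$species <- system$species[keep]
  system$mass <- system$mass[keep]
  system$col <- system$col[keep]
  system$row <- system$row[keep]
  system$clamped <- system$clamped[keep]
  system$bonds <- b
  system$notch <- list(center_col = center_col, width_blocks = width_blocks,
                       depth_rows = depth_rows)
  system
}

#' Strain-and-hold loading protocol
#'
#' @param axis loading axis, `"horizontal"` (x) or `"vertical"` (y).
#' @param magnitude engineering strain, dimensionless, >= 0.
#' @param hold_steps number of dynamics steps to hold the strain for.
#' @param mode only `"instantaneous"` (affine deformation applied in one
#'   step, then held) is implemented.
#' @return an object of class `strain_protocol`.
#' @export
strain_protocol <- function(axis = c("horizontal", "vertical"),
                            magnitude = 0.05, hold_steps = 0L,
                            mode = "instantaneous") {
  axis <- match.arg(axis)
  if (!identical(mode, "instantaneous"))
    stop("only instantaneous strain application is implemented", call. = FALSE)
  if (!is.numeric(magnitude) || magnitude < 0)
    stop("strain magnitude must be >= 0", call. = FALSE)
  if (hold_steps < 0) stop("hold_steps must be >= 0", call. = FALSE)
  structure(list(axis = axis, magnitude = as.numeric(magnitude),
                 mode = mode, hold_steps = as.integer(hold_steps)),
            class = "strain_protocol")
}

#' Apply an affine strain to the whole sample
#'
#' Scales every block coordinate along the protocol axis by
#' `(1 + magnitude)` about the sample's low edge. For a clamped-boundary
#' system the leftmost and rightmost block columns become
#' displacement-controlled roller grips: their x (loading-axis)
#' coordinates are held fixed at the strained values while the
#' transverse coordinate stays free, so Poisson contraction is not
#' obstructed at the grips. For a periodic system the box length is
#' scaled instead. Strains beyond 20% lie outside the model's intended
#' validity range and trigger a warning.
#'
#' Successive applications compose multiplicatively:
#' `applied_strain` becomes `(1 + old)(1 + new) - 1`.
#'
#' @param system a [lattice_system].
#' @param protocol a [strain_protocol()].
#' @return the strained system.
#' @export
apply_affine_strain <- function(system, protocol) {
  stopifnot(inherits(system, "lattice_system"), inherits(protocol, "strain_protocol"))
  eps <- protocol$magnitude
  if (eps > 0.2)
    warning("strain ", eps, " exceeds the model's validity range (<= 0.2)", call. = FALSE)
  ax <- if (protocol$axis == "horizontal") 1L else 2L
  lo <- min(system$positions[, ax])
  system$positions[, ax] <- lo + (system$positions[, ax] - lo) * (1 + eps)
  if (identical(system$boundary$mode, "clamped")) {
    system$clamped <- system$col %in% system$boundary$clamped_cols
    system$velocities[system$clamped, ] <- 0
  } else if (identical(system$boundary$mode, "periodic_x") && ax == 1L) {
    system$boundary$box_lx <- system$boundary$box_lx * (1 + eps)
  }
  system$applied_strain <- (1 + system$applied_strain) * (1 + eps) - 1
  system
}
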