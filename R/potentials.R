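#' Building-block species
#'
#' The model knows exactly two building-block species: `"P"` (pristine
#' composite, as before plastic deformation) and `"D"` (damaged composite,
#' softer and with a larger equilibrium distance). The ordering P < D is
#' fixed and used by the mixing rule. Internally species are stored as the
#' integer codes 1 (P) and 2 (D).
#'
#' @format A character vector `c("P", "D")`.
#' @export
SPECIES <- c("P", "D")

#' Coerce a species specification to integer codes
#'
#' @param x character (`"P"`/`"D"`) or integer (1/2) vector.
#' @return integer vector with values in `{1, 2}`.
#' @export
as_species <- function(x) {
  if (is.character(x)) {
    code <- match(toupper(x), SPECIES)
  } else if (is.numeric(x)) {
    code <- as.integer(x)
    code[!(code %in% c(1L, 2L))] <- NA_integer_
  } else {
    stop("species must be character ('P'/'D') or integer (1/2)", call. = FALSE)
  }
  if (anyNA(code)) stop("unknown species value", call. = FALSE)
  code
}

#' Truncated-harmonic pair potential
#'
#' A harmonic well shifted so that it reaches zero at a rupture cutoff
#' `r_c`, beyond which the interaction vanishes identically:
#' \deqn{V(r) = k[(r - r_o)^2 - (r_c - r_o)^2] \quad (r \le r_c), \qquad
#'       V(r) = 0 \quad (r > r_c).}
#' The truncation encodes brittle bond rupture; the well depth is
#' \eqn{k (r_c - r_o)^2}.
#'
#' @param k spring-constant prefactor, kJ mol^-1 nm^-2; must be > 0.
#' @param r0 equilibrium separation, nm; 0 < `r0` < `rc`.
#' @param rc rupture cutoff, nm.
#' @return an object of class `pair_potential`.
#' @examples
#' pp <- pair_potential(1.77e5, 9.17, 9.65)
#' pair_energy(pp, 9.17)   # well depth: -1.77e5 * 0.48^2
#' pair_energy(pp, 9.65)   # exactly 0 at the cutoff
#' @export
pair_potential <- function(k, r0, rc) {
  stopifnot(is.numeric(k), is.numeric(r0), is.numeric(rc),
            length(k) == 1, length(r0) == 1, length(rc) == 1)
  if (!is.finite(k) || k <= 0) stop("spring constant k must be > 0", call. = FALSE)
  if (!is.finite(r0) || r0 <= 0) stop("equilibrium distance r0 must be > 0", call. = FALSE)
  if (!is.finite(rc) || rc <= r0) stop("rupture cutoff rc must exceed r0", call. = FALSE)
  structure(list(k = as.numeric(k), r0 = as.numeric(r0), rc = as.numeric(rc)),
            class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  cat(sprintf(
    "Truncated-harmonic pair potential: k = %.6g kJ/mol/nm^2, r0 = %.4g nm, rc = %.4g nm\n",
    x$k, x$r0, x$rc))
  cat(sprintf("  well depth k(rc - r0)^2 = %.6g kJ/mol\n", x$k * (x$rc - x$r0)^2))
  invisible(x)
}

#' Pair interaction energy
#'
#' @param pot a [pair_potential()].
#' @param r separation(s), nm; all must be > 0.
#' @return energy in kJ/mol, zero at and beyond the cutoff.
#' @export
pair_energy <- function(pot, r) {
  stopifnot(inherits(pot, "pair_potential"))
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("separation r must be positive and finite", call. = FALSE)
  v <- pot$k * ((r - pot$r0)^2 - (pot$rc - pot$r0)^2)
  v[r > pot$rc] <- 0
  v
}

#' Pair force along the bond axis
#'
#' The analytic radial derivative of [pair_energy()], with the convention
#' that positive values are repulsive. Zero exactly beyond the cutoff; the
#' force is discontinuous at `rc` with jump magnitude `2 k (rc - r0)`.
#'
#' @inheritParams pair_energy
#' @return signed scalar force(s), kJ mol^-1 nm^-1; positive = repulsive.
#' @export
pair_force <- function(pot, r) {
  stopifnot(inherits(pot, "pair_potential"))
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("separation r must be positive and finite", call. = FALSE)
  f <- -2 * pot$k * (r - pot$r0)
  f[r > pot$rc] <- 0
  f
}

#' Table of pair potentials for all species pairs
#'
#' Maps every unordered species pair (P-P, P-D, D-D) to a
#' [pair_potential()]. By the mixing rule, a pair involving at least one
#' damaged block uses the damaged potential, so `pd` defaults to `dd`:
#' the pristine potential applies only between two pristine blocks.
#'
#' @param pp,dd,pd pair potentials for the pristine-pristine,
#'   damaged-damaged, and mixed pairs.
#' @return an object of class `potential_table`.
#' @export
potential_table <- function(pp, dd, pd = dd) {
  stopifnot(inherits(pp, "pair_potential"), inherits(dd, "pair_potential"),
            inherits(pd, "pair_potential"))
  structure(list(PP = pp, PD = pd, DD = dd), class = "potential_table")
}

#' Default potentials of the apatite-collagen composite model
#'
#' The parameters of the two building-block species:
#' pristine k = 1.77e5 kJ/mol/nm^2, r0 = 9.17 nm, rc = 9.65 nm;
#' damaged k = 1.10e5 kJ/mol/nm^2, r0 = 9.35 nm, rc = 9.82 nm.
#' The pristine block size (9.17 nm) corresponds to one collagen
#' triple-helix plus a 10x10x10-unit-cell hydroxyapatite prism.
#'
#' @return a [potential_table()].
#' @export
default_potentials <- function() {
  potential_table(pp = pair_potential(1.77e5, 9.17, 9.65),
                  dd = pair_potential(1.10e5, 9.35, 9.82))
}

#' @export
print.potential_table <- function(x, ...) {
  for (nm in names(x)) {
    cat(nm, ": ", sep = "")
    p <- x[[nm]]
    cat(sprintf("k = %.6g, r0 = %.4g nm, rc = %.4g nm\n", p$k, p$r0, p$rc))
  }
  invisible(x)
}

#' Resolve the potential acting between two species
#'
#' Symmetric in its arguments. Two pristine blocks interact through the
#' pristine potential; any pair involving a damaged block uses the
#' table's mixed/damaged entry.
#'
#' @param table a [potential_table()].
#' @param a,b species (`"P"`/`"D"` or codes 1/2).
#' @return the [pair_potential()] for the pair.
#' @export
resolve_potential <- function(table, a, b) {
  stopifnot(inherits(table, "potential_table"))
  a <- as_species(a); b <- as_species(b)
  stopifnot(length(a) == 1, length(b) == 1)
  if (a == 1L && b == 1L) return(table$PP)
  if (a == 2L && b == 2L) return(table$DD)
  table$PD
}

#' Apply the irreversible pristine-to-damaged switching rule
#'
#' Every pristine block with at least one bonded neighbour at separation
#' >= the pristine rupture cutoff `rc^P` becomes damaged. Damaged blocks
#' never revert (self-healing is far slower than damage acquisition and is
#' neglected in this model). All switches implied by the current positions
#' are applied simultaneously, so the result does not depend on block
#' ordering.
#'
#' @param system a [lattice_system].
#' @param potentials a [potential_table()]; the switching threshold is the
#'   pristine pair's `rc`.
#' @return a list with elements `system` (updated) and `switched` (sorted,
#'   duplicate-free integer vector of block identifiers that switched this
#'   call).
#' @export
update_species <- function(system, potentials = default_potentials()) {
  stopifnot(inherits(system, "lattice_system"), inherits(potentials, "potential_table"))
  rcP <- potentials$PP$rc
  if (nrow(system$bonds) == 0L)
    return(list(system = system, switched = integer(0)))
  i <- system$bonds[, 1]; j <- system$bonds[, 2]
  d <- system$positions[j, , drop = FALSE] - system$positions[i, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  over <- len >= rcP
  cand <- unique(c(i[over], j[over]))
  switched <- sort(cand[system$species[cand] == 1L])
  if (length(switched)) system$species[switched] <- 2L
  list(system = system, switched = switched)
}
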