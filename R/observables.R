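#' 2-D virial stress tensor
#'
#' \deqn{\sigma_{ab} = \frac{1}{A}\Big[\sum_{bonds} r_a F_b +
#'   \sum_{blocks} m v_a v_b\Big]}
#' with the bond sum over pair separations r and pair forces F, the
#' kinetic sum over non-clamped blocks, and A the current rectangular
#' sample area (bounding extents of the block positions; box length times
#' y-extent for x-periodic systems). Units are kJ mol^-1 nm^-2 (2-D
#' stress = force per length). With this convention a sample under
#' tension has negative normal stress (pressure-positive sign).
#'
#' @param system a [lattice_system].
#' @param potentials a [potential_table()].
#' @return a symmetric 2 x 2 matrix with an `"area"` attribute (nm^2).
#' @export
virial_stress <- function(system, potentials) {
  stopifnot(inherits(system, "lattice_system"), inherits(potentials, "potential_table"))
  pos <- system$positions
  w <- if (identical(system$boundary$mode, "periodic_x"))
    system$boundary$box_lx else diff(range(pos[, 1]))
  h <- diff(range(pos[, 2]))
  A <- w * h
  if (!is.finite(A) || A <= 0)
    stop("degenerate sample: zero area, stress undefined", call. = FALSE)
  wxx <- wyy <- wxy <- 0
  if (nrow(system$bonds) > 0L) {
    i <- system$bonds[, 1]; j <- system$bonds[, 2]
    d <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
    if (identical(system$boundary$mode, "periodic_x")) {
      lx <- system$boundary$box_lx
      d[, 1] <- d[, 1] - lx * round(d[, 1] / lx)
    }
    r <- sqrt(rowSums(d^2))
    fscal <- .bond_scalar_force(system, potentials, r)
    fr <- fscal / r
    wxx <- sum(fr * d[, 1]^2)
    wyy <- sum(fr * d[, 2]^2)
    wxy <- sum(fr * d[, 1] * d[, 2])
  }
  free <- !system$clamped
  v <- system$velocities[free, , drop = FALSE]
  mm <- system$mass[free]
  kxx <- sum(mm * v[, 1]^2); kyy <- sum(mm * v[, 2]^2); kxy <- sum(mm * v[, 1] * v[, 2])
  s <- matrix(c(wxx + kxx, wxy + kxy, wxy + kxy, wyy + kyy), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y"))) / A
  attr(s, "area") <- A
  s
}

# per-bond scalar force (positive repulsive) and resolved cutoffs,
# vectorised over the bond list for the current species assignment
.bond_scalar_force <- function(system, potentials, r) {
  rp <- .resolve_params(system, potentials)
  f <- -2 * rp$k * (r - rp$r0)
  f[r > rp$rc] <- 0
  f
}

.resolve_params <- function(system, potentials) {
  i <- system$bonds[, 1]; j <- system$bonds[, 2]
  both_p <- system$species[i] == 1L & system$species[j] == 1L
  both_d <- system$species[i] == 2L & system$species[j] == 2L
  k <- ifelse(both_p, potentials$PP$k, ifelse(both_d, potentials$DD$k, potentials$PD$k))
  r0 <- ifelse(both_p, potentials$PP$r0, ifelse(both_d, potentials$DD$r0, potentials$PD$r0))
  rc <- ifelse(both_p, potentials$PP$rc, ifelse(both_d, potentials$DD$rc, potentials$PD$rc))
  list(k = k, r0 = r0, rc = rc)
}

#' Detect currently broken bonds
#'
#' A bond is broken iff its current length is at or beyond the rupture
#' cutoff of the potential resolved for its endpoints' current species.
#' This is the instantaneous criterion; [run_constant_strain()] keeps the
#' monotone record (a bond once broken stays flagged, mirroring the
#' absence of self-healing) with the step of first breakage.
#'
#' @param system a [lattice_system].
#' @param potentials a [potential_table()].
#' @return a data frame with one row per broken bond: `bond` (row index
#'   into `system$bonds`), `i`, `j`, `length`, `rupture_cutoff`.
#' @export
detect_broken_bonds <- function(system, potentials) {
  stopifnot(inherits(system, "lattice_system"), inherits(potentials, "potential_table"))
  if (nrow(system$bonds) == 0L)
    return(data.frame(bond = integer(0), i = integer(0), j = integer(0),
                      length = numeric(0), rupture_cutoff = numeric(0)))
  len <- bond_lengths(system)
  rp <- .resolve_params(system, potentials)
  idx <- which(len >= rp$rc)
  data.frame(bond = idx,
             i = system$bonds[idx, 1], j = system$bonds[idx, 2],
             length = len[idx], rupture_cutoff = rp$rc[idx])
}

#' Cluster broken bonds into micro-cracks and test percolation
#'
#' Broken bonds are the nodes; two broken bonds belong to the same crack
#' iff they share a block or their midpoints lie within one lattice
#' spacing (the latter keeps a bifurcating crack separated by a single
#' intact bond connected as one branched cluster). Connected components
#' give the cracks. Each cluster's bounding extents along x and y are
#' measured from its bonds' endpoint positions; a cluster spans the
#' transverse direction if its y-extent covers the full free sample
#' height (within one spacing, the discretisation length). Material
#' failure under horizontal tension = a transversely spanning cluster
#' (`percolates`).
#'
#' @param broken a data frame as returned by [detect_broken_bonds()] or
#'   the `broken` element of [run_constant_strain()] (columns `i`, `j`).
#' @param system the [lattice_system] supplying positions and spacing.
#' @return an object of class `crack_report`: list with `broken_bonds`,
#'   `clusters` (list of integer vectors indexing rows of
#'   `broken_bonds`), `cluster_extents` (data frame xmin/xmax/ymin/ymax/
#'   span_x/span_y), `spans_transverse`, `spans_longitudinal`,
#'   `percolates`, `sample_width`, `sample_height`.
#' @export
cluster_cracks <- function(broken, system) {
  stopifnot(inherits(system, "lattice_system"), is.data.frame(broken))
  pos <- system$positions
  width <- diff(range(pos[, 1]))
  height <- diff(range(pos[, 2]))
  spacing <- system$spacing
  nb <- nrow(broken)
  empty_ext <- data.frame(xmin = numeric(0), xmax = numeric(0),
                          ymin = numeric(0), ymax = numeric(0),
                          span_x = numeric(0), span_y = numeric(0))
  if (nb == 0L)
    return(structure(list(broken_bonds = broken, clusters = list(),
                          cluster_extents = empty_ext,
                          spans_transverse = logical(0),
                          spans_longitudinal = logical(0),
                          percolates = FALSE,
                          sample_width = width, sample_height = height),
                     class = "crack_report"))

  edges <- .crack_adjacency(broken, pos, spacing)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nb - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  clusters <- split(seq_len(nb), comp)
  names(clusters) <- NULL
  ext <- do.call(rbind, lapply(clusters, function(idx) {
    ids <- c(broken$i[idx], broken$j[idx])
    px <- pos[ids, 1]; py <- pos[ids, 2]
    data.frame(xmin = min(px), xmax = max(px), ymin = min(py), ymax = max(py),
               span_x = diff(range(px)), span_y = diff(range(py)))
  }))
  spans_t <- ext$span_y >= height - spacing
  spans_l <- ext$span_x >= width - spacing
  structure(list(broken_bonds = broken, clusters = clusters,
                 cluster_extents = ext,
                 spans_transverse = spans_t, spans_longitudinal = spans_l,
                 percolates = any(spans_t),
                 sample_width = width, sample_height = height),
            class = "crack_report")
}

# adjacency among broken bonds: shared endpoint, or midpoints within one
# spacing (cell-list over midpoints to stay near-linear in bond count)
.crack_adjacency <- function(broken, pos, spacing) {
  nb <- nrow(broken)
  edges <- matrix(integer(0), 0, 2)
  # shared block: clique edges within each block's incident broken bonds
  inc <- split(rep(seq_len(nb), 2), c(broken$i, broken$j))
  shared <- lapply(inc, function(v) if (length(v) >= 2) t(utils::combn(v, 2)) else NULL)
  shared <- do.call(rbind, shared)
  if (!is.null(shared)) edges <- rbind(edges, shared)
  # midpoint proximity via cell list
  mx <- (pos[broken$i, 1] + pos[broken$j, 1]) / 2
  my <- (pos[broken$i, 2] + pos[broken$j, 2]) / 2
  cx <- floor(mx / spacing); cy <- floor(my / spacing)
  key <- paste(cx, cy)
  cell <- split(seq_len(nb), key)
  coords <- unique(data.frame(cx = cx, cy = cy, key = key))
  near <- list()
  for (r in seq_len(nrow(coords))) {
    here <- cell[[coords$key[r]]]
    for (dx in -1:1) for (dy in 0:1) {
      if (dy == 0 && dx < 0) next  # visit each unordered cell pair once
      other_key <- paste(coords$cx[r] + dx, coords$cy[r] + dy)
      there <- cell[[other_key]]
      if (is.null(there)) next
      if (dx == 0 && dy == 0) {
        if (length(here) >= 2) {
          pr <- t(utils::combn(here, 2))
          d2 <- (mx[pr[, 1]] - mx[pr[, 2]])^2 + (my[pr[, 1]] - my[pr[, 2]])^2
          near[[length(near) + 1]] <- pr[d2 <= spacing^2, , drop = FALSE]
        }
      } else {
        pr <- as.matrix(expand.grid(here, there))
        d2 <- (mx[pr[, 1]] - mx[pr[, 2]])^2 + (my[pr[, 1]] - my[pr[, 2]])^2
        near[[length(near) + 1]] <- pr[d2 <= spacing^2, , drop = FALSE]
      }
    }
  }
  near <- do.call(rbind, near)
  if (!is.null(near) && nrow(near)) edges <- rbind(edges, unname(near))
  storage.mode(edges) <- "integer"
  edges
}

#' @export
print.crack_report <- function(x, ...) {
  cat(sprintf("crack_report: %d broken bonds in %d cluster(s)\n",
              nrow(x$broken_bonds), length(x$clusters)))
  cat(sprintf("  sample %.4g x %.4g nm; percolates (transverse): %s\n",
              x$sample_width, x$sample_height, x$percolates))
  if (length(x$clusters)) {
    sizes <- lengths(x$clusters)
    cat(sprintf("  cluster sizes: largest %d, median %g; largest y-extent %.4g nm\n",
                max(sizes), stats::median(sizes), max(x$cluster_extents$span_y)))
  }
  invisible(x)
}

#' Serialize a crack report to JSON
#'
#' @param report a `crack_report`.
#' @param path output file.
#' @export
write_crack_report <- function(report, path) {
  stopifnot(inherits(report, "crack_report"))
  jsonlite::write_json(list(
    n_broken_bonds = nrow(report$broken_bonds),
    n_clusters = length(report$clusters),
    percolates = report$percolates,
    sample_width = report$sample_width,
    sample_height = report$sample_height,
    clusters = lapply(seq_along(report$clusters), function(ci) list(
      bonds = report$broken_bonds$bond[report$clusters[[ci]]],
      extent = as.list(report$cluster_extents[ci, ]),
      spans_transverse = report$spans_transverse[ci],
      spans_longitudinal = report$spans_longitudinal[ci]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fit an exponential decay to a stress series
#'
#' Least-squares fit of \eqn{\sigma(t) = c + a e^{-t/\tau}} to one stress
#' component, with \eqn{\tau > 0} enforced by bounds
#' (Levenberg-Marquardt). R^2 is computed on the raw series (not
#' log-transformed, since the offset can be near zero). A series with
#' (numerically) zero variance is reported as a degenerate fit rather
#' than an error.
#'
#' @param series a data frame with a `time_ps` column and the stress
#'   component columns, e.g. the `stress` element of
#'   [run_constant_strain()].
#' @param component column to fit, default `"sigma_xx"`.
#' @return a list: `amplitude`, `tau` (ps), `offset`, `r_squared`,
#'   `converged`, `degenerate`, `fitted` (vector), `residuals`.
#' @export
fit_exponential_decay <- function(series, component = "sigma_xx") {
  stopifnot(is.data.frame(series))
  if (!component %in% names(series))
    stop("component '", component, "' not found in series", call. = FALSE)
  t <- series$time_ps
  yv <- series[[component]]
  ok <- is.finite(t) & is.finite(yv)
  t <- t[ok]; yv <- yv[ok]
  if (length(t) < 10) stop("need at least 10 samples to fit a decay", call. = FALSE)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (stats::sd(yv) < 1e-12 * (abs(mean(yv)) + 1)) {
    return(list(amplitude = 0, tau = NA_real_, offset = mean(yv),
                r_squared = NA_real_, converged = FALSE, degenerate = TRUE,
                fitted = rep(mean(yv), length(yv)), residuals = yv - mean(yv)))
  }
  n <- length(yv)
  offset0 <- mean(tail(yv, max(3L, n %/% 10L)))
  amp0 <- yv[1] - offset0
  # tau start from a log-linear fit to the decaying part of the series
  dec <- (yv - offset0) / amp0          # normalised decay, starts near 1
  use <- which(dec > 0.02)
  tau0 <- NA_real_
  if (length(use) >= 3) {
    sl <- stats::coef(stats::lm(log(dec[use]) ~ t[use]))[2]
    if (is.finite(sl) && sl < 0) tau0 <- -1 / sl
  }
  span <- diff(range(t))
  starts <- unique(c(tau0, span / 200, span / 50, span / 20, span / 5, span,
                     if (is.finite(tau0)) tau0 * c(0.1, 10)))
  starts <- starts[is.finite(starts) & starts > 0]
  fit <- NULL
  for (tau_start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(yv ~ offset + amplitude * exp(-(t - t[1]) / tau),
                        start = list(offset = offset0, amplitude = amp0,
                                     tau = tau_start),
                        lower = c(-Inf, -Inf, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    cond <- structure(class = c("cgfrac_fit_failure", "error", "condition"),
                      list(message = paste("exponential fit failed:",
                                           conditionMessage(fit)),
                           call = sys.call(-1),
                           residual_sd = stats::sd(yv)))
    stop(cond)
  }
  cf <- stats::coef(fit)
  yhat <- stats::fitted(fit)
  ss_res <- sum((yv - yhat)^2)
  ss_tot <- sum((yv - mean(yv))^2)
  # report amplitude referenced to t = 0 of the series' own clock
  list(amplitude = unname(cf["amplitude"]),
       tau = unname(cf["tau"]),
       offset = unname(cf["offset"]),
       r_squared = 1 - ss_res / ss_tot,
       converged = TRUE, degenerate = FALSE,
       fitted = as.numeric(yhat), residuals = as.numeric(yv - yhat))
}
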