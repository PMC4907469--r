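#' Tabulated energy-versus-distance profile
#'
#' Container for a per-contact energy profile (the model-reduction input:
#' energy of one building-block contact as a function of centre-to-centre
#' separation, such as obtained by straining a fine-grained model).
#'
#' @param distances strictly increasing separations, nm (>= 6 points).
#' @param energies energies, kJ/mol per building-block contact.
#' @param provenance free-text label recording where the profile came
#'   from.
#' @return an object of class `energy_profile`.
#' @export
energy_profile <- function(distances, energies, provenance = "") {
  if (!is.numeric(distances) || !is.numeric(energies))
    stop("distances and energies must be numeric", call. = FALSE)
  if (length(distances) != length(energies))
    stop("distances and energies must have equal length", call. = FALSE)
  if (length(distances) < 6) stop("need at least 6 points", call. = FALSE)
  if (any(diff(distances) <= 0)) stop("distances must be strictly increasing", call. = FALSE)
  structure(list(distances = as.numeric(distances),
                 energies = as.numeric(energies),
                 provenance = as.character(provenance)[1]),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("energy_profile: %d points, r in [%.4g, %.4g] nm\n",
              length(x$distances), min(x$distances), max(x$distances)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Fit a truncated-harmonic potential to an energy profile
#'
#' The truncation point `rc` makes the objective non-differentiable, so
#' it is found by grid search: for each candidate cutoff, `k` and `r0`
#' are fitted by linear least squares on the points with `r <= rc`,
#' subject to the exact constraint `V(rc) = 0` (with the constraint the
#' model is `V = k (r^2 - rc^2) - 2 k r0 (r - rc)`, linear in
#' `a = k` and `b = -2 k r0`). Points beyond the candidate cutoff are
#' predicted as zero and their residuals counted, so candidates with
#' different point splits compete on the same total squared residual.
#' The candidate minimising that total wins; a winner at either grid
#' edge is flagged as a boundary solution (e.g. a pure, untruncated
#' parabola pushes `rc` to the upper edge).
#'
#' @param profile an [energy_profile()].
#' @param r_c_grid candidate rupture cutoffs, nm.
#' @return a list: `potential` (the best [pair_potential()]),
#'   `rc` (chosen cutoff), `sse` (total squared residual of the winner),
#'   `boundary_solution` (logical), and `diagnostics` (data frame with
#'   per-candidate rc, k, r0, sse, valid).
#' @export
fit_truncated_harmonic <- function(profile, r_c_grid) {
  stopifnot(inherits(profile, "energy_profile"))
  r <- profile$distances; v <- profile$energies
  r_c_grid <- sort(unique(as.numeric(r_c_grid)))
  if (!length(r_c_grid)) stop("empty r_c_grid", call. = FALSE)
  if (all(vapply(r_c_grid, function(rc) sum(r <= rc) < 3, logical(1))))
    stop("insufficient data: fewer than 3 points below every candidate cutoff",
         call. = FALSE)
  rows <- lapply(r_c_grid, function(rc) {
    below <- r <= rc
    if (sum(below) < 3)
      return(data.frame(rc = rc, k = NA_real_, r0 = NA_real_,
                        sse = Inf, valid = FALSE))
    X <- cbind(r[below]^2 - rc^2, r[below] - rc)
    cf <- tryCatch(qr.solve(X, v[below]), error = function(e) NULL)
    if (is.null(cf) || !all(is.finite(cf)))
      return(data.frame(rc = rc, k = NA_real_, r0 = NA_real_,
                        sse = Inf, valid = FALSE))
    k <- cf[1]; r0 <- -cf[2] / (2 * cf[1])
    valid <- is.finite(k) && k > 0 && is.finite(r0) && r0 > 0 && r0 < rc
    sse <- sum((v[below] - X %*% cf)^2) + sum(v[!below]^2)
    data.frame(rc = rc, k = k, r0 = r0, sse = if (valid) sse else Inf,
               valid = valid)
  })
  diag <- do.call(rbind, rows)
  if (!any(diag$valid))
    stop("no candidate cutoff yields a valid truncated-harmonic fit", call. = FALSE)
  best <- which.min(diag$sse)
  list(potential = pair_potential(diag$k[best], diag$r0[best], diag$rc[best]),
       rc = diag$rc[best],
       sse = diag$sse[best],
       boundary_solution = best == 1L || best == nrow(diag),
       diagnostics = diag)
}

#' Generate a synthetic reference energy profile
#'
#' Samples [pair_energy()] of a known potential on an equally spaced
#' distance grid and adds Gaussian noise — a synthetic stand-in for an
#' energy-versus-stretch curve measured on a finer-grained model, used to
#' exercise and validate the fitting machinery. Deterministic per seed;
#' the provenance string records all arguments.
#'
#' @param pot a [pair_potential()].
#' @param r_min,r_max distance range, nm.
#' @param n number of points (>= 6).
#' @param noise_sd Gaussian noise standard deviation, kJ/mol.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @return an [energy_profile()].
#' @export
generate_reference_profile <- function(pot, r_min, r_max, n = 40L,
                                       noise_sd = 0, seed = 1L) {
  stopifnot(inherits(pot, "pair_potential"))
  if (r_min >= r_max) stop("r_min must be less than r_max", call. = FALSE)
  if (r_min <= 0) stop("r_min must be positive", call. = FALSE)
  if (n < 6) stop("need at least 6 points", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  r <- seq(r_min, r_max, length.out = n)
  v <- pair_energy(pot, r)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    v <- v + stats::rnorm(n, 0, noise_sd)
  }
  energy_profile(r, v, provenance = sprintf(
    "synthetic: k=%.6g r0=%.6g rc=%.6g r=[%.4g,%.4g] n=%d noise_sd=%.4g seed=%d",
    pot$k, pot$r0, pot$rc, r_min, r_max, n, noise_sd, seed))
}

#' Read / write energy profiles as two-column text
#'
#' Plain whitespace-delimited text with a comment header; the units line
#' (`# units: nm kJ/mol`) is mandatory on write and checked on read.
#'
#' @param profile an [energy_profile()].
#' @param path file path.
#' @return `read_energy_profile` returns an [energy_profile()];
#'   `write_energy_profile` returns `path` invisibly.
#' @export
write_energy_profile <- function(profile, path) {
  stopifnot(inherits(profile, "energy_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# energy-distance profile (one building-block contact)",
               "# units: nm kJ/mol",
               paste0("# provenance: ", profile$provenance)), con)
  utils::write.table(cbind(profile$distances, profile$energies), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_energy_profile
#' @export
read_energy_profile <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  if (!any(grepl("units:\\s*nm\\s+kJ/mol", header)))
    stop("profile header must declare 'units: nm kJ/mol'", call. = FALSE)
  prov <- sub("^#\\s*provenance:\\s*", "", grep("provenance:", header, value = TRUE))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  tab <- utils::read.table(text = body)
  energy_profile(tab[[1]], tab[[2]],
                 provenance = if (length(prov)) prov[1] else "")
}
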