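#' Write a system snapshot as extended XYZ
#'
#' One frame: atom-count line, a comment line with key=value properties
#' (time_ps, applied_strain, box extents, the species-to-element map),
#' then one line per block with element tag, position (nm) and velocity
#' (nm/ps). Species map to element tags for viewer compatibility:
#' pristine -> "C", damaged -> "O" (recorded in the comment line).
#'
#' @param system a [lattice_system].
#' @param path output file.
#' @param element_map length-2 character vector mapping species P, D to
#'   element tags.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(system, path, element_map = c(P = "C", D = "O")) {
  stopifnot(inherits(system, "lattice_system"))
  n <- nrow(system$positions)
  pos <- system$positions
  ext <- if (n > 0) c(diff(range(pos[, 1])), diff(range(pos[, 2]))) else c(0, 0)
  comment <- sprintf(
    paste0("time_ps=%.9g applied_strain=%.9g extent_x=%.9g extent_y=%.9g ",
           "species_map=P:%s,D:%s Properties=species:S:1:pos:R:2:vel:R:2"),
    system$time, system$applied_strain, ext[1], ext[2],
    element_map[["P"]], element_map[["D"]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(n), comment), con)
  if (n > 0) {
    el <- unname(element_map[system$species])
    writeLines(sprintf("%s %.10f %.10f %.10f %.10f",
                       el, pos[, 1], pos[, 2],
                       system$velocities[, 1], system$velocities[, 2]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ snapshot written by [write_snapshot()]
#'
#' @param path file path.
#' @param element_map the species-to-element map used on write.
#' @return a list with `positions`, `velocities` (n x 2 matrices),
#'   `species` (integer codes), `time` (ps) and `applied_strain`.
#' @export
read_snapshot <- function(path, element_map = c(P = "C", D = "O")) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  comment <- lines[2]
  grab <- function(key) {
    m <- regmatches(comment, regexpr(paste0(key, "=[^ ]+"), comment))
    if (!length(m)) return(NA_real_)
    as.numeric(sub(paste0(key, "="), "", m))
  }
  if (n == 0L)
    return(list(positions = matrix(0, 0, 2), velocities = matrix(0, 0, 2),
                species = integer(0), time = grab("time_ps"),
                applied_strain = grab("applied_strain")))
  tab <- utils::read.table(text = lines[3:(2 + n)])
  sp <- match(tab[[1]], unname(element_map))
  if (anyNA(sp)) stop("unknown element tag in snapshot", call. = FALSE)
  list(positions = cbind(x = tab[[2]], y = tab[[3]]),
       velocities = cbind(x = tab[[4]], y = tab[[5]]),
       species = as.integer(sp),
       time = grab("time_ps"),
       applied_strain = grab("applied_strain"))
}

#' Write / read the bond topology as a two-column integer table
#'
#' @param system a [lattice_system].
#' @param path file path.
#' @return `write_bond_list` returns `path` invisibly; `read_bond_list`
#'   returns an m x 2 integer matrix of block identifiers.
#' @export
write_bond_list <- function(system, path) {
  stopifnot(inherits(system, "lattice_system"))
  utils::write.table(system$bonds, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bond_list
#' @export
read_bond_list <- function(path) {
  tab <- utils::read.table(path)
  b <- cbind(as.integer(tab[[1]]), as.integer(tab[[2]]))
  colnames(b) <- c("i", "j")
  b
}
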