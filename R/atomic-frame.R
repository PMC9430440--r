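# Core container for one atomic configuration. Coordinates are always in
# Angstrom internally; file formats that use other units (GRO, nm) convert at
# the I/O boundary.

#' Construct an atomic frame
#'
#' An `atomic_frame` holds one configuration: Cartesian coordinates, an
#' orthorhombic periodic box, and per-atom labels (site, molecule id,
#' residue name, partial charge). It is the common currency of all analysis
#' functions in the package.
#'
#' @param coords numeric matrix, n x 3, coordinates in Angstrom.
#' @param box numeric length-3, orthorhombic box edges in Angstrom (all > 0).
#' @param site character vector, per-atom site label (e.g. `"OW"`, `"HW1"`,
#'   `"DW"`, `"S"`, `"MW"`).
#' @param molecule_id integer vector, per-atom molecule index. Atoms of one
#'   molecule must be contiguous.
#' @param residue character vector, per-atom residue name (e.g. `"SOL"`,
#'   `"DMS"`).
#' @param charge numeric vector, per-atom partial charge in elementary
#'   charge units. May be `NA` before a topology is attached.
#' @return an object of class `atomic_frame`.
#' @examples
#' fr <- atomic_frame(
#'   coords = rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'   box = c(20, 20, 20),
#'   site = c("OW", "HW1", "HW2"),
#'   molecule_id = c(1L, 1L, 1L),
#'   residue = c("SOL", "SOL", "SOL"),
#'   charge = c(-0.8476, 0.4238, 0.4238)
#' )
#' n_atoms(fr)
#' @export
atomic_frame <- function(coords, box, site, molecule_id, residue,
                         charge = rep(NA_real_, nrow(coords))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive edge lengths (orthorhombic)")
  }
  site <- as.character(site)
  molecule_id <- as.integer(molecule_id)
  residue <- as.character(residue)
  charge <- as.numeric(charge)
  if (length(site) != n || length(molecule_id) != n ||
      length(residue) != n || length(charge) != n) {
    stop("per-atom vectors must match nrow(coords)")
  }
  if (n > 0 && any(diff(molecule_id) < 0)) {
    stop("molecule_id must be non-decreasing (atoms contiguous per molecule)")
  }
  structure(
    list(coords = coords, box = box, site = site,
         molecule_id = molecule_id, residue = residue, charge = charge),
    class = "atomic_frame"
  )
}

#' Number of atoms in a frame
#' @param frame an [atomic_frame()].
#' @return integer atom count.
#' @export
n_atoms <- function(frame) nrow(frame$coords)

#' Number of molecules in a frame
#' @param frame an [atomic_frame()].
#' @return integer molecule count.
#' @export
n_molecules <- function(frame) length(unique(frame$molecule_id))

#' @export
print.atomic_frame <- function(x, ...) {
  cat(sprintf("<atomic_frame> %d atoms, %d molecules, box %.2f x %.2f x %.2f A\n",
              n_atoms(x), n_molecules(x), x$box[1], x$box[2], x$box[3]))
  res <- table(x$residue[!duplicated(x$molecule_id)])
  cat("  molecules:", paste(sprintf("%s=%d", names(res), res), collapse = ", "),
      "\n")
  invisible(x)
}

#' Validate frame invariants
#'
#' Checks the structural invariants an `atomic_frame` must satisfy: positive
#' box, contiguous molecule ids, D-labelled atoms confined to water-family
#' residues, and per-molecule charge neutrality (when charges are attached).
#'
#' @param frame an [atomic_frame()].
#' @param tol charge-neutrality tolerance in e.
#' @return the frame, invisibly; errors describe the violated invariant.
#' @export
validate_frame <- function(frame, tol = 1e-10) {
  stopifnot(inherits(frame, "atomic_frame"))
  if (any(frame$box <= 0)) stop("box components must be positive")
  dlab <- is_d_site(frame$site)
  if (any(dlab & !is_water_residue(frame$residue))) {
    stop("D-labelled atoms must belong to water-family residues")
  }
  if (!anyNA(frame$charge)) {
    qs <- vapply(split(frame$charge, frame$molecule_id), sum, numeric(1))
    bad <- which(abs(qs) > tol)
    if (length(bad)) {
      stop(sprintf("molecule %s carries net charge %.3e e",
                   names(qs)[bad[1]], qs[bad[1]]))
    }
  }
  invisible(frame)
}

# Water-family residues: ordinary 3-site water, 4-site (virtual M) water.
WATER_RESIDUES <- c("SOL", "SOL4", "HOH", "WAT")

is_water_residue <- function(residue) residue %in% WATER_RESIDUES

# D sites are distinguished by label only; charge and mass play no role.
is_d_site <- function(site) startsWith(site, "DW") | site == "D"

is_water_oxygen <- function(frame) {
  frame$site %in% c("OW", "O") & is_water_residue(frame$residue)
}

#' Row indices of atoms belonging to one molecule
#' @param frame an [atomic_frame()].
#' @param molecule_id integer molecule id.
#' @return integer vector of atom indices.
#' @export
molecule_atoms <- function(frame, molecule_id) {
  which(frame$molecule_id == molecule_id)
}

#' Extract a sub-frame by atom indices
#' @param frame an [atomic_frame()].
#' @param idx integer atom indices to keep.
#' @return an [atomic_frame()] with the selected atoms.
#' @export
subset_frame <- function(frame, idx) {
  atomic_frame(frame$coords[idx, , drop = FALSE], frame$box,
               frame$site[idx], frame$molecule_id[idx],
               frame$residue[idx], frame$charge[idx])
}

# ---- periodic geometry ------------------------------------------------------

#' Minimum-image displacement vectors
#'
#' @param dx numeric matrix (n x 3) of raw displacements in Angstrom.
#' @param box numeric length-3 orthorhombic box.
#' @return matrix of displacements wrapped to the nearest periodic image.
#' @export
min_image <- function(dx, box) {
  dx <- as.matrix(dx)
  if (nrow(dx) == 0L) return(dx)
  sweep_box <- matrix(box, nrow = nrow(dx), ncol = 3, byrow = TRUE)
  dx - sweep_box * round(dx / sweep_box)
}

#' Minimum-image distances from a reference point
#'
#' @param coords numeric matrix (n x 3), Angstrom.
#' @param ref numeric length-3 reference point.
#' @param box numeric length-3 orthorhombic box.
#' @return numeric vector of n distances.
#' @export
min_image_dist <- function(coords, ref, box) {
  dx <- min_image(sweep(as.matrix(coords), 2, ref), box)
  sqrt(rowSums(dx * dx))
}

# Pairwise min-image distances between two coordinate sets, chunked to bound
# memory on large frames. Returns the full n_a x n_b matrix.
pair_dist_matrix <- function(a, b, box, chunk = 512L) {
  a <- as.matrix(a); b <- as.matrix(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (start in seq(1L, nrow(a), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(a))
    for (k in 1:3) {
      d <- outer(a[idx, k], b[, k], "-")
      d <- d - box[k] * round(d / box[k])
      if (k == 1) acc <- d * d else acc <- acc + d * d
    }
    out[idx, ] <- sqrt(acc)
  }
  out
}

#' Wrap coordinates into the primary box
#' @param frame an [atomic_frame()].
#' @return the frame with all coordinates wrapped to `[0, box)`.
#' @export
wrap_frame <- function(frame) {
  frame$coords <- sweep(frame$coords, 2, frame$box, "%%")
  frame
}

# Angstrom per Bohr; the single place the unit conversion lives.
BOHR_ANGSTROM <- 0.529177
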