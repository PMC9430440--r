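# Electrostatic frequency map for the O-D stretch of dilute HDO probes.
# The instantaneous frequency is an affine function of the electrostatic
# potential (atomic units) evaluated at the probe's D, O and H atoms from
# all atoms of other molecules within a spherical cutoff, under the
# minimum-image convention. Strong (short) H-bonds to the D atom lower the
# potential there and red-shift the stretch.

#' Map coefficients for the O-D stretch frequency map
#'
#' @param omega0 intercept (unperturbed frequency), cm^-1.
#' @param coeff_d,coeff_o,coeff_h linear coefficients, cm^-1 per atomic
#'   unit of potential (e/Bohr), applied to the potential at the probe's
#'   D, O and H atoms respectively.
#' @param cutoff spherical truncation radius for the potential sum, Angstrom.
#' @return a `map_coefficients` list.
#' @export
map_coefficients <- function(omega0, coeff_d, coeff_o, coeff_h, cutoff = 7.8) {
  stopifnot(cutoff > 0, is.finite(omega0))
  structure(list(omega0 = unname(omega0),
                 coeffs = c(D = unname(coeff_d), O = unname(coeff_o),
                            H = unname(coeff_h)),
                 cutoff = unname(cutoff)),
            class = "map_coefficients")
}

#' Read map coefficients from a keyed CSV
#'
#' The file has columns `parameter,value` with keys `omega0_cm1`,
#' `coeff_D_cm1_per_au`, `coeff_O_cm1_per_au`, `coeff_H_cm1_per_au`,
#' `cutoff_angstrom`. With `path = NULL` the bundled representative map
#' (`map_od_synthetic.csv`) is loaded; its values are synthetic, chosen to
#' follow the literature's potential-map form and sign convention, not
#' transcribed from a published table.
#'
#' @param path CSV path, or `NULL` for the bundled default.
#' @return a [map_coefficients()] object.
#' @export
read_map_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "map_od_synthetic.csv", package = "hbmap",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, comment.char = "#")
  val <- function(key) {
    i <- match(key, tab$parameter)
    if (is.na(i)) stop("map file lacks parameter ", key)
    as.numeric(tab$value[i])
  }
  map_coefficients(val("omega0_cm1"), val("coeff_D_cm1_per_au"),
                   val("coeff_O_cm1_per_au"), val("coeff_H_cm1_per_au"),
                   val("cutoff_angstrom"))
}

#' Electrostatic potential at a point
#'
#' Coulomb sum `phi = sum_j q_j / r_j` in atomic units (charges in e,
#' distances in Bohr) over atoms of non-excluded molecules within the
#' cutoff, under the minimum-image convention. Abrupt truncation, no
#' Ewald: the standard convention for spectroscopic maps. With the default
#' `truncation = "molecule"` a molecule contributes all of its atoms or
#' none, based on the distance of its leading (heavy anchor) atom; this
#' keeps every included contribution charge-neutral and avoids the large
#' spurious monopole terms an atom-wise cutoff creates when it splits a
#' molecule at the boundary. `truncation = "atom"` applies the cutoff to
#' each atom individually.
#'
#' @param frame an [atomic_frame()] with charges attached.
#' @param site_position numeric length-3, Angstrom.
#' @param excluded_molecule molecule id(s) whose atoms are omitted (the
#'   probe's own molecule); `NULL` to include everything.
#' @param cutoff truncation radius in Angstrom; must not exceed half the
#'   smallest box edge (minimum-image validity).
#' @param truncation `"molecule"` (default) or `"atom"`.
#' @return potential in atomic units (e/Bohr).
#' @export
electrostatic_potential <- function(frame, site_position, excluded_molecule,
                                    cutoff,
                                    truncation = c("molecule", "atom")) {
  truncation <- match.arg(truncation)
  if (cutoff > min(frame$box) / 2 + 1e-9) {
    stop("cutoff exceeds half the smallest box edge (minimum image invalid)")
  }
  keep <- if (is.null(excluded_molecule)) rep(TRUE, n_atoms(frame)) else
    !(frame$molecule_id %in% excluded_molecule)
  if (anyNA(frame$charge[keep])) stop("frame has no charges attached")
  if (truncation == "molecule") {
    anchor <- which(!duplicated(frame$molecule_id))
    da <- min_image_dist(frame$coords[anchor, , drop = FALSE], site_position,
                         frame$box)
    mol_in <- frame$molecule_id[anchor][da <= cutoff]
    keep <- keep & frame$molecule_id %in% mol_in
    r <- min_image_dist(frame$coords[keep, , drop = FALSE], site_position,
                        frame$box)
    sum(frame$charge[keep] / (r / BOHR_ANGSTROM))
  } else {
    r <- min_image_dist(frame$coords[keep, , drop = FALSE], site_position,
                        frame$box)
    inside <- r <= cutoff
    sum(frame$charge[keep][inside] / (r[inside] / BOHR_ANGSTROM))
  }
}

# locate the D, O and remaining H atom of an HDO water
hdo_sites <- function(frame, hdo_molecule) {
  idx <- molecule_atoms(frame, hdo_molecule)
  if (length(idx) == 0L) stop("no such molecule: ", hdo_molecule)
  d_at <- idx[is_d_site(frame$site[idx])]
  if (length(d_at) != 1L) {
    stop(sprintf("molecule %d has %d D sites; an HDO probe needs exactly 1",
                 hdo_molecule, length(d_at)))
  }
  o_at <- idx[frame$site[idx] %in% c("OW", "O")]
  h_at <- idx[startsWith(frame$site[idx], "HW")]
  if (length(o_at) != 1L || length(h_at) != 1L) {
    stop(sprintf("molecule %d is not an HDO water (need one O and one H)",
                 hdo_molecule))
  }
  list(D = frame$coords[d_at, ], O = frame$coords[o_at, ],
       H = frame$coords[h_at, ])
}

#' Instantaneous O-D stretch frequency of one HDO probe
#'
#' `omega = omega0 + c_D phi(D) + c_O phi(O) + c_H phi(H)`, the potentials
#' evaluated by [electrostatic_potential()] with the probe's own molecule
#' excluded. An isolated probe therefore sits exactly at `omega0`.
#'
#' @param frame an [atomic_frame()] with charges.
#' @param hdo_molecule molecule id of a water carrying exactly one `DW` site.
#' @param map a [map_coefficients()] object.
#' @return frequency in cm^-1.
#' @export
od_frequency <- function(frame, hdo_molecule, map) {
  s <- hdo_sites(frame, hdo_molecule)
  phi <- vapply(s, function(p) {
    electrostatic_potential(frame, p, hdo_molecule, map$cutoff)
  }, numeric(1))
  unname(map$omega0 + sum(map$coeffs[c("D", "O", "H")] * phi[c("D", "O", "H")]))
}

# min-image distance from a point to the nearest DMSO sulfur; ties broken
# by lowest molecule id (atom order). NA when no DMSO present.
nearest_s_distance <- function(frame, point) {
  s_idx <- which(frame$site == "S" & frame$residue == "DMS")
  if (length(s_idx) == 0L) return(NA_real_)
  r <- min_image_dist(frame$coords[s_idx, , drop = FALSE], point, frame$box)
  min(r)
}

#' Frequency records for all HDO probes across frames
#'
#' For every HDO probe in every frame: the mapped frequency, the
#' minimum-image distance from its D atom to the nearest DMSO sulfur
#' (`NA` without DMSO), and the solvation-shell label at the given cutoff.
#'
#' @param frames a list of [atomic_frame()] (or a single frame).
#' @param map a [map_coefficients()] object.
#' @param shell_cutoff first-shell S...D cutoff, Angstrom.
#' @return data frame with columns `frame`, `molecule`, `omega`, `r_s`,
#'   `shell` (`"first_shell"`, `"bulk"` or `"n/a"`).
#' @export
frequency_records <- function(frames, map, shell_cutoff = 3.6) {
  if (inherits(frames, "atomic_frame")) frames <- list(frames)
  out <- list()
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    probes <- hdo_molecules(fr)
    for (mid in probes) {
      s <- hdo_sites(fr, mid)
      omega <- od_frequency(fr, mid, map)
      r_s <- nearest_s_distance(fr, s$D)
      shell <- if (is.na(r_s)) "n/a" else
        if (r_s <= shell_cutoff) "first_shell" else "bulk"
      out[[length(out) + 1L]] <- data.frame(
        frame = fi, molecule = mid, omega = omega, r_s = r_s, shell = shell)
    }
  }
  if (length(out) == 0L) stop("no HDO probes found in any frame")
  do.call(rbind, out)
}

#' Normalized instantaneous frequency distribution
#'
#' Histogram of all probe frequencies, normalized to unit area
#' (probability density over cm^-1), plus the raw per-probe records.
#'
#' @param frames list of [atomic_frame()].
#' @param map a [map_coefficients()] object.
#' @param bins ascending bin edges in cm^-1, or `NULL` to span the data
#'   with 2 cm^-1 bins.
#' @param shell_cutoff passed to [frequency_records()].
#' @return list with `histogram` (data frame `bin_center`, `density`) and
#'   `records`.
#' @export
frequency_distribution <- function(frames, map, bins = NULL,
                                   shell_cutoff = 3.6) {
  rec <- frequency_records(frames, map, shell_cutoff)
  if (is.null(bins)) {
    lo <- floor(min(rec$omega) / 2) * 2 - 2
    hi <- ceiling(max(rec$omega) / 2) * 2 + 2
    bins <- seq(lo, hi, by = 2)
  }
  if (any(rec$omega < bins[1]) || any(rec$omega > bins[length(bins)])) {
    stop("bin edges do not span the observed frequencies")
  }
  h <- graphics::hist(rec$omega, breaks = bins, plot = FALSE)
  width <- diff(bins)
  density <- h$counts / (sum(h$counts) * width)
  list(histogram = data.frame(bin_center = h$mids, density = density),
       records = rec)
}

#' Frequency ordering along a water-dimer H-bond scan
#'
#' Builds a linear water dimer (donor HDO with its D on the O...O axis,
#' acceptor water facing away) at each donor-acceptor O...O distance and
#' maps the donor's O-D frequency. With the physical sign convention, a
#' shorter (stronger) H-bond gives a lower (red-shifted) frequency, so the
#' returned frequencies increase with distance.
#'
#' @param distances donor-acceptor O...O distances, Angstrom.
#' @param map a [map_coefficients()] object.
#' @param topology `topology_table`; `NULL` for the bundled default.
#' @return data frame `distance`, `omega`.
#' @export
hbond_frequency_scan <- function(distances, map, topology = NULL) {
  if (is.null(topology)) topology <- default_topology()
  box <- rep(max(4 * map$cutoff, 60), 3)
  ctr <- box / 2
  half <- HOH_ANGLE / 2 * pi / 180
  omega <- vapply(distances, function(r_oo) {
    # donor: O at centre, D along +x toward the acceptor, H in the xy-plane
    don_o <- ctr
    don_d <- ctr + c(R_OH, 0, 0)
    don_h <- ctr + R_OH * c(cos(HOH_ANGLE * pi / 180),
                            sin(HOH_ANGLE * pi / 180), 0)
    # acceptor: O on the axis, H's pointing away (bisector along +x)
    acc_o <- ctr + c(r_oo, 0, 0)
    acc_h1 <- acc_o + R_OH * c(cos(half), sin(half), 0)
    acc_h2 <- acc_o + R_OH * c(cos(half), -sin(half), 0)
    fr <- atomic_frame(rbind(don_o, don_d, don_h, acc_o, acc_h1, acc_h2),
                       box,
                       c("OW", "DW", "HW1", "OW", "HW1", "HW2"),
                       c(1L, 1L, 1L, 2L, 2L, 2L),
                       rep("SOL", 6))
    fr <- attach_charges(fr, topology)
    od_frequency(fr, 1L, map)
  }, numeric(1))
  data.frame(distance = distances, omega = omega)
}
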