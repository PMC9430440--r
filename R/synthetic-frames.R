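# Generators for the configurations the analysis assumes: an ideal
# hexagonal-ice lattice (the crystalline reference), a uniform random gas
# (the fully disordered reference), and randomly packed DMSO/water mixture
# boxes at prescribed mass fractions. These stand in for MD trajectories:
# they reproduce the structural limits the analysis is tested against, not
# the thermodynamics of real simulations.

M_H2O <- 18.015
M_D2O <- 20.028
M_DMSO <- 78.13
AMU_PER_G_CM3 <- 1.66054 # V[A^3] = 1.66054 * mass[amu] / density[g/cm^3]

R_OH <- 0.9572   # A, covalent O-H
HOH_ANGLE <- 104.52 # degrees

# ---- molecule templates -----------------------------------------------------

water_template <- function(residue = "SOL") {
  half <- HOH_ANGLE / 2 * pi / 180
  coords <- rbind(
    c(0, 0, 0),
    R_OH * c(sin(half), cos(half), 0),
    R_OH * c(-sin(half), cos(half), 0))
  site <- c("OW", "HW1", "HW2")
  if (residue == "SOL4") {
    coords <- rbind(coords, c(0, 0.1577, 0))
    site <- c(site, "MW")
  }
  list(coords = coords, site = site, residue = residue)
}

dmso_template <- function() {
  # united-atom DMSO: S=O 1.53 A, S-C 1.80 A, O-S-C 106.75 deg, C-S-C 97.4 deg
  th <- 106.75 * pi / 180
  cscs <- cos(97.4 * pi / 180)
  cos2phi <- (cscs - cos(th)^2) / sin(th)^2
  phi <- acos(pmin(1, pmax(-1, cos2phi))) / 2
  coords <- rbind(
    c(0, 0, 0),
    c(0, 0, 1.53),
    1.80 * c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th)),
    1.80 * c(sin(th) * cos(-phi), sin(th) * sin(-phi), cos(th)))
  list(coords = coords, site = c("S", "O", "C1", "C2"), residue = "DMS")
}

# uniform random rotation matrix (Arvo / quaternion method)
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# ---- specs ------------------------------------------------------------------

#' Specification of a hexagonal-ice lattice
#'
#' @param n_cells integer length-3, repeats of the orthorhombic supercell
#'   (which spans `a` x `sqrt(3) a` x `c`).
#' @param oo_distance nearest-neighbour O...O distance in Angstrom.
#' @param a,c hexagonal lattice constants in Angstrom; by default derived
#'   from `oo_distance` at the ideal ratio (`a = d sqrt(8/3)`, `c = 8 d / 3`),
#'   which makes every O exactly tetrahedral.
#' @param proton_scheme `"ordered"` (deterministic proton assignment) or
#'   `"bernal_fowler_random"` (seeded random assignment). Both satisfy the
#'   ice rules: two covalent H per O, one H per O...O link.
#' @return a `lattice_spec` list.
#' @export
lattice_spec <- function(n_cells = c(3L, 3L, 3L), oo_distance = 2.75,
                         a = NULL, c = NULL,
                         proton_scheme = c("ordered", "bernal_fowler_random")) {
  proton_scheme <- match.arg(proton_scheme)
  stopifnot(length(n_cells) == 3, all(n_cells >= 1), oo_distance > 0)
  if (is.null(a)) a <- oo_distance * sqrt(8 / 3)
  if (is.null(c)) c <- 8 * oo_distance / 3
  stopifnot(a > 0, c > 0)
  structure(list(n_cells = as.integer(n_cells), oo_distance = oo_distance,
                 a = a, c = c, proton_scheme = proton_scheme),
            class = "lattice_spec")
}

#' Specification of a DMSO/water mixture
#'
#' @param wt_dmso DMSO mass fraction of the whole mixture, percent.
#' @param wt_d2o heavy-water mass fraction of the aqueous part, percent
#'   (the D2O is realised as HDO-labelled waters; see Details).
#' @param n_molecules_total total molecule count.
#' @param target_density g/cm^3. Default 1.0 for aqueous mixtures, 1.1 at
#'   and above 25 wt% DMSO (cold concentrated mixtures are denser).
#' @details In excess H2O, D2O exchanges to HDO, so the builder never places
#'   a D2O molecule: each molecule counted as D2O in the mass balance is
#'   placed as a water with one hydrogen relabelled `DW`. The label carries
#'   no charge or mass change.
#' @return a `composition_spec` list.
#' @export
composition_spec <- function(wt_dmso = 33, wt_d2o = 5,
                             n_molecules_total = 200,
                             target_density = NULL) {
  stopifnot(wt_dmso >= 0, wt_dmso < 100, wt_d2o >= 0, wt_d2o < 100,
            n_molecules_total >= 1)
  if (is.null(target_density)) {
    target_density <- if (wt_dmso >= 25) 1.1 else 1.0
  }
  stopifnot(target_density > 0)
  structure(list(wt_dmso = wt_dmso, wt_d2o = wt_d2o,
                 n_molecules_total = as.integer(n_molecules_total),
                 target_density = target_density),
            class = "composition_spec")
}

#' Molecule counts matching a mixture composition
#'
#' Closed-form mass balance: chooses DMSO, H2O and D2O counts whose
#' recomputed mass fractions are as close as the one-molecule granularity
#' allows to the requested ones.
#'
#' @param spec a [composition_spec()].
#' @return list with `n_dmso`, `n_h2o`, `n_d2o` (realised as HDO), and the
#'   achieved `wt_dmso`, `wt_d2o` in percent.
#' @export
mixture_counts <- function(spec) {
  n <- spec$n_molecules_total
  f_d <- spec$wt_dmso / 100
  f_h <- spec$wt_d2o / 100
  best <- NULL
  for (n_dmso in 0:(n - 1L)) {
    n_w <- n - n_dmso
    n_d2o <- round(f_h * n_w * M_H2O / (M_D2O * (1 - f_h) + f_h * M_H2O))
    n_d2o <- min(max(n_d2o, 0L), n_w)
    n_h2o <- n_w - n_d2o
    m_aq <- n_h2o * M_H2O + n_d2o * M_D2O
    m_dmso <- n_dmso * M_DMSO
    got <- m_dmso / (m_dmso + m_aq)
    if (is.null(best) || abs(got - f_d) < best$err) {
      best <- list(n_dmso = n_dmso, n_h2o = n_h2o, n_d2o = n_d2o,
                   err = abs(got - f_d),
                   wt_dmso = 100 * got,
                   wt_d2o = if (m_aq > 0) 100 * n_d2o * M_D2O / m_aq else 0)
    }
  }
  best$err <- NULL
  best
}

# ---- ice --------------------------------------------------------------------

# Eulerian orientation of the 4-regular O-O bond graph: every vertex gets
# out-degree 2 (its covalent H's) and in-degree 2 (accepted H-bonds), and
# every edge carries exactly one H -- the Bernal-Fowler ice rules.
eulerian_orientation <- function(edges, n_vertices, randomize = FALSE) {
  m <- nrow(edges)
  adj <- vector("list", n_vertices)
  for (e in seq_len(m)) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], e)
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], e)
  }
  if (randomize) adj <- lapply(adj, function(v) v[sample.int(length(v))])
  used <- logical(m)
  ptr <- rep(1L, n_vertices)
  orient_from <- integer(m) # vertex the edge is directed out of
  # Hierholzer: walk unused edges until stuck, splice remaining cycles
  stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]
    advanced <- FALSE
    while (ptr[v] <= length(adj[[v]])) {
      e <- adj[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      if (!used[e]) {
        used[e] <- TRUE
        orient_from[e] <- v
        w <- if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
        stack <- c(stack, w)
        advanced <- TRUE
        break
      }
    }
    if (!advanced) stack <- stack[-length(stack)]
  }
  if (!all(used)) stop("O-O bond graph is disconnected; cannot orient protons")
  orient_from
}

#' Build a hexagonal-ice configuration
#'
#' Oxygens are placed on the lonsdaleite (wurtzite-type) sublattice of ice
#' Ih in an orthorhombic supercell; at the ideal lattice-constant ratio
#' every oxygen has exactly four neighbours at `oo_distance` in perfect
#' tetrahedral directions, so the tetrahedral order parameter is exactly 1.
#' Hydrogens are placed along O...O axes subject to the Bernal-Fowler ice
#' rules, either deterministically (`ordered`) or with a seeded random
#' Eulerian orientation (`bernal_fowler_random`).
#'
#' @param spec a [lattice_spec()].
#' @param seed integer seed (only used by the random proton scheme).
#' @param topology `topology_table` used to attach charges; `NULL` for the
#'   bundled default.
#' @return an [atomic_frame()] of `SOL` waters.
#' @export
build_ice_lattice <- function(spec, seed = 1L, topology = NULL) {
  stopifnot(inherits(spec, "lattice_spec"))
  a <- spec$a; cc <- spec$c
  cell <- c(a, sqrt(3) * a, cc)
  box <- spec$n_cells * cell
  if (any(box < 2 * spec$oo_distance)) {
    stop("n_cells too small: every box edge must exceed twice oo_distance; ",
         "increase n_cells")
  }
  a1 <- c(a, 0, 0); a2 <- c(-a / 2, sqrt(3) * a / 2, 0)
  basis_hex <- rbind(c(1 / 3, 2 / 3, 0), c(2 / 3, 1 / 3, 1 / 2),
                     c(1 / 3, 2 / 3, 3 / 8), c(2 / 3, 1 / 3, 7 / 8))
  base <- t(apply(basis_hex, 1, function(f) {
    f[1] * a1 + f[2] * a2 + c(0, 0, f[3] * cc)
  }))
  base <- rbind(base, sweep(base, 2, a2 + a1, "+")) # second hex point of ortho cell
  base <- sweep(base, 2, cell, "%%")
  reps <- expand.grid(x = seq_len(spec$n_cells[1]) - 1L,
                      y = seq_len(spec$n_cells[2]) - 1L,
                      z = seq_len(spec$n_cells[3]) - 1L)
  ox <- do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
    sweep(base, 2, as.numeric(reps[i, ]) * cell, "+")
  }))
  n_ox <- nrow(ox)

  # O-O bond graph at oo_distance (min image)
  d <- pair_dist_matrix(ox, ox, box)
  nb <- which(d > 1e-9 & abs(d - spec$oo_distance) < 1e-6, arr.ind = TRUE)
  nb <- nb[nb[, 1] < nb[, 2], , drop = FALSE]
  deg <- tabulate(c(nb[, 1], nb[, 2]), n_ox)
  if (any(deg != 4L)) {
    stop("lattice construction failed: some oxygen lacks 4 neighbours")
  }
  set.seed(seed)
  orient <- eulerian_orientation(nb, n_ox,
                                 randomize = spec$proton_scheme ==
                                   "bernal_fowler_random")
  donors <- vector("list", n_ox)
  for (e in seq_len(nrow(nb))) {
    v <- orient[e]
    w <- if (nb[e, 1] == v) nb[e, 2] else nb[e, 1]
    donors[[v]] <- c(donors[[v]], w)
  }
  coords <- matrix(0, 3 * n_ox, 3)
  site <- character(3 * n_ox); mol <- integer(3 * n_ox)
  for (i in seq_len(n_ox)) {
    j <- 3L * (i - 1L)
    coords[j + 1L, ] <- ox[i, ]
    for (k in 1:2) {
      dv <- min_image(matrix(ox[donors[[i]][k], ] - ox[i, ], 1), box)[1, ]
      coords[j + 1L + k, ] <- ox[i, ] + R_OH * dv / sqrt(sum(dv^2))
    }
    site[j + 1:3] <- c("OW", "HW1", "HW2")
    mol[j + 1:3] <- i
  }
  fr <- atomic_frame(coords, box, site, mol, rep("SOL", 3 * n_ox))
  if (is.null(topology)) topology <- default_topology()
  validate_frame(attach_charges(wrap_frame(fr), topology))
}

# ---- random gas -------------------------------------------------------------

#' Build a uniform random gas
#'
#' Single-site "molecules" placed uniformly in the box: the fully
#' disordered reference whose tetrahedral order parameter averages zero and
#' whose pair correlation g(r) is 1.
#'
#' @param n number of particles (>= 5, since the order parameter needs 4
#'   neighbours).
#' @param box numeric length-3 box in Angstrom (a scalar is recycled).
#' @param seed integer seed.
#' @return an [atomic_frame()] of single-site `GAS` particles.
#' @export
build_random_gas <- function(n, box, seed = 1L) {
  if (length(box) == 1L) box <- rep(box, 3)
  if (any(box <= 0)) stop("box dimensions must be positive")
  if (n < 5) stop("need n >= 5 (order parameter requires 4 neighbours)")
  set.seed(seed)
  coords <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                  stats::runif(n, 0, box[3]))
  atomic_frame(coords, box, rep("X", n), seq_len(n), rep("GAS", n),
               rep(0, n))
}

# ---- mixture packing --------------------------------------------------------

#' Build a randomly packed DMSO/water mixture box
#'
#' Molecule counts come from the closed-form mass balance
#' ([mixture_counts()]); the cubic box volume is set by the target density;
#' molecules are placed at random positions and orientations by rejection
#' sampling with a hard minimum intermolecular atom distance.
#'
#' @param spec a [composition_spec()].
#' @param seed integer seed.
#' @param min_dist minimum intermolecular atom-atom distance, Angstrom.
#' @param max_attempts total rejection-sampling attempts before giving up.
#' @param topology `topology_table`; `NULL` for the bundled default.
#' @return an [atomic_frame()]; waters counted as D2O carry one `DW` site.
#' @export
build_mixture_box <- function(spec, seed = 1L, min_dist = 1.5,
                              max_attempts = 1e5, topology = NULL) {
  stopifnot(inherits(spec, "composition_spec"))
  cnt <- mixture_counts(spec)
  mass <- cnt$n_dmso * M_DMSO + cnt$n_h2o * M_H2O + cnt$n_d2o * M_D2O
  vol <- AMU_PER_G_CM3 * mass / spec$target_density
  box <- rep(vol^(1 / 3), 3)
  set.seed(seed)
  templates <- c(rep(list(dmso_template()), cnt$n_dmso),
                 rep(list(water_template()), cnt$n_h2o + cnt$n_d2o))
  placed <- NULL
  coords_l <- list(); site <- character(); mol <- integer(); res <- character()
  attempts <- 0L
  for (i in seq_along(templates)) {
    tmpl <- templates[[i]]
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("packing failed after ", max_attempts,
             " attempts; lower target_density or molecule count")
      }
      pos <- stats::runif(3) * box
      xyz <- tmpl$coords %*% t(random_rotation())
      xyz <- sweep(xyz, 2, pos, "+")
      if (is.null(placed) ||
          min(pair_dist_matrix(xyz, placed, box)) >= min_dist) break
    }
    placed <- rbind(placed, xyz)
    coords_l[[i]] <- xyz
    site <- c(site, tmpl$site)
    mol <- c(mol, rep(i, nrow(xyz)))
    res <- c(res, rep(tmpl$residue, nrow(xyz)))
  }
  fr <- atomic_frame(do.call(rbind, coords_l), box, site, mol, res)
  # the D2O share of the aqueous part is realised as HDO probes
  if (cnt$n_d2o > 0) {
    water_ids <- unique(fr$molecule_id[is_water_residue(fr$residue)])
    pick <- water_ids[sample.int(length(water_ids), cnt$n_d2o)]
    for (mid in pick) {
      idx <- molecule_atoms(fr, mid)
      h <- idx[startsWith(fr$site[idx], "HW")]
      fr$site[h[sample.int(length(h), 1L)]] <- "DW"
    }
  }
  if (is.null(topology)) topology <- default_topology()
  fr <- attach_charges(wrap_frame(fr), topology)
  attr(fr, "counts") <- cnt
  validate_frame(fr)
}

# ---- perturbation and isotope labelling -------------------------------------

#' Apply Gaussian positional disorder
#'
#' Adds i.i.d. Gaussian displacements to every atom (or, with
#' `rigid = TRUE`, one displacement per molecule), emulating thermal
#' disorder on top of an ordered configuration.
#'
#' @param frame an [atomic_frame()].
#' @param sigma displacement standard deviation per Cartesian component,
#'   Angstrom. `sigma = 0` returns the frame unchanged.
#' @param seed integer seed.
#' @param rigid logical; displace whole molecules instead of atoms.
#' @return the perturbed [atomic_frame()].
#' @export
perturb_frame <- function(frame, sigma, seed = 1L, rigid = FALSE) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(frame)
  set.seed(seed)
  n <- n_atoms(frame)
  if (rigid) {
    ids <- unique(frame$molecule_id)
    disp <- matrix(stats::rnorm(3 * length(ids), sd = sigma), ncol = 3)
    frame$coords <- frame$coords +
      disp[match(frame$molecule_id, ids), , drop = FALSE]
  } else {
    frame$coords <- frame$coords + matrix(stats::rnorm(3 * n, sd = sigma),
                                          ncol = 3)
  }
  frame
}

#' Label a fraction of waters as HDO probes
#'
#' Relabels exactly one hydrogen site of `round(fraction * n_waters)`
#' randomly chosen waters as `DW`. The relabelling is purely isotopic:
#' charges and coordinates are untouched.
#'
#' @param frame an [atomic_frame()] containing waters.
#' @param fraction fraction of waters to deuterate, in `[0, 1]`.
#' @param seed integer seed.
#' @return the relabelled [atomic_frame()].
#' @export
substitute_hdo <- function(frame, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  water_ids <- unique(frame$molecule_id[is_water_residue(frame$residue)])
  if (length(water_ids) == 0L) stop("no water molecules in frame")
  # start from undeuterated labels so the call is idempotent in intent
  dw <- is_d_site(frame$site)
  frame$site[dw] <- "HW1"
  n_pick <- round(fraction * length(water_ids))
  if (n_pick > 0) {
    set.seed(seed)
    pick <- water_ids[sample.int(length(water_ids), n_pick)]
    for (mid in pick) {
      idx <- molecule_atoms(frame, mid)
      h <- idx[startsWith(frame$site[idx], "HW")]
      frame$site[h[sample.int(length(h), 1L)]] <- "DW"
    }
  }
  frame
}

#' Molecule ids of HDO probes in a frame
#' @param frame an [atomic_frame()].
#' @return integer vector of molecule ids carrying exactly one `DW` site.
#' @export
hdo_molecules <- function(frame) {
  dmol <- frame$molecule_id[is_d_site(frame$site)]
  as.integer(names(which(table(dmol) == 1L)))
}
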