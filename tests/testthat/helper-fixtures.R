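# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# reduced-cutoff map so desk-scale boxes satisfy the minimum-image bound
test_map <- function(cutoff = 6) {
  map_coefficients(2650, 2300, -2000, -300, cutoff = cutoff)
}

fixture_ice <- function() {
  cached("ice", function() {
    substitute_hdo(build_ice_lattice(lattice_spec(n_cells = c(3L, 2L, 2L))),
                   fraction = 0.3, seed = 1)
  })
}

fixture_liquid <- function() {
  cached("liquid", function() {
    lapply(1:3, function(i) {
      perturb_frame(
        build_mixture_box(composition_spec(0, 30, 140, 1.0), seed = i),
        sigma = 0.05, seed = i)
    })
  })
}

fixture_mixture <- function() {
  cached("mixture", function() {
    build_mixture_box(composition_spec(33, 20, 140), seed = 11)
  })
}

# one DMSO molecule embedded in an ice lattice: waters overlapping the
# solute are removed, and (optionally) waters within shell_cutoff of the
# sulfur are positionally scrambled while the bulk stays ice-like. The
# carved cavity pushes the nearest waters beyond the liquid-state 3.6 A
# shell, so fixture analyses use a matching wider cutoff.
fixture_dmso_in_ice <- function(scramble_sigma = 0, shell_cutoff = 5) {
  ice <- build_ice_lattice(lattice_spec(n_cells = c(3L, 2L, 2L)))
  ctr <- ice$box / 2
  tmpl <- hbmap:::dmso_template()
  dxyz <- sweep(tmpl$coords, 2, ctr, "+")
  # drop waters clashing with the solute
  keep_mol <- unique(ice$molecule_id)
  for (mid in unique(ice$molecule_id)) {
    idx <- which(ice$molecule_id == mid)
    dmin <- min(hbmap:::pair_dist_matrix(ice$coords[idx, , drop = FALSE],
                                         dxyz, ice$box))
    if (dmin < 2.4) keep_mol <- setdiff(keep_mol, mid)
  }
  wat <- subset_frame(ice, which(ice$molecule_id %in% keep_mol))
  coords <- rbind(dxyz, wat$coords)
  site <- c(tmpl$site, wat$site)
  mol <- c(rep(1L, nrow(dxyz)), 1L + match(wat$molecule_id,
                                           unique(wat$molecule_id)))
  res <- c(rep("DMS", nrow(dxyz)), wat$residue)
  fr <- atomic_frame(coords, ice$box, site, mol, res)
  fr <- attach_charges(fr, default_topology())
  if (scramble_sigma > 0) {
    sp <- shell_partition(fr, shell_cutoff)
    shell_mols <- sp$molecule[sp$shell == "first_shell"]
    set.seed(42)
    idx <- which(fr$molecule_id %in% shell_mols)
    fr$coords[idx, ] <- fr$coords[idx, ] +
      matrix(stats::rnorm(3 * length(idx), sd = scramble_sigma), ncol = 3)
  }
  fr
}

# canonical 4-component truth for fitting studies: three narrow peaks and
# one broad ~120 cm^-1 component
truth_components <- function() {
  data.frame(center = c(2425, 2350, 2490, 2470),
             fwhm = c(30, 28, 32, 120),
             amplitude = c(1, 0.2, 0.25, 0.35))
}
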