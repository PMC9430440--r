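test_that("ideal ice lattice is perfectly tetrahedral with 4 neighbours", {
  ice <- build_ice_lattice(lattice_spec(n_cells = c(3L, 3L, 3L),
                                        oo_distance = 2.75))
  qt <- tetrahedral_q(ice)
  expect_equal(nrow(qt), n_molecules(ice))
  expect_true(all(abs(qt$q - 1) < 1e-9))
  nd <- as.matrix(qt[, c("d1", "d2", "d3", "d4")])
  expect_true(all(abs(nd - 2.75) < 1e-6))
})

test_that("ice builder rejects boxes too small for minimum imaging", {
  expect_error(build_ice_lattice(lattice_spec(n_cells = c(1L, 1L, 1L))),
               "n_cells")
})

test_that("O-H bonds lie on O...O axes and obey the Bernal-Fowler rules", {
  for (scheme in c("ordered", "bernal_fowler_random")) {
    ice <- build_ice_lattice(lattice_spec(n_cells = c(2L, 2L, 2L),
                                          proton_scheme = scheme), seed = 5)
    o_idx <- which(ice$site == "OW")
    ox <- ice$coords[o_idx, ]
    d <- hbmap:::pair_dist_matrix(ox, ox, ice$box)
    links <- which(d > 1e-9 & abs(d - 2.75) < 1e-6, arr.ind = TRUE)
    links <- links[links[, 1] < links[, 2], , drop = FALSE]
    # every H lies on an axis to a neighbour at oo_distance, and each
    # O...O link carries exactly one covalent H
    h_idx <- which(startsWith(ice$site, "HW"))
    assign_link <- integer(0)
    for (h in h_idx) {
      mid <- ice$molecule_id[h]
      o_at <- which(ice$molecule_id == mid & ice$site == "OW")
      i <- match(o_at, o_idx)
      vh <- min_image(matrix(ice$coords[h, ] - ice$coords[o_at, ], 1),
                      ice$box)[1, ]
      vh <- vh / sqrt(sum(vh^2))
      nb <- which(d[i, ] > 1e-9 & abs(d[i, ] - 2.75) < 1e-6)
      cosines <- vapply(nb, function(j) {
        vj <- min_image(matrix(ox[j, ] - ox[i, ], 1), ice$box)[1, ]
        sum(vh * vj) / sqrt(sum(vj^2))
      }, numeric(1))
      j <- nb[which.max(cosines)]
      expect_gt(max(cosines), 1 - 1e-9) # H exactly on an O...O axis
      assign_link <- c(assign_link,
                       paste(min(i, j), max(i, j), sep = "-"))
    }
    expect_equal(length(assign_link), nrow(links))
    expect_equal(anyDuplicated(assign_link), 0L) # one H per link
  }
})

test_that("random proton scheme reuses oxygen positions but not H layout", {
  spec <- lattice_spec(n_cells = c(2L, 2L, 2L),
                       proton_scheme = "bernal_fowler_random")
  a <- build_ice_lattice(spec, seed = 1)
  b <- build_ice_lattice(spec, seed = 2)
  expect_equal(a$coords[a$site == "OW", ], b$coords[b$site == "OW", ])
  expect_false(isTRUE(all.equal(a$coords[a$site == "HW1", ],
                                b$coords[b$site == "HW1", ])))
  # deterministic under the same seed
  expect_equal(build_ice_lattice(spec, seed = 1)$coords, a$coords)
})

test_that("random gas has vanishing mean order parameter and is seeded", {
  gas <- build_random_gas(4096, 40, seed = 2)
  q <- tetrahedral_q(gas)$q
  expect_lt(abs(mean(q)), 0.02)
  expect_equal(build_random_gas(50, 20, seed = 9)$coords,
               build_random_gas(50, 20, seed = 9)$coords)
  expect_error(build_random_gas(4, 20), "n >= 5")
  expect_error(build_random_gas(10, -1), "positive")
})

test_that("q = 1 for a perfect tetrahedron around a gas particle", {
  a <- 1 / sqrt(3)
  tet <- rbind(c(a, a, a), c(a, -a, -a), c(-a, a, -a), c(-a, -a, a)) * 3
  coords <- rbind(c(0, 0, 0), tet) + 10
  fr <- atomic_frame(coords, c(20, 20, 20), rep("X", 5), 1:5,
                     rep("GAS", 5), rep(0, 5))
  expect_equal(tetrahedral_q(fr, molecule_ids = 1L)$q, 1, tolerance = 1e-12)
})

test_that("mixture counts satisfy the closed-form mass balance", {
  for (wt in c(0, 11, 22, 33)) {
    spec <- composition_spec(wt, 5, 1000)
    cnt <- mixture_counts(spec)
    m_dmso <- cnt$n_dmso * 78.13
    m_aq <- cnt$n_h2o * 18.015 + cnt$n_d2o * 20.028
    achieved <- 100 * m_dmso / (m_dmso + m_aq)
    # within one molecule's mass share of the target
    share <- 100 * 78.13 / (m_dmso + m_aq)
    expect_lt(abs(achieved - wt), max(share, 1e-9) + 1e-9)
    if (wt == 0) expect_identical(cnt$n_dmso, 0L)
    if (wt > 0) {
      aq_share <- 100 * 20.028 / m_aq
      expect_lt(abs(cnt$wt_d2o - 5), aq_share)
    }
  }
})

test_that("mixture box is neutral, packed and correctly deuterated", {
  mb <- fixture_mixture()
  cnt <- attr(mb, "counts")
  expect_lt(abs(sum(mb$charge)), 1e-10)
  qs <- vapply(split(mb$charge, mb$molecule_id), sum, numeric(1))
  expect_true(all(abs(qs) < 1e-10))
  expect_equal(length(hdo_molecules(mb)), cnt$n_d2o)
  # no intermolecular contact below the packing minimum
  d <- hbmap:::pair_dist_matrix(mb$coords, mb$coords, mb$box)
  same <- outer(mb$molecule_id, mb$molecule_id, "==")
  expect_gte(min(d[!same]), 1.5)
  # deterministic under seed
  mb2 <- build_mixture_box(composition_spec(33, 20, 140), seed = 11)
  expect_equal(mb$coords, mb2$coords)
  expect_identical(mb$site, mb2$site)
})

test_that("impossible packing densities fail with guidance", {
  expect_error(
    build_mixture_box(composition_spec(0, 0, 60, target_density = 8),
                      seed = 1, max_attempts = 2000),
    "lower target_density")
})

test_that("perturbation is seeded, optional and monotone in disorder", {
  ice <- build_ice_lattice(lattice_spec(n_cells = c(2L, 2L, 2L)))
  expect_identical(perturb_frame(ice, 0)$coords, ice$coords)
  expect_equal(perturb_frame(ice, 0.1, seed = 3)$coords,
               perturb_frame(ice, 0.1, seed = 3)$coords)
  mean_q <- vapply(c(0, 0.05, 0.1, 0.2), function(s) {
    mean(tetrahedral_q(perturb_frame(ice, s, seed = 7))$q)
  }, numeric(1))
  expect_true(all(diff(mean_q) < 0))
  expect_lt(mean_q[2], 1)
  # rigid mode preserves intramolecular geometry
  rig <- perturb_frame(ice, 0.3, seed = 2, rigid = TRUE)
  i1 <- molecule_atoms(ice, 1L)
  expect_equal(as.numeric(dist(rig$coords[i1, ])),
               as.numeric(dist(ice$coords[i1, ])), tolerance = 1e-12)
})

test_that("HDO substitution follows the rounding contract", {
  ice <- build_ice_lattice(lattice_spec(n_cells = c(2L, 2L, 2L)))
  expect_length(hdo_molecules(substitute_hdo(ice, 0)), 0)
  all_d <- substitute_hdo(ice, 1, seed = 4)
  expect_length(hdo_molecules(all_d), n_molecules(ice))
  per_mol <- table(all_d$molecule_id[hbmap:::is_d_site(all_d$site)])
  expect_true(all(per_mol == 1))
  frac <- substitute_hdo(ice, 0.05, seed = 4)
  expect_length(hdo_molecules(frac), round(0.05 * n_molecules(ice)))
  gas <- build_random_gas(10, 20)
  expect_error(substitute_hdo(gas, 0.5), "no water")
})

test_that("synthetic spectra realize the Gaussian model exactly", {
  sp <- synth_spectrum(spectrum_spec(
    data.frame(center = 2500, fwhm = 40, amplitude = 0.8),
    grid = c(2300, 2700, 0.5)))
  expect_equal(max(sp$absorbance), 0.8)
  expect_equal(sp$wavenumber[which.max(sp$absorbance)], 2500)
  at <- function(nu) sp$absorbance[match(nu, sp$wavenumber)]
  expect_equal(at(2500 - 20), 0.4, tolerance = 1e-12)
  expect_equal(at(2500 + 20), 0.4, tolerance = 1e-12)
  # integral equals the sum of closed-form component areas
  truth <- truth_components()
  sp4 <- synth_spectrum(spectrum_spec(truth, grid = c(2100, 2900, 0.25)))
  num <- sum(sp4$absorbance) * 0.25
  ana <- sum(truth$amplitude * truth$fwhm * sqrt(pi / (4 * log(2))))
  expect_equal(num, ana, tolerance = 1e-6)
  # seeded noise is reproducible
  s1 <- synth_spectrum(spectrum_spec(truth, noise_sd = 0.01, seed = 3))
  s2 <- synth_spectrum(spectrum_spec(truth, noise_sd = 0.01, seed = 3))
  expect_identical(s1$absorbance, s2$absorbance)
})
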