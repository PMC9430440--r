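make_center_frame <- function(neighbour_offsets) {
  coords <- rbind(c(0, 0, 0), neighbour_offsets) + 15
  n <- nrow(coords)
  atomic_frame(coords, c(30, 30, 30), rep("X", n), seq_len(n),
               rep("GAS", n), rep(0, n))
}

test_that("tetrahedral q hits its closed-form limits", {
  a <- 1 / sqrt(3)
  tet <- rbind(c(a, a, a), c(a, -a, -a), c(-a, a, -a), c(-a, -a, a)) * 2.7
  expect_equal(tetrahedral_q(make_center_frame(tet), 1L)$q, 1,
               tolerance = 1e-12)
  # square planar: four 90-degree pairs and two 180-degree pairs -> 1/2
  sq <- rbind(c(2.7, 0, 0), c(-2.7, 0, 0), c(0, 2.7, 0), c(0, -2.7, 0))
  expect_equal(tetrahedral_q(make_center_frame(sq), 1L)$q, 0.5,
               tolerance = 1e-12)
  # all four neighbours collinear on one side -> the -3 minimum
  col <- rbind(c(2.0, 0, 0), c(2.5, 0, 0), c(3.0, 0, 0), c(3.5, 0, 0))
  expect_equal(tetrahedral_q(make_center_frame(col), 1L)$q, -3,
               tolerance = 1e-12)
})

test_that("q respects its analytic range on arbitrary configurations", {
  for (s in 1:10) {
    gas <- build_random_gas(60, 18, seed = s)
    q <- tetrahedral_q(gas)$q
    expect_true(all(q <= 1 + 1e-12 & q > -3 - 1e-12))
  }
})

test_that("rdf matches the brute-force pair-count oracle", {
  mb <- build_mixture_box(composition_spec(33, 20, 30), seed = 4)
  r <- rdf(mb, "OW", c("HW", "DW"), r_max = 5, dr = 0.25)
  edges <- seq(0, 5, by = 0.25)
  want <- brute_force_pair_counts(mb, hbmap:::select_sites(mb, "OW"),
                                  hbmap:::select_sites(mb, c("HW", "DW")),
                                  edges)
  expect_equal(r$counts, want)
})

test_that("rdf of an ideal gas is unity away from zero", {
  frames <- lapply(1:4, function(i) build_random_gas(2000, 25, seed = i))
  r <- rdf(frames, "X", "X", r_max = 10, dr = 0.5)
  use <- r$bin_center > 1
  # counting error: sd of g estimate per bin ~ g/sqrt(counts)
  sigma <- 1 / sqrt(pmax(r$counts[use], 1))
  expect_true(all(abs(r$g[use] - 1) < 3.5 * sigma + 0.02))
  # density sum rule: rho * integral g 4 pi r^2 dr ~ N - 1 over the range
  rho <- 2000 / 25^3
  integral <- sum(r$g * 4 * pi * r$bin_center^2 * 0.5)
  expect_equal(rho * integral, 4 / 3 * pi * 10^3 * rho, tolerance = 0.02)
})

test_that("a single fixed pair lands in its distance bin", {
  fr <- atomic_frame(rbind(c(5, 5, 5), c(8, 5, 5)), c(20, 20, 20),
                     c("A", "B"), 1:2, c("ION", "ION"), c(0, 0))
  r <- rdf(fr, "A", "B", r_max = 6, dr = 0.2)
  expect_equal(sum(r$counts), 1)
  expect_lt(abs(r$bin_center[which(r$counts == 1)] - 3.0), 0.11)
})

test_that("empty selections are rejected", {
  gas <- build_random_gas(10, 15)
  expect_error(rdf(gas, "QQ", "X"), "empty")
})

test_that("shell partition applies the 3.6 A cutoff to the S...D distance", {
  build_pair <- function(r_sd) {
    w <- hbmap:::water_template()
    dm <- hbmap:::dmso_template()
    # D on the x-axis facing the sulfur at distance r_sd
    wat <- w$coords %*% diag(3)
    wat <- sweep(wat, 2, c(10, 10, 10), "+")
    dmc <- sweep(dm$coords, 2, wat[2, ] + c(r_sd, 0, 0), "+")
    fr <- atomic_frame(rbind(wat, dmc), c(40, 40, 40),
                       c("OW", "DW", "HW2", dm$site),
                       c(1L, 1L, 1L, rep(2L, 4)),
                       c(rep("SOL", 3), rep("DMS", 4)))
    attach_charges(fr, default_topology())
  }
  expect_equal(shell_partition(build_pair(3.5))$shell, "first_shell")
  expect_equal(shell_partition(build_pair(3.7))$shell, "bulk")
  # threshold monotonicity: raising the cutoff never demotes a water
  fr <- build_pair(3.7)
  lab1 <- shell_partition(fr, 3.6)$shell
  lab2 <- shell_partition(fr, 4.5)$shell
  expect_false(any(lab1 == "first_shell" & lab2 == "bulk"))
  expect_equal(lab2, "first_shell")
  # no DMSO: labels n/a
  ice <- build_ice_lattice(lattice_spec(n_cells = c(2L, 2L, 2L)))
  expect_true(all(shell_partition(ice)$shell == "n/a"))
})

test_that("P(omega, r) implements the per-frame per-shell definition", {
  rec <- data.frame(frame = 1L, molecule = 1L, omega = 2500, r_s = 3.0,
                    shell = "first_shell")
  h <- omega_r_histogram(rec, omega_edges = seq(2400, 2600, 50),
                         r_edges = seq(0, 5, 0.2))
  expect_equal(sum(h$values > 0), 1L)
  expect_equal(max(h$values), 5.0) # 1 count / (1 frame x 0.2 A)
  expect_error(omega_r_histogram(rec[0, ], seq(2400, 2600, 50),
                                 seq(0, 5, 0.2)), "no records")
})

test_that("marginalizing P(omega, r) over r recovers the omega histogram", {
  map <- test_map()
  mb <- fixture_mixture()
  frames <- lapply(1:3, function(i) perturb_frame(mb, 0.04, seed = i))
  rec <- frequency_records(frames, map)
  omega_edges <- seq(floor(min(rec$omega) / 50) * 50,
                     ceiling(max(rec$omega) / 50) * 50, by = 10)
  r_edges <- seq(0, min(mb$box) / 2, by = 0.2)
  h2d <- omega_r_histogram(rec, omega_edges, r_edges)
  marg <- omega_marginal(h2d)
  in_range <- rec[!is.na(rec$r_s) & rec$r_s <= max(r_edges), ]
  want <- graphics::hist(in_range$omega, breaks = omega_edges,
                         plot = FALSE)$counts / h2d$n_frames
  expect_lt(max(abs(marg - want)), 1e-9)
})

test_that("shell-dependent broadening is visible in the 2D population", {
  # records built with known broadening below the 3.6 A shell boundary
  set.seed(8)
  n <- 4000
  r_s <- stats::runif(n, 2.5, 6.5)
  broad <- r_s < 3.6
  omega <- ifelse(broad, stats::rnorm(n, 2520, 80), stats::rnorm(n, 2500, 20))
  rec <- data.frame(frame = rep(1:10, length.out = n), molecule = 1:n,
                    omega = omega, r_s = r_s, shell = "")
  h <- omega_r_histogram(rec, seq(2200, 2800, 10), seq(2, 7, 0.5))
  r_centers <- seq(2.25, 6.75, 0.5)
  o_centers <- seq(2205, 2795, 10)
  spread_at <- function(j) {
    w <- h$values[, j]
    mu <- sum(o_centers * w) / sum(w)
    sqrt(sum(w * (o_centers - mu)^2) / sum(w))
  }
  occupied <- which(colSums(h$values) > 0)
  below <- intersect(which(r_centers < 3.4), occupied)
  above <- intersect(which(r_centers > 3.9), occupied)
  expect_gt(min(vapply(below, spread_at, numeric(1))),
            max(vapply(above, spread_at, numeric(1))))
})

test_that("orientational distribution separates ice from random packing", {
  ice <- build_ice_lattice(lattice_spec(n_cells = c(2L, 2L, 2L)))
  oi <- orientational_distribution(ice, oo_cutoff = 3.0)
  # in ideal ice 1/4 of O-H bonds point exactly along the O...O axis
  frac_axis <- mean(oi$cos_theta > 0.999)
  expect_equal(frac_axis, 0.25, tolerance = 1e-9)
  # randomly oriented waters: flat distribution
  liq <- fixture_liquid()
  ol <- orientational_distribution(liq, oo_cutoff = 3.6)
  expect_gt(length(ol$cos_theta), 200)
  expect_lt(abs(mean(ol$cos_theta)),
            3 * stats::sd(ol$cos_theta) / sqrt(length(ol$cos_theta)) + 0.05)
  # perturbed ice: broadened but still peaked near the axis
  pice <- perturb_frame(ice, 0.12, seed = 3)
  op <- orientational_distribution(pice, oo_cutoff = 3.0)
  expect_lt(mean(op$cos_theta > 0.999), 0.25)
  expect_gt(mean(op$cos_theta > 0.9), 0.20)
})

test_that("first-shell scrambling lowers the shell-resolved mean q", {
  fr <- fixture_dmso_in_ice(scramble_sigma = 0.5, shell_cutoff = 5)
  sq <- shell_resolved_q(fr, cutoff = 5)
  expect_gt(length(sq$q$first_shell), 3)
  expect_lt(sq$mean_q["first_shell"], sq$mean_q["bulk"])
  expect_gt(sq$mean_q["bulk"], 0.8) # bulk stays ice-like
})

test_that("shell-resolved q without DMSO reduces to a single bulk ensemble", {
  ice <- build_ice_lattice(lattice_spec(n_cells = c(2L, 2L, 2L)))
  sq <- shell_resolved_q(ice)
  expect_equal(sq$empty_shells, "first_shell")
  expect_length(sq$q$bulk, n_molecules(ice))
  expect_true(all(abs(sq$q$bulk - 1) < 1e-9))
  expect_equal(nrow(sq$histograms$first_shell), 0)
})
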