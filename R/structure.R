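# Structural statistics under periodic boundaries: radial distribution
# functions, the Errington-Debenedetti tetrahedral order parameter,
# solvation-shell partitioning around DMSO, orientational distributions of
# O-H bonds, and the joint frequency-distance population P(omega, r).

# Site selectors: a character vector of site-label prefixes, optionally
# constrained to a residue as "RES:site" (e.g. "DMS:S", "SOL:OW"). "HW"
# matches HW1/HW2; c("HW", "DW") selects all water hydrogens.
select_sites <- function(frame, sel) {
  hit <- rep(FALSE, n_atoms(frame))
  for (s in sel) {
    if (grepl(":", s, fixed = TRUE)) {
      part <- strsplit(s, ":", fixed = TRUE)[[1]]
      hit <- hit | (frame$residue == part[1] & startsWith(frame$site, part[2]))
    } else {
      hit <- hit | startsWith(frame$site, s)
    }
  }
  which(hit)
}

#' Radial distribution function
#'
#' Standard pair-correlation normalization under the minimum-image
#' convention: `g(r) = <n_pairs(r, r+dr)> / (rho_b 4 pi r^2 dr N_a)`,
#' averaged over frames, with `rho_b` the partner density. Intramolecular
#' pairs are excluded by default.
#'
#' @param frames list of [atomic_frame()] (or one frame).
#' @param sel_a,sel_b site selectors (see Details in [shell_partition()]);
#'   e.g. `sel_a = "DMS:S"`, `sel_b = c("HW", "DW")` for the sulfur-water
#'   hydrogen RDF.
#' @param r_max maximum distance, Angstrom; default half the smallest box
#'   edge. Must not exceed that bound.
#' @param dr bin width, Angstrom.
#' @param exclude_same_molecule drop intramolecular pairs (default `TRUE`).
#' @return an `rdf_result`: data frame `bin_center`, `g`, `counts`.
#' @export
rdf <- function(frames, sel_a, sel_b, r_max = NULL, dr = 0.1,
                exclude_same_molecule = TRUE) {
  if (inherits(frames, "atomic_frame")) frames <- list(frames)
  half_box <- min(vapply(frames, function(f) min(f$box), numeric(1))) / 2
  if (is.null(r_max)) r_max <- half_box
  if (r_max > half_box + 1e-9) {
    stop("r_max exceeds half the smallest box edge")
  }
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + dr)
  counts <- numeric(length(edges) - 1L)
  norm <- 0
  for (fr in frames) {
    ia <- select_sites(fr, sel_a)
    ib <- select_sites(fr, sel_b)
    if (length(ia) == 0L || length(ib) == 0L) stop("empty site selection")
    d <- pair_dist_matrix(fr$coords[ia, , drop = FALSE],
                          fr$coords[ib, , drop = FALSE], fr$box)
    same_atom <- outer(ia, ib, "==")
    drop <- same_atom
    if (exclude_same_molecule) {
      drop <- drop | outer(fr$molecule_id[ia], fr$molecule_id[ib], "==")
    }
    dv <- d[!drop]
    counts <- counts + graphics::hist(dv[dv < edges[length(edges)]],
                                      breaks = edges, plot = FALSE)$counts
    # expected ordered-pair density for an uncorrelated system
    n_pairs <- length(ia) * length(ib) - sum(drop)
    norm <- norm + n_pairs / prod(fr$box)
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  shell_vol <- 4 * pi * centers^2 * dr
  g <- counts / (norm * shell_vol)
  out <- data.frame(bin_center = centers, g = g, counts = counts)
  attr(out, "selections") <- list(a = sel_a, b = sel_b)
  attr(out, "dr") <- dr
  class(out) <- c("rdf_result", "data.frame")
  out
}

#' First-minimum shell cutoff from an RDF
#'
#' Locates the first local minimum of g(r) after its first maximum and
#' refines it by a quadratic fit through the three surrounding bins; used
#' to auto-set the solvation-shell cutoff from the S-H(water) RDF.
#'
#' @param rdf_result an [rdf()] result.
#' @param min_r ignore bins below this distance (excludes the excluded-volume
#'   region), Angstrom.
#' @return cutoff in Angstrom, or `NA` if no interior minimum exists.
#' @export
rdf_first_minimum <- function(rdf_result, min_r = 1.0) {
  r <- rdf_result$bin_center; g <- rdf_result$g
  use <- r >= min_r
  r <- r[use]; g <- g[use]
  ipk <- which(diff(sign(diff(g))) < 0) + 1L # local maxima
  if (length(ipk) == 0L) return(NA_real_)
  after <- seq(ipk[1] + 1L, length(g) - 1L)
  imin <- after[which(g[after] < g[after - 1L] & g[after] <= g[after + 1L])]
  if (length(imin) == 0L) return(NA_real_)
  i <- imin[1]
  # quadratic refinement through (i-1, i, i+1)
  y <- g[(i - 1L):(i + 1L)]
  denom <- y[1] - 2 * y[2] + y[3]
  offset <- if (abs(denom) < 1e-15) 0 else 0.5 * (y[1] - y[3]) / denom
  r[i] + offset * (r[2] - r[1])
}

# q-neighbour candidate atoms
q_candidates <- function(frame, neighbors) {
  has_water <- any(is_water_residue(frame$residue))
  if (!has_water) return(seq_len(n_atoms(frame))) # e.g. single-site gas
  idx <- which(is_water_oxygen(frame))
  if (neighbors == "heavy_atoms") {
    idx <- sort(c(idx, which(frame$residue == "DMS" &
                               frame$site %in% c("S", "O", "C1", "C2"))))
  }
  idx
}

#' Tetrahedral order parameter
#'
#' Errington-Debenedetti definition:
#' `q = 1 - (3/8) sum_(j<k) (cos psi_jk + 1/3)^2` over the four nearest
#' neighbour centres (minimum image), with `psi_jk` the angle they subtend
#' at the central molecule. q = 1 for a perfect tetrahedron, averages 0 for
#' a random gas, and has minimum -3 (all neighbours collinear).
#'
#' @param frame an [atomic_frame()].
#' @param molecule_ids molecules to evaluate; default all molecules owning
#'   a candidate centre (water oxygens, or every particle in an all-gas
#'   frame).
#' @param neighbors `"water_oxygens"` (default) or `"heavy_atoms"` (also
#'   admits DMSO S/O/C sites as neighbour candidates).
#' @return data frame `molecule`, `q`, `d1`..`d4` (neighbour distances, A).
#' @export
tetrahedral_q <- function(frame, molecule_ids = NULL,
                          neighbors = c("water_oxygens", "heavy_atoms")) {
  neighbors <- match.arg(neighbors)
  cand <- q_candidates(frame, neighbors)
  has_water <- any(is_water_residue(frame$residue))
  centers <- if (has_water) cand[is_water_oxygen(frame)[cand]] else cand
  if (!is.null(molecule_ids)) {
    centers <- centers[frame$molecule_id[centers] %in% molecule_ids]
  }
  if (length(cand) < 5L) stop("need at least 4 neighbour candidates")
  d <- pair_dist_matrix(frame$coords[centers, , drop = FALSE],
                        frame$coords[cand, , drop = FALSE], frame$box)
  # own molecule cannot be its own neighbour
  d[outer(frame$molecule_id[centers], frame$molecule_id[cand], "==")] <- Inf
  q <- numeric(length(centers)); nd <- matrix(0, length(centers), 4)
  for (i in seq_along(centers)) {
    ord <- order(d[i, ])[1:4]
    if (!all(is.finite(d[i, ord]))) stop("fewer than 4 neighbours available")
    v <- min_image(sweep(frame$coords[cand[ord], , drop = FALSE], 2,
                         frame$coords[centers[i], ]), frame$box)
    v <- v / sqrt(rowSums(v * v))
    s <- 0
    for (j in 1:3) for (k in (j + 1):4) {
      s <- s + (sum(v[j, ] * v[k, ]) + 1 / 3)^2
    }
    q[i] <- 1 - 3 / 8 * s
    nd[i, ] <- sort(d[i, ord])
  }
  out <- data.frame(molecule = frame$molecule_id[centers], q = q)
  out[c("d1", "d2", "d3", "d4")] <- nd
  out
}

#' Partition waters into DMSO solvation shells
#'
#' A water is `first_shell` iff the minimum-image distance from its D atom
#' (or, for undeuterated waters, its first hydrogen) to any DMSO sulfur is
#' within the cutoff; otherwise `bulk`. Without DMSO all labels are `"n/a"`.
#'
#' @param frame an [atomic_frame()].
#' @param cutoff shell cutoff in Angstrom; the default 3.6 A is the first
#'   minimum of the S-H(water) RDF.
#' @return data frame `molecule`, `r_s`, `shell`.
#' @export
shell_partition <- function(frame, cutoff = 3.6) {
  water_ids <- unique(frame$molecule_id[is_water_residue(frame$residue)])
  has_s <- any(frame$site == "S" & frame$residue == "DMS")
  out <- data.frame(molecule = water_ids, r_s = NA_real_, shell = "n/a",
                    stringsAsFactors = FALSE)
  for (i in seq_along(water_ids)) {
    idx <- molecule_atoms(frame, water_ids[i])
    d_at <- idx[is_d_site(frame$site[idx])]
    probe <- if (length(d_at)) d_at[1] else
      idx[startsWith(frame$site[idx], "HW")][1]
    if (!has_s) next
    r_s <- nearest_s_distance(frame, frame$coords[probe, ])
    out$r_s[i] <- r_s
    out$shell[i] <- if (r_s <= cutoff) "first_shell" else "bulk"
  }
  out
}

#' Joint frequency-distance population P(omega, r)
#'
#' The average number of probe molecules per frame with frequency in a
#' given omega bin located at distance r from the nearest DMSO sulfur, per
#' shell of thickness dr: `values[i, j] = count(i, j) / (n_frames * dr)`.
#' Summing `values * dr` over r therefore recovers the per-frame frequency
#' histogram exactly.
#'
#' @param records data frame from [frequency_records()] with defined `r_s`.
#' @param omega_edges ascending bin edges, cm^-1.
#' @param r_edges ascending uniform bin edges, Angstrom.
#' @return a `histogram2d`: list with `omega_edges`, `r_edges`, `values`
#'   (omega bins x r bins), `n_frames`, `dr`.
#' @export
omega_r_histogram <- function(records, omega_edges, r_edges) {
  rec <- records[!is.na(records$r_s), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records with a defined S...D distance")
  dr <- diff(r_edges)
  if (any(abs(dr - dr[1]) > 1e-9)) stop("r bins must be uniform")
  dr <- dr[1]
  oi <- findInterval(rec$omega, omega_edges, rightmost.closed = TRUE)
  ri <- findInterval(rec$r_s, r_edges, rightmost.closed = TRUE)
  keep <- oi >= 1 & oi <= length(omega_edges) - 1L &
    ri >= 1 & ri <= length(r_edges) - 1L
  n_frames <- length(unique(records$frame))
  values <- matrix(0, length(omega_edges) - 1L, length(r_edges) - 1L)
  for (k in which(keep)) {
    values[oi[k], ri[k]] <- values[oi[k], ri[k]] + 1
  }
  values <- values / (n_frames * dr)
  structure(list(omega_edges = omega_edges, r_edges = r_edges,
                 values = values, n_frames = n_frames, dr = dr),
            class = "histogram2d")
}

#' Marginalize P(omega, r) over distance
#' @param h2d a `histogram2d` from [omega_r_histogram()].
#' @return numeric per-frame counts per omega bin (`sum_r values * dr`).
#' @export
omega_marginal <- function(h2d) {
  rowSums(h2d$values) * h2d$dr
}

#' Orientational distribution of O-H bonds along O...O axes
#'
#' For every pair of water oxygens within `oo_cutoff` and every covalent
#' O-H (or O-D) bond of each partner, the cosine of the angle between the
#' bond vector and the O...O axis (pointing at the other oxygen). In ideal
#' ice the bonding hydrogens lie exactly on the axis (delta at cos = 1,
#' with the remaining bonds near the tetrahedral -1/3); randomly oriented
#' waters give a flat distribution.
#'
#' @param frames list of [atomic_frame()].
#' @param oo_cutoff O...O neighbour cutoff, Angstrom.
#' @param shell_filter optional `"first_shell"` or `"bulk"`: restrict donor
#'   waters by [shell_partition()] at 3.6 A.
#' @param breaks histogram breaks on `[-1, 1]`.
#' @return list with `cos_theta` (raw values) and `histogram`
#'   (data frame `bin_center`, `density`).
#' @export
orientational_distribution <- function(frames, oo_cutoff = 3.5,
                                       shell_filter = NULL,
                                       breaks = seq(-1, 1, by = 0.05)) {
  if (inherits(frames, "atomic_frame")) frames <- list(frames)
  vals <- numeric(0)
  for (fr in frames) {
    o_idx <- which(is_water_oxygen(fr))
    if (length(o_idx) < 2L) next
    keep_mol <- unique(fr$molecule_id[o_idx])
    if (!is.null(shell_filter)) {
      sp <- shell_partition(fr)
      keep_mol <- sp$molecule[sp$shell == shell_filter]
    }
    d <- pair_dist_matrix(fr$coords[o_idx, , drop = FALSE],
                          fr$coords[o_idx, , drop = FALSE], fr$box)
    for (i in seq_along(o_idx)) {
      if (!fr$molecule_id[o_idx[i]] %in% keep_mol) next
      nb <- which(d[i, ] > 1e-9 & d[i, ] <= oo_cutoff)
      if (length(nb) == 0L) next
      midx <- molecule_atoms(fr, fr$molecule_id[o_idx[i]])
      h_at <- midx[startsWith(fr$site[midx], "HW") |
                     is_d_site(fr$site[midx])]
      o <- fr$coords[o_idx[i], ]
      hv <- min_image(sweep(fr$coords[h_at, , drop = FALSE], 2, o), fr$box)
      hv <- hv / sqrt(rowSums(hv * hv))
      for (j in nb) {
        axis <- min_image(matrix(fr$coords[o_idx[j], ] - o, 1), fr$box)[1, ]
        axis <- axis / sqrt(sum(axis^2))
        vals <- c(vals, as.numeric(hv %*% axis))
      }
    }
  }
  if (length(vals) == 0L) {
    return(list(cos_theta = numeric(0),
                histogram = data.frame(bin_center = numeric(0),
                                       density = numeric(0))))
  }
  h <- graphics::hist(pmin(pmax(vals, -1), 1), breaks = breaks, plot = FALSE)
  list(cos_theta = vals,
       histogram = data.frame(bin_center = h$mids, density = h$density))
}

#' Shell-resolved tetrahedral order parameter
#'
#' Computes per-water q values and partitions them into the DMSO first
#' solvation shell and the bulk. A shell with no members yields an empty
#' histogram (flagged), not an error; without DMSO everything is bulk.
#'
#' @param frames list of [atomic_frame()].
#' @param cutoff shell cutoff, Angstrom.
#' @param neighbors passed to [tetrahedral_q()].
#' @param breaks histogram breaks for q.
#' @return list with per-shell `q` values, `mean_q`, histograms, and an
#'   `empty_shells` character vector.
#' @export
shell_resolved_q <- function(frames, cutoff = 3.6,
                             neighbors = c("water_oxygens", "heavy_atoms"),
                             breaks = seq(-3, 1, by = 0.05)) {
  neighbors <- match.arg(neighbors)
  if (inherits(frames, "atomic_frame")) frames <- list(frames)
  qs <- list(first_shell = numeric(0), bulk = numeric(0))
  for (fr in frames) {
    qt <- tetrahedral_q(fr, neighbors = neighbors)
    sp <- shell_partition(fr, cutoff)
    lab <- sp$shell[match(qt$molecule, sp$molecule)]
    lab[lab == "n/a"] <- "bulk" # no DMSO: everything is bulk
    qs$first_shell <- c(qs$first_shell, qt$q[lab == "first_shell"])
    qs$bulk <- c(qs$bulk, qt$q[lab == "bulk"])
  }
  hist_of <- function(v) {
    if (length(v) == 0L) {
      return(data.frame(bin_center = numeric(0), density = numeric(0)))
    }
    h <- graphics::hist(pmin(pmax(v, -3), 1), breaks = breaks, plot = FALSE)
    data.frame(bin_center = h$mids, density = h$density)
  }
  list(q = qs,
       mean_q = vapply(qs, function(v) if (length(v)) mean(v) else NA_real_,
                       numeric(1)),
       histograms = lapply(qs, hist_of),
       empty_shells = names(qs)[vapply(qs, length, integer(1)) == 0L])
}
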