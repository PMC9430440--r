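# Independent oracles, written as plain loops so they share no code with
# the implementation paths they check.

# Brute-force electrostatic potential: explicit enumeration of the 27
# periodic images; the minimum over images is the minimum-image distance
# for any cutoff below half the box edge.
brute_force_potential <- function(frame, point, excluded_molecule, cutoff,
                                  truncation = "molecule") {
  bohr <- 0.529177
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  img_dist <- function(p) {
    best <- Inf
    for (s in seq_len(nrow(shifts))) {
      d <- p + shifts[s, ] * frame$box - point
      best <- min(best, sqrt(sum(d^2)))
    }
    best
  }
  phi <- 0
  for (mid in unique(frame$molecule_id)) {
    if (!is.null(excluded_molecule) && mid %in% excluded_molecule) next
    idx <- which(frame$molecule_id == mid)
    if (truncation == "molecule") {
      if (img_dist(frame$coords[idx[1], ]) > cutoff) next
      for (i in idx) {
        phi <- phi + frame$charge[i] / (img_dist(frame$coords[i, ]) / bohr)
      }
    } else {
      for (i in idx) {
        r <- img_dist(frame$coords[i, ])
        if (r <= cutoff) phi <- phi + frame$charge[i] / (r / bohr)
      }
    }
  }
  phi
}

# Brute-force RDF pair counts: plain double loop over selected atoms with
# component-wise minimum-image wrapping.
brute_force_pair_counts <- function(frame, ia, ib, edges,
                                    exclude_same_molecule = TRUE) {
  counts <- numeric(length(edges) - 1L)
  for (i in ia) {
    for (j in ib) {
      if (i == j) next
      if (exclude_same_molecule &&
          frame$molecule_id[i] == frame$molecule_id[j]) next
      d <- frame$coords[i, ] - frame$coords[j, ]
      for (k in 1:3) {
        d[k] <- d[k] - frame$box[k] * round(d[k] / frame$box[k])
      }
      r <- sqrt(sum(d^2))
      if (r < edges[length(edges)]) {
        bin <- findInterval(r, edges, rightmost.closed = TRUE)
        if (bin >= 1 && bin <= length(counts)) counts[bin] <- counts[bin] + 1
      }
    }
  }
  counts
}

# Molecular dipole from charges and positions (no minimum imaging: intended
# for whole molecules far from the box edge).
molecular_dipole <- function(frame, molecule_id) {
  idx <- which(frame$molecule_id == molecule_id)
  colSums(frame$coords[idx, , drop = FALSE] * frame$charge[idx])
}

# Random frame of single-atom "molecules" with random charges, for the
# potential oracle tests.
random_charge_frame <- function(n, box, seed) {
  set.seed(seed)
  atomic_frame(
    coords = cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                   stats::runif(n, 0, box[3])),
    box = box,
    site = rep("X", n),
    molecule_id = seq_len(n),
    residue = rep("ION", n),
    charge = stats::runif(n, -1, 1))
}
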