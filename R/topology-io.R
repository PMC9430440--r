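# Readers and writers for GRO / PDB / XYZ coordinate files and for the
# partial-charge topology table. GRO files store nm; everything is converted
# to Angstrom on read and back on write. Only orthorhombic boxes are
# supported: the systems treated here are cubic or orthorhombic, and a
# triclinic box line is rejected rather than silently mangled.

#' Read a partial-charge topology table
#'
#' The topology is a CSV with columns `residue`, `site`, `charge` and an
#' optional `vsite_dist` column giving, for virtual (M) sites, the distance
#' in Angstrom from the oxygen along the H-O-H bisector. Charges within each
#' residue must sum to zero.
#'
#' @param path CSV file path.
#' @return a `topology_table` (data frame).
#' @seealso [default_topology()]
#' @export
read_topology <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(residue = "character",
                                        site = "character"))
  need <- c("residue", "site", "charge")
  if (!all(need %in% names(tab))) {
    stop("topology must have columns residue, site, charge")
  }
  if (!"vsite_dist" %in% names(tab)) tab$vsite_dist <- NA_real_
  # D rows are isotopic alternates of H rows, not extra sites: skip them in
  # the neutrality check
  real <- !is_d_site(tab$site)
  qs <- tapply(tab$charge[real], tab$residue[real], sum)
  bad <- which(abs(qs) > 1e-10)
  if (length(bad)) {
    stop(sprintf("residue %s charges sum to %.3e e (must be neutral)",
                 names(qs)[bad[1]], qs[bad[1]]))
  }
  class(tab) <- c("topology_table", "data.frame")
  tab
}

#' Bundled default topology
#'
#' Charges for 3-site water (`SOL`, SPC/E values), 4-site water with an
#' off-oxygen M virtual site (`SOL4`, TIP4P-like values), and a 4-site
#' united-atom DMSO (`DMS`: S, O, two CH3 sites). D-labelled water hydrogens
#' (`DW`) carry the same charge as H: deuteration is an isotopic label and
#' leaves the electrostatics unchanged.
#'
#' @return a `topology_table`.
#' @export
default_topology <- function() {
  read_topology(system.file("extdata", "charges.csv", package = "hbmap",
                            mustWork = TRUE))
}

topology_lookup <- function(topology, residue, site) {
  i <- which(topology$residue == residue & topology$site == site)
  if (length(i) == 0L) return(NA_real_)
  topology$charge[i[1]]
}

#' Attach per-atom charges from a topology
#'
#' @param frame an [atomic_frame()].
#' @param topology a `topology_table`.
#' @return the frame with its `charge` vector filled by residue+site lookup.
#' @export
attach_charges <- function(frame, topology) {
  key <- paste(frame$residue, frame$site, sep = "\r")
  tkey <- paste(topology$residue, topology$site, sep = "\r")
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    if (!frame$residue[miss] %in% topology$residue) {
      stop(sprintf("residue '%s' not present in topology", frame$residue[miss]))
    }
    stop(sprintf("site '%s' of residue '%s' not present in topology",
                 frame$site[miss], frame$residue[miss]))
  }
  frame$charge <- topology$charge[idx]
  frame
}

# ---- GRO --------------------------------------------------------------------

parse_gro_block <- function(lines, first) {
  natoms <- suppressWarnings(as.integer(trimws(lines[first + 1L])))
  if (is.na(natoms)) {
    stop(sprintf("malformed GRO atom count at line %d", first + 1L))
  }
  atom_lines <- lines[(first + 2L):(first + 1L + natoms)]
  resnum <- integer(natoms); resname <- character(natoms)
  site <- character(natoms); xyz <- matrix(0, natoms, 3)
  for (i in seq_len(natoms)) {
    ln <- atom_lines[i]
    if (nchar(ln) < 44) {
      stop(sprintf("malformed GRO fixed-width line %d", first + 1L + i))
    }
    resnum[i]  <- as.integer(substr(ln, 1, 5))
    resname[i] <- trimws(substr(ln, 6, 10))
    site[i]    <- trimws(substr(ln, 11, 15))
    xyz[i, ]   <- as.numeric(c(substr(ln, 21, 28), substr(ln, 29, 36),
                               substr(ln, 37, 44)))
    if (anyNA(xyz[i, ]) || is.na(resnum[i])) {
      stop(sprintf("malformed GRO fixed-width line %d", first + 1L + i))
    }
  }
  boxline <- as.numeric(strsplit(trimws(lines[first + 2L + natoms]),
                                 "\\s+")[[1]])
  if (length(boxline) > 3 && any(abs(boxline[4:length(boxline)]) > 0)) {
    stop("triclinic GRO box not supported (orthorhombic only)")
  }
  box <- boxline[1:3] * 10 # nm -> Angstrom
  # residue numbers in GRO wrap at 100000; renumber contiguously
  mol <- cumsum(c(1L, diff(resnum) != 0L))
  fr <- atomic_frame(xyz * 10, box, site, mol, resname)
  list(frame = fr, next_line = first + 3L + natoms)
}

read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); pos <- 1L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    blk <- parse_gro_block(lines, pos)
    frames[[length(frames) + 1L]] <- blk$frame
    pos <- blk$next_line
  }
  frames
}

write_gro <- function(frames, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    writeLines("generated by hbmap", con)
    writeLines(sprintf("%5d", n_atoms(fr)), con)
    nm <- fr$coords / 10
    mol_serial <- match(fr$molecule_id, unique(fr$molecule_id))
    for (i in seq_len(n_atoms(fr))) {
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         mol_serial[i] %% 100000L, fr$residue[i], fr$site[i],
                         i %% 100000L, nm[i, 1], nm[i, 2], nm[i, 3]), con)
    }
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1] / 10, fr$box[2] / 10,
                       fr$box[3] / 10), con)
  }
}

# ---- PDB --------------------------------------------------------------------

read_pdb <- function(path) {
  lines <- readLines(path)
  frames <- list()
  box <- NULL
  cur <- NULL # accumulator: list of parsed atom rows
  flush_model <- function() {
    if (is.null(cur) || length(cur$site) == 0L) return(invisible())
    if (is.null(box)) stop("PDB file lacks a CRYST1 record (box required)")
    mol <- cumsum(c(1L, diff(cur$resseq) != 0L))
    frames[[length(frames) + 1L]] <<- atomic_frame(
      cur$xyz, box, cur$site, mol, cur$resname)
    cur <<- NULL
  }
  for (k in seq_along(lines)) {
    ln <- lines[k]
    rec <- substr(ln, 1, 6)
    if (startsWith(rec, "CRYST1")) {
      vals <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                           substr(ln, 25, 33), substr(ln, 34, 40),
                           substr(ln, 41, 47), substr(ln, 48, 54)))
      if (any(abs(vals[4:6] - 90) > 1e-6)) {
        stop("non-orthorhombic CRYST1 angles not supported")
      }
      box <- vals[1:3]
    } else if (rec == "ATOM  " || rec == "HETATM") {
      if (is.null(cur)) cur <- list(site = character(), resname = character(),
                                    resseq = integer(),
                                    xyz = matrix(0, 0, 3))
      xyz <- as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                          substr(ln, 47, 54)))
      if (anyNA(xyz)) stop(sprintf("malformed ATOM record at line %d", k))
      cur$site <- c(cur$site, trimws(substr(ln, 13, 16)))
      cur$resname <- c(cur$resname, trimws(substr(ln, 18, 20)))
      cur$resseq <- c(cur$resseq, as.integer(substr(ln, 23, 26)))
      cur$xyz <- rbind(cur$xyz, xyz)
    } else if (startsWith(rec, "ENDMDL") || startsWith(rec, "END")) {
      flush_model()
    }
  }
  flush_model()
  frames
}

write_pdb <- function(frames, path) {
  con <- file(path, "w"); on.exit(close(con))
  multi <- length(frames) > 1L
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     frames[[1]]$box[1], frames[[1]]$box[2],
                     frames[[1]]$box[3], 90, 90, 90), con)
  for (m in seq_along(frames)) {
    fr <- frames[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    mol_serial <- match(fr$molecule_id, unique(fr$molecule_id))
    for (i in seq_len(n_atoms(fr))) {
      writeLines(sprintf("ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00",
                         i %% 100000L, fr$site[i], fr$residue[i],
                         mol_serial[i] %% 10000L, fr$coords[i, 1],
                         fr$coords[i, 2], fr$coords[i, 3]), con)
    }
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
}

# ---- XYZ --------------------------------------------------------------------

# Extended XYZ dialect: the comment line carries the box, atom lines carry
# two extra columns (residue name, molecule id) so labels survive a
# round-trip. Plain 4-column XYZ is accepted on read.

read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); pos <- 1L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    natoms <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(natoms)) stop(sprintf("malformed XYZ atom count at line %d", pos))
    comment <- lines[pos + 1L]
    bm <- regmatches(comment,
                     regexec("box\\s*=\\s*\"?([0-9.eE+ -]+)\"?", comment))[[1]]
    if (length(bm) < 2) stop("XYZ comment line must carry box=\"bx by bz\"")
    box <- as.numeric(strsplit(trimws(bm[2]), "\\s+")[[1]])[1:3]
    site <- character(natoms); resname <- character(natoms)
    mol <- integer(natoms); xyz <- matrix(0, natoms, 3)
    for (i in seq_len(natoms)) {
      tok <- strsplit(trimws(lines[pos + 1L + i]), "\\s+")[[1]]
      if (length(tok) < 4) {
        stop(sprintf("malformed XYZ line %d", pos + 1L + i))
      }
      site[i] <- tok[1]
      xyz[i, ] <- as.numeric(tok[2:4])
      resname[i] <- if (length(tok) >= 6) tok[5] else "UNK"
      mol[i] <- if (length(tok) >= 6) as.integer(tok[6]) else i
    }
    frames[[length(frames) + 1L]] <- atomic_frame(xyz, box, site, mol, resname)
    pos <- pos + 2L + natoms
  }
  frames
}

write_xyz <- function(frames, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    writeLines(sprintf("%d", n_atoms(fr)), con)
    writeLines(sprintf("box=\"%.6f %.6f %.6f\"", fr$box[1], fr$box[2],
                       fr$box[3]), con)
    for (i in seq_len(n_atoms(fr))) {
      writeLines(sprintf("%-5s %14.6f %14.6f %14.6f %s %d", fr$site[i],
                         fr$coords[i, 1], fr$coords[i, 2], fr$coords[i, 3],
                         fr$residue[i], fr$molecule_id[i]), con)
    }
  }
}

# ---- public interface -------------------------------------------------------

#' Read atomic configurations
#'
#' Reads one or more frames from a coordinate file. Multi-frame files
#' (concatenated GRO blocks, PDB MODEL records, stacked XYZ blocks) return
#' one frame per block. GRO coordinates are converted from nm to Angstrom.
#' If a topology is supplied, per-atom partial charges are attached by
#' residue + site lookup; a residue missing from the topology is an error.
#'
#' @param path file path.
#' @param format one of `"gro"`, `"pdb"`, `"xyz"`; default inferred from the
#'   file extension.
#' @param topology optional `topology_table` (see [read_topology()]).
#' @return list of [atomic_frame()] objects.
#' @export
read_frames <- function(path, format = c("auto", "gro", "pdb", "xyz"),
                        topology = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("gro", "pdb", "xyz")) {
      stop("cannot infer format from extension; pass format=")
    }
  }
  frames <- switch(format,
                   gro = read_gro(path),
                   pdb = read_pdb(path),
                   xyz = read_xyz(path))
  if (!is.null(topology)) {
    frames <- lapply(frames, attach_charges, topology = topology)
    lapply(frames, validate_frame)
  }
  frames
}

#' Write atomic configurations
#'
#' Inverse of [read_frames()]. GRO is written in nm with fixed columns and
#' no velocities; XYZ uses an extended comment line carrying the box and two
#' extra columns (residue, molecule id) so labels round-trip.
#'
#' @param frames a single [atomic_frame()] or a list of them.
#' @param path output file path.
#' @param format one of `"gro"`, `"pdb"`, `"xyz"`; default from extension.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, format = c("auto", "gro", "pdb", "xyz")) {
  if (inherits(frames, "atomic_frame")) frames <- list(frames)
  if (length(frames) == 0L) stop("no frames to write")
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("gro", "pdb", "xyz")) {
      stop("cannot infer format from extension; pass format=")
    }
  }
  switch(format,
         gro = write_gro(frames, path),
         pdb = write_pdb(frames, path),
         xyz = write_xyz(frames, path))
  invisible(path)
}

#' Recompute virtual (M) site positions
#'
#' For 4-site water models the negative charge sits on a massless M site on
#' the H-O-H bisector rather than on the oxygen. This recomputes every M
#' site's coordinates from the current O and H positions (distance taken
#' from the topology's `vsite_dist`) and re-attaches charges, which places
#' the charge on M and leaves O neutral per the topology.
#'
#' @param frame an [atomic_frame()] containing waters with `MW` sites.
#' @param topology a `topology_table` defining `vsite_dist` for the M site.
#' @return the frame with M positions and charges refreshed.
#' @export
resolve_virtual_sites <- function(frame, topology) {
  for (mid in unique(frame$molecule_id)) {
    idx <- molecule_atoms(frame, mid)
    if (!is_water_residue(frame$residue[idx[1]])) next
    m_at <- idx[frame$site[idx] == "MW"]
    if (length(m_at) == 0L) next
    rule <- topology$vsite_dist[topology$residue == frame$residue[idx[1]] &
                                  topology$site == "MW"]
    if (length(rule) == 0L || is.na(rule[1])) {
      stop("topology defines no vsite_dist for the MW site")
    }
    o_at <- idx[frame$site[idx] %in% c("OW", "O")]
    h_at <- idx[startsWith(frame$site[idx], "HW") |
                  is_d_site(frame$site[idx])]
    if (length(h_at) != 2L || length(o_at) != 1L) {
      stop(sprintf("molecule %d is not a 2-hydrogen water", mid))
    }
    o <- frame$coords[o_at, ]
    # bisector from minimum-image O->H vectors so split molecules work
    v1 <- min_image(matrix(frame$coords[h_at[1], ] - o, 1), frame$box)[1, ]
    v2 <- min_image(matrix(frame$coords[h_at[2], ] - o, 1), frame$box)[1, ]
    bis <- v1 / sqrt(sum(v1^2)) + v2 / sqrt(sum(v2^2))
    nb <- sqrt(sum(bis^2))
    if (nb < 1e-12) stop(sprintf("degenerate H-O-H geometry in molecule %d", mid))
    frame$coords[m_at, ] <- o + rule[1] * bis / nb
  }
  attach_charges(frame, topology)
}
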