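# Seed-deterministic generators for idealized capture complexes and decoys.
#
# Strands are built at ideal extended dihedrals (phi = -139, psi = +135,
# omega = 180) with standard bond lengths/angles, which makes Kabsch-Sander
# hydrogen bonds form between properly registered neighbouring strands
# without any optimization. The substrate strand is sandwiched between two
# receptor anchor strands (author-numbered to the Catch-domain anchor
# ranges) at a configurable inter-strand spacing; strand registry against
# each anchor is fixed by a deterministic grid search maximizing the number
# of Kabsch-Sander bonds the package's own energy function declares.

.BOND_N_CA <- 1.458
.BOND_CA_C <- 1.525
.BOND_C_N <- 1.329
.BOND_C_O <- 1.231
.BOND_CA_CB <- 1.521
.ANGLE_N_CA_C <- 111.0
.ANGLE_CA_C_N <- 116.2
.ANGLE_C_N_CA <- 121.7
.ANGLE_CA_C_O <- 120.8
.ANGLE_N_CA_CB <- 110.5
.DIHEDRAL_CB <- -122.6  # improper C-N-CA-CB

.PHI_STRAND <- -139; .PSI_STRAND <- 135
.PHI_HELIX <- -57; .PSI_HELIX <- -47
.PHI_PPII <- -75; .PSI_PPII <- 145  # flank state: extended-ish, never "E"

#' Build an idealized backbone from per-residue dihedrals
#'
#' @param sequence one-letter sequence.
#' @param phi,psi dihedrals in degrees, recycled to the sequence length.
#' @param omega peptide-bond dihedral (default 180, trans).
#' @return list of n x 3 matrices \code{N, CA, C, O, CB} (CB \code{NA} for
#'   glycine).
#' @export
build_backbone <- function(sequence, phi = .PHI_STRAND, psi = .PSI_STRAND,
                           omega = 180) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  stopifnot(n >= 1)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  xyz <- lapply(c(N = 1, CA = 2, C = 3, O = 4, CB = 5),
                function(k) matrix(NA_real_, n, 3))
  xyz$N[1, ] <- c(0, 0, 0)
  xyz$CA[1, ] <- c(.BOND_N_CA, 0, 0)
  ang <- (180 - .ANGLE_N_CA_C) * pi / 180
  xyz$C[1, ] <- xyz$CA[1, ] + .BOND_CA_C * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    xyz$N[i + 1, ] <- place_atom(xyz$N[i, ], xyz$CA[i, ], xyz$C[i, ],
                                 .BOND_C_N, .ANGLE_CA_C_N, psi[i])
    xyz$CA[i + 1, ] <- place_atom(xyz$CA[i, ], xyz$C[i, ], xyz$N[i + 1, ],
                                  .BOND_N_CA, .ANGLE_C_N_CA, omega)
    xyz$C[i + 1, ] <- place_atom(xyz$C[i, ], xyz$N[i + 1, ], xyz$CA[i + 1, ],
                                 .BOND_CA_C, .ANGLE_N_CA_C, phi[i + 1])
    xyz$O[i, ] <- place_atom(xyz$N[i + 1, ], xyz$CA[i, ], xyz$C[i, ],
                             .BOND_C_O, .ANGLE_CA_C_O, 180)
  }
  xyz$O[n, ] <- place_atom(xyz$N[n, ], xyz$CA[n, ], xyz$C[n, ],
                           .BOND_C_O, .ANGLE_CA_C_O, psi[n] + 180)
  for (i in seq_len(n)) {
    if (aa[i] == "G") next
    xyz$CB[i, ] <- place_atom(xyz$C[i, ], xyz$N[i, ], xyz$CA[i, ],
                              .BOND_CA_CB, .ANGLE_N_CA_CB, .DIHEDRAL_CB)
  }
  xyz
}

# Rigidly move a backbone into a canonical frame: the CA axis of residues
# `idx` along +x, the mid carbonyl in the xy-plane, centered at the axis
# midpoint. Returns the transformed backbone.
.orient_backbone <- function(xyz, idx = seq_len(nrow(xyz$CA))) {
  ca <- xyz$CA
  e1 <- .vunit(ca[idx[length(idx)], ] - ca[idx[1], ])
  mid <- idx[ceiling(length(idx) / 2)]
  u <- xyz$O[mid, ] - xyz$C[mid, ]
  e2 <- .vunit(u - sum(u * e1) * e1)
  e3 <- .vcross(e1, e2)
  M <- rbind(e1, e2, e3)
  center <- (ca[idx[1], ] + ca[idx[length(idx)], ]) / 2
  lapply(xyz, function(m) {
    out <- m
    ok <- stats::complete.cases(m)
    if (any(ok)) out[ok, ] <- sweep(m[ok, , drop = FALSE], 2, center) %*% t(M)
    out
  })
}

.transform_backbone <- function(xyz, R = diag(3), shift = c(0, 0, 0)) {
  lapply(xyz, function(m) {
    out <- m
    ok <- stats::complete.cases(m)
    if (any(ok))
      out[ok, ] <- sweep(m[ok, , drop = FALSE] %*% t(R), 2, shift, "+")
    out
  })
}

.backbone_chain <- function(xyz, chain_id, resno, aa, plddt = 90) {
  chain_model(chain_id, resno, aa, xyz, rep_len(plddt, length(resno)))
}

# Count Kabsch-Sander bonds between two chains (either donor direction).
.inter_bond_count <- function(chain_a, chain_b) {
  tab <- .residue_table(list(chain_a, chain_b))
  hb <- .hbond_matrix(tab)
  sum(hb & outer(tab$chain, tab$chain, "!="))
}

# Deterministic registry search: orientation in {Ry(180), Rz(180)} (both
# reverse the strand for antiparallel pairing; identity / Rx(180) for
# parallel), x-offset on a 0.1 A grid and a small z-offset grid to match
# the pleat phase. Primary score: number of Kabsch-Sander bonds to the
# substrate strand; tie-break: the smallest worst-case Calpha rung
# distance (max over substrate strand residues of the min Calpha distance
# to the anchor), which keeps every rung inside a beta-sheet-like spacing.
# Remaining ties resolve to the smaller |offset| and earlier orientation.
.place_anchor <- function(anchor_xyz, anchor_aa, substrate_chain, y_offset,
                          parallel = FALSE) {
  orients <- if (parallel) list(diag(3), .rot_x(180))
             else list(.rot_y(180), .rot_z(180))
  offsets <- seq(-4, 4, by = 0.1)
  offsets <- offsets[order(abs(offsets), offsets)]
  z_offsets <- seq(-1, 1, by = 0.5)
  z_offsets <- z_offsets[order(abs(z_offsets), z_offsets)]
  sub_ca <- substrate_chain$xyz$CA
  best <- NULL; best_bonds <- -1L; best_rung <- Inf
  for (oi in seq_along(orients)) {
    for (dx in offsets) {
      for (dz in z_offsets) {
        cand <- .transform_backbone(anchor_xyz, orients[[oi]],
                                    c(dx, y_offset, dz))
        ch <- .backbone_chain(cand, "X", seq_along(anchor_aa), anchor_aa)
        bonds <- .inter_bond_count(ch, substrate_chain)
        if (bonds < best_bonds) next
        rung <- max(apply(.pairwise_dist(sub_ca, cand$CA), 1, min))
        if (bonds > best_bonds || rung < best_rung - 1e-9) {
          best <- cand; best_bonds <- bonds; best_rung <- rung
        }
      }
    }
  }
  list(xyz = best, n_bonds = best_bonds, max_rung = best_rung)
}

.sample_seq <- function(n, pool) paste(sample(pool, n, replace = TRUE),
                                       collapse = "")

.STRAND_POOL <- c("V", "I", "T", "F", "L", "Y", "E", "K")
.FLANK_POOL <- c("S", "N", "Q", "A", "D", "K", "G", "T")

#' Build an idealized capture-complex fixture
#'
#' Three-strand antiparallel beta sheet: receptor anchor strand A (author
#' numbers 148..157), the substrate strand sandwiched between the anchors
#' at the stated spacing, and receptor anchor strand B (279..286), plus an
#' isolated receptor reference residue I309 placed on the Catch-core side
#' of the sheet so that inward-facing side chains are geometrically true.
#' Helical flanking residues on the substrate carry the strand into a
#' larger chain. Output is seed-deterministic (identical bytes for
#' identical spec and seed when written).
#'
#' @param strand_length planted substrate strand length (residues).
#' @param spacing inter-strand spacing in Angstroms, in (4.0, 5.5);
#'   default 4.8 (beta sheets typically run under 5 A).
#' @param substrate_sequence optional full substrate sequence (length
#'   >= strand_length); by default one is sampled.
#' @param flank helical flank length on each side of the planted strand
#'   (ignored when \code{substrate_sequence} is given).
#' @param parallel build the substrate parallel instead of antiparallel to
#'   the anchors (robustness testing).
#' @param seed RNG seed.
#' @param out_pdb,out_truth optional paths; when given, the complex is
#'   written as PDB and the ground truth as JSON.
#' @return list with \code{model} (a \code{complex_model}), \code{truth}
#'   (planted interval, inward positions/parity, anchor bond counts), and
#'   the generating parameters.
#' @export
build_capture_complex <- function(strand_length = 8L, spacing = 4.8,
                                  substrate_sequence = NULL, flank = 6L,
                                  parallel = FALSE, seed = 1L,
                                  out_pdb = NULL, out_truth = NULL) {
  if (spacing <= 4.0 || spacing >= 5.5)
    stop("spacing must lie in (4.0, 5.5) Angstroms")
  stopifnot(strand_length >= 3)
  withr::with_seed(seed, {
    if (is.null(substrate_sequence)) {
      substrate_sequence <- paste0(.sample_seq(flank, .FLANK_POOL),
                                   .sample_seq(strand_length, .STRAND_POOL),
                                   .sample_seq(flank, .FLANK_POOL))
      start <- flank + 1L
    } else {
      if (nchar(substrate_sequence) < strand_length)
        stop("substrate_sequence shorter than strand_length")
      start <- (nchar(substrate_sequence) - strand_length) %/% 2L + 1L
    }
    anchor_a_aa <- strsplit(.sample_seq(10L, .STRAND_POOL), "")[[1]]
    anchor_b_aa <- strsplit(.sample_seq(8L, .STRAND_POOL), "")[[1]]
  })
  end <- start + strand_length - 1L
  n_sub <- nchar(substrate_sequence)
  phi <- rep(.PHI_PPII, n_sub); psi <- rep(.PSI_PPII, n_sub)
  phi[start:end] <- .PHI_STRAND; psi[start:end] <- .PSI_STRAND
  # the peptide unit entering the strand belongs to its hydrogen-bonding
  # network: psi of the preceding residue places the carbonyl from which
  # the strand's first amide hydrogen is reconstructed
  if (start > 1L) psi[start - 1L] <- .PSI_STRAND
  sub_xyz <- build_backbone(substrate_sequence, phi, psi)
  sub_xyz <- .orient_backbone(sub_xyz, idx = start:end)
  sub_aa <- strsplit(substrate_sequence, "")[[1]]
  substrate <- .backbone_chain(sub_xyz, "B", seq_len(n_sub), sub_aa)

  # substrate strand only, for registry scoring (flanks must not bias it)
  strand_only <- .backbone_chain(
    lapply(sub_xyz, function(m) m[start:end, , drop = FALSE]),
    "B", start:end, sub_aa[start:end])

  a_xyz <- .orient_backbone(build_backbone(paste(anchor_a_aa, collapse = "")))
  b_xyz <- .orient_backbone(build_backbone(paste(anchor_b_aa, collapse = "")))
  place_a <- .place_anchor(a_xyz, anchor_a_aa, strand_only, -spacing, parallel)
  place_b <- .place_anchor(b_xyz, anchor_b_aa, strand_only, +spacing, parallel)

  ref_xyz <- .reference_residue(c(0, 0, 8))
  rec_xyz <- lapply(names(place_a$xyz), function(atom)
    rbind(place_a$xyz[[atom]], place_b$xyz[[atom]], ref_xyz[[atom]]))
  names(rec_xyz) <- names(place_a$xyz)
  receptor <- .backbone_chain(rec_xyz, "A", c(148:157, 279:286, 309L),
                              c(anchor_a_aa, anchor_b_aa, "I"))
  model <- complex_model(receptor, substrate, rank = 0L)

  ca_z <- sub_xyz$CA[start:end, 3]
  cb_z <- sub_xyz$CB[start:end, 3]
  toward <- which(!is.na(cb_z) & cb_z > ca_z)  # reference sits at +z
  odd <- seq(1L, strand_length, 2L); even <- seq(2L, strand_length, 2L)
  parity <- if (length(intersect(toward, odd)) >=
                length(intersect(toward, even))) "odd" else "even"
  truth <- list(interval = c(start, end),
                strand_sequence = substr(substrate_sequence, start, end),
                inward_positions = toward,
                inward_resno = start + toward - 1L,
                inward_parity = parity,
                anchor_bonds = c(a = place_a$n_bonds, b = place_b$n_bonds),
                spacing = spacing, seed = seed)
  if (!is.null(out_pdb)) write_pdb_model(list(receptor, substrate), out_pdb)
  if (!is.null(out_truth))
    jsonlite::write_json(truth, out_truth, auto_unbox = TRUE, digits = NA)
  list(model = model, truth = truth,
       params = list(strand_length = strand_length, spacing = spacing,
                     flank = flank, parallel = parallel, seed = seed))
}

# Isolated reference residue (Ile) with its CA at `at`.
.reference_residue <- function(at) {
  ca <- at
  n <- ca + c(-.BOND_N_CA, 0, 0)
  ang <- (180 - .ANGLE_N_CA_C) * pi / 180
  cc <- ca + .BOND_CA_C * c(cos(ang), sin(ang), 0)
  o <- place_atom(n, ca, cc, .BOND_C_O, .ANGLE_CA_C_O, -45)
  cb <- place_atom(cc, n, ca, .BOND_CA_CB, .ANGLE_N_CA_CB, .DIHEDRAL_CB)
  list(N = rbind(n), CA = rbind(ca), C = rbind(cc), O = rbind(o),
       CB = rbind(cb))
}

#' Build a decoy complex (no capture)
#'
#' Same receptor as \code{\link{build_capture_complex}}, but the substrate
#' is folded as an alpha helix and docked away from the anchor groove:
#' either at least 8 Angstroms from both anchors (\code{contact = "none"},
#' a guaranteed negative) or touching only anchor A within the seed cutoff
#' while staying over 8 Angstroms from anchor B (\code{contact = "a"},
#' which exercises the double-anchor AND condition).
#'
#' @param helix_length substrate helix length.
#' @param spacing anchor spacing as in the capture builder.
#' @param contact "none" or "a".
#' @param seed RNG seed.
#' @param out_pdb optional PDB output path.
#' @return list with \code{model} and \code{truth} (captured = FALSE).
#' @export
build_decoy_complex <- function(helix_length = 12L, spacing = 4.8,
                                contact = c("none", "a"), seed = 1L,
                                out_pdb = NULL) {
  contact <- match.arg(contact)
  scaffold <- build_capture_complex(strand_length = 8L, spacing = spacing,
                                    flank = 0L, seed = seed)
  receptor <- scaffold$model$receptor
  withr::with_seed(seed + 1L, {
    helix_seq <- .sample_seq(helix_length, .FLANK_POOL)
  })
  h_xyz <- .orient_backbone(build_backbone(helix_seq, .PHI_HELIX, .PSI_HELIX))
  anchor_rows <- receptor$resno <= 286  # exclude the reference residue
  a_ca <- receptor$xyz$CA[receptor$resno <= 157, , drop = FALSE]
  b_ca <- receptor$xyz$CA[receptor$resno >= 279 & anchor_rows, , drop = FALSE]
  min_dist <- function(xyz, target) min(.pairwise_dist(xyz$CA, target))
  if (contact == "none") {
    cand <- .transform_backbone(h_xyz, diag(3), c(0, 0, 20))
    if (min_dist(cand, a_ca) <= 8 || min_dist(cand, b_ca) <= 8)
      stop("decoy placement failed to clear both anchors by 8 Angstroms")
  } else {
    cand <- NULL
    for (d in seq(3.0, 10, by = 0.05)) {
      trial <- .transform_backbone(h_xyz, diag(3), c(0, -spacing - d, 0))
      da <- min_dist(trial, a_ca); db <- min_dist(trial, b_ca)
      if (da < 5.4 && da > 4.0 && db > 8) { cand <- trial; break }
    }
    if (is.null(cand))
      stop("no placement touching only anchor A found for this geometry")
  }
  substrate <- .backbone_chain(cand, "B", seq_len(helix_length),
                               strsplit(helix_seq, "")[[1]])
  model <- complex_model(receptor, substrate, rank = 0L)
  if (!is.null(out_pdb)) write_pdb_model(list(receptor, substrate), out_pdb)
  list(model = model, truth = list(captured = FALSE, contact = contact,
                                   seed = seed))
}

#' Plant a pLDDT profile on a monomer chain
#'
#' Draws per-residue pLDDT from two normal distributions - one inside the
#' stated interval, one elsewhere - clipped to \[0, 100\], emulating a
#' disordered (low-confidence) captured region within an otherwise
#' well-predicted substrate.
#'
#' @param chain a \code{chain_model}.
#' @param interval \code{c(start, end)} in author numbering.
#' @param in_mean,in_sd pLDDT distribution inside the interval.
#' @param out_mean,out_sd pLDDT distribution elsewhere.
#' @param seed RNG seed.
#' @return the chain with replaced pLDDT.
#' @export
plant_plddt <- function(chain, interval, in_mean = 50, in_sd = 5,
                        out_mean = 85, out_sd = 5, seed = 1L) {
  stopifnot(inherits(chain, "chain_model"), length(interval) == 2)
  inside <- chain$resno >= interval[1] & chain$resno <= interval[2]
  if (!any(inside)) stop("interval outside the chain")
  withr::with_seed(seed, {
    p <- numeric(length(chain$resno))
    p[inside] <- stats::rnorm(sum(inside), in_mean, in_sd)
    p[!inside] <- stats::rnorm(sum(!inside), out_mean, out_sd)
  })
  chain$plddt <- pmin(pmax(p, 0), 100)
  chain
}
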