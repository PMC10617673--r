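# Fixtures built in code: tiny PDB snippets, dummy chains, and rigid-body
# transforms used across test files.

# A minimal, column-correct ATOM record.
atom_line <- function(serial, name, res3, chain, resno, x, y, z, b = 90) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, res3, chain, resno, x, y, z, 1.00, b,
          substr(name, 1, 1))
}

write_lines_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# A chain whose CA atoms lie on a line; enough for distance/pLDDT work.
dummy_chain <- function(n, chain_id = "A", resno = seq_len(n),
                        aa = rep("A", n), plddt = rep(90, n)) {
  ca <- cbind(3.8 * seq_len(n), 0, 0)
  xyz <- list(N = ca + rep(c(-1, 0.5, 0), each = n),
              CA = ca,
              C = ca + rep(c(1, 0.5, 0), each = n),
              O = ca + rep(c(1, 1.7, 0), each = n),
              CB = ca + rep(c(0, -1, 1), each = n))
  chain_model(chain_id, resno, aa, xyz, plddt)
}

# Random rigid-body transform applied to every atom block of a chain.
rigid_transform_chain <- function(chain, seed = 1) {
  set.seed(seed)
  ang <- stats::runif(3, -180, 180)
  R <- betacatch:::.rot_z(ang[1]) %*% betacatch:::.rot_y(ang[2]) %*%
    betacatch:::.rot_x(ang[3])
  shift <- stats::runif(3, -20, 20)
  chain$xyz <- lapply(chain$xyz, function(m) {
    ok <- stats::complete.cases(m)
    m[ok, ] <- sweep(m[ok, , drop = FALSE] %*% t(R), 2, shift, "+")
    m
  })
  chain
}

# Secondary-structure string with residue numbers attached, as assign_ss
# would return it.
ss_string <- function(codes, resno = seq_len(nchar(codes))) {
  structure(codes, resno = resno)
}

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")
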