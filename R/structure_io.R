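# Chain-level backbone representation of predicted PDB models.
#
# A `chain_model` keeps, per residue: the author residue number, the
# one-letter amino acid, the pLDDT score (read from the B-factor column),
# and backbone/CB coordinates as n x 3 matrices (rows of NA where an atom
# is absent; CB is absent for glycine).

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "CB")

#' Construct a chain model
#'
#' @param chain_id single-character chain identifier.
#' @param resno integer vector of author residue numbers, strictly increasing.
#' @param aa character vector of one-letter amino-acid codes.
#' @param xyz named list of n x 3 coordinate matrices for atoms
#'   \code{N, CA, C, O, CB}; rows of \code{NA} mark absent atoms.
#' @param plddt numeric vector of per-residue pLDDT scores in \[0, 100\]
#'   (values outside the range raise a warning, not an error).
#' @return an object of class \code{chain_model}.
#' @export
chain_model <- function(chain_id, resno, aa, xyz, plddt) {
  n <- length(resno)
  stopifnot(length(aa) == n, length(plddt) == n)
  if (n > 1 && any(diff(resno) <= 0))
    stop("residue author numbers must be strictly increasing in chain '",
         chain_id, "'")
  for (atom in .BACKBONE_ATOMS) {
    if (is.null(xyz[[atom]])) xyz[[atom]] <- matrix(NA_real_, n, 3)
    if (!is.matrix(xyz[[atom]]) || nrow(xyz[[atom]]) != n ||
        ncol(xyz[[atom]]) != 3)
      stop("coordinate block for atom ", atom, " must be an n x 3 matrix")
  }
  bad_ca <- which(!stats::complete.cases(xyz[["CA"]]))
  if (length(bad_ca))
    stop("missing CA coordinates for residue(s) ",
         paste(resno[bad_ca], collapse = ", "), " in chain '", chain_id, "'")
  out_of_range <- !is.na(plddt) & (plddt < 0 | plddt > 100)
  if (any(out_of_range))
    warning(sum(out_of_range), " pLDDT value(s) outside [0, 100] in chain '",
            chain_id, "'")
  structure(
    list(chain_id = chain_id,
         resno = as.integer(resno),
         aa = aa,
         xyz = xyz[.BACKBONE_ATOMS],
         plddt = as.numeric(plddt)),
    class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat("<chain_model> chain", x$chain_id, "-", length(x$resno), "residues,",
      "resno", min(x$resno), "..", max(x$resno), "\n")
  invisible(x)
}

#' @export
length.chain_model <- function(x) length(x$resno)

#' One-letter sequence of a chain model
#' @param chain a \code{chain_model}.
#' @return single character string.
#' @export
chain_sequence <- function(chain) paste(chain$aa, collapse = "")

#' A receptor-substrate complex model
#'
#' @param receptor,substrate \code{chain_model} objects; must have distinct
#'   chain identifiers.
#' @param rank integer model rank within its prediction set (0 = best).
#' @param source_path optional file identifier.
#' @return an object of class \code{complex_model}.
#' @export
complex_model <- function(receptor, substrate, rank = 0L, source_path = NA_character_) {
  stopifnot(inherits(receptor, "chain_model"), inherits(substrate, "chain_model"))
  if (identical(receptor$chain_id, substrate$chain_id))
    stop("receptor and substrate must be distinct chains")
  structure(
    list(receptor = receptor, substrate = substrate,
         rank = as.integer(rank), source_path = source_path),
    class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat("<complex_model> rank", x$rank, "- receptor chain", x$receptor$chain_id,
      paste0("(", length(x$receptor), " aa),"), "substrate chain",
      x$substrate$chain_id, paste0("(", length(x$substrate), " aa)\n"))
  invisible(x)
}

# Select the model_index-th MODEL block of a multi-model file (AlphaFold
# ranked models are one file per rank, so normally there is none).
.select_model_block <- function(lines, model_index) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(lines)
  if (model_index > length(starts))
    stop("file has only ", length(starts), " MODEL block(s); requested ",
         model_index)
  ends <- grep("^ENDMDL", lines)
  end <- if (model_index <= length(ends)) ends[model_index] else length(lines)
  lines[seq(starts[model_index] + 1L, end - 1L)]
}

#' Read a PDB model file into chain models
#'
#' Parses ATOM records (via \pkg{bio3d}), keeps backbone and beta-carbon
#' atoms, stores the B-factor of the alpha carbon as the residue's pLDDT,
#' and returns one \code{chain_model} per chain, residues ordered by author
#' number. Only the requested MODEL block of a multi-model file is read;
#' for alternate locations the first listed conformer is kept. Heteroatoms
#' and waters are ignored.
#'
#' @param path PDB file path.
#' @param model_index 1-based MODEL block to read (default first).
#' @return named list of \code{chain_model}, one per chain identifier.
#' @export
read_pdb_model <- function(path, model_index = 1L) {
  lines <- readLines(path, warn = FALSE)
  lines <- .select_model_block(lines, model_index)
  atom_idx <- grep("^ATOM", lines)
  if (!length(atom_idx)) stop("no ATOM records in ", path)
  short <- atom_idx[nchar(lines[atom_idx]) < 54]
  if (length(short))
    stop("malformed ATOM record at line ", short[1], " of ", path,
         " (record shorter than the coordinate columns)")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  bad <- which(!stats::complete.cases(at[, c("x", "y", "z")]))
  if (length(bad)) {
    ln <- atom_idx[min(bad[1], length(atom_idx))]
    stop("malformed ATOM record near line ", ln, " of ", path,
         " (unparseable coordinates)")
  }
  at <- at[at$elety %in% .BACKBONE_ATOMS, , drop = FALSE]
  # first-listed altloc wins
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]
  chains <- unique(at$chain)
  out <- lapply(chains, function(ch) {
    sub <- at[at$chain == ch, , drop = FALSE]
    resno <- sort(unique(sub$resno))
    n <- length(resno)
    xyz <- lapply(.BACKBONE_ATOMS, function(a) matrix(NA_real_, n, 3))
    names(xyz) <- .BACKBONE_ATOMS
    aa <- character(n)
    plddt <- rep(NA_real_, n)
    row_of <- match(sub$resno, resno)
    for (k in seq_len(nrow(sub))) {
      r <- row_of[k]
      xyz[[sub$elety[k]]][r, ] <- c(sub$x[k], sub$y[k], sub$z[k])
      if (sub$elety[k] == "CA") {
        aa[r] <- bio3d::aa321(sub$resid[k])
        plddt[r] <- sub$b[k]
      }
    }
    no_ca <- which(is.na(xyz[["CA"]][, 1]))
    if (length(no_ca))
      stop("residue(s) ", paste(resno[no_ca], collapse = ", "), " in chain '",
           ch, "' of ", path, " have no CA atom")
    chain_model(ch, resno, aa, xyz, plddt)
  })
  names(out) <- chains
  out
}

#' Write chain models as a PDB file
#'
#' Fixed-column ATOM records; each residue's pLDDT is written to the
#' B-factor column of all its atoms. Deterministic output (byte-identical
#' for identical input).
#'
#' @param chains a \code{chain_model} or list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pdb_model <- function(chains, path) {
  if (inherits(chains, "chain_model")) chains <- list(chains)
  con <- file(path, "wb")  # "wb": fixed newlines across platforms
  on.exit(close(con))
  serial <- 0L
  for (chain in chains) {
    for (i in seq_along(chain$resno)) {
      res3 <- bio3d::aa123(chain$aa[i])
      b <- chain$plddt[i]
      if (is.na(b)) b <- 0
      for (atom in .BACKBONE_ATOMS) {
        co <- chain$xyz[[atom]][i, ]
        if (anyNA(co)) next
        serial <- serial + 1L
        elem <- substr(atom, 1, 1)
        writeLines(sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, atom, res3, chain$chain_id, chain$resno[i],
          co[1], co[2], co[3], 1.00, b, elem), con)
      }
    }
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Best ungapped (sliding, gap-free) identity of s against ref, as a fraction
# of the reference length.
.ungapped_identity <- function(s, ref) {
  a <- strsplit(s, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  na <- length(a); nb <- length(b)
  best <- 0L
  for (shift in seq(-(na - 1L), nb - 1L)) {
    ia <- max(1L, 1L - shift); ib <- ia + shift
    len <- min(na - ia, nb - ib) + 1L
    if (len < 1L) next
    m <- sum(a[ia:(ia + len - 1L)] == b[ib:(ib + len - 1L)])
    if (m > best) best <- m
  }
  best / nb
}

#' Assign receptor and substrate roles to a two-chain model
#'
#' The chain with the higher ungapped sequence identity to the receptor
#' reference sequence becomes the receptor; the other chain the substrate.
#' Invariant to chain order. An exact identity tie is an error (pass the
#' receptor chain explicitly in that degenerate case).
#'
#' @param chains list of exactly two \code{chain_model}s.
#' @param receptor_sequence one-letter reference sequence of the receptor.
#' @param rank,source_path passed to \code{\link{complex_model}}.
#' @return a \code{complex_model}.
#' @export
assign_roles <- function(chains, receptor_sequence, rank = 0L,
                         source_path = NA_character_) {
  if (length(chains) != 2)
    stop("expected exactly 2 chains, got ", length(chains))
  if (!nzchar(receptor_sequence)) stop("receptor_sequence must be nonempty")
  ident <- vapply(chains, function(ch)
    .ungapped_identity(chain_sequence(ch), receptor_sequence), numeric(1))
  if (abs(ident[1] - ident[2]) < 1e-12)
    stop("chains tie on identity to the receptor reference (",
         signif(ident[1], 3), "); disambiguate by passing the receptor ",
         "chain to complex_model() explicitly")
  r <- which.max(ident)
  complex_model(chains[[r]], chains[[3 - r]], rank = rank,
                source_path = source_path)
}

#' Load a ranked model set from a directory
#'
#' Discovers ranked model files by filename glob (AlphaFold convention
#' \code{ranked_<k>.pdb}), reads each, assigns receptor/substrate roles
#' against the reference sequence, and returns models ordered by rank.
#'
#' @param directory directory containing the ranked PDB files.
#' @param receptor_sequence one-letter receptor reference sequence.
#' @param n_models maximum number of ranked models expected (default 25).
#' @param glob filename glob for model files.
#' @return list of \code{complex_model}, ordered by ascending rank.
#' @export
load_model_set <- function(directory, receptor_sequence, n_models = 25L,
                           glob = "ranked_*.pdb") {
  files <- Sys.glob(file.path(directory, glob))
  if (!length(files))
    stop("no model files matching '", glob, "' in ", directory)
  rank <- suppressWarnings(
    as.integer(sub(".*?([0-9]+)[^0-9]*$", "\\1", basename(files))))
  if (anyNA(rank)) rank[is.na(rank)] <- seq_len(sum(is.na(rank))) - 1L
  ord <- order(rank)
  files <- files[ord]; rank <- rank[ord]
  if (length(files) > n_models) {
    files <- files[seq_len(n_models)]
    rank <- rank[seq_len(n_models)]
  }
  if (length(files) < n_models)
    warning("found ", length(files), " model(s) in ", directory,
            " (expected ", n_models, ")")
  models <- vector("list", length(files))
  for (k in seq_along(files)) {
    chains <- read_pdb_model(files[k])
    models[[k]] <- assign_roles(chains, receptor_sequence, rank = rank[k],
                                source_path = files[k])
  }
  models
}
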