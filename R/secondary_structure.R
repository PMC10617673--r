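# Internal Kabsch-Sander secondary-structure assignment.
#
# Backbone hydrogen bonds are scored with the electrostatic energy
#   E = 0.084 * 332 * (1/r(ON) + 1/r(CH) - 1/r(OH) - 1/r(CN))  [kcal/mol]
# between an acceptor carbonyl (C, O) and a donor amide (N, H); a bond is
# declared below -0.5 kcal/mol. The amide hydrogen is reconstructed 1.0 A
# from N, anti to the preceding residue's C=O. Beta bridges (parallel and
# antiparallel i/j hydrogen-bond patterns) are chained into ladders; only
# residues in ladders of >= 2 consecutive bridges are coded "E" (an isolated
# bridge stays "-"). Alpha helices are coded "H" from consecutive i -> i+4
# turns, and take precedence over "E". The first and last residue of each
# chain cannot be assigned and carry "?" until terminal propagation.

.KS_Q1Q2F <- 0.084 * 332  # 27.888 kcal/mol * A
.KS_CUTOFF <- -0.5        # bond threshold, kcal/mol
.KS_EMIN <- -9.9          # clamp for near-clash geometries (r < 0.5 A)

#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' @param donor list with 3-vector elements \code{N} and \code{H} (amide).
#' @param acceptor list with 3-vector elements \code{C} and \code{O}
#'   (carbonyl).
#' @return energy in kcal/mol; the bond criterion is energy < -0.5. Any
#'   interatomic distance under 0.5 Angstrom (a clash) clamps the energy to
#'   -9.9, the conventional minimum.
#' @export
hbond_energy <- function(donor, acceptor) {
  r_on <- .vnorm(acceptor$O - donor$N)
  r_ch <- .vnorm(acceptor$C - donor$H)
  r_oh <- .vnorm(acceptor$O - donor$H)
  r_cn <- .vnorm(acceptor$C - donor$N)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(.KS_EMIN)
  e <- .KS_Q1Q2F * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  max(e, .KS_EMIN)
}

# Flatten a list of chains into one residue table for joint assignment.
# `linked[i]` is TRUE when residue i-1 precedes i by a real peptide bond
# (same chain, consecutive author number, C-N distance < 2.5 A).
.residue_table <- function(chains) {
  n_per <- vapply(chains, function(ch) length(ch$resno), integer(1))
  n <- sum(n_per)
  tab <- list(
    chain = rep(seq_along(chains), n_per),
    resno = unlist(lapply(chains, `[[`, "resno")),
    aa = unlist(lapply(chains, `[[`, "aa")),
    N = do.call(rbind, lapply(chains, function(ch) ch$xyz$N)),
    CA = do.call(rbind, lapply(chains, function(ch) ch$xyz$CA)),
    C = do.call(rbind, lapply(chains, function(ch) ch$xyz$C)),
    O = do.call(rbind, lapply(chains, function(ch) ch$xyz$O)))
  tab$complete <- stats::complete.cases(cbind(tab$N, tab$CA, tab$C, tab$O))
  linked <- rep(FALSE, n)
  for (i in seq_len(n)[-1]) {
    if (tab$chain[i] != tab$chain[i - 1]) next
    if (tab$resno[i] != tab$resno[i - 1] + 1L) next
    if (!tab$complete[i] || !tab$complete[i - 1]) next
    if (.vnorm(tab$N[i, ] - tab$C[i - 1, ]) < 2.5) linked[i] <- TRUE
  }
  tab$linked <- linked
  tab$n <- n
  tab
}

# n x n logical matrix: HB[i, j] is TRUE when the carbonyl of residue i
# accepts a hydrogen bond from the amide of residue j.
.hbond_matrix <- function(tab) {
  n <- tab$n
  H <- matrix(NA_real_, n, 3)
  for (j in seq_len(n)) {
    if (!tab$linked[j] || tab$aa[j] == "P") next  # no donor H
    H[j, ] <- tab$N[j, ] + .vunit(tab$C[j - 1, ] - tab$O[j - 1, ])
  }
  hb <- matrix(FALSE, n, n)
  can_accept <- tab$complete
  can_donate <- !is.na(H[, 1]) & tab$complete
  cd2 <- function(A, B) {  # squared cross-distances, rows of A vs rows of B
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  }
  ai <- which(can_accept)
  dj <- which(can_donate)
  if (!length(ai) || !length(dj)) return(hb)
  d_on <- sqrt(pmax(cd2(tab$O[ai, , drop = FALSE], tab$N[dj, , drop = FALSE]), 0))
  d_ch <- sqrt(pmax(cd2(tab$C[ai, , drop = FALSE], H[dj, , drop = FALSE]), 0))
  d_oh <- sqrt(pmax(cd2(tab$O[ai, , drop = FALSE], H[dj, , drop = FALSE]), 0))
  d_cn <- sqrt(pmax(cd2(tab$C[ai, , drop = FALSE], tab$N[dj, , drop = FALSE]), 0))
  e <- .KS_Q1Q2F * (1 / d_on + 1 / d_ch - 1 / d_oh - 1 / d_cn)
  e[d_on < 0.5 | d_ch < 0.5 | d_oh < 0.5 | d_cn < 0.5] <- .KS_EMIN
  bond <- e < .KS_CUTOFF
  bond[outer(ai, dj, "==")] <- FALSE  # no self bonds
  hb[ai, dj] <- bond
  hb
}

# Bridge partners must be separated by > 2 positions within a chain; any
# inter-chain pair is allowed.
.bridge_allowed <- function(tab, i, j) {
  tab$chain[i] != tab$chain[j] || abs(i - j) > 2
}

.assign_ss_multi <- function(chains) {
  tab <- .residue_table(chains)
  n <- tab$n
  codes <- rep("-", n)
  if (any(!tab$complete)) {
    warning("residue(s) with incomplete backbone coded '-': ",
            paste(tab$resno[!tab$complete], collapse = ", "))
  }
  if (n >= 3) {
    hb <- .hbond_matrix(tab)
    # helper: HB(i,j) = CO of i to NH of j, guarded for index validity
    HB <- function(i, j) {
      i >= 1 & i <= n & j >= 1 & j <= n & hb[cbind(pmax(i, 1), pmax(j, 1))]
    }
    # within-chain neighbours; steps across a chain break invalidate a pattern
    nb <- function(i, d) {
      k <- i + d
      if (k < 1 || k > n) return(NA_integer_)
      # every step from i to k must be peptide-linked
      rng <- if (d > 0) (i + 1):k else (k + 1):i
      if (all(tab$linked[rng])) k else NA_integer_
    }
    bridges <- list()  # each: c(i, j, type) with type 1=parallel, 2=anti
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (!.bridge_allowed(tab, i, j)) next
        im1 <- nb(i, -1); ip1 <- nb(i, 1)
        jm1 <- nb(j, -1); jp1 <- nb(j, 1)
        par <- (!is.na(im1) && !is.na(ip1) && HB(im1, j) && HB(j, ip1)) ||
               (!is.na(jm1) && !is.na(jp1) && HB(jm1, i) && HB(i, jp1))
        anti <- (HB(i, j) && HB(j, i)) ||
                (!is.na(im1) && !is.na(jp1) && !is.na(jm1) && !is.na(ip1) &&
                 HB(im1, jp1) && HB(jm1, ip1))
        if (par) bridges[[length(bridges) + 1L]] <- c(i, j, 1L)
        if (anti) bridges[[length(bridges) + 1L]] <- c(i, j, 2L)
      }
    }
    if (length(bridges)) {
      bm <- do.call(rbind, bridges)
      # chain bridges into ladders: (i, j) extends to (i+1, j+1) for parallel
      # ladders and (i+1, j-1) for antiparallel ones
      keyset <- paste(bm[, 1], bm[, 2], bm[, 3])
      in_ladder <- rep(FALSE, nrow(bm))
      for (k in seq_len(nrow(bm))) {
        i <- bm[k, 1]; j <- bm[k, 2]; ty <- bm[k, 3]
        jstep <- if (ty == 1L) j + 1L else j - 1L
        succ <- paste(i + 1L, jstep, ty) %in% keyset
        jprev <- if (ty == 1L) j - 1L else j + 1L
        pred <- paste(i - 1L, jprev, ty) %in% keyset
        if (succ || pred) in_ladder[k] <- TRUE
      }
      e_res <- unique(c(bm[in_ladder, 1], bm[in_ladder, 2]))
      codes[e_res] <- "E"
    }
    # alpha helix: two consecutive i -> i+4 turns make residues i..i+3 "H"
    turn4 <- rep(FALSE, n)
    for (i in seq_len(n)) {
      k <- nb(i, 4)
      if (!is.na(k) && HB(i, k)) turn4[i] <- TRUE
    }
    for (i in seq_len(n - 1)) {
      if (turn4[i] && turn4[i + 1]) codes[(i + 1):(i + 4)] <- "H"
    }
  }
  # chain termini cannot be assigned
  first <- c(TRUE, tab$chain[-1] != tab$chain[-n])
  last <- c(tab$chain[-1] != tab$chain[-n], TRUE)
  codes[first | last] <- "?"
  split(codes, tab$chain)
}

#' Assign per-residue secondary structure to a chain
#'
#' Minimal Kabsch-Sander assignment: "E" for residues in beta ladders,
#' "H" for alpha helices, "-" otherwise, "?" at the two chain termini
#' (which lack the flanking context the algorithm needs). Apply
#' \code{\link{propagate_terminal_E}} to resolve the termini. The
#' assignment depends only on interatomic distances, so it is invariant
#' to rigid-body motion.
#'
#' @param chain a \code{chain_model} with at least 3 residues.
#' @param partners optional list of additional \code{chain_model}s whose
#'   backbones can hydrogen-bond with \code{chain} (inter-chain bridges);
#'   used when assigning a substrate in complex with its receptor.
#' @return character string of per-residue codes aligned to the chain, with
#'   the residue numbers as the \code{resno} attribute.
#' @export
assign_ss <- function(chain, partners = list()) {
  stopifnot(inherits(chain, "chain_model"))
  if (length(chain$resno) < 3)
    stop("secondary-structure assignment needs >= 3 residues")
  codes <- .assign_ss_multi(c(list(chain), partners))[[1]]
  structure(paste(codes, collapse = ""), resno = chain$resno)
}

#' Resolve terminal "?" codes by neighbour propagation
#'
#' A terminal residue left unassigned ("?") is coded "E" when its single
#' neighbour is "E" (so genuine strand ends are not clipped), otherwise "-".
#' No other position changes.
#'
#' @param ss secondary-structure string from \code{\link{assign_ss}}.
#' @return string of the same length over \{E, H, -\}.
#' @export
propagate_terminal_E <- function(ss) {
  codes <- strsplit(unclass(ss)[1], "")[[1]]
  L <- length(codes)
  if (L == 0) return(ss)
  fix <- function(pos, nbr) {
    if (codes[pos] == "?")
      codes[pos] <<- if (!is.na(nbr) && codes[nbr] == "E") "E" else "-"
  }
  fix(1L, if (L >= 2) 2L else NA_integer_)
  fix(L, if (L >= 2) L - 1L else NA_integer_)
  codes[codes == "?"] <- "-"  # any interior leftovers (chain breaks)
  structure(paste(codes, collapse = ""), resno = attr(ss, "resno"))
}

#' Write a secondary-structure string as a two-column TSV
#'
#' @param ss string from \code{\link{assign_ss}} or
#'   \code{\link{propagate_terminal_E}} (carries residue numbers).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ss_tsv <- function(ss, path) {
  codes <- strsplit(unclass(ss)[1], "")[[1]]
  utils::write.table(
    data.frame(resno = attr(ss, "resno"), code = codes),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
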