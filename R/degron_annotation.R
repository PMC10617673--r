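# Annotation of captured strands and cohort statistics: inward/outward
# side-chain facing by the Cbeta-vs-Calpha rule with odd/even parity
# reconciliation, positional amino-acid enrichment against background,
# and paired-t contrasts (hydrophobicity, pLDDT disorder).

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Hydrophobicity index at pH 7
#'
#' Per-residue hydrophobicity scale at pH 7 (Monera et al. normalized
#' octanol scale; dimensionless, most hydrophobic = 100). The scale is a
#' default: every consumer accepts an alternative named vector over the 20
#' amino acids.
#'
#' @format named numeric vector of length 20, one-letter codes as names.
#' @export
hydro_scale_ph7 <- c(
  F = 100, I = 99, W = 97, L = 97, V = 76, M = 74, Y = 63, C = 49, A = 41,
  T = 13, H = 8, G = 0, S = -5, Q = -10, R = -14, K = -23, N = -28,
  E = -31, P = -46, D = -55)

#' Reconcile raw facing calls to a pure parity set
#'
#' Side chains along a beta strand alternate sides, so the raw inward
#' calls (noisy at glycines and strand ends) are replaced by whichever of
#' the odd-position or even-position sets they overlap more. Positions are
#' 1-based within the strand, N to C.
#'
#' @param raw_inward integer vector of raw inward positions (1..L).
#' @param strand_length strand length L (>= 2).
#' @return list with \code{inward}, \code{outward} (position vectors) and
#'   \code{parity} ("odd" or "even"). An exact overlap tie is an error; pass
#'   the parity explicitly in that degenerate case.
#' @export
reconcile_parity <- function(raw_inward, strand_length) {
  stopifnot(strand_length >= 2)
  raw_inward <- as.integer(raw_inward)
  if (length(raw_inward) && (min(raw_inward) < 1 || max(raw_inward) > strand_length))
    stop("raw positions outside 1..", strand_length)
  odd <- seq(1L, strand_length, by = 2L)
  even <- seq(2L, strand_length, by = 2L)
  n_odd <- length(intersect(raw_inward, odd))
  n_even <- length(intersect(raw_inward, even))
  if (n_odd == n_even)
    stop("facing parity tie (", n_odd, " odd vs ", n_even,
         " even matches); resolve by specifying the parity manually")
  if (n_odd > n_even) list(inward = odd, outward = even, parity = "odd")
  else list(inward = even, outward = odd, parity = "even")
}

#' Annotate inward/outward facing of a captured strand
#'
#' A strand residue faces the receptor when its Cbeta is strictly closer
#' than its Calpha to the reference Calpha in the receptor core (default
#' residue 309, the Catch-domain isoleucine used as the domain proxy).
#' Glycines (no Cbeta) are skipped in the raw calling; raw calls are then
#' reconciled to a pure odd or even parity set with
#' \code{\link{reconcile_parity}}, which overrides rotationally variable
#' strand-end calls.
#'
#' @param strand a \code{\link{captured_strand}}.
#' @param model the \code{complex_model} the strand came from.
#' @param ref_residue receptor author number of the reference residue.
#' @return list with 1-based strand positions \code{inward} and
#'   \code{outward}, the winning \code{parity}, author-number vectors
#'   \code{inward_resno}/\code{outward_resno}, and the \code{raw_inward}
#'   positions before reconciliation.
#' @export
assign_facing <- function(strand, model, ref_residue = 309L) {
  stopifnot(inherits(strand, "captured_strand"), inherits(model, "complex_model"))
  ref_idx <- match(ref_residue, model$receptor$resno)
  if (is.na(ref_idx))
    stop("reference residue ", ref_residue, " absent from receptor chain")
  ref <- model$receptor$xyz$CA[ref_idx, ]
  resno <- seq(strand$interval[1], strand$interval[2])
  idx <- match(resno, model$substrate$resno)
  if (anyNA(idx)) stop("strand interval not resolvable in substrate chain")
  L <- length(resno)
  raw <- integer(0)
  for (p in seq_len(L)) {
    cb <- model$substrate$xyz$CB[idx[p], ]
    if (anyNA(cb)) next  # glycine (or missing CB): no raw call
    ca <- model$substrate$xyz$CA[idx[p], ]
    if (.vnorm(cb - ref) < .vnorm(ca - ref)) raw <- c(raw, p)
  }
  rec <- reconcile_parity(raw, L)
  list(inward = rec$inward, outward = rec$outward, parity = rec$parity,
       inward_resno = resno[rec$inward], outward_resno = resno[rec$outward],
       raw_inward = raw)
}

#' Background amino-acid frequencies of a sequence cohort
#'
#' @param sequences character vector of one-letter sequences.
#' @return named numeric vector over the 20 amino acids, summing to 1.
#' @export
background_frequencies <- function(sequences) {
  letters_all <- unlist(strsplit(sequences, ""))
  letters_all <- letters_all[letters_all %in% .AA20]
  tab <- table(factor(letters_all, levels = .AA20))
  f <- as.numeric(tab) / sum(tab)
  names(f) <- .AA20
  f
}

.freq_ratio_rows <- function(letters, background, side, n, n_strands) {
  counts <- table(factor(letters[letters %in% .AA20], levels = .AA20))
  freq <- as.numeric(counts) / max(sum(counts), 1L)
  ratio <- freq / background[.AA20]
  zero_bg <- background[.AA20] == 0 & freq > 0
  if (any(zero_bg)) {
    warning("background frequency 0 for observed amino acid(s) ",
            paste(.AA20[zero_bg], collapse = ", "), "; ratio set to Inf")
    ratio[zero_bg] <- Inf
  }
  data.frame(side = side, n = n, aa = .AA20, count = as.integer(counts),
             freq = freq, ratio = as.numeric(ratio), n_strands = n_strands,
             row.names = NULL)
}

#' Positional amino-acid enrichment of a strand cohort
#'
#' For each depth n into the strand from the N- or C-terminal side, the
#' frequency of each amino acid over strands of length >= 2n (so no strand
#' contributes the same residue to both sides) is divided by the background
#' frequency across the substrate sequences. Flanking positions (the
#' residues immediately preceding and following each strand) are tabulated
#' the same way, excluding strands sitting at the protein's N- or C-
#' terminus respectively.
#'
#' @param cohort data.frame with columns \code{sequence} (full substrate
#'   sequence), \code{start}, \code{end} (1-based strand interval within
#'   the sequence).
#' @param background named frequency vector over the 20 amino acids,
#'   summing to 1 (default: computed from the cohort's sequences).
#' @param max_depth largest depth n to tabulate (default: floor of half the
#'   longest strand).
#' @return data.frame with columns side ("N", "C", "flank_preceding",
#'   "flank_following"), n (depth; NA for flanks), aa, count, freq, ratio,
#'   n_strands. Within each (side, n) group, sum(ratio * background) = 1.
#' @export
positional_enrichment <- function(cohort, background = NULL, max_depth = NULL) {
  stopifnot(nrow(cohort) >= 1,
            all(c("sequence", "start", "end") %in% names(cohort)))
  if (is.null(background)) background <- background_frequencies(cohort$sequence)
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  strand_seq <- substr(cohort$sequence, cohort$start, cohort$end)
  len <- nchar(strand_seq)
  if (is.null(max_depth)) max_depth <- max(len %/% 2L)
  out <- list()
  for (n in seq_len(max_depth)) {
    ok <- len >= 2L * n
    if (!any(ok)) break
    out[[length(out) + 1L]] <- .freq_ratio_rows(
      substr(strand_seq[ok], n, n), background, "N", n, sum(ok))
    out[[length(out) + 1L]] <- .freq_ratio_rows(
      substr(strand_seq[ok], len[ok] - n + 1L, len[ok] - n + 1L),
      background, "C", n, sum(ok))
  }
  pre_ok <- cohort$start > 1L
  if (any(pre_ok))
    out[[length(out) + 1L]] <- .freq_ratio_rows(
      substr(cohort$sequence[pre_ok], cohort$start[pre_ok] - 1L,
             cohort$start[pre_ok] - 1L),
      background, "flank_preceding", NA_integer_, sum(pre_ok))
  post_ok <- cohort$end < nchar(cohort$sequence)
  if (any(post_ok))
    out[[length(out) + 1L]] <- .freq_ratio_rows(
      substr(cohort$sequence[post_ok], cohort$end[post_ok] + 1L,
             cohort$end[post_ok] + 1L),
      background, "flank_following", NA_integer_, sum(post_ok))
  do.call(rbind, out)
}

# Two-sided paired t-test from the closed form (mean/SD of differences,
# df = n - 1). Both differences zero everywhere -> t = 0, p = 1.
.paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("paired t-test needs at least 2 pairs")
  d <- x - y
  md <- mean(d)
  sd_d <- stats::sd(d)
  t <- if (sd_d == 0) {
    if (md == 0) 0 else sign(md) * Inf
  } else md / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, df = n - 1L, p = p, mean_difference = md, n = n)
}

.contrast_result <- function(tt, pairs, n_dropped = 0L) {
  structure(c(tt, list(pairs = pairs, n_dropped = n_dropped)),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("<contrast_result> n =", x$n, " mean difference =",
      signif(x$mean_difference, 4), " t =", signif(x$t, 4),
      " df =", x$df, " p =", signif(x$p, 3), "\n")
  invisible(x)
}

#' Hydrophobicity contrast: strand versus rest of substrate
#'
#' For each substrate, pairs the mean hydrophobicity index over the captured
#' strand with the mean over the rest of the sequence, and tests the paired
#' differences with a two-sided paired t-test. Invariant to substrate order.
#'
#' @param cohort data.frame with columns \code{sequence}, \code{start},
#'   \code{end} (strand strictly inside the sequence); >= 2 rows.
#' @param scale named hydrophobicity vector over the 20 amino acids
#'   (default \code{\link{hydro_scale_ph7}}).
#' @return a \code{contrast_result}: t, df, two-sided p, mean difference
#'   (strand minus rest), n, and the per-substrate paired means.
#' @export
hydrophobicity_contrast <- function(cohort, scale = hydro_scale_ph7) {
  stopifnot(nrow(cohort) >= 2, all(.AA20 %in% names(scale)))
  if (any(cohort$start < 1 | cohort$end > nchar(cohort$sequence) |
          cohort$start > cohort$end))
    stop("strand interval outside its sequence")
  if (any(cohort$start == 1 & cohort$end == nchar(cohort$sequence)))
    stop("strand spans the whole sequence; no complement to contrast")
  mean_scale <- function(s) mean(scale[strsplit(s, "")[[1]]], na.rm = TRUE)
  in_mean <- vapply(substr(cohort$sequence, cohort$start, cohort$end),
                    mean_scale, numeric(1), USE.NAMES = FALSE)
  out_mean <- vapply(seq_len(nrow(cohort)), function(i) {
    s <- cohort$sequence[i]
    rest <- paste0(substr(s, 1, cohort$start[i] - 1),
                   substr(s, cohort$end[i] + 1, nchar(s)))
    mean_scale(rest)
  }, numeric(1))
  tt <- .paired_t(in_mean, out_mean)
  .contrast_result(tt, data.frame(strand_mean = in_mean, rest_mean = out_mean))
}

#' pLDDT disorder contrast: captured region versus rest of the monomer
#'
#' For each substrate, pairs the mean pLDDT over the captured interval (in
#' the substrate's monomer model) with the mean over the rest of the chain,
#' and applies a two-sided paired t-test. A negative mean difference means
#' the captured region is predicted more disordered. Substrates whose
#' interval cannot be resolved in the monomer numbering are dropped with a
#' warning and counted in \code{n_dropped}.
#'
#' @param monomers named list of monomer \code{chain_model}s with pLDDT.
#' @param intervals data.frame with columns \code{id} (matching
#'   \code{names(monomers)}), \code{start}, \code{end} (author numbering).
#' @return a \code{contrast_result}.
#' @export
plddt_contrast <- function(monomers, intervals) {
  stopifnot(all(c("id", "start", "end") %in% names(intervals)))
  in_means <- numeric(0); out_means <- numeric(0); kept <- character(0)
  dropped <- character(0)
  for (i in seq_len(nrow(intervals))) {
    id <- as.character(intervals$id[i])
    ch <- monomers[[id]]
    if (is.null(ch)) { dropped <- c(dropped, id); next }
    sel <- ch$resno >= intervals$start[i] & ch$resno <= intervals$end[i]
    if (!any(sel) || all(sel)) { dropped <- c(dropped, id); next }
    in_means <- c(in_means, mean(ch$plddt[sel], na.rm = TRUE))
    out_means <- c(out_means, mean(ch$plddt[!sel], na.rm = TRUE))
    kept <- c(kept, id)
  }
  if (length(dropped))
    warning(length(dropped), " substrate(s) dropped (interval not ",
            "resolvable in monomer): ", paste(dropped, collapse = ", "))
  tt <- .paired_t(in_means, out_means)
  .contrast_result(
    tt,
    data.frame(id = kept, region_mean = in_means, rest_mean = out_means),
    n_dropped = length(dropped))
}
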