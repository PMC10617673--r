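# Protein stability index (PSI) from six-bin GPS reporter-screen read
# counts. Reads are depth-corrected per bin, converted to per-ORF
# proportions across the six bins of one condition, and summarized as
#   PSI = sum_{i=1..6} R_i * i          (1 = most unstable, 6 = most stable)
# delta PSI = PSI(treatment) - PSI(control); the destabilization filter
# keeps genes with delta PSI strictly below -0.5.

.N_BINS <- 6L

#' Depth-normalize a count matrix across stability bins
#'
#' Corrects per-bin sequencing depth before proportions are computed.
#' \code{"total"} scales each bin's column so all column totals equal the
#' mean library size, preserving within-bin composition. \code{"median-ratio"}
#' estimates each bin's depth factor as the median, over ORFs with
#' positive counts in every bin, of the ratio of the ORF's count to its
#' geometric-mean row reference; this estimate is driven by the unshifted
#' majority of the library and is therefore robust to a minority of ORFs
#' with genuine stability shifts, which distort plain column totals.
#'
#' @param counts ORF x 6 nonnegative count matrix.
#' @param method "median-ratio" (default) or "total".
#' @return matrix of the same shape, columns rescaled.
#' @export
depth_normalize <- function(counts, method = c("median-ratio", "total")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == .N_BINS, all(counts >= 0))
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("stability bin(s) with zero total reads: bin ",
         paste(which(totals == 0), collapse = ", "))
  if (method == "total") {
    factors <- totals / mean(totals)
  } else {
    pos <- rowSums(counts > 0) == .N_BINS
    if (sum(pos) < 10) {  # too few complete rows to trust medians
      factors <- totals / mean(totals)
    } else {
      m <- counts[pos, , drop = FALSE]
      ref <- exp(rowMeans(log(m)))
      factors <- apply(m / ref, 2, stats::median)
      factors <- factors / exp(mean(log(factors)))
    }
  }
  sweep(counts, 2, factors, "/")
}

#' Protein stability index of a bin-proportion vector
#'
#' @param R numeric 6-vector of nonnegative read proportions across
#'   stability bins 1..6, summing to 1 (tolerance 1e-6).
#' @return PSI = sum(R_i * i), a score in \[1, 6\].
#' @export
compute_psi <- function(R) {
  stopifnot(length(R) == .N_BINS)
  if (any(R < 0)) stop("bin proportions must be nonnegative")
  if (abs(sum(R) - 1) > 1e-6)
    stop("bin proportions must sum to 1 (got ", format(sum(R)), ")")
  sum(R * seq_len(.N_BINS))
}

#' Change in protein stability index
#'
#' @param psi_treatment PSI under receptor/effector overexpression.
#' @param psi_control PSI under the fluorophore-only control.
#' @return delta PSI = treatment minus control, in \[-5, 5\].
#' @export
delta_psi <- function(psi_treatment, psi_control) psi_treatment - psi_control

#' Read a long-format screen count table
#'
#' @param path tab-delimited file with columns gene, barcode, condition
#'   ("control"/"treatment"), bin (1..6), reads.
#' @return validated data.frame.
#' @export
read_screen_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "barcode", "condition", "bin", "reads")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("screen table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(df$bin %in% seq_len(.N_BINS)))
    stop("bin values must be integers 1..6")
  if (any(df$reads < 0)) stop("negative read counts")
  df
}

# long counts -> gene x bin matrix for one condition, barcodes summed
.condition_matrix <- function(counts, condition, genes) {
  sub <- counts[counts$condition == condition, , drop = FALSE]
  m <- matrix(0, length(genes), .N_BINS, dimnames = list(genes, NULL))
  if (nrow(sub)) {
    agg <- stats::aggregate(reads ~ gene + bin, data = sub, FUN = sum)
    m[cbind(match(agg$gene, genes), agg$bin)] <- agg$reads
  }
  m
}

#' Per-gene PSI and delta PSI from a screen count table
#'
#' Barcode counts are summed at the gene level, each condition's bins are
#' depth-normalized, per-gene proportions are computed across the six bins,
#' and PSI / delta PSI are derived. Genes with zero total reads in a
#' condition get \code{NA} PSI and are reported via a message.
#'
#' @param counts long-format data.frame as from
#'   \code{\link{read_screen_counts}}.
#' @param method depth-normalization method, see
#'   \code{\link{depth_normalize}}.
#' @return data.frame with columns gene, psi_control, psi_treatment,
#'   delta_psi, ordered by gene.
#' @export
screen_psi <- function(counts, method = c("median-ratio", "total")) {
  method <- match.arg(method)
  stopifnot(all(c("gene", "condition", "bin", "reads") %in% names(counts)))
  genes <- sort(unique(counts$gene))
  psi_of <- function(condition) {
    m <- depth_normalize(.condition_matrix(counts, condition, genes), method)
    tot <- rowSums(m)
    psi <- rep(NA_real_, length(genes))
    ok <- tot > 0
    psi[ok] <- (m[ok, , drop = FALSE] %*% seq_len(.N_BINS))[, 1] / tot[ok]
    psi
  }
  psi_c <- psi_of("control")
  psi_t <- psi_of("treatment")
  n_missing <- sum(is.na(psi_c) | is.na(psi_t))
  if (n_missing > 0)
    message(n_missing, " gene(s) with zero reads in a condition; PSI set NA")
  data.frame(gene = genes, psi_control = psi_c, psi_treatment = psi_t,
             delta_psi = delta_psi(psi_t, psi_c))
}

#' Destabilization filter on delta PSI
#'
#' Keeps genes whose delta PSI is strictly below the threshold (a gene at
#' exactly the threshold is excluded), ordered by ascending delta PSI.
#' Genes with missing PSI are excluded.
#'
#' @param psi_table data.frame from \code{\link{screen_psi}}.
#' @param threshold delta-PSI cutoff (default -0.5).
#' @return subset of \code{psi_table}, strongest destabilization first.
#' @export
filter_destabilized <- function(psi_table, threshold = -0.5) {
  stopifnot("delta_psi" %in% names(psi_table))
  keep <- !is.na(psi_table$delta_psi) & psi_table$delta_psi < threshold
  out <- psi_table[keep, , drop = FALSE]
  out[order(out$delta_psi), , drop = FALSE]
}
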