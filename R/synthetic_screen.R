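# Simulated six-bin GPS screen counts with planted stability shifts.
#
# Each gene's control bin distribution is drawn around the baseline
# (Dirichlet, conditioned so the planted shift stays within the six-bin
# range); the treatment distribution is the control distribution
# exponentially tilted along the bin axis so that the expected PSI
# difference equals the planted delta PSI exactly. Sequencing is simulated
# per bin library: each bin's reads are multinomial across gene barcodes
# with weights proportional to the genes' probability of sorting into that
# bin, at deliberately unequal per-bin depths - which is what the
# depth correction in the analysis undoes.

#' Tilt a bin distribution to a planted PSI shift
#'
#' Moves probability mass along the bin axis by exponential tilting:
#' q_i proportional to p_i * exp(theta * i), with theta solved so that the
#' expected bin index (the PSI) changes by exactly \code{delta}. Errors
#' when the target PSI falls outside what the support of \code{p} can
#' reach (mass would be needed outside bins 1..6).
#'
#' @param p numeric 6-vector of bin probabilities summing to 1.
#' @param delta planted PSI shift, in \[-5, 5\].
#' @return tilted 6-vector with \code{sum(q * 1:6) == sum(p * 1:6) + delta}.
#' @export
tilt_bin_distribution <- function(p, delta) {
  stopifnot(length(p) == 6, all(p >= 0))
  if (abs(sum(p) - 1) > 1e-8) stop("bin probabilities must sum to 1")
  if (delta == 0) return(p)
  if (abs(delta) > 5) stop("planted delta PSI outside [-5, 5]")
  i <- 1:6
  target <- sum(p * i) + delta
  supp <- range(i[p > 0])
  if (target <= supp[1] || target >= supp[2])
    stop("planted delta PSI ", delta, " infeasible for this baseline ",
         "(target PSI ", signif(target, 4), " outside achievable (",
         supp[1], ", ", supp[2], "))")
  f <- function(th) {
    w <- p * exp(th * (i - 3.5))
    sum(w * i) / sum(w) - target
  }
  th <- stats::uniroot(f, c(-80, 80), tol = 1e-13)$root
  w <- p * exp(th * (i - 3.5))
  w / sum(w)
}

#' Simulate a six-bin GPS screen count table
#'
#' @param n_genes number of genes.
#' @param depth average reads per gene per condition; each bin library is
#'   sequenced to \code{n_genes * depth / 6} reads scaled by
#'   \code{bin_depth_weights}.
#' @param effects planted delta PSI per gene, recycled to \code{n_genes}.
#' @param baseline baseline bin distribution (default uniform: sorting
#'   gates are set so one sixth of the control population falls per bin).
#' @param dirichlet_conc concentration of the per-gene Dirichlet draw
#'   around the baseline (larger = tighter; \code{Inf} = no gene-to-gene
#'   variation). Default 50, a moderate spread of basal stabilities.
#' @param bin_depth_weights relative sequencing depth of the six bin
#'   libraries; the default is deliberately unequal so that the analysis'
#'   depth correction is genuinely exercised.
#' @param n_barcodes barcodes per gene (counts are later summed at the
#'   gene level by \code{\link{screen_psi}}).
#' @param seed RNG seed.
#' @return list with \code{counts} (long data.frame: gene, barcode,
#'   condition, bin, reads) and \code{truth} (gene, delta_true,
#'   psi_control_true).
#' @export
simulate_screen <- function(n_genes = 2000L, depth = 500L, effects = 0,
                            baseline = rep(1 / 6, 6), dirichlet_conc = 50,
                            bin_depth_weights = c(0.8, 1.2, 0.9, 1.1, 1, 1),
                            n_barcodes = 1L, seed = 1L) {
  stopifnot(n_genes >= 1, depth >= 1, length(baseline) == 6,
            all(baseline >= 0), length(bin_depth_weights) == 6,
            all(bin_depth_weights > 0), n_barcodes >= 1)
  baseline <- baseline / sum(baseline)
  effects <- rep_len(effects, n_genes)
  if (any(abs(effects) > 5)) stop("planted effects must lie in [-5, 5]")
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  feasible <- function(p, delta) {
    target <- sum(p * 1:6) + delta
    supp <- range((1:6)[p > 0])
    target > supp[1] + 1e-3 && target < supp[2] - 1e-3
  }
  bin_reads <- round(n_genes * depth * bin_depth_weights /
                       sum(bin_depth_weights))
  withr::with_seed(seed, {
    p_ctrl <- matrix(0, n_genes, 6)
    p_trt <- matrix(0, n_genes, 6)
    for (g in seq_len(n_genes)) {
      if (!feasible(baseline, effects[g]))
        stop("planted delta PSI ", effects[g],
             " infeasible for the baseline distribution")
      p <- baseline
      if (is.finite(dirichlet_conc)) {
        # conditioned on the planted shift staying inside the bin range
        for (try in 1:1000) {
          w <- stats::rgamma(6, shape = dirichlet_conc * baseline)
          if (sum(w) > 0 && feasible(w / sum(w), effects[g])) {
            p <- w / sum(w)
            break
          }
        }
      }
      p_ctrl[g, ] <- p
      p_trt[g, ] <- tilt_bin_distribution(p, effects[g])
    }
    # per-barcode sorting weights (equal gene abundance, barcodes split it)
    bc_weight <- function(pm) pm[rep(seq_len(n_genes), each = n_barcodes), ,
                                 drop = FALSE] / n_barcodes
    draw <- function(pm) {
      w <- bc_weight(pm)
      counts <- matrix(0L, nrow(w), 6)
      for (b in 1:6)
        counts[, b] <- stats::rmultinom(1, bin_reads[b], w[, b])[, 1]
      counts
    }
    c_ctrl <- draw(p_ctrl)
    c_trt <- draw(p_trt)
  })
  bc_names <- paste0(rep(genes, each = n_barcodes), "_bc",
                     rep(seq_len(n_barcodes), n_genes))
  long <- function(counts, condition) {
    data.frame(gene = rep(rep(genes, each = n_barcodes), 6L),
               barcode = rep(bc_names, 6L),
               condition = condition,
               bin = rep(1:6, each = length(bc_names)),
               reads = as.integer(counts))
  }
  counts <- rbind(long(c_ctrl, "control"), long(c_trt, "treatment"))
  counts <- counts[order(counts$gene, counts$barcode, counts$condition,
                         counts$bin), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts,
       truth = data.frame(gene = genes, delta_true = effects,
                          psi_control_true = as.numeric(p_ctrl %*% (1:6))))
}
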