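# Detection of substrate beta strands captured between the receptor's two
# anchor strands: Calpha distance matrix -> 5.5 A double-anchor seeds ->
# intersect with "E" secondary structure -> expand +/- 7 and intersect
# again -> keep the longest contiguous "E" stretch.

#' Capture-detection parameters
#'
#' @param anchor_a,anchor_b inclusive receptor author-number ranges of the
#'   two anchor strands, as \code{c(start, end)}. Defaults are the Catch
#'   domain anchor strands 148-157 and 279-286 (receptor numbering assumed
#'   to follow UniProt Q504T8).
#' @param cutoff Calpha-Calpha distance cutoff in Angstroms (default 5.5;
#'   most beta sheets have inter-strand distances under 5 A).
#' @param pad sequence-space expansion of the seed set, residues in each
#'   direction (default 7).
#' @param min_run minimum consecutive seed run length (default 2:
#'   "sequential residues" implies at least two).
#' @return list of class \code{capture_params}.
#' @export
capture_params <- function(anchor_a = c(148L, 157L), anchor_b = c(279L, 286L),
                           cutoff = 5.5, pad = 7L, min_run = 2L) {
  stopifnot(length(anchor_a) == 2, length(anchor_b) == 2,
            anchor_a[1] <= anchor_a[2], anchor_b[1] <= anchor_b[2],
            cutoff >= 0, pad >= 0, min_run >= 1)
  if (max(anchor_a[1], anchor_b[1]) <= min(anchor_a[2], anchor_b[2]))
    stop("anchor ranges must not overlap")
  structure(list(anchor_a = as.integer(anchor_a),
                 anchor_b = as.integer(anchor_b),
                 cutoff = cutoff, pad = as.integer(pad),
                 min_run = as.integer(min_run)),
            class = "capture_params")
}

.pairwise_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Calpha-Calpha distance matrix between substrate and receptor
#'
#' @param substrate,receptor \code{chain_model}s.
#' @return matrix of Euclidean distances in Angstroms, rows indexed by
#'   substrate author numbers and columns by receptor author numbers
#'   (dimnames carry the numbers); \code{atom_kind} attribute "CA".
#' @export
calpha_distance_matrix <- function(substrate, receptor) {
  stopifnot(length(substrate) > 0, length(receptor) > 0)
  D <- .pairwise_dist(substrate$xyz$CA, receptor$xyz$CA)
  dimnames(D) <- list(substrate$resno, receptor$resno)
  attr(D, "atom_kind") <- "CA"
  D
}

#' Cbeta(substrate)-Calpha(receptor) distance matrix
#'
#' As \code{\link{calpha_distance_matrix}} but using substrate beta-carbon
#' positions; glycine rows (no CB) are \code{NA}.
#' @inheritParams calpha_distance_matrix
#' @export
cbeta_distance_matrix <- function(substrate, receptor) {
  stopifnot(length(substrate) > 0, length(receptor) > 0)
  CB <- substrate$xyz$CB
  has <- stats::complete.cases(CB)
  D <- matrix(NA_real_, nrow(CB), length(receptor$resno))
  if (any(has))
    D[has, ] <- .pairwise_dist(CB[has, , drop = FALSE], receptor$xyz$CA)
  dimnames(D) <- list(substrate$resno, receptor$resno)
  attr(D, "atom_kind") <- "CB"
  D
}

# maximal runs of consecutive integers, as a list of vectors
.consecutive_runs <- function(x) {
  if (!length(x)) return(list())
  x <- sort(unique(x))
  split(x, cumsum(c(1L, diff(x) != 1L)))
}

#' Find seed residues within cutoff of both anchor strands
#'
#' A substrate residue qualifies when its minimum Calpha distance to the
#' anchor-A range and to the anchor-B range are both under the cutoff;
#' qualifying residues are then restricted to maximal consecutive runs of at
#' least \code{min_run} residues.
#'
#' @param D distance matrix from \code{\link{calpha_distance_matrix}}.
#' @param params a \code{\link{capture_params}}.
#' @return sorted integer vector of substrate author numbers (possibly
#'   empty).
#' @export
find_seed_residues <- function(D, params = capture_params()) {
  rcols <- as.integer(colnames(D))
  in_a <- rcols >= params$anchor_a[1] & rcols <= params$anchor_a[2]
  in_b <- rcols >= params$anchor_b[1] & rcols <= params$anchor_b[2]
  if (!any(in_a))
    stop("anchor A range ", params$anchor_a[1], "-", params$anchor_a[2],
         " is absent from the receptor chain")
  if (!any(in_b))
    stop("anchor B range ", params$anchor_b[1], "-", params$anchor_b[2],
         " is absent from the receptor chain")
  d_a <- apply(D[, in_a, drop = FALSE], 1, min)
  d_b <- apply(D[, in_b, drop = FALSE], 1, min)
  seeds <- as.integer(rownames(D))[d_a < params$cutoff & d_b < params$cutoff]
  runs <- .consecutive_runs(seeds)
  keep <- runs[vapply(runs, length, integer(1)) >= params$min_run]
  if (!length(keep)) return(integer(0))
  sort(unlist(keep, use.names = FALSE))
}

#' A captured substrate strand
#'
#' @param interval inclusive author-number range \code{c(start, end)}.
#' @param residues one-letter sequence over the interval.
#' @param model_rank rank of the model the call came from.
#' @param per_residue_ss per-residue codes over the interval (all "E").
#' @return object of class \code{captured_strand}.
#' @export
captured_strand <- function(interval, residues, model_rank = NA_integer_,
                            per_residue_ss = strrep("E", nchar(residues))) {
  stopifnot(length(interval) == 2, interval[1] <= interval[2],
            nchar(residues) == interval[2] - interval[1] + 1)
  structure(list(interval = as.integer(interval), residues = residues,
                 model_rank = as.integer(model_rank),
                 per_residue_ss = per_residue_ss),
            class = "captured_strand")
}

#' @export
print.captured_strand <- function(x, ...) {
  cat("<captured_strand> ", x$interval[1], "-", x$interval[2], " (",
      x$residues, "), model rank ", x$model_rank, "\n", sep = "")
  invisible(x)
}

#' Refine seeds by secondary structure, expand, and trim
#'
#' The three post-processing steps applied to the distance seeds:
#' (1) keep only seeds coded "E"; (2) expand the surviving set by
#' \code{pad} residues in each direction (clipped to the chain) and keep
#' only "E"-coded positions; (3) return the longest contiguous "E" stretch
#' within the expanded set, or \code{NULL} if step 1 empties. Equal-length
#' stretches tie-break to the most N-terminal.
#'
#' @param seeds integer vector of substrate author numbers.
#' @param ss terminal-propagated secondary-structure string of the substrate
#'   (with \code{resno} attribute), from \code{\link{propagate_terminal_E}}.
#' @param params a \code{\link{capture_params}}.
#' @return \code{c(start, end)} interval or \code{NULL}.
#' @export
refine_expand_trim <- function(seeds, ss, params = capture_params()) {
  resno <- attr(ss, "resno")
  codes <- strsplit(unclass(ss)[1], "")[[1]]
  e_set <- resno[codes == "E"]
  step1 <- intersect(seeds, e_set)
  if (!length(step1)) return(NULL)
  expanded <- unique(unlist(lapply(step1, function(r)
    seq(r - params$pad, r + params$pad))))
  expanded <- intersect(intersect(expanded, resno), e_set)
  runs <- .consecutive_runs(expanded)
  lens <- vapply(runs, length, integer(1))
  best <- runs[[which.max(lens)]]  # which.max takes the first => N-terminal
  c(min(best), max(best))
}

#' Detect the captured substrate strand in one complex model
#'
#' Runs the full per-model procedure: joint receptor+substrate
#' secondary-structure assignment with terminal propagation, the Calpha
#' distance-matrix double-anchor seed scan, and the refine/expand/trim
#' post-processing.
#'
#' @param model a \code{complex_model}.
#' @param params a \code{\link{capture_params}}.
#' @return a \code{\link{captured_strand}} or \code{NULL} when no stage
#'   yields a call.
#' @export
detect_captured_strand <- function(model, params = capture_params()) {
  stopifnot(inherits(model, "complex_model"))
  if (length(model$substrate) == 0) stop("substrate chain is empty")
  ss <- assign_ss(model$substrate, partners = list(model$receptor))
  ss <- propagate_terminal_E(ss)
  D <- calpha_distance_matrix(model$substrate, model$receptor)
  seeds <- find_seed_residues(D, params)
  if (!length(seeds)) return(NULL)
  interval <- refine_expand_trim(seeds, ss, params)
  if (is.null(interval)) return(NULL)
  idx <- which(model$substrate$resno >= interval[1] &
               model$substrate$resno <= interval[2])
  captured_strand(interval,
                  paste(model$substrate$aa[idx], collapse = ""),
                  model_rank = model$rank)
}

#' Aggregate capture calls over a ranked model set
#'
#' A substrate is called captured when at least one model yields a strand;
#' the representative interval is taken from the best-ranked (lowest rank
#' number) qualifying model. All per-model results are retained for
#' downstream cohort statistics.
#'
#' @param models list of \code{complex_model} for one substrate.
#' @param params a \code{\link{capture_params}}.
#' @return list with elements \code{captured} (logical),
#'   \code{representative} (\code{captured_strand} or \code{NULL}),
#'   \code{per_model} (list parallel to \code{models}, \code{NULL} entries
#'   for non-qualifying models), and \code{n_models}.
#' @export
aggregate_models <- function(models, params = capture_params()) {
  stopifnot(length(models) >= 1)
  per_model <- lapply(models, detect_captured_strand, params = params)
  hits <- which(!vapply(per_model, is.null, logical(1)))
  representative <- NULL
  if (length(hits)) {
    ranks <- vapply(models[hits], `[[`, integer(1), "rank")
    representative <- per_model[[hits[which.min(ranks)]]]
  }
  list(captured = length(hits) > 0, representative = representative,
       per_model = per_model, n_models = length(models))
}

#' Tabulate aggregated capture calls for a substrate cohort
#'
#' @param calls named list of \code{\link{aggregate_models}} results, one
#'   per substrate.
#' @return data.frame with columns substrate_id, captured, model_rank,
#'   interval_start, interval_end, strand_sequence.
#' @export
capture_summary <- function(calls) {
  rows <- lapply(names(calls), function(id) {
    x <- calls[[id]]
    if (x$captured) {
      data.frame(substrate_id = id, captured = TRUE,
                 model_rank = x$representative$model_rank,
                 interval_start = x$representative$interval[1],
                 interval_end = x$representative$interval[2],
                 strand_sequence = x$representative$residues)
    } else {
      data.frame(substrate_id = id, captured = FALSE,
                 model_rank = NA_integer_, interval_start = NA_integer_,
                 interval_end = NA_integer_, strand_sequence = NA_character_)
    }
  })
  do.call(rbind, rows)
}
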