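test_that("distance matrices are Euclidean and match a brute-force oracle", {
  s <- dummy_chain(1, "B")
  r <- dummy_chain(1, "A")
  s$xyz$CA[1, ] <- c(0, 0, 0)
  r$xyz$CA[1, ] <- c(3, 4, 0)
  expect_equal(calpha_distance_matrix(s, r)[1, 1], 5)
  r$xyz$CA[1, ] <- c(0, 0, 0)
  expect_equal(calpha_distance_matrix(s, r)[1, 1], 0)

  set.seed(7)
  s <- dummy_chain(20, "B")
  r <- dummy_chain(30, "A")
  s$xyz$CA <- matrix(stats::runif(60, -30, 30), 20, 3)
  r$xyz$CA <- matrix(stats::runif(90, -30, 30), 30, 3)
  D <- calpha_distance_matrix(s, r)
  oracle <- matrix(0, 20, 30)
  for (i in 1:20) for (j in 1:30)
    oracle[i, j] <- sqrt(sum((s$xyz$CA[i, ] - r$xyz$CA[j, ])^2))
  expect_lt(max(abs(D - oracle)), 1e-9)
})

test_that("seed detection enforces the double-anchor AND rule and run length", {
  x <- build_capture_complex(strand_length = 8, seed = 1)
  D <- calpha_distance_matrix(x$model$substrate, x$model$receptor)
  seeds <- find_seed_residues(D)
  planted <- seq(x$truth$interval[1], x$truth$interval[2])
  expect_true(all(seeds %in% planted))
  expect_gte(length(seeds), 4)
  # brute-force re-scan oracle
  p <- capture_params()
  rcols <- as.integer(colnames(D))
  oracle <- c()
  for (i in seq_len(nrow(D))) {
    da <- min(D[i, rcols >= 148 & rcols <= 157])
    db <- min(D[i, rcols >= 279 & rcols <= 286])
    if (da < p$cutoff && db < p$cutoff)
      oracle <- c(oracle, as.integer(rownames(D))[i])
  }
  runs <- betacatch:::.consecutive_runs(oracle)
  oracle <- sort(unlist(runs[vapply(runs, length, integer(1)) >= 2],
                 use.names = FALSE))
  expect_equal(seeds, oracle)

  # displaced substrate yields nothing; cutoff 0 yields nothing
  far <- x$model$substrate
  far$xyz$CA <- far$xyz$CA + 20
  expect_length(find_seed_residues(calpha_distance_matrix(far, x$model$receptor)),
                0)
  expect_length(find_seed_residues(D, capture_params(cutoff = 0)), 0)
  # absent anchor range is an error
  expect_error(find_seed_residues(D, capture_params(anchor_b = c(900L, 910L))),
               "anchor B")
})

test_that("refine/expand/trim applies its three steps and the N-terminal tie-break", {
  p <- capture_params()
  # expansion annexes flanking E
  ss <- ss_string(paste0(strrep("-", 7), strrep("E", 10), strrep("-", 8)),
                  resno = 1:25)
  expect_equal(refine_expand_trim(10:15, ss, p), c(8L, 17L))
  # no E-coded seed: no call
  expect_null(refine_expand_trim(1:5, ss, p))
  # equal-length stretches tie-break to the more N-terminal
  ss2 <- ss_string("--EEE--EEE--", resno = 1:12)
  expect_equal(refine_expand_trim(c(4, 9), ss2, p), c(3L, 5L))
  # enumeration oracle over random seed/ss configurations
  set.seed(42)
  for (rep in 1:25) {
    codes <- sample(c("E", "-"), 30, replace = TRUE, prob = c(0.4, 0.6))
    ssr <- ss_string(paste(codes, collapse = ""), resno = 1:30)
    seeds <- sort(sample(1:30, 5))
    got <- refine_expand_trim(seeds, ssr, p)
    e_set <- which(codes == "E")
    s1 <- intersect(seeds, e_set)
    if (!length(s1)) {
      expect_null(got)
    } else {
      exp_set <- intersect(unique(unlist(lapply(s1, function(r)
        (r - 7):(r + 7)))), e_set)
      exp_set <- exp_set[exp_set >= 1 & exp_set <= 30]
      runs <- betacatch:::.consecutive_runs(exp_set)
      lens <- vapply(runs, length, integer(1))
      best <- runs[[which.max(lens)]]
      expect_equal(got, c(min(best), max(best)))
    }
  }
})

test_that("capture detection recovers planted strands and rejects decoys", {
  x <- build_capture_complex(strand_length = 6, seed = 13)
  cs <- detect_captured_strand(x$model)
  expect_false(is.null(cs))
  expect_equal(cs$interval, x$truth$interval)
  expect_equal(cs$residues, x$truth$strand_sequence)
  expect_null(detect_captured_strand(build_decoy_complex(seed = 13)$model))
  expect_null(detect_captured_strand(
    build_decoy_complex(seed = 13, contact = "a")$model))
})

test_that("capture calls are invariant to rigid-body motion of the complex", {
  x <- build_capture_complex(strand_length = 8, seed = 21)
  cs0 <- detect_captured_strand(x$model)
  m <- x$model
  m$receptor <- rigid_transform_chain(m$receptor, seed = 5)
  m$substrate <- rigid_transform_chain(m$substrate, seed = 5)
  cs1 <- detect_captured_strand(m)
  expect_equal(cs1$interval, cs0$interval)
})

test_that("cutoff and pad act monotonically", {
  x <- build_capture_complex(strand_length = 8, seed = 17)
  D <- calpha_distance_matrix(x$model$substrate, x$model$receptor)
  s55 <- find_seed_residues(D, capture_params(cutoff = 5.5))
  s60 <- find_seed_residues(D, capture_params(cutoff = 6.0))
  s70 <- find_seed_residues(D, capture_params(cutoff = 7.0))
  expect_true(all(s55 %in% s60))
  expect_true(all(s60 %in% s70))
  cs0 <- detect_captured_strand(x$model, capture_params(pad = 0L))
  cs7 <- detect_captured_strand(x$model, capture_params(pad = 7L))
  if (!is.null(cs0)) {
    expect_gte(cs0$interval[1], cs7$interval[1])
    expect_lte(cs0$interval[2], cs7$interval[2])
  }
})

test_that("model aggregation picks the best-ranked qualifying model", {
  pos <- build_capture_complex(strand_length = 6, seed = 23)$model
  neg <- build_decoy_complex(seed = 23)$model
  neg$rank <- 0L
  m1 <- pos; m1$rank <- 3L
  m2 <- pos; m2$rank <- 1L
  agg <- aggregate_models(list(neg, m1, m2))
  expect_true(agg$captured)
  expect_equal(agg$representative$model_rank, 1L)
  expect_equal(sum(!vapply(agg$per_model, is.null, logical(1))), 2L)

  none <- aggregate_models(list(neg))
  expect_false(none$captured)
  expect_null(none$representative)

  one <- aggregate_models(list(m1))
  expect_true(one$captured)
  expect_equal(one$representative$model_rank, 3L)

  tab <- capture_summary(list(subA = agg, subB = none))
  expect_equal(tab$captured, c(TRUE, FALSE))
  expect_equal(tab$interval_start[1], agg$representative$interval[1])
  expect_true(is.na(tab$strand_sequence[2]))
})
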