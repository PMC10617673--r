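test_that("PSI follows the bin-weighted-sum formula and its bounds", {
  expect_equal(compute_psi(c(0, 0, 0, 0, 0, 1)), 6)
  expect_equal(compute_psi(c(1, 0, 0, 0, 0, 0)), 1)
  expect_equal(compute_psi(rep(1 / 6, 6)), 3.5)
  expect_equal(compute_psi(c(0.5, 0, 0, 0, 0, 0.5)), 3.5)
  expect_error(compute_psi(c(0.5, 0, 0, 0, 0, 0.6)), "sum to 1")
  expect_error(compute_psi(c(-0.1, 0.1, 0, 0, 0, 1)), "nonnegative")
  # linearity in R
  r1 <- c(0.2, 0.1, 0.3, 0.1, 0.2, 0.1)
  r2 <- c(0.1, 0.3, 0.1, 0.2, 0.1, 0.2)
  expect_equal(compute_psi(0.5 * r1 + 0.5 * r2),
               0.5 * compute_psi(r1) + 0.5 * compute_psi(r2))
})

test_that("delta PSI is a plain difference with its natural bounds", {
  expect_equal(delta_psi(2.0, 4.5), -2.5)
  expect_equal(delta_psi(3.3, 3.3), 0)
  expect_equal(delta_psi(1, 6), -5)
})

test_that("depth normalization equalizes bin depth and preserves composition", {
  set.seed(5)
  m <- matrix(rpois(600, lambda = rep(c(50, 200, 80, 120, 100, 150),
                                      each = 100)), 100, 6)
  out <- depth_normalize(m, method = "total")
  expect_lt(diff(range(colSums(out))), 1e-9)
  # within-bin composition preserved
  for (b in 1:6)
    expect_equal(out[, b] / sum(out[, b]), m[, b] / sum(m[, b]),
                 tolerance = 1e-12)
  # already equal-depth matrix unchanged up to scale
  eq <- matrix(10, 5, 6)
  expect_equal(depth_normalize(eq, method = "total"), eq)
  # median-ratio output is invariant (up to one global scale) to any
  # column-wise depth distortion
  set.seed(6)
  abundance <- rgamma(200, 5, 1 / 20)
  profile <- matrix(rep(c(0.1, 0.2, 0.25, 0.2, 0.15, 0.1), each = 200),
                    200, 6)
  true <- abundance * profile * exp(matrix(rnorm(1200, 0, 0.1), 200, 6))
  s <- c(0.5, 2, 1, 1.5, 0.8, 1.2)
  rec1 <- depth_normalize(true)
  rec2 <- depth_normalize(sweep(true, 2, s, "*"))
  scale_ratio <- rec2 / rec1
  expect_lt(diff(range(scale_ratio)) / mean(scale_ratio), 1e-9)
  zero <- matrix(1, 4, 6); zero[, 3] <- 0
  expect_error(depth_normalize(zero), "bin 3")
})

test_that("screen PSI pipeline collapses barcodes and flags empty genes", {
  counts <- data.frame(
    gene = rep("g1", 12),
    barcode = rep(c("g1_a", "g1_b"), each = 6),
    condition = "control",
    bin = rep(1:6, 2),
    reads = c(0, 0, 0, 0, 0, 30, 0, 0, 0, 0, 0, 10))
  counts <- rbind(counts, within(counts, {
    condition <- "treatment"
    reads <- c(40, 0, 0, 0, 0, 0, 20, 0, 0, 0, 0, 0)
  }))
  # a second gene spreads reads so every bin has depth
  filler <- data.frame(gene = "g0", barcode = "g0_a",
                       condition = rep(c("control", "treatment"), each = 6),
                       bin = rep(1:6, 2), reads = 100)
  tab <- screen_psi(rbind(counts, filler), method = "total")
  g1 <- tab[tab$gene == "g1", ]
  expect_equal(g1$psi_control, 6)
  expect_equal(g1$psi_treatment, 1)
  expect_equal(g1$delta_psi, -5)
})

test_that("the destabilization filter is strict and ordered", {
  tab <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    psi_control = 4, psi_treatment = 4,
                    delta_psi = c(-0.4, -0.5, -0.51, -2.0, NA))
  hits <- filter_destabilized(tab)
  expect_equal(hits$gene, c("d", "c"))  # strict; ordered ascending
  expect_equal(nrow(filter_destabilized(tab[0, ])), 0)
})

test_that("planted strong destabilizers are recovered exactly at default depth", {
  eff <- c(rep(-2, 10), rep(0, 990))
  sim <- simulate_screen(n_genes = 1000, depth = 500, effects = eff,
                         seed = 19)
  tab <- screen_psi(sim$counts)
  hits <- filter_destabilized(tab)
  planted <- sim$truth$gene[sim$truth$delta_true < 0]
  expect_setequal(hits$gene, planted)
})

test_that("PSI estimates respect bounds even at depth 1", {
  sim <- simulate_screen(n_genes = 40, depth = 1, effects = 0, seed = 2)
  tab <- suppressMessages(screen_psi(sim$counts))
  est <- c(tab$psi_control, tab$psi_treatment)
  est <- est[!is.na(est)]
  expect_true(all(est >= 1 & est <= 6))
})

test_that("screen tables read from disk are validated", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(gene = "g1", barcode = "b1", condition = "control",
                   bin = 1:6, reads = 10)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_screen_counts(path)
  expect_equal(nrow(back), 6)
  bad <- df; names(bad)[5] <- "n"
  utils::write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_screen_counts(path), "reads")
})

test_that("delta-PSI error shrinks with sequencing depth", {
  rmse_at <- function(depth) {
    eff <- c(rep(-1, 20), rep(0, 380))
    sim <- simulate_screen(n_genes = 400, depth = depth, effects = eff,
                           seed = 9)
    m <- merge(screen_psi(sim$counts), sim$truth)
    sqrt(mean((m$delta_psi - m$delta_true)^2))
  }
  expect_lt(rmse_at(1000), rmse_at(100))
})
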