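test_that("parity reconciliation counts overlaps and adopts the winning set", {
  expect_equal(reconcile_parity(c(1, 3, 5), 6),
               list(inward = c(1L, 3L, 5L), outward = c(2L, 4L, 6L),
                    parity = "odd"))
  # odd overlap 2 vs even overlap 1
  expect_equal(reconcile_parity(c(1, 2, 5), 6)$inward, c(1L, 3L, 5L))
  # even set adopted wholesale
  expect_equal(reconcile_parity(c(2, 4), 6)$inward, c(2L, 4L, 6L))
  expect_error(reconcile_parity(c(1, 2), 6), "tie")
  expect_error(reconcile_parity(integer(0), 4), "tie")
})

test_that("reconciled facing is always exactly the odd or the even set", {
  for (L in 2:8) {
    for (mask in 0:(2^L - 1)) {
      raw <- which(bitwAnd(mask, 2^(0:(L - 1))) > 0)
      odd <- seq(1L, L, 2L); even <- seq(2L, L, 2L)
      tie <- length(intersect(raw, odd)) == length(intersect(raw, even))
      if (tie) {
        expect_error(reconcile_parity(raw, L), "tie")
      } else {
        rec <- reconcile_parity(raw, L)
        expect_true(identical(rec$inward, odd) || identical(rec$inward, even))
        win <- if (length(intersect(raw, odd)) > length(intersect(raw, even)))
          odd else even
        expect_equal(rec$inward, win)
      }
    }
  }
})

test_that("facing calls use the strict Cbeta-closer rule against the reference", {
  # strand of 4 residues: CB of 1,3 moved toward the reference point, CB of
  # 2,4 placed exactly equidistant (strict < means they stay outward)
  ref <- c(0, 0, 50)
  sub <- dummy_chain(4, "B", aa = rep("V", 4))
  for (i in 1:4) {
    ca <- sub$xyz$CA[i, ]
    if (i %% 2 == 1) {
      sub$xyz$CB[i, ] <- ca + c(0, 0, 1)  # toward reference
    } else {
      sub$xyz$CB[i, ] <- ca               # exactly equidistant
    }
  }
  rec <- dummy_chain(1, "A", resno = 309L, aa = "I")
  rec$xyz$CA[1, ] <- ref
  model <- complex_model(rec, sub)
  strand <- captured_strand(c(1, 4), "VVVV")
  fa <- assign_facing(strand, model, ref_residue = 309L)
  expect_equal(fa$raw_inward, c(1L, 3L))
  expect_equal(fa$parity, "odd")
  expect_equal(fa$inward_resno, c(1L, 3L))
  expect_error(assign_facing(strand, model, ref_residue = 999L), "absent")
})

test_that("facing on generated complexes matches constructed ground truth", {
  for (s in c(3, 8, 15)) {
    x <- build_capture_complex(strand_length = 8, seed = s)
    cs <- detect_captured_strand(x$model)
    fa <- assign_facing(cs, x$model)
    expect_equal(sort(fa$inward_resno),
                 intersect(x$truth$inward_resno,
                           seq(cs$interval[1], cs$interval[2])))
  }
})

test_that("a glycine-only strand cannot resolve parity", {
  sub <- dummy_chain(4, "B", aa = rep("G", 4))
  sub$xyz$CB[] <- NA_real_
  rec <- dummy_chain(1, "A", resno = 309L, aa = "I")
  model <- complex_model(rec, sub)
  strand <- captured_strand(c(1, 4), "GGGG")
  expect_error(assign_facing(strand, model), "parity")
})

test_that("enrichment ratios are 1 under a null cohort and count exact frequencies", {
  null_cohort <- data.frame(sequence = c("AC", "CA"),
                            start = 1L, end = 2L)
  tab <- positional_enrichment(null_cohort)
  n1 <- tab[tab$side == "N" & tab$n == 1, ]
  expect_equal(n1$ratio[n1$aa %in% c("A", "C")], c(1, 1))

  vv <- data.frame(sequence = "GVVVVG", start = 2L, end = 5L)
  bg <- stats::setNames(rep(0.05, 20), aa20)
  tab <- positional_enrichment(vv, background = bg)
  for (side in c("N", "C")) for (n in 1:2) {
    cell <- tab[tab$side == side & tab$n == n, ]
    expect_equal(cell$ratio[cell$aa == "V"], 20)
    expect_equal(sum(cell$ratio[cell$aa != "V"]), 0)
  }
  expect_equal(tab$aa[tab$side == "flank_preceding" & tab$count > 0], "G")
  expect_equal(tab$aa[tab$side == "flank_following" & tab$count > 0], "G")
})

test_that("strands shorter than 2n are excluded from depth n", {
  cohort <- data.frame(sequence = c("AVLFA", "AVLIVLIVA"),
                       start = 2L, end = c(4L, 8L))  # lengths 3 and 7
  bg <- stats::setNames(rep(0.05, 20), aa20)
  tab <- positional_enrichment(cohort, background = bg)
  expect_equal(unique(tab$n_strands[tab$side == "N" & tab$n == 1]), 2L)
  expect_equal(unique(tab$n_strands[tab$side == "N" & tab$n == 2]), 1L)
  expect_equal(unique(tab$n_strands[tab$side == "N" & tab$n == 3]), 1L)
  expect_false(any(tab$n == 4, na.rm = TRUE))  # 2n = 8 > 7
})

test_that("strands at protein termini are excluded from flank frequencies", {
  cohort <- data.frame(sequence = c("VVVAA", "AAVVV", "AVVVA"),
                       start = c(1L, 3L, 2L), end = c(3L, 5L, 4L))
  tab <- positional_enrichment(cohort)
  expect_equal(unique(tab$n_strands[tab$side == "flank_preceding"]), 2L)
  expect_equal(unique(tab$n_strands[tab$side == "flank_following"]), 2L)
})

test_that("the enrichment conservation identity holds in every (side, n) cell", {
  set.seed(31)
  cohort <- data.frame(
    sequence = vapply(1:20, function(i) random_aa(50), ""),
    start = sample(5:20, 20, TRUE))
  cohort$end <- cohort$start + sample(3:11, 20, TRUE)
  tab <- positional_enrichment(cohort)
  bg <- background_frequencies(cohort$sequence)
  for (grp in split(tab, paste(tab$side, tab$n))) {
    expect_equal(sum(grp$ratio * bg[grp$aa], na.rm = TRUE), 1,
                 tolerance = 1e-9)
  }
})
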