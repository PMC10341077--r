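toy_ploh <- 100 * 15e6 / 158e6  # worked example: 15 Mb LOH over 158 Mb observed

test_that("expected state is the modal allele-specific state with tie rules", {
  b <- toy_build()
  # 85 Mb at (2,1) vs 15 Mb at (2,0) -> (2,1)
  es <- expected_state(toy_profile(b), b)
  expect_equal(es$total_cn[es$chrom == "chrA"], 2)
  expect_equal(es$minor_cn[es$chrom == "chrA"], 1)

  # uniform (3,1) chromosome defines its own expectation, deviation 0
  seg <- data.frame(chrom = "chrA", start = 0, end = 1e8,
                    total_cn = 3, minor_cn = 1)
  p <- cn_profile("U", seg, b)
  es2 <- expected_state(p, b)
  expect_equal(c(es2$total_cn, es2$minor_cn), c(3, 1))
  expect_equal(compute_pcna(p, b)$value, 0)

  # exact coverage tie (49.5 Mb observed each on arms) -> smaller total wins
  seg3 <- data.frame(chrom = "chrA", start = c(0, 50.5e6),
                     end = c(50.5e6, 1e8),
                     total_cn = c(3, 2), minor_cn = c(1, 1))
  p3 <- cn_profile("T", seg3, b)
  covA <- sum(arm_of(b, "chrA", 0, 50.5e6)[c("p", "q")])
  covB <- sum(arm_of(b, "chrA", 50.5e6, 1e8)[c("p", "q")])
  expect_equal(covA, covB)  # genuinely tied on observed arm coverage
  es3 <- expected_state(p3, b)
  expect_equal(c(es3$total_cn, es3$minor_cn), c(2, 1))
})

test_that("PLOH matches the worked example and honors the size filter", {
  b <- toy_build()
  expect_equal(compute_ploh(toy_profile(b), b)$value, toy_ploh)

  # a 9 Mb LOH run is not larger than 10 Mb: contributes nothing
  seg <- data.frame(chrom = c("chrA", "chrA", "chrB"),
                    start = c(0, 9e6, 0), end = c(9e6, 1e8, 6e7),
                    total_cn = 2, minor_cn = c(0, 1, 1))
  expect_equal(compute_ploh(cn_profile("S", seg, b), b)$value, 0)

  # exactly 10 Mb is still excluded (strict inequality)
  seg10 <- seg; seg10$end[1] <- 1e7; seg10$start[2] <- 1e7
  res10 <- compute_ploh(cn_profile("S", seg10, b), b)
  expect_equal(res10$value, 0)
  expect_equal(res10$regions$reason[1], "below_min_region")
  # one base over passes
  seg11 <- seg; seg11$end[1] <- 1e7 + 1; seg11$start[2] <- 1e7 + 1
  expect_gt(compute_ploh(cn_profile("S", seg11, b), b)$value, 0)
})

test_that("LOH affecting a whole chromosome arm is not counted", {
  b <- toy_build()
  seg <- data.frame(chrom = c("chrA", "chrA", "chrB"),
                    start = c(0, 40e6, 0), end = c(40e6, 1e8, 6e7),
                    total_cn = 2, minor_cn = c(0, 1, 1))
  res <- compute_ploh(cn_profile("S", seg, b), b)
  expect_equal(res$value, 0)
  expect_equal(res$regions$reason[1], "whole_arm")

  # 50% of the arm does count
  seg2 <- seg; seg2$end[1] <- 20e6; seg2$start[2] <- 20e6
  expect_equal(compute_ploh(cn_profile("S", seg2, b), b)$value,
               100 * 20e6 / 158e6)
})

test_that("LOH runs fuse across differing total copy numbers", {
  b <- toy_build()
  # 6 Mb (2,0) + 6 Mb (1,0): neither passes 10 Mb alone, the fused run does
  seg <- data.frame(chrom = c("chrA", "chrA", "chrA", "chrB"),
                    start = c(0, 6e6, 12e6, 0), end = c(6e6, 12e6, 1e8, 6e7),
                    total_cn = c(2, 1, 2, 2), minor_cn = c(0, 0, 1, 1))
  res <- compute_ploh(cn_profile("S", seg, b), b)
  expect_equal(nrow(res$regions), 1)
  expect_equal(res$regions$span_bp, 12e6)
  expect_equal(res$value, 100 * 12e6 / 158e6)
})

test_that("homozygous deletions count as LOH and are flagged", {
  b <- toy_build()
  seg <- data.frame(chrom = c("chrA", "chrA", "chrB"),
                    start = c(0, 12e6, 0), end = c(12e6, 1e8, 6e7),
                    total_cn = c(0, 2, 2), minor_cn = c(0, 1, 1))
  res <- compute_ploh(cn_profile("S", seg, b), b)
  expect_equal(res$value, 100 * 12e6 / 158e6)
  expect_true(res$regions$homozygous_deletion[1])
})

test_that("PCNA measures allele-specific deviation from the expected state", {
  b <- toy_build()
  # the worked example: the 15 Mb copy-neutral LOH deviates from (2,1)
  expect_equal(compute_pcna(toy_profile(b), b)$value, toy_ploh)

  # deviant run covering >= 90% of an arm's observed territory is excluded
  seg <- data.frame(chrom = c("chrA", "chrA", "chrB"),
                    start = c(0, 37e6, 0), end = c(37e6, 1e8, 6e7),
                    total_cn = c(3, 2, 2), minor_cn = 1)
  res <- compute_pcna(cn_profile("S", seg, b), b)
  expect_equal(res$value, 0)
  expect_equal(res$regions$reason[1], "whole_arm")

  # mixed deviant states fuse into one region by default
  seg2 <- data.frame(chrom = c("chrA", "chrA", "chrA", "chrB"),
                     start = c(0, 6e6, 12e6, 0),
                     end = c(6e6, 12e6, 1e8, 6e7),
                     total_cn = c(3, 4, 2, 2), minor_cn = c(1, 1, 1, 1))
  p2 <- cn_profile("S", seg2, b)
  expect_equal(compute_pcna(p2, b)$value, 100 * 12e6 / 158e6)
  # state-uniform runs: each 6 Mb piece fails the 10 Mb filter
  strict <- gis_params(fuse_mixed_states = FALSE)
  expect_equal(compute_pcna(p2, b, strict)$value, 0)
})

test_that("PTCNA counts altered telomeres among evaluable ones", {
  b <- toy_build()
  res <- compute_ptcna(toy_profile(b), b)
  expect_equal(res$n_evaluable, 4)
  expect_equal(res$value, 25)
  tel <- res$telomeres
  expect_true(tel$altered[tel$chrom == "chrA" & tel$arm == "p"])

  # fully diploid genome: nothing altered
  expect_equal(compute_ptcna(toy_null_profile(b), b)$value, 0)

  # a 0.8 Mb deviant terminal segment is too small to be considered
  seg <- data.frame(chrom = c("chrA", "chrA", "chrB"),
                    start = c(0, 0.8e6, 0), end = c(0.8e6, 1e8, 6e7),
                    total_cn = 2, minor_cn = c(0, 1, 1))
  res2 <- compute_ptcna(cn_profile("S", seg, b), b)
  expect_equal(res2$value, 0)
  expect_equal(res2$telomeres$reason[1], "below_min_telomeric_segment")

  # unassembled telomeres leave the denominator
  arms <- b$arms
  arms$telomere_assembled[arms$chrom == "chrA" & arms$arm == "p"] <- FALSE
  b2 <- genome_build("toy2", b$chromosomes, arms)
  res3 <- compute_ptcna(toy_profile(b2), b2)
  expect_equal(res3$n_evaluable, 3)
  expect_equal(res3$value, 0)  # the altered telomere was the unassembled one
})

test_that("telomere window boundary is strict", {
  b <- toy_build()
  # chromosome observed only from 5 Mb (0-based) onward: start not < 5 Mb
  seg <- data.frame(chrom = c("chrA", "chrB"), start = c(5e6, 0),
                    end = c(1e8, 6e7), total_cn = 2, minor_cn = 1)
  res <- compute_ptcna(cn_profile("S", seg, b), b)
  tel <- res$telomeres
  expect_false(tel$evaluable[tel$chrom == "chrA" & tel$arm == "p"])
  expect_equal(tel$reason[tel$chrom == "chrA" & tel$arm == "p"],
               "no_terminal_segment")
  # one base inside the window is enough
  seg2 <- seg; seg2$start[1] <- 5e6 - 1
  res2 <- compute_ptcna(cn_profile("S", seg2, b), b)
  expect_true(res2$telomeres$evaluable[1])
})

test_that("GIS sums the components and classifies against the cutoff", {
  b <- toy_build()
  res <- compute_gis(toy_profile(b), b)
  expect_equal(res$gis, res$ploh_pct + res$pcna_pct + res$ptcna_pct)
  expect_equal(res$gis, 2 * toy_ploh + 25)
  expect_true(res$evaluable)
  expect_false(res$gi_positive)

  null_res <- compute_gis(toy_null_profile(b), b)
  expect_equal(null_res$gis, 0)

  # gi_positive flips exactly at gis == cutoff (>= convention)
  g <- res$gis
  expect_true(compute_gis(toy_profile(b), b,
                          gis_params(cutoff = g))$gi_positive)
  expect_false(compute_gis(toy_profile(b), b,
                           gis_params(cutoff = g + 1e-9))$gi_positive)
})

test_that("profiles straddling the default cutoff classify correctly", {
  b <- hg19_build()
  # LOH/deviation territory tuned to bracket GIS 83 on hg19: x Mb of
  # qualifying copy-neutral LOH on otherwise diploid genome contributes
  # 2 * 100 * x / observed to PLOH+PCNA plus telomeric alterations
  make <- function(n_tel) {
    segs <- list()
    for (ch in b$included) {
      len <- b$chromosomes$length[b$chromosomes$chrom == ch]
      segs[[ch]] <- data.frame(chrom = ch, start = 0, end = len,
                               total_cn = 2, minor_cn = 1)
    }
    qarms <- b$arms[b$arms$arm == "q" & b$arms$chrom %in% b$included, ]
    qarms <- qarms[order(-(qarms$end - qarms$start)), ][seq_len(n_tel), ]
    for (i in seq_len(n_tel)) {
      ch <- qarms$chrom[i]
      len <- b$chromosomes$length[b$chromosomes$chrom == ch]
      s <- segs[[ch]]
      segs[[ch]] <- data.frame(
        chrom = ch, start = c(0, len - 30e6), end = c(len - 30e6, len),
        total_cn = 2, minor_cn = c(1, 0))
    }
    cn_profile(paste0("straddle", n_tel), do.call(rbind, segs), b)
  }
  res_lo <- compute_gis(make(14), b)
  res_hi <- compute_gis(make(20), b)
  expect_lt(res_lo$gis, 83); expect_false(res_lo$gi_positive)
  expect_gte(res_hi$gis, 83); expect_true(res_hi$gi_positive)
})

test_that("whole-genome duplication leaves the score unchanged", {
  b <- toy_build()
  p <- toy_profile(b)
  wgd <- p
  wgd$segments$total_cn <- 2 * wgd$segments$total_cn
  wgd$segments$minor_cn <- 2 * wgd$segments$minor_cn
  wgd <- cn_profile("wgd", wgd$segments, b)
  expect_equal(compute_gis(wgd, b)$gis, compute_gis(p, b)$gis)
})

test_that("evaluability requires observed fraction and defined PTCNA", {
  b <- toy_build()
  # 45% of territory observed but clear telomeres: evaluable
  seg <- data.frame(chrom = "chrA", start = 0, end = 72e6,
                    total_cn = 2, minor_cn = 1)
  res <- compute_gis(cn_profile("S", seg, b), b)
  expect_true(res$evaluable)
  # below the 40% floor: unevaluable
  seg2 <- data.frame(chrom = "chrA", start = 0, end = 50e6,
                     total_cn = 2, minor_cn = 1)
  res2 <- compute_gis(cn_profile("S", seg2, b), b)
  expect_false(res2$evaluable)
  expect_true(is.na(res2$gi_positive))
  # no telomere reachable: PTCNA undefined even with enough territory
  seg3 <- data.frame(chrom = c("chrA", "chrB"), start = c(6e6, 6e6),
                     end = c(94e6, 54e6), total_cn = 2, minor_cn = 1)
  res3 <- compute_gis(cn_profile("S", seg3, b), b)
  expect_true(is.na(res3$ptcna_pct))
  expect_false(res3$evaluable)
})

test_that("HRD calls combine GI status and BRCA status", {
  b <- toy_build()
  res <- compute_gis(toy_profile(b), b)          # GI-negative
  expect_equal(call_hrd(res, "pathogenic")$hrd_status, "positive")
  expect_equal(call_hrd(res, "wildtype")$hrd_status, "negative")
  expect_equal(call_hrd(res, "unknown")$hrd_status, "negative")

  res$gi_positive <- TRUE
  expect_equal(call_hrd(res, "wildtype")$hrd_status, "positive")

  res$gi_positive <- NA
  expect_equal(call_hrd(res, "wildtype")$hrd_status, "unevaluable")
  expect_equal(call_hrd(res, "pathogenic")$hrd_status, "positive")
})

test_that("components stay within bounds on random profiles", {
  for (seed in 1:12) {
    b <- random_toy_build(seed)
    p <- random_toy_profile(b, seed)
    res <- compute_gis(p, b, scaled_params())
    obs <- res$observed_genome_bp
    expect_lte(sum(res$ploh_regions$observed_bp[res$ploh_regions$qualifies]),
               obs)
    expect_lte(sum(res$pcna_regions$observed_bp[res$pcna_regions$qualifies]),
               obs)
    for (v in c(res$ploh_pct, res$pcna_pct, res$ptcna_pct)) {
      if (!is.na(v)) { expect_gte(v, 0); expect_lte(v, 100) }
    }
    if (!is.na(res$gis)) expect_lte(res$gis, 300)
  }
})
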