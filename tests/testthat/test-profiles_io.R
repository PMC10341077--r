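write_seg_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("sample\tchromosome\tstart\tend\ttotal_cn\tminor_cn", lines),
             path)
  path
}

test_that("segmentation reading builds profiles and the observed genome", {
  b <- toy_build()
  path <- write_seg_file(c(
    "S1\tchrA\t1\t15000000\t2\t0",
    "S1\tchrA\t15000001\t100000000\t2\t1"))
  profiles <- read_segmentation(path, b)
  expect_length(profiles, 1)
  p <- profiles$S1
  expect_equal(nrow(p$segments), 2)
  expect_equal(p$segments$start, c(0, 15e6))    # 1-based -> 0-based
  expect_equal(p$segments$end, c(15e6, 1e8))
  # 100 Mb covered, 1 Mb centromere excluded
  expect_equal(observed_genome_bp(p, b), 99e6)
})

test_that("segmentation reading rejects invalid rows by name", {
  b <- toy_build()
  expect_error(read_segmentation(
    write_seg_file("S1\tchrA\t1\t10000000\t2\t2"), b), "minor_cn")
  expect_error(read_segmentation(
    write_seg_file("S1\tchrA\t1\t200000000\t2\t1"), b), "bounds")
  expect_error(read_segmentation(
    write_seg_file(c("S1\tchrA\t1\t10000000\t2\t1",
                     "S1\tchrA\t5000000\t20000000\t2\t1")), b), "overlapping")
  expect_error(read_segmentation(
    write_seg_file("S1\tchrQ\t1\t1000\t2\t1"), b), "chrQ")
})

test_that("empty segmentation yields an empty profile list, not an error", {
  b <- toy_build()
  path <- write_seg_file(character())
  profiles <- read_segmentation(path, b)
  expect_length(profiles, 0)
  expect_equal(attr(profiles, "load_report")$n_rows, 0L)
})

test_that("purity and ploidy metadata are carried but not required", {
  b <- toy_build()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchromosome\tstart\tend\ttotal_cn\tminor_cn",
               "#purity=0.63", "#ploidy=2.4",
               "S1\tchrA\t1\t100000000\t2\t1",
               "S2\tchrA\t1\t100000000\t2\t1"), path)
  profiles <- read_segmentation(path, b)
  expect_equal(profiles$S1$purity, 0.63)
  expect_equal(profiles$S1$ploidy, 2.4)
  expect_true(is.na(profiles$S2$purity))

  meta <- data.frame(sample = "S2", purity = 0.4, ploidy = 3.1)
  profiles2 <- read_segmentation(path, b, metadata = meta)
  expect_equal(profiles2$S2$purity, 0.4)
})

test_that("rows on excluded chromosomes are dropped and counted", {
  chroms <- data.frame(chrom = c("chrA", "chrB"), length = c(1e8, 6e7))
  arms <- toy_build()$arms
  b <- genome_build("toy", chroms, arms, included = "chrA")
  path <- write_seg_file(c("S1\tchrA\t1\t100000000\t2\t1",
                           "S1\tchrB\t1\t60000000\t2\t1"))
  profiles <- read_segmentation(path, b)
  expect_equal(nrow(profiles$S1$segments), 1)
  expect_equal(attr(profiles, "load_report")$n_dropped_excluded_chrom, 1L)
})

test_that("equal-state runs fuse across small gaps only", {
  b <- toy_build()
  seg <- data.frame(chrom = "chrA", start = c(0, 6.5e6),
                    end = c(6e6, 12e6), total_cn = 2, minor_cn = 0)
  p <- cn_profile("S1", seg, b)

  m <- merge_equal_state_runs(p, max_gap_bp = 1e6)
  expect_equal(nrow(m$segments), 1)
  expect_equal(c(m$segments$start, m$segments$end), c(0, 12e6))
  expect_equal(nrow(m$gaps), 1)
  expect_equal(c(m$gaps$start, m$gaps$end), c(6e6, 6.5e6))
  # gap counted in span, not in observation
  expect_equal(observed_genome_bp(m, b), observed_genome_bp(p, b))
  # idempotent
  expect_identical(merge_equal_state_runs(m, 1e6), m)

  # zero tolerance: nothing fuses
  expect_equal(nrow(merge_equal_state_runs(p, max_gap_bp = 0)$segments), 2)

  # unequal states never fuse
  seg2 <- data.frame(chrom = "chrA", start = c(0, 6e6), end = c(6e6, 12e6),
                     total_cn = c(2, 3), minor_cn = c(0, 0))
  m2 <- merge_equal_state_runs(cn_profile("S2", seg2, b), 1e6)
  expect_equal(nrow(m2$segments), 2)
})

test_that("merging preserves the per-base state of observed territory", {
  for (seed in 1:10) {
    b <- random_toy_build(seed)
    p <- random_toy_profile(b, seed)
    m <- merge_equal_state_runs(p, max_gap_bp = 10e3)
    for (ch in unique(p$segments$chrom)) {
      len <- b$chromosomes$length[b$chromosomes$chrom == ch]
      paint <- function(prof) {
        st <- rep(NA_real_, len); obs <- rep(FALSE, len)
        s <- prof$segments[prof$segments$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(s))) {
          idx <- (s$start[i] + 1):s$end[i]
          st[idx] <- s$total_cn[i] * 1000 + s$minor_cn[i]; obs[idx] <- TRUE
        }
        g <- prof$gaps[prof$gaps$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(g))) obs[(g$start[i] + 1):g$end[i]] <- FALSE
        st[!obs] <- NA
        st
      }
      expect_identical(paint(p), paint(m))
    }
  }
})

test_that("segmentation writing round-trips simulated profiles", {
  b <- toy_build()
  sp <- simulation_params(b, n_loh_events = 2, n_cna_events = 1,
                          size_min = 5e6, size_max = 15e6,
                          dropout_fraction = 0.05)
  sim <- simulate_profile(sp, sample_id = "RT", seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segmentation(sim$profile, path)
  back <- read_segmentation(path, b)$RT
  expect_equal(back$segments, sim$profile$segments)
})

test_that("results writing covers HRD call rules and round-trips", {
  b <- toy_build()
  res <- compute_gis(toy_profile(b), b)
  hc <- call_hrd(res, "wildtype")
  res$brca <- hc$brca; res$hrd_status <- hc$hrd_status

  # unevaluable sample (tiny observed fraction) with pathogenic BRCA
  small <- cn_profile("U1", data.frame(chrom = "chrA", start = 50e6,
                                       end = 51e6, total_cn = 2,
                                       minor_cn = 1), b)
  res_u <- compute_gis(small, b)
  expect_false(res_u$evaluable)
  hc_u <- call_hrd(res_u, "pathogenic")
  expect_equal(hc_u$hrd_status, "positive")
  res_u$brca <- hc_u$brca; res_u$hrd_status <- hc_u$hrd_status

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_results(list(res, res_u), tsv, "tsv")
  tab <- read.delim(tsv, colClasses = "character")
  expect_equal(tab$hrd_status, c("negative", "positive"))
  expect_equal(tab$gis[1], "43.9873")
  expect_equal(tab$gis[2], "")            # unevaluable: empty score fields
  expect_equal(tab$ploh_pct[2], "")

  json <- withr::local_tempfile(fileext = ".json")
  write_results(list(res, res_u), json, "json")
  back <- read_results(json)
  expect_equal(back[[1]]$gis, round(res$gis, 4))
  expect_equal(back[[1]]$ploh_pct, round(res$ploh_pct, 4))
  expect_equal(back[[2]]$hrd_status, "positive")
})
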