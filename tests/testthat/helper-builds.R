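# toy genomes and randomized fixtures used across the suite

# two-chromosome toy build: chrA 100 Mb with centromere [40, 41) Mb,
# chrB 60 Mb with centromere [30, 31) Mb; all telomeres assembled
toy_build <- function() {
  chroms <- data.frame(chrom = c("chrA", "chrB"), length = c(1e8, 6e7))
  arms <- data.frame(
    chrom = rep(c("chrA", "chrB"), each = 2),
    arm = c("p", "q", "p", "q"),
    start = c(0, 41e6, 0, 31e6),
    end = c(40e6, 1e8, 30e6, 6e7),
    telomere_assembled = TRUE)
  genome_build("toy", chroms, arms)
}

# the worked example: 15 Mb copy-neutral LOH at the chrA p terminus,
# the rest diploid heterozygous
toy_profile <- function(build = toy_build()) {
  seg <- data.frame(
    chrom = c("chrA", "chrA", "chrB"),
    start = c(0, 15e6, 0), end = c(15e6, 1e8, 6e7),
    total_cn = c(2, 2, 2), minor_cn = c(0, 1, 1))
  cn_profile("toy", seg, build)
}

# uniformly diploid heterozygous profile on the toy build
toy_null_profile <- function(build = toy_build()) {
  seg <- data.frame(chrom = c("chrA", "chrB"), start = c(0, 0),
                    end = c(1e8, 6e7), total_cn = 2, minor_cn = 1)
  cn_profile("null", seg, build)
}

# parameters scaled to sub-Mb toy genomes so every filter branch is
# reachable on chromosomes the per-base painter can afford to paint
scaled_params <- function(...) {
  gis_params(max_gap_bp = 10e3, telomere_window_bp = 25e3,
             min_region_bp = 50e3, min_telomeric_segment_bp = 5e3,
             min_observed_fraction = 0, ...)
}

# random toy genome: 2-5 chromosomes of 0.15-0.45 Mb with an interior
# centromere and random telomere-assembly flags; small enough that the
# per-base oracle stays affordable
random_toy_build <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  chroms <- paste0("c", seq_len(n))
  len <- round(runif(n, 1.5e5, 4.5e5))
  cen_mid <- round(len * runif(n, 0.25, 0.75))
  cen_half <- round(len * runif(n, 0.01, 0.05))
  arms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chrom = chroms[i], arm = c("p", "q"),
               start = c(0, cen_mid[i] + cen_half[i]),
               end = c(cen_mid[i] - cen_half[i], len[i]),
               telomere_assembled = runif(2) > 0.15)
  }))
  genome_build(paste0("rand", seed),
               data.frame(chrom = chroms, length = len), arms)
}

# random profile on a toy build: random breakpoints, states drawn with
# LOH / deviation mass, random dropout of whole pieces
random_toy_profile <- function(build, seed, max_segments = 50) {
  set.seed(seed + 7)
  states <- matrix(c(2, 1, 2, 1, 2, 1, 2, 0, 1, 0, 3, 1, 4, 2, 3, 0, 0, 0),
                   ncol = 2, byrow = TRUE)
  rows <- list()
  for (ch in build$included) {
    len <- build$chromosomes$length[build$chromosomes$chrom == ch]
    k <- sample(3:9, 1)
    bp <- sort(sample(seq(5e3, len - 5e3, by = 1e3), k - 1))
    s <- c(0, bp); e <- c(bp, len)
    st <- states[sample.int(nrow(states), k, replace = TRUE), , drop = FALSE]
    keep <- runif(k) > 0.15  # dropout
    if (!any(keep)) keep[1] <- TRUE
    rows[[ch]] <- data.frame(chrom = ch, start = s[keep], end = e[keep],
                             total_cn = st[keep, 1], minor_cn = st[keep, 2])
  }
  seg <- do.call(rbind, rows)
  if (nrow(seg) > max_segments) seg <- seg[seq_len(max_segments), ]
  cn_profile(paste0("rand", seed), seg, build)
}
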