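#' Scoring parameters
#'
#' Collects the tunable parameters of the genomic-instability score. The
#' defaults are the calibrated operating point of the assay.
#'
#' @param cutoff GI-positivity threshold on the GIS; a sample is
#'   GI-positive when `gis >= cutoff` (default 83).
#' @param max_gap_bp Largest unobserved gap (bp) fused across when building
#'   equal-state and alteration runs (default 1 Mb).
#' @param whole_arm_fraction A region is treated as affecting a whole
#'   chromosome arm -- and therefore not counted -- when its observed
#'   overlap with that arm reaches this fraction of the arm's observed
#'   territory (default 0.9). Segmentation never lands exactly on arm
#'   boundaries, so an exact-match rule would never trigger.
#' @param min_observed_fraction Evaluability floor: minimum ratio of
#'   observed genome to assembled reference territory (default 0.4).
#' @param telomere_window_bp A terminal segment reflects a telomere only if
#'   it starts (p) or ends (q) strictly within this distance of the
#'   chromosome terminus (default 5 Mb).
#' @param min_region_bp Minimum span (strict, bp) of an LOH or
#'   copy-number-alteration region to enter PLOH/PCNA (default 10 Mb).
#' @param min_telomeric_segment_bp Minimum span (strict, bp) of a telomeric
#'   segment to be considered for PTCNA (default 1 Mb).
#' @param fuse_mixed_states Fuse adjacent deviant segments into one
#'   alteration run even when their deviant states differ (default `TRUE`;
#'   the size filter is on altered territory, not on uniform state). Set
#'   `FALSE` for state-uniform runs.
#' @return A list of class `gis_params`.
#' @export
gis_params <- function(cutoff = 83,
                       max_gap_bp = 1e6,
                       whole_arm_fraction = 0.9,
                       min_observed_fraction = 0.4,
                       telomere_window_bp = 5e6,
                       min_region_bp = 1e7,
                       min_telomeric_segment_bp = 1e6,
                       fuse_mixed_states = TRUE) {
  stopifnot(cutoff >= 0, max_gap_bp >= 0,
            whole_arm_fraction > 0, whole_arm_fraction <= 1,
            min_observed_fraction >= 0, min_observed_fraction <= 1,
            telomere_window_bp > 0, min_region_bp >= 0,
            min_telomeric_segment_bp >= 0, is.logical(fuse_mixed_states))
  structure(list(cutoff = cutoff, max_gap_bp = max_gap_bp,
                 whole_arm_fraction = whole_arm_fraction,
                 min_observed_fraction = min_observed_fraction,
                 telomere_window_bp = telomere_window_bp,
                 min_region_bp = min_region_bp,
                 min_telomeric_segment_bp = min_telomeric_segment_bp,
                 fuse_mixed_states = fuse_mixed_states),
            class = "gis_params")
}

# vectorized net arm overlap for a segment table: matrix with obs_p, obs_q
seg_arm_obs <- function(build, seg, gaps) {
  arms <- build$arms
  p_end <- stats::setNames(arms$end[arms$arm == "p"], arms$chrom[arms$arm == "p"])
  q_start <- stats::setNames(arms$start[arms$arm == "q"], arms$chrom[arms$arm == "q"])
  q_end <- stats::setNames(arms$end[arms$arm == "q"], arms$chrom[arms$arm == "q"])
  obs_p <- pmax(0, pmin(seg$end, p_end[seg$chrom]) - pmax(seg$start, 0))
  obs_q <- pmax(0, pmin(seg$end, q_end[seg$chrom]) - pmax(seg$start, q_start[seg$chrom]))
  if (!is.null(gaps) && nrow(gaps)) {
    for (k in seq_len(nrow(gaps))) {
      ch <- gaps$chrom[k]
      hit <- which(seg$chrom == ch & seg$start <= gaps$start[k] &
                   seg$end >= gaps$end[k])
      if (!length(hit)) next
      gp <- max(0, min(gaps$end[k], p_end[ch]) - gaps$start[k])
      gq <- max(0, gaps$end[k] - max(gaps$start[k], q_start[ch]))
      obs_p[hit] <- obs_p[hit] - gp
      obs_q[hit] <- obs_q[hit] - gq
    }
  }
  cbind(obs_p = unname(obs_p), obs_q = unname(obs_q))
}

# maximal runs of flagged segments; a run breaks at an unflagged segment,
# at an unobserved inter-segment gap > max_gap, or (when state_key given)
# at a state change; returns a 2-column matrix of (i0, i1) index pairs
build_runs <- function(start, end, flag, max_gap, state_key = NULL) {
  n <- length(flag)
  idx <- which(flag)
  if (!length(idx)) return(matrix(integer(), ncol = 2))
  if (length(idx) == 1L) return(matrix(c(idx, idx), ncol = 2))
  prev <- idx[-length(idx)]; nxt <- idx[-1]
  joined <- (nxt == prev + 1L) &                      # no unflagged segment between
    (start[nxt] - end[prev]) <= max_gap
  if (!is.null(state_key)) joined <- joined & state_key[nxt] == state_key[prev]
  first <- idx[c(TRUE, !joined)]
  last <- c(idx[c(!joined, FALSE)], idx[length(idx)])
  cbind(first, last)
}

# whole-arm test: TRUE when the region must be excluded; an arm with zero
# region overlap never disqualifies
is_whole_arm <- function(region_p, region_q, arm_total, frac) {
  (region_p > 0 & region_p >= frac * arm_total[["obs_p"]]) |
  (region_q > 0 & region_q >= frac * arm_total[["obs_q"]])
}

# one-pass scoring context shared by the component functions; per-chromosome
# data are kept as plain vectors for speed
score_context <- function(profile, build, params) {
  stopifnot(inherits(profile, "cn_profile"), inherits(build, "genome_build"),
            inherits(params, "gis_params"))
  m <- merge_equal_state_runs(profile, params$max_gap_bp)
  seg <- m$segments
  seg <- seg[seg$chrom %in% build$included, , drop = FALSE]
  obs <- if (nrow(seg)) seg_arm_obs(build, seg, m$gaps) else
    cbind(obs_p = numeric(), obs_q = numeric())
  chrom <- seg$chrom
  start <- seg$start; end <- seg$end
  total <- seg$total_cn; minor <- seg$minor_cn
  obs_p <- obs[, "obs_p"]; obs_q <- obs[, "obs_q"]
  obs_all <- obs_p + obs_q
  observed_bp <- sum(obs_all)

  chrom_info <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    at <- c(obs_p = sum(obs_p[idx]), obs_q = sum(obs_q[idx]))
    if (sum(at) <= 0) next  # nothing observed on arms: chromosome skipped
    # modal (total, minor) state by observed arm coverage
    code <- total[idx] * 10000 + minor[idx]
    cov <- rowsum(obs_all[idx], code)
    codes <- as.numeric(rownames(cov))
    st <- cbind(codes %/% 10000, codes %% 10000)
    o <- order(-cov[, 1], st[, 1], st[, 2])[1]
    ci <- list(start = start[idx], end = end[idx],
               total = total[idx], minor = minor[idx],
               obs_p = obs_p[idx], obs_q = obs_q[idx], obs = obs_all[idx],
               arm_total = at,
               expected = c(total_cn = st[o, 1], minor_cn = st[o, 2]),
               expected_covered = cov[o, 1])
    ci$dev <- ci$total != ci$expected[["total_cn"]] |
              ci$minor != ci$expected[["minor_cn"]]
    chrom_info[[ch]] <- ci
  }
  arms <- build$arms
  list(profile = m, observed_bp = observed_bp,
       assembled_bp = assembled_territory(build),
       chrom_info = chrom_info, params = params, build = build,
       chrom_len = stats::setNames(build$chromosomes$length,
                                   build$chromosomes$chrom),
       p_assembled = stats::setNames(arms$telomere_assembled[arms$arm == "p"],
                                     arms$chrom[arms$arm == "p"]),
       q_assembled = stats::setNames(arms$telomere_assembled[arms$arm == "q"],
                                     arms$chrom[arms$arm == "q"]))
}

# evaluate candidate regions of one chromosome; returns parallel vectors
region_fields <- function(ci, runs, params) {
  k <- nrow(runs)
  if (!k) return(NULL)
  i0 <- runs[, 1]; i1 <- runs[, 2]
  csum <- function(v) { s <- cumsum(c(0, v)); s[i1 + 1L] - s[i0] }
  region_p <- csum(ci$obs_p); region_q <- csum(ci$obs_q)
  span_start <- ci$start[i0]; span_end <- ci$end[i1]
  span <- span_end - span_start
  whole_arm <- is_whole_arm(region_p, region_q, ci$arm_total,
                            params$whole_arm_fraction)
  too_small <- !(span > params$min_region_bp)
  qualifies <- !too_small & !whole_arm
  list(span_start = span_start, span_end = span_end, span_bp = span,
       observed_bp = csum(ci$obs), qualifies = qualifies,
       reason = ifelse(qualifies, "",
                       ifelse(too_small, "below_min_region", "whole_arm")),
       i0 = i0, i1 = i1)
}

regions_table <- function(parts, loh = FALSE) {
  if (!length(parts)) {
    d <- data.frame(chrom = character(), span_start = numeric(),
                    span_end = numeric(), span_bp = numeric(),
                    observed_bp = numeric(), qualifies = logical(),
                    reason = character(), stringsAsFactors = FALSE)
    if (loh) d$homozygous_deletion <- logical()
    return(d)
  }
  d <- data.frame(
    chrom = unlist(lapply(parts, function(p) rep(p$chrom, length(p$f$i0)))),
    span_start = unlist(lapply(parts, function(p) p$f$span_start)),
    span_end = unlist(lapply(parts, function(p) p$f$span_end)),
    span_bp = unlist(lapply(parts, function(p) p$f$span_bp)),
    observed_bp = unlist(lapply(parts, function(p) p$f$observed_bp)),
    qualifies = unlist(lapply(parts, function(p) p$f$qualifies)),
    reason = unlist(lapply(parts, function(p) p$f$reason)),
    stringsAsFactors = FALSE)
  if (loh)
    d$homozygous_deletion <- unlist(lapply(parts, function(p) p$hd))
  d
}

ploh_from_context <- function(ctx) {
  params <- ctx$params
  parts <- list()
  for (ch in names(ctx$chrom_info)) {
    ci <- ctx$chrom_info[[ch]]
    loh <- ci$minor == 0  # homozygous deletions (total 0) count as LOH
    runs <- build_runs(ci$start, ci$end, loh, params$max_gap_bp)
    f <- region_fields(ci, runs, params)
    if (is.null(f)) next
    hd <- vapply(seq_along(f$i0), function(k)
      any(ci$total[f$i0[k]:f$i1[k]] == 0), logical(1))
    parts[[length(parts) + 1L]] <- list(chrom = ch, f = f, hd = hd)
  }
  regions <- regions_table(parts, loh = TRUE)
  value <- if (ctx$observed_bp > 0)
    100 * sum(regions$observed_bp[regions$qualifies]) / ctx$observed_bp
  else NA_real_
  list(value = value, regions = regions)
}

dev_runs_for_chrom <- function(ci, params) {
  key <- if (params$fuse_mixed_states) NULL else paste(ci$total, ci$minor)
  build_runs(ci$start, ci$end, ci$dev, params$max_gap_bp, state_key = key)
}

pcna_from_context <- function(ctx) {
  params <- ctx$params
  parts <- list()
  for (ch in names(ctx$chrom_info)) {
    ci <- ctx$chrom_info[[ch]]
    f <- region_fields(ci, dev_runs_for_chrom(ci, params), params)
    if (is.null(f)) next
    parts[[length(parts) + 1L]] <- list(chrom = ch, f = f)
  }
  regions <- regions_table(parts)
  value <- if (ctx$observed_bp > 0)
    100 * sum(regions$observed_bp[regions$qualifies]) / ctx$observed_bp
  else NA_real_
  list(value = value, regions = regions)
}

ptcna_from_context <- function(ctx) {
  params <- ctx$params
  build <- ctx$build
  chroms <- names(ctx$chrom_info)
  tel_chrom <- tel_arm <- tel_reason <- character()
  tel_eval <- tel_alt <- logical()
  for (ch in chroms) {
    ci <- ctx$chrom_info[[ch]]
    n <- length(ci$start)
    len <- ctx$chrom_len[[ch]]
    runs <- dev_runs_for_chrom(ci, params)
    run_of <- rep(NA_integer_, n)
    run_whole_arm <- logical(nrow(runs))
    if (nrow(runs)) {
      for (k in seq_len(nrow(runs))) run_of[runs[k, 1]:runs[k, 2]] <- k
      csum_p <- cumsum(c(0, ci$obs_p)); csum_q <- cumsum(c(0, ci$obs_q))
      run_whole_arm <- is_whole_arm(
        csum_p[runs[, 2] + 1L] - csum_p[runs[, 1]],
        csum_q[runs[, 2] + 1L] - csum_q[runs[, 1]],
        ci$arm_total, params$whole_arm_fraction)
    }
    for (arm in c("p", "q")) {
      assembled <- if (arm == "p") ctx$p_assembled[[ch]] else ctx$q_assembled[[ch]]
      anchor <- if (arm == "p") 1L else n
      in_window <- if (arm == "p") ci$start[anchor] < params$telomere_window_bp
                   else ci$end[anchor] > len - params$telomere_window_bp
      evaluable <- isTRUE(assembled) && in_window
      altered <- FALSE; reason <- ""
      if (evaluable) {
        if (!ci$dev[anchor]) {
          reason <- "matches_expected"
        } else if (!(ci$end[anchor] - ci$start[anchor] >
                     params$min_telomeric_segment_bp)) {
          reason <- "below_min_telomeric_segment"
        } else if (run_whole_arm[run_of[anchor]]) {
          reason <- "whole_arm"
        } else {
          altered <- TRUE
        }
      } else {
        reason <- if (!isTRUE(assembled)) "telomere_unassembled"
                  else "no_terminal_segment"
      }
      tel_chrom <- c(tel_chrom, ch); tel_arm <- c(tel_arm, arm)
      tel_eval <- c(tel_eval, evaluable); tel_alt <- c(tel_alt, altered)
      tel_reason <- c(tel_reason, reason)
    }
  }
  tel <- data.frame(chrom = tel_chrom, arm = tel_arm, evaluable = tel_eval,
                    altered = tel_alt, reason = tel_reason,
                    stringsAsFactors = FALSE)
  n_eval <- sum(tel$evaluable)
  value <- if (n_eval > 0) 100 * sum(tel$altered) / n_eval else NA_real_
  list(value = value, telomeres = tel, n_evaluable = n_eval)
}

#' Expected allele-specific state of each chromosome
#'
#' The expected copy number of a chromosome is the allele-specific state
#' `(total_cn, minor_cn)` covering the largest part of its observed arm
#' territory; ties break toward the smaller total, then the smaller minor,
#' copy number. Chromosomes with no observed arm territory have no expected
#' state and are skipped by PCNA and PTCNA.
#'
#' @param profile A [cn_profile()].
#' @param build A [genome_build()].
#' @param params A [gis_params()].
#' @return `data.frame` with columns `chrom`, `total_cn`, `minor_cn`,
#'   `covered_bp`.
#' @export
expected_state <- function(profile, build, params = gis_params()) {
  ctx <- score_context(profile, build, params)
  expected_states_table(ctx)
}

expected_states_table <- function(ctx) {
  ci <- ctx$chrom_info
  data.frame(
    chrom = names(ci),
    total_cn = vapply(ci, function(x) x$expected[["total_cn"]], numeric(1),
                      USE.NAMES = FALSE),
    minor_cn = vapply(ci, function(x) x$expected[["minor_cn"]], numeric(1),
                      USE.NAMES = FALSE),
    covered_bp = vapply(ci, function(x) x$expected_covered, numeric(1),
                        USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Percent loss of heterozygosity (PLOH)
#'
#' Percentage of the observed genome lying in qualifying LOH regions. A
#' base is in LOH state when its minor-allele copy number is 0 (homozygous
#' deletions are included and flagged). Maximal LOH runs are built by
#' fusing consecutive LOH segments -- regardless of total copy number --
#' across unobserved gaps of at most `max_gap_bp`; a run qualifies when its
#' span exceeds `min_region_bp` (strictly) and it does not affect a whole
#' chromosome arm (see [gis_params()]).
#'
#' @inheritParams expected_state
#' @return List with `value` (percentage) and `regions` (all candidate
#'   regions with qualification flags).
#' @export
compute_ploh <- function(profile, build, params = gis_params()) {
  ploh_from_context(score_context(profile, build, params))
}

#' Percent copy-number alteration (PCNA)
#'
#' Percentage of the observed genome deviating from the chromosome's
#' expected allele-specific state. Deviation is allele-specific, so
#' copy-neutral LOH counts. Deviant runs are fused across unobserved gaps
#' (and across differing deviant states unless `fuse_mixed_states` is
#' `FALSE`); a run qualifies when its span exceeds `min_region_bp` and it
#' does not affect a whole chromosome arm.
#'
#' @inheritParams expected_state
#' @return List with `value` (percentage) and `regions`.
#' @export
compute_pcna <- function(profile, build, params = gis_params()) {
  pcna_from_context(score_context(profile, build, params))
}

#' Percent telomeric copy-number alteration (PTCNA)
#'
#' Percentage of evaluable telomeres whose terminal segment deviates from
#' the chromosome's expected state. A telomere is evaluable when it is
#' assembled in the reference and a segment starts (p) or ends (q) strictly
#' within `telomere_window_bp` of the chromosome terminus. It is altered
#' when that terminal segment spans more than `min_telomeric_segment_bp`,
#' deviates from the expected state, and the alteration run containing it
#' does not affect a whole arm. With zero evaluable telomeres the component
#' is undefined and the profile unevaluable.
#'
#' @inheritParams expected_state
#' @return List with `value` (percentage), `telomeres` (per-telomere
#'   verdicts) and `n_evaluable`.
#' @export
compute_ptcna <- function(profile, build, params = gis_params()) {
  ptcna_from_context(score_context(profile, build, params))
}

#' Genomic instability score (GIS)
#'
#' Computes PLOH, PCNA and PTCNA and sums them into the GIS. A sample is
#' evaluable when its observed genome reaches `min_observed_fraction` of
#' the assembled reference territory and PTCNA is defined; evaluable
#' samples are GI-positive when `gis >= cutoff`.
#'
#' @inheritParams expected_state
#' @return An object of class `gis_result`: components, `gis`,
#'   `observed_genome_bp`, `observed_fraction`, `evaluable`, `gi_positive`
#'   (`NA` when unevaluable), `expected_states`, contributing regions and
#'   per-telomere verdicts.
#' @export
compute_gis <- function(profile, build, params = gis_params()) {
  ctx <- score_context(profile, build, params)
  ploh <- ploh_from_context(ctx)
  pcna <- pcna_from_context(ctx)
  ptcna <- ptcna_from_context(ctx)
  observed_fraction <- if (ctx$assembled_bp > 0)
    ctx$observed_bp / ctx$assembled_bp else 0
  evaluable <- ctx$observed_bp > 0 &&
    observed_fraction >= params$min_observed_fraction &&
    !is.na(ptcna$value)
  gis <- if (!is.na(ploh$value) && !is.na(pcna$value) && !is.na(ptcna$value))
    ploh$value + pcna$value + ptcna$value else NA_real_
  gi_positive <- if (evaluable) gis >= params$cutoff else NA
  structure(
    list(sample_id = profile$sample_id,
         ploh_pct = ploh$value, pcna_pct = pcna$value,
         ptcna_pct = ptcna$value, gis = gis,
         observed_genome_bp = ctx$observed_bp,
         observed_fraction = observed_fraction,
         evaluable = evaluable, gi_positive = gi_positive,
         cutoff = params$cutoff,
         expected_states = expected_states_table(ctx),
         ploh_regions = ploh$regions, pcna_regions = pcna$regions,
         telomeres = ptcna$telomeres, params = params),
    class = "gis_result")
}

#' @export
print.gis_result <- function(x, ...) {
  cat("<gis_result> ", x$sample_id, "\n", sep = "")
  if (isTRUE(x$evaluable)) {
    cat(sprintf("  PLOH %.4f + PCNA %.4f + PTCNA %.4f = GIS %.4f\n",
                x$ploh_pct, x$pcna_pct, x$ptcna_pct, x$gis))
    cat("  GI status: ", if (isTRUE(x$gi_positive)) "positive" else "negative",
        " (cutoff ", x$cutoff, ")\n", sep = "")
  } else {
    cat("  unevaluable\n")
  }
  cat(sprintf("  observed genome: %s bp (%.1f%% of assembled territory)\n",
              format(x$observed_genome_bp, big.mark = ",", scientific = FALSE),
              100 * x$observed_fraction))
  invisible(x)
}

#' HRD call from GI status and BRCA1/2 mutation status
#'
#' A sample is HRD-positive when it is GI-positive and/or harbors a
#' pathogenic BRCA1 or BRCA2 mutation. A pathogenic BRCA mutation makes
#' the sample HRD-positive even when the GI score is unevaluable; with
#' undefined GI status and no pathogenic mutation the HRD status is
#' unevaluable. Unknown BRCA status is treated as wildtype for the call
#' but recorded as given.
#'
#' @param gis_result A `gis_result` from [compute_gis()].
#' @param brca One of `"pathogenic"`, `"wildtype"`, `"unknown"`.
#' @return List of class `hrd_call` with `sample_id`, `gi_positive`,
#'   `brca`, `hrd_status` (`"positive"`, `"negative"` or `"unevaluable"`).
#' @export
call_hrd <- function(gis_result, brca = c("unknown", "wildtype", "pathogenic")) {
  brca <- match.arg(brca)
  gi <- gis_result$gi_positive
  hrd_status <- if (isTRUE(gi) || brca == "pathogenic") "positive"
                else if (is.na(gi)) "unevaluable"
                else "negative"
  structure(list(sample_id = gis_result$sample_id, gi_positive = gi,
                 brca = brca, hrd_status = hrd_status),
            class = "hrd_call")
}

#' Score a set of profiles and call HRD status
#'
#' Convenience wrapper: runs [compute_gis()] and [call_hrd()] per sample
#' and returns combined records ready for [write_results()].
#'
#' @param profiles List of [cn_profile()].
#' @param build A [genome_build()].
#' @param params A [gis_params()].
#' @param brca Named character vector of BRCA status
#'   (`"pathogenic"`/`"wildtype"`/`"unknown"`) keyed by sample id; samples
#'   not named default to `"unknown"`.
#' @return List of `gis_result` objects with `brca` and `hrd_status` fields
#'   added.
#' @export
score_profiles <- function(profiles, build, params = gis_params(),
                           brca = NULL) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  lapply(profiles, function(p) {
    res <- compute_gis(p, build, params)
    b <- if (!is.null(brca) && p$sample_id %in% names(brca))
      match.arg(brca[[p$sample_id]], c("unknown", "wildtype", "pathogenic"))
    else "unknown"
    hc <- call_hrd(res, b)
    res$brca <- hc$brca
    res$hrd_status <- hc$hrd_status
    res
  })
}
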