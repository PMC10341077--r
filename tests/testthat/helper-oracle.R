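# independent per-base oracle: paints every base of a toy genome with its
# allele-specific state and applies the scoring rules positionally, with no
# interval arithmetic shared with the package implementation

# regions of positionally-applied run logic: given a per-base class vector
# (0 unobserved, 1 in-state, 2 observed out-of-state), return matrix of
# 1-based inclusive [first, last] base positions of maximal in-state runs,
# where unobserved stretches <= max_gap inside a run are bridged
oracle_runs <- function(cls, max_gap) {
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- NULL
  open <- FALSE; a <- b <- NA_integer_; gap_ok <- TRUE
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v == 1) {
      if (open && gap_ok) {
        b <- ends[k]
      } else {
        if (open) out <- rbind(out, c(a, b))
        a <- starts[k]; b <- ends[k]; open <- TRUE
      }
      gap_ok <- TRUE
    } else if (v == 2) {
      if (open) { out <- rbind(out, c(a, b)); open <- FALSE }
    } else {
      if (open && r$lengths[k] > max_gap) gap_ok <- FALSE
      else if (open) gap_ok <- TRUE
    }
  }
  if (open) out <- rbind(out, c(a, b))
  out
}

oracle_gis <- function(profile, build, params) {
  seg_all <- profile$segments
  gaps_all <- profile$gaps
  max_gap <- params$max_gap_bp
  frac <- params$whole_arm_fraction

  observed_total <- 0
  ploh_num <- 0
  pcna_num <- 0
  tel_eval <- 0L; tel_alt <- 0L

  for (ch in build$included) {
    seg <- seg_all[seg_all$chrom == ch, , drop = FALSE]
    if (!nrow(seg)) next
    len <- build$chromosomes$length[build$chromosomes$chrom == ch]
    a <- build$arms[build$arms$chrom == ch, , drop = FALSE]
    ap <- a[a$arm == "p", ]; aq <- a[a$arm == "q", ]

    total <- rep(NA_integer_, len)
    minor <- rep(NA_integer_, len)
    observed <- rep(FALSE, len)
    for (i in seq_len(nrow(seg))) {
      idx <- (seg$start[i] + 1):seg$end[i]
      total[idx] <- seg$total_cn[i]; minor[idx] <- seg$minor_cn[i]
      observed[idx] <- TRUE
    }
    if (!is.null(gaps_all) && nrow(gaps_all)) {
      g <- gaps_all[gaps_all$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(g))) observed[(g$start[i] + 1):g$end[i]] <- FALSE
    }
    armv <- integer(len)
    armv[(ap$start + 1):ap$end] <- 1L
    armv[(aq$start + 1):aq$end] <- 2L

    obs_arm <- observed & armv > 0L
    arm_tot <- c(sum(observed & armv == 1L), sum(observed & armv == 2L))
    observed_total <- observed_total + sum(obs_arm)
    has_expected <- any(obs_arm)

    # whole-arm exclusion on a positional region of in-state bases
    region_excluded <- function(a1, b1, in_state) {
      seg_idx <- a1:b1
      rp <- sum(in_state[seg_idx] & armv[seg_idx] == 1L)
      rq <- sum(in_state[seg_idx] & armv[seg_idx] == 2L)
      (rp > 0 && rp >= frac * arm_tot[1]) || (rq > 0 && rq >= frac * arm_tot[2])
    }

    # PLOH
    is_loh <- observed & !is.na(minor) & minor == 0L
    cls <- ifelse(!observed, 0L, ifelse(is_loh, 1L, 2L))
    runs <- oracle_runs(cls, max_gap)
    for (k in seq_len(NROW(runs))) {
      a1 <- runs[k, 1]; b1 <- runs[k, 2]
      span <- b1 - a1 + 1
      if (span > params$min_region_bp && !region_excluded(a1, b1, is_loh))
        ploh_num <- ploh_num + sum(is_loh[a1:b1] & armv[a1:b1] > 0L)
    }

    if (!has_expected) next

    # expected state: modal (total, minor) over observed arm bases
    code <- total[obs_arm] * 10000 + minor[obs_arm]
    tab <- table(code)
    codes <- as.numeric(names(tab))
    o <- order(-as.numeric(tab), codes %/% 10000, codes %% 10000)[1]
    exp_total <- codes[o] %/% 10000; exp_minor <- codes[o] %% 10000

    # PCNA (mixed-state deviation runs)
    is_dev <- observed & (total != exp_total | minor != exp_minor)
    cls_d <- ifelse(!observed, 0L, ifelse(is_dev, 1L, 2L))
    druns <- oracle_runs(cls_d, max_gap)
    dev_keep <- logical(NROW(druns))
    for (k in seq_len(NROW(druns))) {
      a1 <- druns[k, 1]; b1 <- druns[k, 2]
      dev_keep[k] <- !region_excluded(a1, b1, is_dev)
      if ((b1 - a1 + 1) > params$min_region_bp && dev_keep[k])
        pcna_num <- pcna_num + sum(is_dev[a1:b1] & armv[a1:b1] > 0L)
    }

    # pseudo-segments: maximal equal-state observed runs bridged across
    # unobserved gaps <= max_gap
    state_code <- ifelse(observed, total * 10000 + minor, -1)
    r <- rle(state_code)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ps <- NULL  # rows: first, last, code
    gap_len <- Inf
    for (k in seq_along(r$values)) {
      if (r$values[k] < 0) { gap_len <- r$lengths[k]; next }
      if (!is.null(ps) && ps[nrow(ps), 3] == r$values[k] && gap_len <= max_gap) {
        ps[nrow(ps), 2] <- ends[k]
      } else {
        ps <- rbind(ps, c(starts[k], ends[k], r$values[k]))
      }
      gap_len <- 0
    }

    # PTCNA: anchor = outermost pseudo-segment within the telomere window
    tel_verdict <- function(side) {
      assembled <- if (side == "p") ap$telomere_assembled else aq$telomere_assembled
      if (!isTRUE(assembled)) return(NULL)
      row <- if (side == "p") ps[1, ] else ps[nrow(ps), ]
      in_window <- if (side == "p") (row[1] - 1) < params$telomere_window_bp
                   else row[2] > len - params$telomere_window_bp
      if (!in_window) return(NULL)
      anchor_dev <- row[3] != exp_total * 10000 + exp_minor
      span <- row[2] - row[1] + 1
      altered <- FALSE
      if (anchor_dev && span > params$min_telomeric_segment_bp) {
        # deviation run containing the anchor must not be whole-arm
        base <- if (side == "p") row[1] else row[2]
        k <- which(druns[, 1] <= base & druns[, 2] >= base)
        altered <- length(k) == 1 && dev_keep[k]
      }
      altered
    }
    for (side in c("p", "q")) {
      v <- tel_verdict(side)
      if (!is.null(v)) { tel_eval <- tel_eval + 1L; tel_alt <- tel_alt + v }
    }
  }

  list(
    observed_bp = observed_total,
    ploh = if (observed_total > 0) 100 * ploh_num / observed_total else NA_real_,
    pcna = if (observed_total > 0) 100 * pcna_num / observed_total else NA_real_,
    ptcna = if (tel_eval > 0) 100 * tel_alt / tel_eval else NA_real_,
    n_eval_telomeres = tel_eval)
}
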