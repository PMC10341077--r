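# allele-specific states used for simulated copy-number events, relative
# to a (2,1) diploid baseline: gains, copy-neutral LOH, and loss LOH
cna_event_states <- matrix(c(3, 1, 4, 1, 4, 2, 5, 2), ncol = 2, byrow = TRUE,
                           dimnames = list(NULL, c("total", "minor")))
loh_event_states <- matrix(c(2, 0, 1, 0), ncol = 2, byrow = TRUE,
                           dimnames = list(NULL, c("total", "minor")))

#' Simulation parameters for synthetic copy-number profiles
#'
#' Describes one synthetic tumor profile: a uniform base state across the
#' genome, a number of interstitial LOH events, interstitial copy-number
#' events, and telomere-anchored events, with log-uniform event sizes, plus
#' random coverage dropout emulating the patchy observation of degraded
#' FFPE libraries.
#'
#' @param build A [genome_build()].
#' @param base_state `(total_cn, minor_cn)` of the unaltered genome
#'   (default `c(2, 1)`, diploid heterozygous).
#' @param n_loh_events Interstitial LOH events (minor allele lost;
#'   copy-neutral or with loss, chosen per event).
#' @param n_cna_events Interstitial copy-number events deviating from the
#'   base state with the minor allele retained.
#' @param n_telomeric_events Deviant events anchored at a chromosome
#'   terminus.
#' @param size_min,size_max Event-size range in bp; sizes are drawn
#'   log-uniformly (defaults 5 Mb to 40 Mb).
#' @param dropout_fraction Fraction of chromosome territory removed from
#'   observation, in `[0, 1)`.
#' @param seed Integer seed; may also be supplied to [simulate_profile()].
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(build, base_state = c(2, 1),
                              n_loh_events = 0, n_cna_events = 0,
                              n_telomeric_events = 0,
                              size_min = 5e6, size_max = 4e7,
                              dropout_fraction = 0, seed = NULL) {
  stopifnot(inherits(build, "genome_build"),
            length(base_state) == 2, base_state[1] >= 0, base_state[2] >= 0,
            base_state[2] <= base_state[1] - base_state[2],
            n_loh_events >= 0, n_cna_events >= 0, n_telomeric_events >= 0,
            size_min > 0, size_min <= size_max,
            dropout_fraction >= 0, dropout_fraction < 1)
  structure(list(build = build, base_state = as.numeric(base_state),
                 n_loh_events = as.integer(n_loh_events),
                 n_cna_events = as.integer(n_cna_events),
                 n_telomeric_events = as.integer(n_telomeric_events),
                 size_min = size_min, size_max = size_max,
                 dropout_fraction = dropout_fraction, seed = seed),
            class = "simulation_params")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# remove [s, e) from a row-sorted (start, end, total, minor) matrix;
# overlapped rows form a contiguous block, so no re-sort is needed
punch_interval <- function(M, s, e) {
  n <- nrow(M)
  if (!n) return(M)
  hit <- which(M[, 1] < e & M[, 2] > s)
  if (!length(hit)) return(M)
  first <- hit[1]; last <- hit[length(hit)]
  mid <- NULL
  if (M[first, 1] < s) { row <- M[first, ]; row[2] <- s; mid <- rbind(mid, row) }
  if (M[last, 2] > e) { row <- M[last, ]; row[1] <- e; mid <- rbind(mid, row) }
  rbind(if (first > 1L) M[seq_len(first - 1L), , drop = FALSE],
        mid,
        if (last < n) M[(last + 1L):n, , drop = FALSE])
}

carve_interval <- function(M, s, e, total, minor) {
  M2 <- punch_interval(M, s, e)
  pos <- sum(M2[, 1] < s)
  rbind(if (pos > 0L) M2[seq_len(pos), , drop = FALSE],
        c(s, e, total, minor),
        if (pos < nrow(M2)) M2[(pos + 1L):nrow(M2), , drop = FALSE])
}

pick_deviant_state <- function(pool, base) {
  dev <- pool[pool[, 1] != base[1] | pool[, 2] != base[2], , drop = FALSE]
  dev[sample.int(nrow(dev), 1L), ]
}

#' Simulate one allele-specific copy-number profile
#'
#' Places the requested events on the included chromosomes (uniformly over
#' arms, rejecting overlaps between events), carves them into a base-state
#' segmentation, then removes randomly placed observation gaps until the
#' dropout target is reached. Interstitial events are kept clear of the
#' 5 Mb telomeric windows so that planted event types map one-to-one onto
#' the scorer's component rules. Deterministic for a fixed seed.
#'
#' @param params A [simulation_params()].
#' @param sample_id Sample label for the emitted profile.
#' @param seed Integer seed; overrides `params$seed`.
#' @param max_tries Placement retries per event before giving up.
#' @return List with `profile` (a [cn_profile()]) and `ledger`, a
#'   `data.frame` recording every planted event (type, interval, state,
#'   span, and whether its span passes the default size filter of its
#'   component).
#' @export
simulate_profile <- function(params, sample_id = "sim1", seed = NULL,
                             max_tries = 200L) {
  stopifnot(inherits(params, "simulation_params"))
  if (is.null(seed)) seed <- params$seed
  with_seed(seed, {
    build <- params$build
    base <- params$base_state
    chroms <- build$included
    lens <- stats::setNames(
      build$chromosomes$length[match(chroms, build$chromosomes$chrom)], chroms)
    armtab <- build$arms[build$arms$chrom %in% chroms, , drop = FALSE]
    arm_chrom <- armtab$chrom; arm_side <- armtab$arm
    arm_start <- armtab$start; arm_end <- armtab$end
    arm_len <- arm_end - arm_start
    tel_window <- 5e6

    # genome as per-chromosome (start, end, total, minor) matrices
    genome <- lapply(chroms, function(ch)
      matrix(c(0, lens[[ch]], base[1], base[2]), nrow = 1))
    names(genome) <- chroms
    events <- list()  # per chrom: matrix of placed event intervals
    ledger <- list()

    overlaps_existing <- function(ch, s, e) {
      ev <- events[[ch]]
      !is.null(ev) && any(ev[, 1] < e & ev[, 2] > s)
    }
    add_event <- function(type, ch, s, e, state) {
      events[[ch]] <<- rbind(events[[ch]], c(s, e))
      genome[[ch]] <<- carve_interval(genome[[ch]], s, e, state[1], state[2])
      min_span <- if (type == "telomeric") 1e6 else 1e7
      ledger[[length(ledger) + 1L]] <<- list(
        type = type, chrom = ch, start = s, end = e,
        total_cn = state[1], minor_cn = state[2], span_bp = e - s,
        passes_size_filter = (e - s) > min_span)
    }

    # telomere-anchored events
    for (k in seq_len(params$n_telomeric_events)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        i <- sample.int(length(arm_chrom), 1L)
        ch <- arm_chrom[i]; arm <- arm_side[i]
        size_hi <- min(params$size_max, 0.8 * arm_len[i])
        if (size_hi < params$size_min) next
        size <- runif_log(1, params$size_min, size_hi)
        if (arm == "p") { s <- 0; e <- round(size) }
        else { e <- lens[[ch]]; s <- e - round(size) }
        if (overlaps_existing(ch, s, e)) next
        state <- pick_deviant_state(rbind(cna_event_states, loh_event_states),
                                    base)
        add_event("telomeric", ch, s, e, state)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place telomeric event ", k, " without overlap after ",
             max_tries, " tries")
    }

    # interstitial events, kept out of the telomeric windows
    place_interstitial <- function(type) {
      pool <- if (type == "loh") loh_event_states else cna_event_states
      for (try in seq_len(max_tries)) {
        i <- sample.int(length(arm_chrom), 1L, prob = arm_len)
        ch <- arm_chrom[i]; arm <- arm_side[i]
        lo <- arm_start[i]; hi <- arm_end[i]
        if (arm == "p") lo <- max(lo, tel_window)
        if (arm == "q") hi <- min(hi, lens[[ch]] - tel_window)
        if (hi - lo < params$size_min) next
        size_hi <- min(params$size_max, 0.8 * (hi - lo))
        if (size_hi < params$size_min) next
        size <- round(runif_log(1, params$size_min, size_hi))
        s <- round(stats::runif(1, lo, hi - size))
        e <- s + size
        if (overlaps_existing(ch, s, e)) next
        state <- pick_deviant_state(pool, base)
        add_event(type, ch, s, e, state)
        return(invisible(TRUE))
      }
      stop("could not place interstitial ", type,
           " event without overlap after ", max_tries, " tries")
    }
    for (k in seq_len(params$n_loh_events)) place_interstitial("loh")
    for (k in seq_len(params$n_cna_events)) place_interstitial("cna")

    # coverage dropout: punch random observation holes until the target
    # fraction of chromosome territory is removed
    if (params$dropout_fraction > 0) {
      target <- params$dropout_fraction * sum(lens)
      removed <- 0
      guard <- 0L
      while (removed < target && guard < 100000L) {
        guard <- guard + 1L
        ch <- chroms[sample.int(length(chroms), 1L, prob = lens)]
        size <- round(runif_log(1, 5e5, 5e6))
        s <- round(stats::runif(1, 0, max(1, lens[[ch]] - size)))
        e <- min(s + size, lens[[ch]])
        M <- genome[[ch]]
        before <- sum(M[, 2] - M[, 1])
        genome[[ch]] <- punch_interval(M, s, e)
        removed <- removed + (before - sum(genome[[ch]][, 2] - genome[[ch]][, 1]))
      }
    }

    M <- do.call(rbind, genome)
    seg <- data.frame(
      chrom = rep(chroms, vapply(genome, nrow, integer(1))),
      start = M[, 1], end = M[, 2], total_cn = M[, 3], minor_cn = M[, 4],
      stringsAsFactors = FALSE)
    pull <- function(field, mode) vapply(ledger, `[[`, mode, field)
    ledger <- data.frame(
      type = pull("type", character(1)), chrom = pull("chrom", character(1)),
      start = pull("start", numeric(1)), end = pull("end", numeric(1)),
      total_cn = pull("total_cn", numeric(1)),
      minor_cn = pull("minor_cn", numeric(1)),
      span_bp = pull("span_bp", numeric(1)),
      passes_size_filter = pull("passes_size_filter", logical(1)),
      stringsAsFactors = FALSE)
    list(profile = cn_profile(sample_id, seg, build),
         ledger = ledger)
  })
}

#' Default per-group event-count ranges for cohort simulation
#'
#' Event counts per sample are drawn uniformly from these inclusive ranges,
#' producing a continuum of genomic instability rather than two point
#' masses -- as in clinical cohorts, where scores spread across the cutoff
#' region. The HRD-like group is centred well above the default cutoff and
#' the HRP-like group below it, with overlapping tails.
#'
#' @param group `"hrd"` or `"hrp"`.
#' @return List with `loh_range`, `cna_range`, `tel_range`,
#'   `dropout_range`.
#' @export
cohort_group_params <- function(group = c("hrd", "hrp")) {
  group <- match.arg(group)
  if (group == "hrd")
    list(loh_range = c(20, 34), cna_range = c(14, 24), tel_range = c(16, 28),
         dropout_range = c(0, 0.1))
  else
    list(loh_range = c(0, 12), cna_range = c(0, 10), tel_range = c(0, 14),
         dropout_range = c(0, 0.1))
}

#' Simulate a calibration cohort
#'
#' Simulates and scores `n_hrd` HRD-like and `n_hrp` HRP-like samples and
#' emits the calibration table consumed by [scan_cutoffs()]: the reference
#' label of each sample is its own scored GI status (GIS at or above the
#' cutoff), with a fraction `label_noise` of labels flipped at random --
#' emulating the imperfect agreement between two assays. Deterministic for
#' a fixed seed.
#'
#' @param n_hrd,n_hrp Group sizes (> 0).
#' @param hrd_params,hrp_params Per-group event-count ranges as returned by
#'   [cohort_group_params()].
#' @param label_noise Fraction of reference labels flipped.
#' @param seed Integer seed.
#' @param build A [genome_build()] (default [hg19_build()]).
#' @param score_params A [gis_params()].
#' @return `data.frame` with columns `sample`, `gis`, `reference_status`,
#'   `group`, `true_status`; scored results attached as attribute
#'   `"results"`.
#' @export
simulate_cohort <- function(n_hrd, n_hrp,
                            hrd_params = cohort_group_params("hrd"),
                            hrp_params = cohort_group_params("hrp"),
                            label_noise = 0, seed = NULL,
                            build = hg19_build(),
                            score_params = gis_params()) {
  stopifnot(n_hrd > 0, n_hrp > 0, label_noise >= 0, label_noise <= 1)
  with_seed(seed, {
    groups <- c(rep("hrd", n_hrd), rep("hrp", n_hrp))
    rows <- vector("list", length(groups))
    results <- vector("list", length(groups))
    draw <- function(range) if (range[1] == range[2]) range[1] else
      sample(seq(range[1], range[2]), 1L)
    for (i in seq_along(groups)) {
      gp <- if (groups[i] == "hrd") hrd_params else hrp_params
      sp <- simulation_params(
        build,
        n_loh_events = draw(gp$loh_range),
        n_cna_events = draw(gp$cna_range),
        n_telomeric_events = draw(gp$tel_range),
        dropout_fraction = stats::runif(1, gp$dropout_range[1],
                                        gp$dropout_range[2]))
      id <- sprintf("%s_%03d", groups[i], i)
      sim <- simulate_profile(sp, sample_id = id)
      res <- compute_gis(sim$profile, build, score_params)
      results[[i]] <- res
      rows[[i]] <- data.frame(sample = id, gis = res$gis, group = groups[i],
                              stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    true_status <- ifelse(!is.na(tab$gis) & tab$gis >= score_params$cutoff,
                          "positive", "negative")
    flip <- stats::runif(nrow(tab)) < label_noise
    ref <- ifelse(flip,
                  ifelse(true_status == "positive", "negative", "positive"),
                  true_status)
    out <- data.frame(sample = tab$sample, gis = tab$gis,
                      reference_status = ref, group = tab$group,
                      true_status = true_status, stringsAsFactors = FALSE)
    attr(out, "results") <- results
    out
  })
}
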