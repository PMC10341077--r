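#' Construct an allele-specific copy-number profile
#'
#' A `cn_profile` holds one sample's allele-specific segmentation: ordered,
#' non-overlapping segments with an integer total (`total_cn`) and
#' minor-allele (`minor_cn`) copy number, as produced by a tumor-only
#' purity/ploidy caller. Purity and ploidy are carried as metadata only;
#' the score operates on the integer allele-specific states, which are
#' already purity/ploidy-resolved upstream.
#'
#' `gaps` records unobserved territory lying *inside* segments; it is
#' populated by [merge_equal_state_runs()] when equal-state segments are
#' fused across a coverage gap. Gap bases count toward a region's span but
#' never toward the observed genome.
#'
#' @param sample_id Sample label.
#' @param segments `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), `total_cn`, `minor_cn`.
#' @param build A [genome_build()]; segments on chromosomes absent from the
#'   build are rejected.
#' @param purity Tumor-cell fraction in (0, 1], or `NA` if unknown.
#' @param ploidy Average tumor genome copy number, or `NA` if unknown.
#' @param gaps Optional `data.frame` (`chrom`, `start`, `end`) of unobserved
#'   intervals inside segments.
#' @return An object of class `cn_profile`.
#' @export
cn_profile <- function(sample_id, segments, build, purity = NA_real_,
                       ploidy = NA_real_, gaps = NULL) {
  stopifnot(is.data.frame(segments))
  req <- c("chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(req %in% names(segments)))
    stop("segments must have columns: ", paste(req, collapse = ", "))
  seg <- segments[, req]
  seg$chrom <- as.character(seg$chrom)
  for (col in c("start", "end", "total_cn", "minor_cn"))
    seg[[col]] <- as.numeric(seg[[col]])
  if (nrow(seg)) {
    if (any(!is.finite(as.matrix(seg[, -1]))))
      stop("sample ", sample_id, ": non-numeric segment field")
    if (any(seg$start >= seg$end)) {
      i <- which(seg$start >= seg$end)[1]
      stop("sample ", sample_id, " segment ", i, " (", seg$chrom[i],
           "): start >= end")
    }
    if (any(seg$total_cn < 0 | seg$minor_cn < 0 |
            seg$total_cn != round(seg$total_cn) |
            seg$minor_cn != round(seg$minor_cn)))
      stop("sample ", sample_id, ": copy numbers must be non-negative integers")
    bad <- which(seg$minor_cn > seg$total_cn - seg$minor_cn)
    if (length(bad))
      stop("sample ", sample_id, " segment ", bad[1], " (", seg$chrom[bad[1]],
           ":", seg$start[bad[1]] + 1, "-", seg$end[bad[1]],
           "): minor_cn ", seg$minor_cn[bad[1]],
           " exceeds the major allele (total_cn ", seg$total_cn[bad[1]], ")")
    unknown <- setdiff(unique(seg$chrom), build$chromosomes$chrom)
    if (length(unknown))
      stop("sample ", sample_id, ": chromosome(s) not in build '",
           build$name, "': ", paste(unknown, collapse = ", "))
    # sort and check bounds / overlap per chromosome
    seg <- seg[order(match(seg$chrom, build$chromosomes$chrom), seg$start), ]
    rownames(seg) <- NULL
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, ]
      len <- chrom_length(build, ch)
      if (any(s$start < 0) || any(s$end > len))
        stop("sample ", sample_id, ": segment outside ", ch,
             " bounds [0, ", len, ")")
      if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)]))
        stop("sample ", sample_id, ": overlapping segments on ", ch)
    }
  }
  if (is.null(gaps)) {
    gaps <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  } else {
    gaps <- gaps[, c("chrom", "start", "end")]
    gaps$chrom <- as.character(gaps$chrom)
  }
  structure(
    list(sample_id = as.character(sample_id),
         purity = as.numeric(purity), ploidy = as.numeric(ploidy),
         segments = seg, gaps = gaps),
    class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("<cn_profile> ", x$sample_id, ": ", nrow(x$segments), " segments on ",
      length(unique(x$segments$chrom)), " chromosomes",
      if (!is.na(x$purity)) paste0(", purity ", x$purity) else "",
      if (!is.na(x$ploidy)) paste0(", ploidy ", x$ploidy) else "", "\n",
      sep = "")
  invisible(x)
}

# net arm overlap of [start, end) on one chromosome: c(p, q) bp observed,
# i.e. arm overlap minus any recorded unobserved gap territory
arm_overlap_net <- function(build, chrom, start, end, gaps = NULL) {
  a <- arms_of_chrom(build, chrom)
  out <- c(p = 0, q = 0)
  for (arm in c("p", "q")) {
    r <- a[a$arm == arm, ]
    lo <- max(start, r$start); hi <- min(end, r$end)
    bp <- max(0, hi - lo)
    if (bp > 0 && !is.null(gaps) && nrow(gaps)) {
      g <- gaps[gaps$chrom == chrom, , drop = FALSE]
      if (nrow(g)) {
        glo <- pmax(g$start, lo); ghi <- pmin(g$end, hi)
        bp <- bp - sum(pmax(0, ghi - glo))
      }
    }
    out[[arm]] <- bp
  }
  out
}

#' Observed genome of a profile
#'
#' The observed genome is the territory actually covered by segments on the
#' arms of included chromosomes (centromere overlap and recorded coverage
#' gaps excluded). It is the denominator for PLOH and PCNA, so scores adapt
#' to the fraction of the genome that could actually be sequenced.
#'
#' @param profile A [cn_profile()].
#' @param build A [genome_build()].
#' @return Observed territory in bp.
#' @export
observed_genome_bp <- function(profile, build) {
  seg <- profile$segments
  seg <- seg[seg$chrom %in% build$included, , drop = FALSE]
  if (!nrow(seg)) return(0)
  tot <- 0
  for (i in seq_len(nrow(seg))) {
    tot <- tot + sum(arm_overlap_net(build, seg$chrom[i], seg$start[i],
                                     seg$end[i], profile$gaps))
  }
  tot
}

#' Read allele-specific segmentation into profiles
#'
#' Reads a tab-delimited segmentation table with columns `sample`,
#' `chromosome`, `start`, `end`, `total_cn`, `minor_cn` (coordinates 1-based
#' inclusive on disk). Optional comment lines `#purity=<x>` and
#' `#ploidy=<y>` apply to the next sample appearing below them; a sidecar
#' metadata table (`sample`, `purity`, `ploidy`) may be given instead.
#' Scoring does not require purity or ploidy; missing values stay `NA`.
#'
#' Segments on chromosomes excluded from the build's scored set are dropped
#' and counted in the load report (attribute `"load_report"` of the result);
#' segments on chromosomes absent from the build altogether, overlapping
#' segments, and rows violating the minor-allele invariant are rejected
#' with an error naming the offender.
#'
#' @param path Path to the segmentation file.
#' @param build A [genome_build()].
#' @param metadata Optional `data.frame` with columns `sample`, `purity`,
#'   `ploidy`.
#' @return Named list of [cn_profile()] (possibly empty), with attribute
#'   `load_report`: a list with `n_rows`, `n_dropped_excluded_chrom`,
#'   `samples`.
#' @export
read_segmentation <- function(path, build, metadata = NULL) {
  lines <- readLines(path)
  meta <- list()
  if (length(lines)) {
    # associate #purity=/#ploidy= lines with the first sample named below
    hdr_meta <- grep("^#(purity|ploidy)=", lines, value = FALSE)
    if (length(hdr_meta)) {
      non_comment <- which(!grepl("^#", lines))
      non_comment <- non_comment[-1]  # skip header row
      for (i in hdr_meta) {
        nxt <- non_comment[non_comment > i]
        if (!length(nxt)) next
        fields <- strsplit(lines[nxt[1]], "\t")[[1]]
        key <- sub("^#(purity|ploidy)=.*$", "\\1", lines[i])
        val <- as.numeric(sub("^#(purity|ploidy)=", "", lines[i]))
        samp <- fields[1]
        if (is.null(meta[[samp]])) meta[[samp]] <- list()
        meta[[samp]][[key]] <- val
      }
    }
  }
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!nrow(tab)) {
    out <- list()
    attr(out, "load_report") <- list(n_rows = 0L,
                                     n_dropped_excluded_chrom = 0L,
                                     samples = character())
    return(out)
  }
  req <- c("sample", "chromosome", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("segmentation ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("start", "end", "total_cn", "minor_cn")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("segmentation row ", bad, " (sample ", tab$sample[bad],
           "): non-numeric ", col, " value '", tab[[col]][bad], "'")
    }
    tab[[col]] <- v
  }
  tab$sample <- as.character(tab$sample)
  tab$chromosome <- as.character(tab$chromosome)

  unknown <- setdiff(unique(tab$chromosome), build$chromosomes$chrom)
  if (length(unknown))
    stop("segmentation ", path, ": chromosome(s) not in build '", build$name,
         "': ", paste(unknown, collapse = ", "))
  excluded <- !(tab$chromosome %in% build$included)
  n_dropped <- sum(excluded)
  tab <- tab[!excluded, , drop = FALSE]

  profiles <- list()
  for (samp in unique(tab$sample)) {
    rows <- tab[tab$sample == samp, , drop = FALSE]
    segs <- data.frame(chrom = rows$chromosome,
                       start = rows$start - 1,  # 1-based inclusive -> 0-based
                       end = rows$end,
                       total_cn = rows$total_cn,
                       minor_cn = rows$minor_cn,
                       stringsAsFactors = FALSE)
    purity <- ploidy <- NA_real_
    if (!is.null(meta[[samp]])) {
      if (!is.null(meta[[samp]]$purity)) purity <- meta[[samp]]$purity
      if (!is.null(meta[[samp]]$ploidy)) ploidy <- meta[[samp]]$ploidy
    }
    if (!is.null(metadata)) {
      m <- metadata[metadata$sample == samp, , drop = FALSE]
      if (nrow(m)) {
        if ("purity" %in% names(m)) purity <- as.numeric(m$purity[1])
        if ("ploidy" %in% names(m)) ploidy <- as.numeric(m$ploidy[1])
      }
    }
    profiles[[samp]] <- cn_profile(samp, segs, build,
                                   purity = purity, ploidy = ploidy)
  }
  attr(profiles, "load_report") <- list(
    n_rows = nrow(tab) + n_dropped,
    n_dropped_excluded_chrom = n_dropped,
    samples = names(profiles))
  profiles
}

#' Write profiles back to the segmentation TSV dialect
#'
#' Inverse of [read_segmentation()]: emits 1-based inclusive coordinates and
#' per-sample `#purity=`/`#ploidy=` comment lines where known. Recorded
#' coverage gaps (from [merge_equal_state_runs()]) are not representable in
#' the flat dialect, so profiles carrying gaps are refused.
#'
#' @param profiles List of [cn_profile()] (or a single profile).
#' @param path Output path.
#' @export
write_segmentation <- function(profiles, path) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample", "chromosome", "start", "end",
                     "total_cn", "minor_cn"), collapse = "\t"), con)
  for (p in profiles) {
    if (nrow(p$gaps))
      stop("profile ", p$sample_id,
           " carries merged coverage gaps; not representable in the flat dialect")
    if (!is.na(p$purity)) writeLines(sprintf("#purity=%.6g", p$purity), con)
    if (!is.na(p$ploidy)) writeLines(sprintf("#ploidy=%.6g", p$ploidy), con)
    s <- p$segments
    if (nrow(s))
      writeLines(sprintf("%s\t%s\t%d\t%d\t%d\t%d", p$sample_id, s$chrom,
                         as.integer(s$start + 1), as.integer(s$end),
                         as.integer(s$total_cn), as.integer(s$minor_cn)), con)
  }
  invisible(path)
}

#' Fuse runs of equal allele-specific state
#'
#' Consecutive same-chromosome segments with identical `(total_cn,
#' minor_cn)` separated by an unobserved gap of at most `max_gap_bp` are
#' fused into one segment spanning both. The fused gap is recorded in the
#' profile's `gaps` table: it counts toward the segment's span (so the
#' region-size filters see the biological event size) but not toward the
#' observed genome (coverage completeness is unchanged). The operation is
#' idempotent and never changes the per-base state of observed territory.
#'
#' Segmentation of degraded FFPE material is patchy; without this fusion a
#' single large event broken by small coverage holes would fall below the
#' region-size filters.
#'
#' @param profile A [cn_profile()].
#' @param max_gap_bp Largest unobserved gap fused across (default 1 Mb);
#'   `0` fuses only strictly adjacent equal-state segments.
#' @return A [cn_profile()] with fused segments and updated `gaps`.
#' @export
merge_equal_state_runs <- function(profile, max_gap_bp = 1e6) {
  seg <- profile$segments
  n <- nrow(seg)
  if (n < 2L) return(profile)
  # segments are sorted by (chrom, start); fuse row i+1 into row i when the
  # chromosome and state match and the unobserved gap is small enough
  chrom <- seg$chrom; start <- seg$start; end <- seg$end
  fuse <- chrom[-1] == chrom[-n] &
    seg$total_cn[-1] == seg$total_cn[-n] &
    seg$minor_cn[-1] == seg$minor_cn[-n] &
    (start[-1] - end[-n]) <= max_gap_bp
  if (!any(fuse)) return(profile)
  first <- which(c(TRUE, !fuse))
  last <- c(first[-1] - 1L, n)
  seg2 <- data.frame(chrom = chrom[first], start = start[first],
                     end = end[last], total_cn = seg$total_cn[first],
                     minor_cn = seg$minor_cn[first], stringsAsFactors = FALSE)
  gi <- which(fuse & (start[-1] - end[-n]) > 0)  # real coverage holes fused over
  new_gaps <- data.frame(chrom = chrom[gi], start = end[gi],
                         end = start[gi + 1L], stringsAsFactors = FALSE)
  gaps2 <- rbind(profile$gaps, new_gaps)
  gaps2 <- gaps2[order(match(gaps2$chrom, unique(seg2$chrom)), gaps2$start),
                 , drop = FALSE]
  out <- profile
  out$segments <- seg2
  out$gaps <- gaps2
  rownames(out$segments) <- rownames(out$gaps) <- NULL
  out
}

fmt4 <- function(x) ifelse(is.na(x), "", sprintf("%.4f", x))

results_table <- function(results) {
  rows <- lapply(results, function(r) {
    ev <- isTRUE(r$evaluable)
    data.frame(
      sample = r$sample_id,
      ploh_pct = if (ev) fmt4(r$ploh_pct) else "",
      pcna_pct = if (ev) fmt4(r$pcna_pct) else "",
      ptcna_pct = if (ev) fmt4(r$ptcna_pct) else "",
      gis = if (ev) fmt4(r$gis) else "",
      evaluable = tolower(as.character(r$evaluable)),
      gi_status = if (isTRUE(r$evaluable))
        ifelse(isTRUE(r$gi_positive), "positive", "negative") else "",
      brca_status = if (is.null(r$brca)) "unknown" else r$brca,
      hrd_status = if (is.null(r$hrd_status)) "" else r$hrd_status,
      observed_genome_bp = sprintf("%.0f", r$observed_genome_bp),
      observed_fraction = fmt4(r$observed_fraction),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write scoring results
#'
#' TSV: one row per sample with the three components, the GIS, evaluability,
#' GI/BRCA/HRD status and the observed-genome accounting; numbers with 4
#' decimal places; unevaluable samples have empty score fields. JSON adds
#' the per-chromosome expected states and the contributing regions of each
#' component.
#'
#' @param results List of results from [compute_gis()]/[call_hrd()] (each a
#'   `gis_result`, optionally with `brca`/`hrd_status` fields filled in).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(results, "gis_result")) results <- list(results)
  if (format == "tsv") {
    tab <- results_table(results)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    out <- lapply(results, function(r) {
      list(sample = r$sample_id,
           ploh_pct = round_or_null(r$ploh_pct),
           pcna_pct = round_or_null(r$pcna_pct),
           ptcna_pct = round_or_null(r$ptcna_pct),
           gis = round_or_null(r$gis),
           evaluable = r$evaluable,
           gi_status = if (isTRUE(r$evaluable))
             ifelse(isTRUE(r$gi_positive), "positive", "negative") else NULL,
           brca_status = if (is.null(r$brca)) "unknown" else r$brca,
           hrd_status = if (is.null(r$hrd_status)) NULL else r$hrd_status,
           observed_genome_bp = r$observed_genome_bp,
           observed_fraction = round_or_null(r$observed_fraction),
           expected_states = r$expected_states,
           contributing_regions = list(
             ploh = r$ploh_regions, pcna = r$pcna_regions,
             telomeres = r$telomeres))
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", na = "null")
  }
  invisible(path)
}

round_or_null <- function(x) if (is.null(x) || is.na(x)) NULL else round(x, 4)

#' Read scoring results back from JSON
#'
#' Round-trip companion of [write_results()] (JSON format); values come
#' back at the serialized 4-decimal precision.
#'
#' @param path Path to a JSON results file.
#' @return List of result records (one list per sample).
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
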