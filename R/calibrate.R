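#' Confusion table against a reference assay
#'
#' Counts are oriented with the reference assay as truth: `tp` = positive
#' by both, `fp` = positive by the score only, `fn` = positive by the
#' reference only, `tn` = negative by both.
#'
#' @param tp,fp,fn,tn Non-negative integer counts; total must be positive.
#' @return A list of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (sum(counts) <= 0) stop("confusion table must have a positive total")
  structure(as.list(counts), class = "confusion_table")
}

as_confusion <- function(t) {
  if (inherits(t, "confusion_table")) return(t)
  if (is.numeric(t) && length(t) == 4)
    return(confusion_table(t[[1]], t[[2]], t[[3]], t[[4]]))
  stop("expected a confusion_table or a numeric vector (tp, fp, fn, tn)")
}

#' Cohen's kappa of a confusion table
#'
#' Chance-corrected agreement between the score's binary call and the
#' reference status: `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (tp + tn)/n` and chance agreement
#' `p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / n^2`. When all mass sits in
#' one agreement cell (`p_e == 1`), kappa is 1 if agreement is perfect and
#' undefined otherwise (an error).
#'
#' @param t A [confusion_table()] or numeric `c(tp, fp, fn, tn)`.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(t) {
  t <- as_confusion(t)
  n <- t$tp + t$fp + t$fn + t$tn
  p_o <- (t$tp + t$tn) / n
  p_e <- ((t$tp + t$fp) * (t$tp + t$fn) + (t$fn + t$tn) * (t$fp + t$tn)) / n^2
  if (p_e >= 1) {
    if (p_o == 1) return(1)
    stop("kappa undefined: degenerate marginals with imperfect agreement")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Sensitivity, specificity, PPV, NPV and concordance
#'
#' Standard diagnostic agreement statistics of a confusion table. A
#' statistic whose denominator is zero is undefined and reported as `NA`,
#' never as 0.
#'
#' @param t A [confusion_table()] or numeric `c(tp, fp, fn, tn)`.
#' @return Named list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `concordance`.
#' @export
confusion_stats <- function(t) {
  t <- as_confusion(t)
  n <- t$tp + t$fp + t$fn + t$tn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = safe_div(t$tp, t$tp + t$fn),
       specificity = safe_div(t$tn, t$tn + t$fp),
       ppv = safe_div(t$tp, t$tp + t$fp),
       npv = safe_div(t$tn, t$tn + t$fn),
       concordance = (t$tp + t$tn) / n)
}

#' Kappa-maximizing cutoff scan
#'
#' Sweeps candidate cutoffs over an integer grid; at each cutoff `c` a
#' sample is predicted positive when `gis >= c`, and Cohen's kappa plus the
#' diagnostic statistics against the reference labels are computed. The
#' maximizing interval is the first maximal contiguous grid run attaining
#' the maximum kappa; the selected cutoff is its lower end, which
#' maximizes the number of patients classified positive (and hence
#' eligible to benefit) among equally concordant cutoffs.
#'
#' Samples with undefined (`NA`) GIS are excluded from the scan and counted
#' in the dropout report.
#'
#' @param scores `data.frame` with columns `sample` and `gis`.
#' @param labels `data.frame` with columns `sample` and `reference_status`
#'   (`"positive"`/`"negative"`, or logical).
#' @param grid Integer grid of candidate cutoffs (default `0:300`, the
#'   score's range).
#' @return An object of class `cutoff_scan`: `scan` (per-cutoff table),
#'   `max_kappa`, `interval` (`c(lo, hi)`), `selected_cutoff`, `n_used`,
#'   `dropout` (list with `n_unevaluable` and the dropped sample ids).
#' @export
scan_cutoffs <- function(scores, labels, grid = 0:300) {
  stopifnot(is.data.frame(scores), is.data.frame(labels))
  if (!all(c("sample", "gis") %in% names(scores)))
    stop("scores must have columns sample, gis")
  if (!all(c("sample", "reference_status") %in% names(labels)))
    stop("labels must have columns sample, reference_status")
  if (!length(grid)) stop("empty cutoff grid")
  grid <- sort(unique(as.integer(grid)))
  if (anyDuplicated(scores$sample))
    stop("duplicated sample id in scores: ",
         scores$sample[duplicated(scores$sample)][1])
  if (anyDuplicated(labels$sample))
    stop("duplicated sample id in labels: ",
         labels$sample[duplicated(labels$sample)][1])
  miss <- setdiff(scores$sample, labels$sample)
  if (length(miss))
    stop("scored sample(s) without a reference label: ",
         paste(utils::head(miss, 5), collapse = ", "))

  ref <- labels$reference_status[match(scores$sample, labels$sample)]
  if (is.character(ref) || is.factor(ref)) {
    ref <- as.character(ref)
    if (!all(ref %in% c("positive", "negative")))
      stop("reference_status must be 'positive' or 'negative'")
    ref <- ref == "positive"
  }
  ref <- as.logical(ref)

  dropped <- is.na(scores$gis)
  dropout <- list(n_unevaluable = sum(dropped),
                  samples = scores$sample[dropped])
  gis <- scores$gis[!dropped]
  ref <- ref[!dropped]
  if (!length(gis)) stop("no evaluable sample to scan")
  if (all(ref) || !any(ref))
    stop("single-class reference labels: kappa is degenerate at every cutoff")

  n <- length(gis)
  npos <- sum(ref); nneg <- n - npos
  tp <- colSums(outer(gis[ref], grid, ">="))
  fp <- colSums(outer(gis[!ref], grid, ">="))
  fn <- npos - tp; tn <- nneg - fp
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- ifelse(p_e >= 1, ifelse(p_o == 1, 1, NA_real_),
                  (p_o - p_e) / (1 - p_e))
  safe <- function(num, den) { r <- num / den; r[den <= 0] <- NA_real_; r }
  scan <- data.frame(cutoff = grid, kappa = kappa,
                     sensitivity = tp / npos, specificity = tn / nneg,
                     ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
                     concordance = p_o, tp = tp, fp = fp, fn = fn, tn = tn)
  if (all(is.na(scan$kappa)))
    stop("kappa undefined at every cutoff")
  max_kappa <- max(scan$kappa, na.rm = TRUE)
  at_max <- !is.na(scan$kappa) & (scan$kappa >= max_kappa - 1e-12)
  # first maximal contiguous run attaining the maximum
  r <- rle(at_max)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  first <- which(r$values)[1]
  lo <- grid[run_start[first]]
  hi <- grid[run_end[first]]
  structure(
    list(scan = scan, max_kappa = max_kappa, interval = c(lo = lo, hi = hi),
         selected_cutoff = lo, n_used = length(gis), dropout = dropout),
    class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat("<cutoff_scan> ", nrow(x$scan), " candidate cutoffs, n = ", x$n_used,
      if (x$dropout$n_unevaluable)
        paste0(" (", x$dropout$n_unevaluable, " unevaluable excluded)") else "",
      "\n", sep = "")
  cat(sprintf("  max kappa %.4f on [%d, %d]; selected cutoff %d\n",
              x$max_kappa, x$interval[["lo"]], x$interval[["hi"]],
              x$selected_cutoff))
  i <- match(x$selected_cutoff, x$scan$cutoff)
  cat(sprintf("  at selection: sens %.3f spec %.3f ppv %.3f npv %.3f conc %.3f\n",
              x$scan$sensitivity[i], x$scan$specificity[i], x$scan$ppv[i],
              x$scan$npv[i], x$scan$concordance[i]))
  invisible(x)
}

#' Minimum sequencing depth to detect a variant
#'
#' Smallest number of unique reads `N` such that at least `min_alt_reads`
#' of them carry the variant with probability at least `sensitivity`,
#' under an exact binomial model with per-read success probability `af`
#' (the allele frequency). No normal approximation is used.
#'
#' @param af Allele frequency in `(0, 1]`.
#' @param min_alt_reads Minimum variant-supporting reads required by the
#'   caller (>= 1).
#' @param sensitivity Required detection probability in `(0, 1)`.
#' @return Integer depth.
#' @export
min_depth_for_detection <- function(af, min_alt_reads, sensitivity) {
  stopifnot(af > 0, af <= 1, min_alt_reads >= 1,
            min_alt_reads == round(min_alt_reads),
            sensitivity > 0, sensitivity < 1)
  n <- as.integer(min_alt_reads)
  # P(X >= k) is non-decreasing in N, so the first N reaching the target
  # sensitivity is the answer
  repeat {
    p <- stats::pbinom(min_alt_reads - 1, n, af, lower.tail = FALSE)
    if (p >= sensitivity) return(n)
    n <- n + 1L
  }
}

#' Write a cutoff scan to disk
#'
#' Emits the per-cutoff table as TSV and a JSON summary (max kappa,
#' maximizing interval, selected cutoff, dropout report).
#'
#' @param scan A `cutoff_scan` from [scan_cutoffs()].
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_cutoff_scan <- function(scan, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(scan$scan, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(max_kappa = scan$max_kappa,
           interval = list(lo = scan$interval[["lo"]],
                           hi = scan$interval[["hi"]]),
           selected_cutoff = scan$selected_cutoff,
           n_used = scan$n_used,
           dropout = scan$dropout),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(scan)
}
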