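#' Construct a genome build
#'
#' A `genome_build` is the coordinate frame for all scoring rules: it holds
#' chromosome lengths, arm boundaries (the centromere interval separates the
#' p and q arm), and per-telomere assembly flags. Some telomeres are not
#' sufficiently assembled in older reference builds (e.g. the p arms of the
#' acrocentric chromosomes in hg19), so copy-number alteration at those
#' termini cannot be assessed; the flags remove them from the PTCNA
#' denominator.
#'
#' All internal coordinates are 0-based half-open. File loaders
#' ([load_arm_table()], [load_cytoband()]) convert from their on-disk
#' conventions at the boundary.
#'
#' @param name Build label, e.g. `"hg19"`.
#' @param chromosomes `data.frame` with columns `chrom` (character) and
#'   `length` (positive integer bp).
#' @param arms `data.frame` with columns `chrom`, `arm` (`"p"` or `"q"`),
#'   `start`, `end` (0-based half-open) and `telomere_assembled` (logical).
#'   For every included chromosome the p arm must start at 0, the q arm must
#'   end at the chromosome length, and the interval between p-arm end and
#'   q-arm start is the centromere (scored as part of neither arm).
#' @param included Character vector of chromosome names entering the score;
#'   defaults to all chromosomes in `chromosomes`.
#' @return An object of class `genome_build`.
#' @export
genome_build <- function(name, chromosomes, arms, included = chromosomes$chrom) {
  stopifnot(is.data.frame(chromosomes), is.data.frame(arms))
  req_c <- c("chrom", "length")
  req_a <- c("chrom", "arm", "start", "end", "telomere_assembled")
  if (!all(req_c %in% names(chromosomes)))
    stop("chromosomes must have columns: ", paste(req_c, collapse = ", "))
  if (!all(req_a %in% names(arms)))
    stop("arms must have columns: ", paste(req_a, collapse = ", "))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  arms$chrom <- as.character(arms$chrom)
  arms$arm <- as.character(arms$arm)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicated chromosome names")
  if (!all(arms$arm %in% c("p", "q")))
    stop("arm must be 'p' or 'q'")
  included <- as.character(included)
  if (!all(included %in% chromosomes$chrom))
    stop("included chromosomes absent from chromosome table: ",
         paste(setdiff(included, chromosomes$chrom), collapse = ", "))

  for (ch in included) {
    len <- chromosomes$length[chromosomes$chrom == ch]
    if (!is.finite(len) || len <= 0)
      stop("chromosome ", ch, ": non-positive length")
    a <- arms[arms$chrom == ch, , drop = FALSE]
    if (nrow(a) != 2L || !setequal(a$arm, c("p", "q")))
      stop("chromosome ", ch, ": needs exactly one p and one q arm")
    p <- a[a$arm == "p", ]
    q <- a[a$arm == "q", ]
    if (any(a$start >= a$end))
      stop("chromosome ", ch, ": arm with start >= end")
    if (p$start != 0)
      stop("chromosome ", ch, ": p arm must start at 0")
    if (q$end != len)
      stop("chromosome ", ch, ": q arm must end at chromosome length (", len, ")")
    if (p$end > q$start)
      stop("chromosome ", ch, ": p arm overlaps q arm")
  }

  build <- structure(
    list(name = name,
         chromosomes = chromosomes[, req_c],
         arms = arms[, req_a],
         included = included),
    class = "genome_build")
  build
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build> ", x$name, ": ", nrow(x$chromosomes), " chromosomes, ",
      length(x$included), " included, assembled arm territory ",
      format(assembled_territory(x), big.mark = ",", scientific = FALSE),
      " bp\n", sep = "")
  invisible(x)
}

chrom_length <- function(build, chrom) {
  i <- match(chrom, build$chromosomes$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  build$chromosomes$length[i]
}

arms_of_chrom <- function(build, chrom) {
  build$arms[build$arms$chrom == chrom, , drop = FALSE]
}

#' Total assembled reference territory of a build
#'
#' Sum of arm lengths over included chromosomes (centromeres excluded).
#' This is the denominator of the observed-genome fraction used for
#' evaluability.
#'
#' @param build A [genome_build()].
#' @return Territory in bp.
#' @export
assembled_territory <- function(build) {
  a <- build$arms[build$arms$chrom %in% build$included, ]
  sum(as.numeric(a$end - a$start))
}

#' Attribute an interval to chromosome arms
#'
#' Splits a genomic interval into the number of bases overlapping the p arm,
#' the q arm and the centromere of its chromosome. The three overlap lengths
#' always sum to the interval length. Scoring rules are arm-based, so
#' segment territory falling into the centromere gap contributes to none of
#' the components.
#'
#' @param build A [genome_build()].
#' @param chrom Chromosome name (must exist in the build).
#' @param start,end 0-based half-open interval, within chromosome bounds.
#' @return Named numeric vector `c(p=, q=, centromere=)` in bp.
#' @export
arm_of <- function(build, chrom, start, end) {
  len <- chrom_length(build, chrom)
  if (!is.finite(start) || !is.finite(end) || start >= end)
    stop("invalid interval [", start, ", ", end, "): start must be < end")
  if (start < 0 || end > len)
    stop("interval [", start, ", ", end, ") outside chromosome ", chrom,
         " bounds [0, ", len, ")")
  a <- arms_of_chrom(build, chrom)
  p <- a[a$arm == "p", ]
  q <- a[a$arm == "q", ]
  ov <- function(s, e) max(0, min(end, e) - max(start, s))
  pbp <- ov(p$start, p$end)
  qbp <- ov(q$start, q$end)
  c(p = pbp, q = qbp, centromere = (end - start) - pbp - qbp)
}

read_tsv_file <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

parse_flag <- function(x) {
  v <- tolower(as.character(x))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Load a genome build from an arm-definition table
#'
#' Reads a tab-delimited file with columns `chromosome`, `length`,
#' `centromere_start`, `centromere_end`, `p_telomere_assembled`,
#' `q_telomere_assembled`. Coordinates on disk are 1-based inclusive and
#' converted to the internal 0-based half-open convention: the p arm is
#' `[0, centromere_start - 1)` and the q arm `[centromere_end, length)`.
#' Chromosomes not listed are excluded from scoring.
#'
#' @param path Path to the arm table.
#' @param name Build label; defaults to the file name.
#' @return A [genome_build()].
#' @export
load_arm_table <- function(path, name = basename(path)) {
  tab <- read_tsv_file(path)
  req <- c("chromosome", "length", "centromere_start", "centromere_end",
           "p_telomere_assembled", "q_telomere_assembled")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("arm table ", path, " missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("length", "centromere_start", "centromere_end")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("arm table row ", bad, " (", tab$chromosome[bad],
           "): non-numeric ", col, " value '", tab[[col]][bad], "'")
    }
    tab[[col]] <- v
  }
  for (col in c("p_telomere_assembled", "q_telomere_assembled")) {
    v <- parse_flag(tab[[col]])
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("arm table row ", bad, " (", tab$chromosome[bad],
           "): unparseable ", col, " value '", tab[[col]][bad], "'")
    }
    tab[[col]] <- v
  }
  bad <- which(tab$centromere_end < tab$centromere_start |
               tab$centromere_start < 2 |
               tab$centromere_end > tab$length - 1)
  if (length(bad))
    stop("arm table row ", bad[1], " (", tab$chromosome[bad[1]],
         "): centromere [", tab$centromere_start[bad[1]], ", ",
         tab$centromere_end[bad[1]], "] invalid or outside chromosome")

  chromosomes <- data.frame(chrom = as.character(tab$chromosome),
                            length = tab$length,
                            stringsAsFactors = FALSE)
  arms <- rbind(
    data.frame(chrom = chromosomes$chrom, arm = "p",
               start = 0, end = tab$centromere_start - 1,
               telomere_assembled = tab$p_telomere_assembled,
               stringsAsFactors = FALSE),
    data.frame(chrom = chromosomes$chrom, arm = "q",
               start = tab$centromere_end, end = tab$length,
               telomere_assembled = tab$q_telomere_assembled,
               stringsAsFactors = FALSE))
  genome_build(name, chromosomes, arms)
}

#' Default acrocentric chromosomes whose p telomere is unassembled in hg19
#' @export
acrocentric_p_default <- c("chr13", "chr14", "chr15", "chr21", "chr22")

#' Load a genome build from a UCSC cytoband file
#'
#' Reads a UCSC-style cytoBand table (columns chrom, start, end, band name,
#' Giemsa stain; 0-based half-open as distributed by UCSC). Arm boundaries
#' are derived from the `acen` stain interval of each chromosome (the union
#' of the p-side and q-side acen bands) and the chromosome length is the
#' largest band end. Chromosomes without an acen band are excluded with a
#' warning. Telomere-assembly flags default to assembled except for the p
#' arms of a configurable acrocentric list.
#'
#' @param path Path to the cytoband file (no header).
#' @param name Build label; defaults to the file name.
#' @param acrocentric_p Chromosomes whose p telomere is marked unassembled.
#' @param included Optional subset of chromosomes to score; defaults to all
#'   chromosomes with an acen band.
#' @return A [genome_build()].
#' @export
load_cytoband <- function(path, name = basename(path),
                          acrocentric_p = acrocentric_p_default,
                          included = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "band", "stain"))
  chroms <- unique(tab$chrom)
  rows_c <- list(); rows_a <- list(); skipped <- character()
  for (ch in chroms) {
    b <- tab[tab$chrom == ch, , drop = FALSE]
    len <- max(b$end)
    acen <- b[b$stain == "acen", , drop = FALSE]
    if (nrow(acen) == 0L) {
      skipped <- c(skipped, ch)
      next
    }
    cen_start <- min(acen$start)
    cen_end <- max(acen$end)
    if (cen_start <= 0 || cen_end >= len) {
      # no arm territory on one side: cannot form two arms
      skipped <- c(skipped, ch)
      next
    }
    rows_c[[ch]] <- data.frame(chrom = ch, length = len,
                               stringsAsFactors = FALSE)
    rows_a[[ch]] <- data.frame(
      chrom = ch, arm = c("p", "q"),
      start = c(0, cen_end), end = c(cen_start, len),
      telomere_assembled = c(!(ch %in% acrocentric_p), TRUE),
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("cytoband file ", path, ": no acen band for ",
            paste(skipped, collapse = ", "), "; excluded from the build")
  if (!length(rows_c))
    stop("cytoband file ", path, ": no chromosome with an acen band")
  chromosomes <- do.call(rbind, rows_c)
  arms <- do.call(rbind, rows_a)
  rownames(chromosomes) <- rownames(arms) <- NULL
  if (is.null(included)) included <- chromosomes$chrom
  genome_build(name, chromosomes, arms, included = included)
}

#' The hg19 genome build bundled with the package
#'
#' Chromosome lengths and centromere gap coordinates for GRCh37/hg19
#' (autosomes 1-22, X and Y), read from the arm table shipped in
#' `inst/extdata/hg19_arms.tsv`. The p telomeres of the acrocentric
#' chromosomes (13, 14, 15, 21, 22) are flagged unassembled. By default the
#' scored chromosome set is chr1-chr22 plus chrX; chrY is present in the
#' build but excluded from scoring.
#'
#' @param include_y Include chrY in the scored chromosome set.
#' @return A [genome_build()].
#' @export
hg19_build <- function(include_y = FALSE) {
  path <- system.file("extdata", "hg19_arms.tsv", package = "hrdgis",
                      mustWork = TRUE)
  b <- load_arm_table(path, name = "hg19")
  incl <- b$chromosomes$chrom
  if (!include_y) incl <- setdiff(incl, "chrY")
  b$included <- incl
  b
}
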