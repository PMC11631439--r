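#' Depth profile over 1-kb windows
#'
#' Container for per-window mean sequencing depth. Windows are BED-style
#' 0-based half-open intervals that tile each chromosome in order; the
#' window size is fixed (default 1 kb, the last window of a chromosome may
#' be short).
#'
#' @param df data.frame with columns chrom, start, end, depth.
#' @param sample optional sample id.
#' @return object of class `depth_profile` (a data.frame).
#' @export
depth_profile <- function(df, sample = NA_character_) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end", "depth") %in% names(df)),
            all(df$end > df$start), all(df$depth >= 0))
  o <- order(match(df$chrom, unique(df$chrom)), df$start)
  df <- df[o, c("chrom", "start", "end", "depth")]
  rownames(df) <- NULL
  structure(df, class = c("depth_profile", "data.frame"), sample = sample)
}

#' Read a per-window depth table
#'
#' Reads a BED-like TSV (`chrom start end depth`, no header or header) into
#' a [depth_profile()].
#'
#' @param path TSV/BED path.
#' @param sample optional sample id.
#' @export
read_depth_profile <- function(path, sample = NA_character_) {
  first <- readLines(path, n = 1)
  header <- grepl("chrom", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!header) names(df) <- c("chrom", "start", "end", "depth")
  depth_profile(df, sample = sample)
}

#' Normalize a depth profile to a genome-wide center
#'
#' Divides each window's raw depth by a genome-wide center so that
#' copy-neutral windows sit near 1. The default center is the median of
#' all window depths (robust to aneuploid chromosomes); `mode` instead
#' takes the mode of a density-smoothed depth histogram, which is safer
#' when a large fraction of the genome deviates from one copy.
#'
#' @param profile a [depth_profile()].
#' @param center_method "median" or "mode".
#' @return object of class `normalized_depth_track`: the profile with an
#'   `rd` column (normalized depth) and the center recorded as an
#'   attribute.
#' @export
normalize_depth <- function(profile, center_method = c("median", "mode")) {
  stopifnot(inherits(profile, "depth_profile"))
  center_method <- match.arg(center_method)
  d <- profile$depth
  if (!any(d > 0)) stop("all-zero depth profile; cannot normalize")
  center <- switch(center_method,
                   median = stats::median(d[d > 0]),
                   mode = {
                     dens <- stats::density(d[d > 0])
                     dens$x[which.max(dens$y)]
                   })
  out <- as.data.frame(profile)
  out$rd <- d / center
  structure(out, class = c("normalized_depth_track", "data.frame"),
            center = center, sample = attr(profile, "sample"))
}

#' Segment a normalized depth track into CNV regions
#'
#' Threshold-merge segmentation: windows with |RD - 1| > `delta` are CNV
#' windows; maximal runs of at least `min_windows` consecutive CNV windows
#' on a chromosome are merged into regions whose RD is the mean of the
#' member windows. A deliberately simple segmenter — the downstream
#' per-CDS and aneuploidy rules only need regions with a normalized depth.
#'
#' @param track a [normalize_depth()] result.
#' @param delta deviation threshold from RD 1 (default 0.25).
#' @param min_windows minimum run length (default 2).
#' @return data.frame of class `cnv_regions`: chrom, start, end (0-based
#'   half-open), n_windows, rd; sorted, non-overlapping.
#' @export
segment_cnv <- function(track, delta = 0.25, min_windows = 2) {
  stopifnot(inherits(track, "normalized_depth_track"), delta >= 0,
            min_windows >= 1)
  out <- lapply(split(seq_len(nrow(track)), track$chrom), function(idx) {
    idx <- idx[order(track$start[idx])]
    is_cnv <- abs(track$rd[idx] - 1) > delta
    r <- rle(is_cnv)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= min_windows
    if (!any(keep)) return(NULL)
    data.frame(chrom = track$chrom[idx[1]],
               start = track$start[idx[starts[keep]]],
               end = track$end[idx[ends[keep]]],
               n_windows = r$lengths[keep],
               rd = vapply(which(keep), function(k)
                 mean(track$rd[idx[starts[k]:ends[k]]]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_windows = integer(0), rd = numeric(0))
  out <- out[order(match(out$chrom, unique(track$chrom)), out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cnv_regions", "data.frame"),
            sample = attr(track, "sample"))
}

#' Per-position normalized depth given CNV regions
#'
#' Every reference position is assigned a normalized depth of exactly 1
#' unless it falls inside a detected CNV region, in which case it takes
#' the region's RD. Positions are 0-based; regions are half-open, so a
#' region's `end` position itself returns 1.
#'
#' @param regions a `cnv_regions` data.frame ([segment_cnv()]).
#' @param chrom chromosome id (scalar).
#' @param pos integer vector of 0-based positions.
#' @param chrom_lengths optional named vector for bounds checking.
#' @return numeric vector of normalized depths.
#' @export
position_rd <- function(regions, chrom, pos, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    if (is.null(len) || any(pos < 0 | pos >= len))
      stop("position outside chromosome bounds on ", chrom)
  }
  out <- rep(1, length(pos))
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(r))) {
    inside <- pos >= r$start[i] & pos < r$end[i]
    out[inside] <- r$rd[i]
  }
  out
}

#' Median normalized depth per coding sequence
#'
#' The copy-number summary of each CDS is the median of the per-position
#' normalized depth over all its positions (all exons pooled for
#' multi-exon CDS). A CDS intersecting no CNV region therefore scores
#' exactly 1. Computed on the run-length structure of the position-level
#' track, equivalent to the median over every base of the CDS.
#'
#' @param cds data.frame with columns chrom, start, end (0-based
#'   half-open) and a CDS id column `name`; multiple rows per name pool
#'   their positions.
#' @param regions a `cnv_regions` data.frame.
#' @return data.frame: name, median_rd.
#' @export
cds_median_rd <- function(cds, regions) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(cds)))
  if (any(cds$end <= cds$start)) stop("zero- or negative-length CDS interval")
  res <- vapply(split(seq_len(nrow(cds)), cds$name), function(rows) {
    vals <- numeric(0); lens <- numeric(0)
    for (i in rows) {
      pieces <- rd_pieces(regions, cds$chrom[i], cds$start[i], cds$end[i])
      vals <- c(vals, pieces$rd)
      lens <- c(lens, pieces$len)
    }
    rle_median(vals, lens)
  }, numeric(1))
  data.frame(name = names(res), median_rd = unname(res),
             stringsAsFactors = FALSE)
}

# piecewise-constant RD decomposition of [start, end) on a chromosome
rd_pieces <- function(regions, chrom, start, end) {
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  r <- r[r$end > start & r$start < end, , drop = FALSE]
  r <- r[order(r$start), , drop = FALSE]
  vals <- numeric(0); lens <- numeric(0)
  cur <- start
  for (i in seq_len(nrow(r))) {
    s <- max(r$start[i], start); e <- min(r$end[i], end)
    if (s > cur) { vals <- c(vals, 1); lens <- c(lens, s - cur) }
    vals <- c(vals, r$rd[i]); lens <- c(lens, e - s)
    cur <- e
  }
  if (cur < end) { vals <- c(vals, 1); lens <- c(lens, end - cur) }
  list(rd = vals, len = lens)
}

#' Call whole-chromosome aneuploidies from CNV regions
#'
#' A chromosome is aneuploid when strictly more than half of its length
#' lies inside CNV regions (gains and losses both count).
#'
#' @param regions a `cnv_regions` data.frame.
#' @param chrom_lengths named numeric vector (or two-column data.frame
#'   chrom/length) of chromosome lengths in bases.
#' @return data.frame: chrom, cnv_length, chrom_length, fraction, aneuploid.
#' @export
call_aneuploidy <- function(regions, chrom_lengths) {
  if (is.data.frame(chrom_lengths))
    chrom_lengths <- stats::setNames(chrom_lengths[[2]], chrom_lengths[[1]])
  chroms <- names(chrom_lengths)
  cnv_len <- vapply(chroms, function(ch) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    sum(r$end - r$start)
  }, numeric(1))
  fraction <- cnv_len / chrom_lengths
  data.frame(chrom = chroms,
             cnv_length = unname(cnv_len),
             chrom_length = unname(chrom_lengths),
             fraction = unname(fraction),
             aneuploid = unname(fraction > 0.5),
             stringsAsFactors = FALSE, row.names = NULL)
}
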