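#' Read and write BED / narrowPeak peak files
#'
#' Tab-separated, no header, 0-based half-open. `read_bed` accepts BED3 or
#' BED6; `read_narrowpeak` reads ENCODE narrowPeak (BED6+4) preserving
#' `signalValue`, `pValue`, `qValue` and `peak` (summit offset) when
#' present.
#'
#' @param path File path.
#' @param sizes A [chrom_sizes()] object.
#' @return A `GRanges`.
#' @export
read_bed <- function(path, sizes) {
  if (empty_file(path)) return(empty_granges(sizes))
  gr <- rtracklayer::import(path, format = "BED")
  set_genome(gr, sizes)
}

#' @rdname read_bed
#' @export
read_narrowpeak <- function(path, sizes) {
  if (empty_file(path)) return(empty_granges(sizes))
  extra <- c(signalValue = "numeric", pValue = "numeric",
             qValue = "numeric", peak = "integer")
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  set_genome(gr, sizes)
}

#' @rdname read_bed
#' @param x A `GRanges`; `name` and `score` metadata columns are written
#'   when present (BED6), otherwise BED3.
#' @export
write_bed <- function(x, path) {
  n <- length(x)
  tab <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
                    start = BiocGenerics::start(x) - 1L,
                    end = BiocGenerics::end(x))
  mc <- S4Vectors::mcols(x)
  if (any(c("name", "score") %in% names(mc))) {
    tab$name <- if ("name" %in% names(mc)) as.character(x$name) else "."
    tab$score <- if ("score" %in% names(mc)) fmt_num(x$score) else "0"
    tab$strand <- sub("\\*", ".", as.character(BiocGenerics::strand(x)))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_bed
#' @export
write_narrowpeak <- function(x, path) {
  n <- length(x)
  get_or <- function(col, default) {
    mc <- S4Vectors::mcols(x)
    if (col %in% names(mc)) mc[[col]] else rep(default, n)
  }
  tab <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
                    start = BiocGenerics::start(x) - 1L,
                    end = BiocGenerics::end(x),
                    name = as.character(get_or("name", ".")),
                    score = fmt_num(get_or("score", 0)),
                    strand = sub("\\*", ".", as.character(BiocGenerics::strand(x))),
                    signalValue = fmt_num(get_or("signalValue", 0)),
                    pValue = fmt_num(get_or("pValue", -1)),
                    qValue = fmt_num(get_or("qValue", -1)),
                    peak = get_or("peak", -1L))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Coverage values are serialized with 6 significant digits (text-format
# stability); in-memory comparisons in tests use much tighter tolerances.
fmt_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15, format(x, scientific = FALSE,
                                               trim = TRUE),
         sprintf("%.6g", x))
}

empty_file <- function(path) {
  file.exists(path) && file.size(path) == 0
}

empty_granges <- function(sizes) {
  GenomicRanges::GRanges(seqinfo = as_seqinfo(sizes))
}

#' Per-base normalized coverage track
#'
#' A `CoverageTrack` holds one run-length-encoded signal vector per
#' chromosome over the full chromosome extent (gaps are zero), a condition
#' label, and the reads-per-million normalization factor that was applied
#' (1 when the track is already normalized).
#'
#' @param cov An [IRanges::RleList], one numeric Rle per chromosome.
#' @param sizes A [chrom_sizes()] object.
#' @param label Condition label, e.g. `"limb_pos_H3K27ac"`.
#' @param norm_factor Normalization factor already applied.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(cov, sizes, label = "", norm_factor = 1) {
  stopifnot(inherits(sizes, "ChromSizes"))
  if (any(vapply(cov, function(r) any(S4Vectors::runValue(r) < 0), logical(1))))
    stop("coverage must be non-negative")
  if (!setequal(names(cov), names(sizes$lengths)))
    stop("coverage must be defined for every chromosome in ChromSizes")
  lens <- vapply(cov, length, numeric(1))[names(sizes$lengths)]
  if (any(lens != sizes$lengths))
    stop("coverage vectors must span the full chromosome lengths")
  structure(list(cov = cov[names(sizes$lengths)], sizes = sizes,
                 label = label, norm_factor = norm_factor),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack", sQuote(x$label), "over",
      length(x$cov), "chromosomes; norm factor", x$norm_factor, "\n")
  invisible(x)
}

#' Read a bedGraph coverage file
#'
#' Four columns (chrom, start, end, value), 0-based half-open, possibly
#' unsorted. Overlapping intervals are a format error (each base must have
#' a single defined value); gaps read as zero; negative values and
#' off-chromosome intervals are rejected.
#'
#' @param path File path.
#' @param sizes A [chrom_sizes()] object.
#' @param label Condition label stored on the track.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, sizes, label = basename(path)) {
  si <- as_seqinfo(sizes)
  if (empty_file(path)) {
    cov <- IRanges::RleList(lapply(sizes$lengths, function(l)
      S4Vectors::Rle(0, l)), compress = FALSE)
    return(coverage_track(cov, sizes, label = label))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- set_genome(gr, sizes)
  if (any(gr$score < 0)) stop("negative coverage value in ", path)
  if (!IRanges::isDisjoint(gr))
    stop("overlapping intervals in bedGraph ", path)
  cov <- GenomicRanges::coverage(gr, weight = "score")
  coverage_track(cov, sizes, label = label)
}

#' @rdname read_bedgraph
#' @param track A `CoverageTrack`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "CoverageTrack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$cov)) {
    r <- track$cov[[chrom]]
    vals <- S4Vectors::runValue(r)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, utils::head(ends, -1L))
    keep <- vals != 0
    if (!any(keep)) next
    lines <- sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                     sprintf("%.6g", vals[keep]))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Mean normalized coverage per region
#'
#' The region statistic is the arithmetic mean of the per-base signal over
#' the region (the default summary of coverage-quantification tools).
#'
#' @param regions A `GRanges` on the track's chromosomes.
#' @param track A [coverage_track()].
#' @return Numeric vector of mean signal, one value per region.
#' @export
quantify <- function(regions, track) {
  stopifnot(is(regions, "GRanges"), inherits(track, "CoverageTrack"))
  regions <- set_genome(regions, track$sizes)
  out <- numeric(length(regions))
  sn <- as.character(GenomeInfoDb::seqnames(regions))
  for (chrom in unique(sn)) {
    idx <- which(sn == chrom)
    v <- IRanges::Views(track$cov[[chrom]],
                        BiocGenerics::start(regions)[idx],
                        BiocGenerics::end(regions)[idx])
    out[idx] <- IRanges::viewSums(v) / BiocGenerics::width(regions)[idx]
  }
  out
}

#' Quantify several condition tracks into a signal matrix
#'
#' @param regions A `GRanges`.
#' @param tracks Named list of [coverage_track()]s (the condition order of
#'   the matrix columns).
#' @return Numeric matrix, regions x conditions.
#' @export
quantify_conditions <- function(regions, tracks) {
  stopifnot(length(names(tracks)) == length(tracks))
  m <- vapply(tracks, function(tr) quantify(regions, tr),
              numeric(length(regions)))
  if (length(regions) == 1L) m <- matrix(m, nrow = 1,
                                         dimnames = list(NULL, names(tracks)))
  m
}

#' Scale a coverage track by a reads-per-million factor
#'
#' Every value is divided by `million_scale`; the factor is recorded on the
#' track (composing with any factor already applied).
#'
#' @param track A [coverage_track()].
#' @param million_scale Positive scalar (millions of reads/tags).
#' @return A normalized `CoverageTrack`.
#' @export
normalize_track <- function(track, million_scale) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (length(million_scale) != 1L || is.na(million_scale) || million_scale <= 0)
    stop("million_scale must be a single positive number")
  cov <- IRanges::RleList(lapply(track$cov, function(r) r / million_scale),
                          compress = FALSE)
  coverage_track(cov, track$sizes, label = track$label,
                 norm_factor = track$norm_factor * million_scale)
}

#' Read / write a per-region signal matrix
#'
#' Tab-separated with header row `chrom start end <condition ...>`
#' (BED-style coordinates). Values are serialized with 6 significant
#' digits.
#'
#' @param path File path.
#' @param sizes A [chrom_sizes()] object.
#' @return A list with `regions` (`GRanges`) and `values` (matrix).
#' @export
read_signal_matrix <- function(path, sizes) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  regions <- gi(tab$chrom, tab$start, tab$end, sizes = sizes)
  values <- as.matrix(tab[, -(1:3), drop = FALSE])
  list(regions = regions, values = values)
}

#' @rdname read_signal_matrix
#' @param regions A `GRanges`.
#' @param values Numeric matrix with named columns (conditions).
#' @export
write_signal_matrix <- function(regions, values, path) {
  stopifnot(nrow(values) == length(regions), !is.null(colnames(values)))
  tab <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(regions)),
                    start = BiocGenerics::start(regions) - 1L,
                    end = BiocGenerics::end(regions), check.names = FALSE)
  for (cn in colnames(values)) tab[[cn]] <- sprintf("%.6g", values[, cn])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
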