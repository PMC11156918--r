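#' Chromosome sizes with autosome annotation
#'
#' A `ChromSizes` object records chromosome lengths (bp) and an autosome
#' flag per chromosome. Every interval operation in the package validates
#' and clips coordinates against it, and the autosome flag drives the
#' autosome-only filter of [top_k_enhancers()].
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#' @param autosome Optional named logical vector (same names as `lengths`).
#'   By default every chromosome not named `chrX`/`chrY`/`chrM` (or
#'   `X`/`Y`/`MT`) is treated as autosomal.
#' @return An object of class `ChromSizes`.
#' @examples
#' chrom_sizes(c(chr1 = 1e6, chrX = 5e5))
#' @export
chrom_sizes <- function(lengths, autosome = NULL) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be a named vector")
  if (anyDuplicated(names(lengths)))
    stop("duplicated chromosome names")
  lens <- as.integer(lengths)
  names(lens) <- names(lengths)
  if (any(is.na(lens)) || any(lens <= 0L))
    stop("chromosome lengths must be positive integers")
  if (is.null(autosome)) {
    sex_mito <- c("chrX", "chrY", "chrM", "X", "Y", "MT", "M")
    autosome <- !(names(lens) %in% sex_mito)
    names(autosome) <- names(lens)
  } else {
    if (!setequal(names(autosome), names(lens)))
      stop("autosome flags must carry the same chromosome names as lengths")
    autosome <- as.logical(autosome[names(lens)])
    names(autosome) <- names(lens)
  }
  structure(list(lengths = lens, autosome = autosome), class = "ChromSizes")
}

#' @export
print.ChromSizes <- function(x, ...) {
  cat("ChromSizes with", length(x$lengths), "chromosomes (",
      sum(x$autosome), "autosomal )\n")
  print(x$lengths)
  invisible(x)
}

#' Convert ChromSizes to a Seqinfo
#' @param sizes A [chrom_sizes()] object.
#' @return A [GenomeInfoDb::Seqinfo] with the same chromosomes and lengths.
#' @export
as_seqinfo <- function(sizes) {
  stopifnot(inherits(sizes, "ChromSizes"))
  GenomeInfoDb::Seqinfo(seqnames = names(sizes$lengths),
                        seqlengths = unname(sizes$lengths))
}

#' Read / write a chromosome-sizes table
#'
#' Tab-separated, three columns: chrom, length, is_autosome (TRUE/FALSE).
#' @param path File path.
#' @return `read_chrom_sizes` returns a `ChromSizes`;
#'   `write_chrom_sizes` returns `path` invisibly.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "logical"))
  lens <- tab$length
  names(lens) <- tab$chrom
  auto <- tab$is_autosome
  names(auto) <- tab$chrom
  chrom_sizes(lens, auto)
}

#' @rdname read_chrom_sizes
#' @param sizes A `ChromSizes` object.
#' @export
write_chrom_sizes <- function(sizes, path) {
  stopifnot(inherits(sizes, "ChromSizes"))
  tab <- data.frame(chrom = names(sizes$lengths),
                    length = unname(sizes$lengths),
                    is_autosome = unname(sizes$autosome))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Normalize chromosome-name dialect ("1" vs "chr1") of a GRanges to the
# spelling used by `sizes`, then stamp the Seqinfo. Errors if a chromosome
# cannot be matched or an interval exceeds the chromosome length.
set_genome <- function(gr, sizes) {
  stopifnot(inherits(sizes, "ChromSizes"))
  want <- names(sizes$lengths)
  have <- GenomeInfoDb::seqlevels(gr)
  unmatched <- setdiff(have, want)
  if (length(unmatched)) {
    # try the "chr" dialect swap
    alt <- ifelse(grepl("^chr", unmatched), sub("^chr", "", unmatched),
                  paste0("chr", unmatched))
    ok <- alt %in% want
    if (!all(ok))
      stop("chromosome(s) not in ChromSizes: ",
           paste(unmatched[!ok], collapse = ", "))
    map <- stats::setNames(have, have)
    map[unmatched] <- alt
    gr <- GenomeInfoDb::renameSeqlevels(gr, map)
  }
  GenomeInfoDb::seqlevels(gr) <- want
  # out-of-bound ranges raise a coordinate error below, not a warning
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- as_seqinfo(sizes))
  validate_intervals(gr)
  gr
}

# Coordinate validation against the stamped Seqinfo.
validate_intervals <- function(gr) {
  if (length(gr) == 0L) return(invisible(gr))
  if (any(BiocGenerics::start(gr) < 1L))
    stop("interval start below chromosome origin")
  lens <- GenomeInfoDb::seqlengths(gr)[as.character(GenomeInfoDb::seqnames(gr))]
  bad <- !is.na(lens) & BiocGenerics::end(gr) > lens
  if (any(bad))
    stop("interval exceeds chromosome length: ",
         paste(utils::head(which(bad), 3), collapse = ", "))
  invisible(gr)
}
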