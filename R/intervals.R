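#' Construct genomic intervals from 0-based half-open coordinates
#'
#' Convenience constructor mirroring the BED convention used by every file
#' format the pipeline consumes. In memory intervals live in standard
#' Bioconductor [GenomicRanges::GRanges] (1-based closed); conversion
#' happens here and at the file readers/writers.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end 0-based half-open coordinates (`end` exclusive).
#' @param strand Strand, one of `"+"`, `"-"`, `"*"` (unstranded).
#' @param score Optional numeric score.
#' @param sizes Optional [chrom_sizes()]; when given, names are normalized
#'   and coordinates validated against chromosome lengths.
#' @return A `GRanges`.
#' @export
gi <- function(chrom, start, end, strand = "*", score = NULL, sizes = NULL) {
  if (any(start < 0)) stop("start must be >= 0")
  if (any(end <= start)) stop("end must be > start")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               strand = strand)
  if (!is.null(score)) gr$score <- score
  if (!is.null(sizes)) gr <- set_genome(gr, sizes)
  gr
}

#' Merge intervals lying within a maximum gap
#'
#' Two intervals on the same chromosome are merged iff the gap between them
#' is at most `max_gap` bp (a gap of 0 merges book-ended intervals; merging
#' is transitive). Merged intervals are unstranded and, when the input
#' carries a `score` column, take the maximum score of their members —
#' preserving the strongest evidence. Output is sorted by (chrom, start)
#' and disjoint.
#'
#' @param x A `GRanges` (optionally with a numeric `score` column).
#' @param max_gap Maximum gap in bp (>= 0).
#' @return Disjoint, sorted `GRanges`.
#' @examples
#' x <- gi("chr1", c(100, 650, 1300), c(200, 700, 1400))
#' merge_within(x, 500)   # first two merge (gap 450), third stays
#' @export
merge_within <- function(x, max_gap) {
  stopifnot(is(x, "GRanges"))
  if (length(max_gap) != 1L || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative number")
  validate_intervals(x)
  if (length(x) == 0L) return(GenomicRanges::granges(x))
  has_score <- "score" %in% names(S4Vectors::mcols(x))
  strand(x) <- "*"
  red <- GenomicRanges::reduce(x, min.gapwidth = max_gap + 1L,
                               with.revmap = TRUE)
  out <- GenomicRanges::granges(red)
  if (has_score) {
    out$score <- vapply(red$revmap, function(i) max(x$score[i]), numeric(1))
  }
  sort(out)
}

#' Flag query intervals overlapping any subject interval
#'
#' Half-open/closed semantics agree here: a flag is `TRUE` iff the query
#' shares at least `min_overlap` bases with some subject interval.
#'
#' @param query,subject `GRanges`.
#' @param min_overlap Minimum shared bases (>= 1).
#' @return Logical vector, one flag per query interval.
#' @export
overlaps_any <- function(query, subject, min_overlap = 1L) {
  if (length(min_overlap) != 1L || is.na(min_overlap) || min_overlap < 1)
    stop("min_overlap must be >= 1")
  IRanges::overlapsAny(query, subject, minoverlap = as.integer(min_overlap),
                       ignore.strand = TRUE)
}

#' Extend intervals by a fixed flank on both sides
#'
#' Each interval grows by `flank` bp left and right, clipped to
#' `[0, chromosome length]`.
#'
#' @param x `GRanges` with seqlengths set (see [set_genome()] via [gi()]).
#' @param flank Flank size in bp (>= 0).
#' @return Extended, clipped `GRanges`.
#' @export
extend_intervals <- function(x, flank) {
  stopifnot(is(x, "GRanges"))
  if (length(flank) != 1L || is.na(flank) || flank < 0)
    stop("flank must be a single non-negative number")
  validate_intervals(x)
  suppressWarnings(x <- x + as.integer(flank))
  GenomicRanges::trim(x)
}

#' Promoter windows of protein-coding genes
#'
#' Strand-aware windows covering 2 kb upstream through 500 bp downstream of
#' each protein-coding transcription start site (2.5 kb total). Genes that
#' are not protein-coding emit no window; genes without orientation are
#' rejected since upstream/downstream is undefined.
#'
#' @param genes A `GRanges` of gene bodies with metadata columns
#'   `is_protein_coding` (logical) and strand set (see [read_gene_table()]).
#' @param upstream,downstream Window extent in bp relative to the TSS.
#' @return `GRanges` of promoter windows (clipped to chromosome bounds).
#' @export
promoter_windows <- function(genes, upstream = 2000L, downstream = 500L) {
  stopifnot(is(genes, "GRanges"))
  if (!"is_protein_coding" %in% names(S4Vectors::mcols(genes)))
    stop("genes must carry an is_protein_coding column")
  pc <- genes[genes$is_protein_coding]
  if (length(pc) && any(BiocGenerics::strand(pc) == "*"))
    stop("protein-coding gene without strand: promoter orientation required")
  if (length(pc) == 0L) return(GenomicRanges::granges(pc))
  win <- suppressWarnings(
    GenomicRanges::promoters(pc, upstream = as.integer(upstream),
                             downstream = as.integer(downstream))
  )
  win <- GenomicRanges::trim(win)
  GenomicRanges::granges(win)
}

#' Read a gene table
#'
#' Tab-separated with header: chrom, start, end, strand, name, biotype
#' (BED-style 0-based half-open coordinates). The TSS is the start of the
#' gene body on the + strand and the last base on the - strand.
#'
#' @param path File path.
#' @param sizes A [chrom_sizes()] object.
#' @return `GRanges` with columns `name`, `biotype`, `is_protein_coding`,
#'   `tss` (0-based TSS position).
#' @export
read_gene_table <- function(path, sizes) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "name", "biotype")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  gr <- gi(tab$chrom, tab$start, tab$end, strand = tab$strand, sizes = sizes)
  gr$name <- tab$name
  gr$biotype <- tab$biotype
  gr$is_protein_coding <- tab$biotype == "protein_coding"
  gr$tss <- ifelse(as.character(BiocGenerics::strand(gr)) == "-",
                   BiocGenerics::end(gr) - 1L,
                   BiocGenerics::start(gr) - 1L)
  gr
}

#' @rdname read_gene_table
#' @param genes `GRanges` as returned by `read_gene_table`.
#' @export
write_gene_table <- function(genes, path) {
  tab <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(genes)),
                    start = BiocGenerics::start(genes) - 1L,
                    end = BiocGenerics::end(genes),
                    strand = as.character(BiocGenerics::strand(genes)),
                    name = genes$name,
                    biotype = genes$biotype)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
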