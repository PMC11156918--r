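#' Read position count matrices (plain-text PCM layout)
#'
#' One motif per block: a header line starting with `>` carrying the motif
#' name, followed by L rows of 4 whitespace-separated counts in A C G T
#' column order (positions as rows). Matrices are returned as 4 x L with
#' rows A, C, G, T.
#'
#' @param path File path.
#' @return Named list of 4 x L numeric matrices.
#' @export
read_pcm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no PCM header lines (\">\") in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    name <- sub("^>\\s*", "", lines[starts[i]])
    body <- lines[(starts[i] + 1L):ends[i]]
    rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
    if (any(lengths(rows) != 4L))
      stop("PCM rows must have 4 columns (A C G T): motif ", name)
    m <- t(do.call(rbind, rows))
    rownames(m) <- c("A", "C", "G", "T")
    if (ncol(m) < 4L) stop("motif length must be >= 4: ", name)
    if (any(m < 0) || any(colSums(m) <= 0))
      stop("PCM counts must be non-negative with positive column sums: ", name)
    out[[name]] <- m
  }
  out
}

#' @rdname read_pcm
#' @param pcms Named list of 4 x L count matrices.
#' @export
write_pcm <- function(pcms, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(pcms)) {
    writeLines(paste0(">", nm), con)
    m <- pcms[[nm]]
    utils::write.table(t(m), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Center regions to a fixed analysis length
#'
#' Fixed-length windows about the region centers (floor division for odd
#' remainders), clipped to chromosome bounds; clipped windows shorter than
#' `length` are flagged in the `clipped` metadata column.
#'
#' @param regions `GRanges` (e.g. merged ATAC peak footprints).
#' @param length Window length in bp (default 500).
#' @return `GRanges` of centered windows with a `clipped` flag.
#' @export
center_regions <- function(regions, length = 500L) {
  length <- as.integer(length)
  s0 <- BiocGenerics::start(regions) - 1L
  e0 <- BiocGenerics::end(regions)
  centers <- (s0 + e0) %/% 2L
  half_lo <- length %/% 2L
  new_start0 <- centers - half_lo
  new_end0 <- new_start0 + length
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(regions),
                                IRanges::IRanges(pmax(new_start0, 0L) + 1L,
                                                 new_end0),
                                seqinfo = GenomeInfoDb::seqinfo(regions))
  out <- GenomicRanges::trim(out)
  out$clipped <- BiocGenerics::width(out) < length
  out
}

# Discretized log-odds score matrix: log2 of pseudocounted position
# frequencies over the zero-order background, on a fixed grid (bits).
# Both the threshold calibration and the scanner use the same integer
# grid, so the two are exactly consistent.
score_matrix <- function(pcm, background = rep(0.25, 4),
                         pseudocount = 0.8, grid = 0.01) {
  stopifnot(nrow(pcm) == 4L, length(background) == 4L,
            all(background > 0), abs(sum(background) - 1) < 1e-6)
  p <- sweep(pcm + pseudocount, 2, colSums(pcm + pseudocount), "/")
  s <- log2(p / background)
  k <- round(s / grid)
  storage.mode(k) <- "integer"
  rownames(k) <- c("A", "C", "G", "T")
  list(k = k, grid = grid, background = background)
}

#' Calibrate a motif score threshold at a false-positive level
#'
#' The PCM is converted to log-odds (pseudocount 0.8 per cell) against a
#' zero-order background and the exact distribution of the total score of
#' a random background L-mer is computed by convolution of the
#' per-position score distributions on a 0.01-bit grid. The threshold is
#' the smallest grid score t with P(score >= t) <= alpha; when no score is
#' that rare the threshold sits one grid step above the maximum score and
#' no window can be a hit.
#'
#' @param pcm 4 x L count matrix (rows A, C, G, T).
#' @param background Zero-order background base frequencies (A, C, G, T).
#' @param alpha False-positive level in (0, 1]; `alpha = 1` yields the
#'   minimum score (every window a hit).
#' @param pseudocount,grid Log-odds pseudocount and score grid (bits).
#' @return Threshold score in bits (on the grid).
#' @export
calibrate_threshold <- function(pcm, background = rep(0.25, 4),
                                alpha = 0.001, pseudocount = 0.8,
                                grid = 0.01) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  sm <- score_matrix(pcm, background, pseudocount, grid)
  k <- sm$k
  L <- ncol(k)
  # distribution over partial integer sums, as a vector with its own origin
  cur <- 1
  cur_lo <- 0L
  for (j in seq_len(L)) {
    kj <- k[, j]
    new_lo <- cur_lo + min(kj)
    new_hi <- cur_lo + length(cur) - 1L + max(kj)
    nxt <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- cur_lo + kj[b] - new_lo
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + background[b] * cur
    }
    cur <- nxt
    cur_lo <- new_lo
  }
  tail_p <- rev(cumsum(rev(cur)))
  ok <- which(tail_p <= alpha + 1e-12)
  t_int <- if (length(ok)) cur_lo + ok[1] - 1L else cur_lo + length(cur)
  t_int * grid
}

# Integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else NA.
encode_dna <- function(s) {
  v <- utf8ToInt(toupper(s))
  code <- rep(NA_integer_, 128)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[v]
}

# Window scores of one encoded sequence against the integer score matrix;
# returns integer scores with NA for windows containing N.
window_scores <- function(xi, k) {
  L <- ncol(k)
  W <- length(xi) - L + 1L
  if (W < 1L) return(integer(0))
  sc <- integer(W)
  for (j in seq_len(L)) {
    sc <- sc + k[, j][xi[j:(j + W - 1L)]]
  }
  sc
}

#' Count motif hits over sequences (both strands)
#'
#' Windows of motif length are scored on the same discretized log-odds
#' grid used by [calibrate_threshold()]; a hit is a window scoring at
#' least the threshold. Both strands are scanned (the reverse strand by
#' scanning the reverse complement). Windows containing N are skipped and
#' excluded from the scanned-position count; sequences shorter than the
#' motif contribute no positions.
#'
#' @param sequences A [Biostrings::DNAStringSet] or character vector.
#' @param pcm 4 x L count matrix.
#' @param threshold Score threshold in bits from [calibrate_threshold()].
#' @param background,pseudocount,grid Must match the calibration.
#' @return List with `hits` and `positions` (both strands pooled).
#' @export
count_hits <- function(sequences, pcm, threshold,
                       background = rep(0.25, 4), pseudocount = 0.8,
                       grid = 0.01) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  sm <- score_matrix(pcm, background, pseudocount, grid)
  t_int <- as.integer(round(threshold / grid))
  hits <- 0L; positions <- 0L
  revcomp <- function(s) chartr("ACGTacgtN", "TGCAtgcaN",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (s in sequences) {
    for (strand_seq in c(s, revcomp(s))) {
      sc <- window_scores(encode_dna(strand_seq), sm$k)
      valid <- !is.na(sc)
      positions <- positions + sum(valid)
      hits <- hits + sum(sc[valid] >= t_int)
    }
  }
  list(hits = hits, positions = positions)
}

#' Pseudocounted motif enrichment between a target and a background set
#'
#' `log2(((hits_t + 0.5) / positions_t) / ((hits_b + 0.5) / positions_b))`:
#' the log2 ratio of hit rates with a 0.5 hit pseudocount, finite for zero
#' hits on either side.
#'
#' @param hits_target,positions_target Hit and scanned-position counts in
#'   the target set.
#' @param hits_background,positions_background Same for the background.
#' @param name Motif name carried through.
#' @return One-row data frame (`MotifEnrichment` record).
#' @export
motif_enrichment <- function(hits_target, positions_target,
                             hits_background, positions_background,
                             name = NA_character_) {
  if (positions_target <= 0 || positions_background <= 0)
    stop("zero scanned positions")
  stopifnot(hits_target <= positions_target,
            hits_background <= positions_background)
  lfc <- log2(((hits_target + 0.5) / positions_target) /
                ((hits_background + 0.5) / positions_background))
  data.frame(motif = name, hits_target = hits_target,
             positions_target = positions_target,
             hits_background = hits_background,
             positions_background = positions_background,
             log2_fold_change = lfc, stringsAsFactors = FALSE)
}

#' Scan a motif collection and rank by enrichment
#'
#' For each PCM: calibrate the score threshold at `alpha`, count hits in
#' the target and background sequence sets, and compute the pseudocounted
#' log2 rate ratio. Results are sorted by decreasing log2 fold change.
#'
#' @param target,background Sequence sets ([Biostrings::DNAStringSet] or
#'   character vectors).
#' @param pcms Named list of PCMs (see [read_pcm()]).
#' @param alpha False-positive level for hit calling.
#' @param background_freqs Zero-order background base frequencies.
#' @return Data frame of [motif_enrichment()] rows, sorted.
#' @export
scan_enrichment <- function(target, background, pcms, alpha = 0.001,
                            background_freqs = rep(0.25, 4)) {
  rows <- lapply(names(pcms), function(nm) {
    thr <- calibrate_threshold(pcms[[nm]], background_freqs, alpha)
    ht <- count_hits(target, pcms[[nm]], thr, background_freqs)
    hb <- count_hits(background, pcms[[nm]], thr, background_freqs)
    motif_enrichment(ht$hits, ht$positions, hb$hits, hb$positions, name = nm)
  })
  out <- do.call(rbind, rows)
  out[order(-out$log2_fold_change, out$motif), , drop = FALSE]
}
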