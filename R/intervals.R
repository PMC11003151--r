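#' Genome layout
#'
#' A genome layout holds the ordered chromosome names and lengths that every
#' interval in an analysis must fit into, plus (optionally) the chromosome
#' sequences. It is the background space for window clipping and for the
#' permutation null that re-places elements uniformly across the genome.
#'
#' @param lengths named numeric vector of chromosome lengths (bp, > 0).
#' @param seqs optional \code{Biostrings::DNAStringSet} named like `lengths`.
#' @return an object of class \code{genome_layout}.
#' @export
genome_layout <- function(lengths, seqs = NULL) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  lengths <- stats::setNames(round(as.numeric(lengths)), names(lengths))
  if (!is.null(seqs)) {
    if (!all(names(lengths) %in% names(seqs)))
      stop("sequences missing for some chromosomes")
    if (any(Biostrings::width(seqs[names(lengths)]) != lengths))
      stop("sequence widths disagree with stated lengths")
  }
  structure(list(lengths = lengths, seqs = seqs), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$lengths), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp",
      if (!is.null(x$seqs)) "(with sequence)" else "", "\n")
  invisible(x)
}

## ---- interval data frames (0-based half-open, BED convention) --------------

#' Construct a genomic interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based half-open), and optionally `id`, `score`, `strand`. This is the
#' coordinate currency of the whole package.
#'
#' @param chrom,start,end,id,score,strand vectors, recycled as usual.
#' @return data.frame of validated intervals.
#' @export
gi <- function(chrom, start, end, id = NULL, score = NULL, strand = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(id)) df$id <- as.character(id)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) df$strand <- as.character(strand)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' @param x interval data.frame.
#' @param layout optional \code{genome_layout}; when given, chromosome names
#'   must be known and intervals must fit within chromosome bounds.
#' @return `x`, invisibly. Errors describe the offending records.
#' @export
validate_intervals <- function(x, layout = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(!nzchar(x$chrom))) stop("empty chromosome name")
  bad <- !(x$start >= 0 & x$start < x$end)
  if (any(bad))
    stop("invalid interval(s): need 0 <= start < end at rows ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  if (!is.null(layout)) {
    unknown <- setdiff(unique(x$chrom), names(layout$lengths))
    if (length(unknown))
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    over <- x$end > layout$lengths[x$chrom]
    if (any(over))
      stop("interval(s) exceed chromosome bounds at rows ",
         paste(utils::head(which(over), 5), collapse = ", "))
  }
  if ("strand" %in% names(x) && any(!x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(x)
}

## conversion between 0-based half-open tables and GRanges (1-based closed)
as_gr <- function(x, layout = NULL) {
  if (!is.null(layout)) validate_intervals(x, layout)
  sl <- if (!is.null(layout)) layout$lengths else NULL
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else rep("*", nrow(x)),
    seqlengths = sl)
  if ("id" %in% names(x)) names(gr) <- x$id
  gr
}

gr_to_gi <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(names(gr))) df$id <- names(gr)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- ifelse(st == "*", ".", st)
  rownames(df) <- NULL
  df
}

sort_intervals <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

## ---- interval algebra ------------------------------------------------------

#' Replicate-consistent peak regions: intersect, then merge
#'
#' Computes the pairwise intersections of two replicate peak sets and merges
#' the result into maximal non-overlapping regions. This is the
#' replicate-consistency step applied to H3K27ac peak calls before enhancer
#' definition. Merging joins intervals only when they overlap by >= 1 bp;
#' abutting intervals are kept apart.
#'
#' @param rep1,rep2 interval data.frames (peaks from the two replicates).
#' @param layout \code{genome_layout}; unknown chromosomes are rejected.
#' @return sorted, non-overlapping interval data.frame.
#' @export
intersect_then_merge <- function(rep1, rep2, layout) {
  g1 <- as_gr(rep1, layout); g2 <- as_gr(rep2, layout)
  GenomicRanges::strand(g1) <- "*"; GenomicRanges::strand(g2) <- "*"
  out <- GenomicRanges::intersect(GenomicRanges::reduce(g1),
                                  GenomicRanges::reduce(g2))
  sort_intervals(gr_to_gi(out)[, c("chrom", "start", "end")])
}

#' Merge intervals that overlap by at least one base
#'
#' @param x interval data.frame.
#' @return sorted merged intervals (abutting intervals stay separate).
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  gr <- as_gr(x); GenomicRanges::strand(gr) <- "*"
  sort_intervals(gr_to_gi(GenomicRanges::reduce(gr, min.gapwidth = 0)))
}

#' Drop regions near anchor features
#'
#' Removes every region that overlaps any anchor expanded by `flank` on both
#' sides. Point anchors (a numeric vector of positions with a parallel
#' `chrom`) occupy one base, so a point p with flank f masks
#' `[p - f, p + f + 1)`. Used with flank = 1000 bp to exclude enhancer calls
#' at transcription start sites, and again to exclude quantification signal
#' near gene and ncRNA bodies.
#'
#' @param regions interval data.frame.
#' @param anchors interval data.frame, or a data.frame with `chrom` and `pos`
#'   columns for point anchors.
#' @param flank non-negative flank in bp.
#' @return the subset of `regions` having zero overlap with any mask window.
#' @export
exclude_near_features <- function(regions, anchors, flank) {
  stopifnot(flank >= 0)
  validate_intervals(regions)
  if (!is.null(anchors$pos) && is.null(anchors$start))
    anchors <- data.frame(chrom = anchors$chrom, start = anchors$pos,
                          end = anchors$pos + 1)
  if (nrow(anchors) == 0) return(regions)
  mask <- data.frame(chrom = anchors$chrom,
                     start = pmax(0, anchors$start - flank),
                     end = anchors$end + flank)
  keep <- !overlaps_any(regions, mask)
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fixed windows around interval centers
#'
#' For each region, returns `[c - flank, c + flank)` where `c` is the floor of
#' the interval midpoint, clipped to chromosome bounds. Windows that become
#' empty after clipping (possible only with flank = 0) are dropped with a
#' warning; callers wanting a real window must use flank >= 1.
#'
#' @param regions interval data.frame.
#' @param flank half-width in bp.
#' @param layout \code{genome_layout} used for clipping.
#' @return interval data.frame parallel to the retained `regions` rows.
#' @export
center_window <- function(regions, flank, layout) {
  validate_intervals(regions, layout)
  ctr <- floor((regions$start + regions$end) / 2)
  out <- regions
  out$start <- pmax(0, ctr - flank)
  out$end <- pmin(layout$lengths[regions$chrom], ctr + flank)
  empty <- out$end <= out$start
  if (any(empty)) {
    warning(sum(empty), " empty window(s) dropped (flank too small)")
    out <- out[!empty, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Expand hits (points or intervals) by a symmetric flank
#'
#' A point hit at position p becomes `[p - flank, p + flank + 1)`; an interval
#' hit is expanded from both ends. Windows are clipped to chromosome bounds.
#' Default flank of 20 kb approximates linkage disequilibrium around GWAS
#' hits.
#'
#' @param hits data.frame with `chrom` and either `pos` (points) or
#'   `start`/`end` (intervals).
#' @param flank non-negative flank in bp.
#' @param layout \code{genome_layout}.
#' @return interval data.frame.
#' @export
expand_points <- function(hits, flank = 20000, layout) {
  stopifnot(flank >= 0)
  if (!is.null(hits$pos) && is.null(hits$start))
    hits <- data.frame(chrom = hits$chrom, start = hits$pos,
                       end = hits$pos + 1,
                       hits[setdiff(names(hits), c("chrom", "pos"))])
  out <- hits
  out$start <- pmax(0, hits$start - flank)
  out$end <- pmin(layout$lengths[hits$chrom], hits$end + flank)
  rownames(out) <- NULL
  out
}

#' Does each query interval overlap any feature?
#'
#' @param query,features interval data.frames.
#' @return logical vector along `query` rows.
#' @export
overlaps_any <- function(query, features) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(features) == 0) return(rep(FALSE, nrow(query)))
  ## disjoint chromosome sets are a legitimate "no overlap", not a problem
  suppressWarnings(IRanges::overlapsAny(as_gr(query), as_gr(features)))
}

## per-record subtraction: region minus mask, record identity preserved
subtract_from_regions <- function(regions, mask) {
  if (nrow(regions) == 0) return(vector("list", 0))
  mgr <- if (nrow(mask)) GenomicRanges::reduce(as_gr(mask)) else
    GenomicRanges::GRanges()
  GenomicRanges::strand(mgr) <- "*"
  lapply(seq_len(nrow(regions)), function(i) {
    g <- as_gr(regions[i, , drop = FALSE])
    GenomicRanges::strand(g) <- "*"
    gr_to_gi(GenomicRanges::setdiff(g, mgr))[, c("chrom", "start", "end")]
  })
}

## ---- readers / writers -----------------------------------------------------

#' Read / write BED3 and BED6
#'
#' Plain-text, tab-separated, headerless BED. Coordinates are kept 0-based
#' half-open as stored. Writing a table read with `read_bed()` reproduces the
#' input bytes for canonical records.
#'
#' @param path file path.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "id"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  validate_intervals(df)
  df
}

#' @rdname read_bed
#' @param x interval data.frame (3 or 6 columns are written).
#' @export
write_bed <- function(x, path) {
  ## BED columns are positional: stop at the first absent one
  want <- c("chrom", "start", "end", "id", "score", "strand")
  n <- 3
  for (k in 4:6) if (want[k] %in% names(x)) n <- k else break
  df <- x[, want[seq_len(n)], drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromosome sizes (name, length TSV)
#' @param path file path.
#' @return \code{genome_layout} without sequence.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  genome_layout(stats::setNames(df[[2]], df[[1]]))
}

#' Read a genome FASTA into a layout
#' @param path FASTA file.
#' @return \code{genome_layout} with sequences attached.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_layout(stats::setNames(Biostrings::width(seqs), names(seqs)), seqs)
}

#' Fetch interval sequences from a layout
#' @param x interval data.frame.
#' @param layout \code{genome_layout} carrying sequences.
#' @return \code{DNAStringSet}, named by `x$id` when present.
#' @export
interval_seqs <- function(x, layout) {
  if (is.null(layout$seqs)) stop("layout has no sequences")
  validate_intervals(x, layout)
  out <- Biostrings::DNAStringSet(lapply(seq_len(nrow(x)), function(i)
    Biostrings::subseq(layout$seqs[[x$chrom[i]]],
                       start = x$start[i] + 1, end = x$end[i])))
  if ("id" %in% names(x)) names(out) <- x$id
  out
}

## ---- annotation ------------------------------------------------------------

#' Build an annotation set
#'
#' Gene and ncRNA records with derived TSS positions. The TSS equals `start`
#' for + strand records and `end - 1` for - strand records (0-based).
#'
#' @param genes data.frame with chrom, start, end, id, strand, biotype.
#' @param ncrnas like `genes` (miRNA, misc_RNA, rRNA, snoRNA, snRNA, tRNA,
#'   lncRNA and similar).
#' @return list of class `annotation_set` with elements `genes`, `ncrnas`;
#'   each table gains a `tss` column.
#' @export
annotation_set <- function(genes, ncrnas = genes[0, ]) {
  add_tss <- function(df) {
    if (nrow(df) == 0) { df$tss <- numeric(0); return(df) }
    if (is.null(df$strand)) df$strand <- "+"
    validate_intervals(df)
    df$tss <- ifelse(df$strand == "-", df$end - 1, df$start)
    df
  }
  structure(list(genes = add_tss(genes), ncrnas = add_tss(ncrnas)),
            class = "annotation_set")
}

#' Read gene/ncRNA annotation from GTF
#'
#' Imports `gene` features from a GTF file (1-based closed coordinates are
#' converted to 0-based half-open on read). Records whose `gene_biotype` is a
#' recognised ncRNA class go to the ncRNA table, everything else to the gene
#' table.
#'
#' @param path GTF file.
#' @return \code{annotation_set}.
#' @export
read_gtf_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  biotype <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else
    rep(NA_character_, length(gr))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   id = gr$gene_id,
                   strand = strand,
                   biotype = biotype,
                   stringsAsFactors = FALSE)
  df$biotype[is.na(df$biotype)] <- "protein_coding"
  nc_classes <- c("miRNA", "misc_RNA", "rRNA", "snoRNA", "snRNA", "tRNA",
                  "lncRNA")
  annotation_set(genes = df[!df$biotype %in% nc_classes, , drop = FALSE],
                 ncrnas = df[df$biotype %in% nc_classes, , drop = FALSE])
}
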