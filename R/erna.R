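#' Define eRNA transcription regions from enhancers
#'
#' Each enhancer yields one candidate eRNA whose transcription region is the
#' enhancer center +/- 3 kb (the transcribed span of an enhancer can exceed
#' the H3K27ac peak itself). Quantification windows are the region minus all
#' gene and ncRNA bodies expanded by +/- 1 kb, so that only signal more than
#' 1 kb away from annotated transcription units is counted. Records whose
#' windows are entirely masked are dropped. Overlapping regions from adjacent
#' enhancers are retained independently: one eRNA per enhancer.
#'
#' @param enhancers interval data.frame with `id`.
#' @param annotation \code{annotation_set}.
#' @param layout \code{genome_layout}.
#' @param region_flank half-width of the transcription region (default 3 kb).
#' @param annot_flank exclusion flank around annotated bodies (default 1 kb).
#' @return data.frame (erna_id, enhancer_id, chrom, start, end, center) with a
#'   list-column `windows` of per-record quantification window tables.
#' @export
define_erna_regions <- function(enhancers, annotation, layout,
                                region_flank = 3000, annot_flank = 1000) {
  regions <- center_window(enhancers, region_flank, layout)
  bodies <- rbind(annotation$genes[c("chrom", "start", "end")],
                  annotation$ncrnas[c("chrom", "start", "end")])
  mask <- if (nrow(bodies)) data.frame(
    chrom = bodies$chrom,
    start = pmax(0, bodies$start - annot_flank),
    end = bodies$end + annot_flank) else bodies
  windows <- subtract_from_regions(regions, mask)
  keep <- vapply(windows, nrow, 0L) > 0
  out <- data.frame(erna_id = sprintf("erna_%s", enhancers$id[keep]),
                    enhancer_id = enhancers$id[keep],
                    chrom = regions$chrom[keep],
                    start = regions$start[keep],
                    end = regions$end[keep],
                    stringsAsFactors = FALSE)
  out$center <- floor((enhancers$start[keep] + enhancers$end[keep]) / 2)
  out$windows <- windows[keep]
  rownames(out) <- NULL
  out
}

#' Quantify eRNA expression (RPM) and strand balance
#'
#' RPM per sample is the total (plus + minus strand) read count over a
#' record's quantification windows, divided by the sample's library size,
#' times 1e6. The plus-strand fraction is computed per breed-tissue group
#' from counts pooled across that group's replicates.
#'
#' @param records output of \code{define_erna_regions}.
#' @param stranded_counts data.frame (erna_id, sample, plus_count,
#'   minus_count); every record/sample pair must be present.
#' @param lib_sizes named vector of total mapped reads per sample.
#' @param samples data.frame (sample, breed, tissue, replicate).
#' @return list with `rpm` (records x samples matrix), `plus_fraction`
#'   (records x breed.tissue matrix, `NA` where a group has zero reads) and
#'   `group_reads` (pooled totals underlying the fractions).
#' @export
quantify_rpm <- function(records, stranded_counts, lib_sizes, samples) {
  if (any(stranded_counts$plus_count < 0 | stranded_counts$minus_count < 0))
    stop("negative counts")
  ids <- records$erna_id
  sam <- samples$sample
  key <- paste(stranded_counts$erna_id, stranded_counts$sample)
  full <- expand.grid(erna_id = ids, sample = sam, stringsAsFactors = FALSE)
  idx <- match(paste(full$erna_id, full$sample), key)
  if (anyNA(idx))
    stop("stranded counts missing for some record/sample pairs")
  plus <- matrix(stranded_counts$plus_count[idx], nrow = length(ids),
                 dimnames = list(ids, sam))
  minus <- matrix(stranded_counts$minus_count[idx], nrow = length(ids),
                  dimnames = list(ids, sam))
  total <- plus + minus
  rpm <- sweep(total, 2, as.numeric(lib_sizes[sam]), "/") * 1e6
  grp <- paste(samples$breed, samples$tissue, sep = ".")
  ug <- unique(grp)
  gplus <- vapply(ug, function(g)
    rowSums(plus[, grp == g, drop = FALSE]), numeric(length(ids)))
  gtot <- vapply(ug, function(g)
    rowSums(total[, grp == g, drop = FALSE]), numeric(length(ids)))
  gplus <- matrix(gplus, nrow = length(ids), dimnames = list(ids, ug))
  gtot <- matrix(gtot, nrow = length(ids), dimnames = list(ids, ug))
  pf <- ifelse(gtot > 0, gplus / gtot, NA)
  list(rpm = rpm, plus_fraction = pf, group_reads = gtot)
}

#' Call detectable eRNAs in one breed-tissue group
#'
#' An eRNA is detectable in a tissue when its mean RPM across that tissue's
#' biological replicates is >= `threshold` (boundary inclusive).
#'
#' @param rpm records x samples RPM matrix.
#' @param samples sample metadata (sample, breed, tissue, replicate).
#' @param tissue,breed group selectors.
#' @param threshold detection cutoff in RPM.
#' @return character vector of detectable record ids.
#' @export
call_detectable <- function(rpm, samples, tissue, breed, threshold = 1) {
  sel <- samples$tissue == tissue & samples$breed == breed
  if (sum(sel) == 0) stop("no samples for ", breed, " ", tissue)
  if (sum(sel) != 2)
    warning("group ", breed, ".", tissue, " has ", sum(sel),
            " replicate(s); mean taken over available replicates")
  mu <- rowMeans(rpm[, samples$sample[sel], drop = FALSE])
  rownames(rpm)[mu >= threshold]
}

#' Classify eRNA transcription direction from strand balance
#'
#' Bidirectional when the plus-strand fraction lies between 5 and 95 percent
#' of the reads (bounds inclusive), unidirectional otherwise. `NA` fractions
#' (zero reads) stay `NA`.
#'
#' @param plus_fraction numeric in [0, 1] (or `NA`).
#' @param lo,hi inclusive bounds.
#' @return character vector: "bidirectional", "unidirectional" or `NA`.
#' @export
classify_direction <- function(plus_fraction, lo = 0.05, hi = 0.95) {
  stopifnot(all(is.na(plus_fraction) |
                (plus_fraction >= 0 & plus_fraction <= 1)))
  ifelse(is.na(plus_fraction), NA_character_,
         ifelse(plus_fraction >= lo & plus_fraction <= hi,
                "bidirectional", "unidirectional"))
}

#' Per-record global direction
#'
#' A record's single direction label is taken from the breed-tissue group in
#' which it is detectable with the highest mean RPM; records detectable
#' nowhere get `NA`.
#'
#' @param rpm records x samples RPM matrix.
#' @param plus_fraction records x group matrix from \code{quantify_rpm}.
#' @param samples sample metadata.
#' @param threshold detectability cutoff (RPM).
#' @return data.frame (erna_id, group, plus_fraction, direction).
#' @export
global_direction <- function(rpm, plus_fraction, samples, threshold = 1) {
  grp <- paste(samples$breed, samples$tissue, sep = ".")
  ug <- colnames(plus_fraction)
  gmean <- vapply(ug, function(g)
    rowMeans(rpm[, samples$sample[grp == g], drop = FALSE]),
    numeric(nrow(rpm)))
  gmean <- matrix(gmean, nrow = nrow(rpm), dimnames = list(rownames(rpm), ug))
  gmean[gmean < threshold] <- NA  # only groups where detectable compete
  best <- apply(gmean, 1, function(v)
    if (all(is.na(v))) NA_integer_ else which.max(v))
  pf <- vapply(seq_along(best), function(i)
    if (is.na(best[i])) NA_real_ else plus_fraction[i, best[i]], 0)
  data.frame(erna_id = rownames(rpm),
             group = ifelse(is.na(best), NA_character_, ug[best]),
             plus_fraction = pf,
             direction = classify_direction(pf),
             stringsAsFactors = FALSE)
}

#' GC fraction of sequences
#'
#' (#G + #C) / length, case-insensitive; N bases count toward the
#' denominator, mirroring length-based GC content of interval sequences.
#'
#' @param seqs character vector or \code{DNAStringSet}.
#' @return numeric vector of fractions in [0, 1].
#' @export
gc_fraction <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  if (any(Biostrings::width(seqs) == 0)) stop("empty sequence")
  as.numeric(Biostrings::letterFrequency(seqs, "GC")) /
    Biostrings::width(seqs)
}

#' Binned correlation between eRNA expression and enhancer activity
#'
#' Records are sorted by expression (descending) and split into `n_bins`
#' near-equal bins, earlier bins absorbing the remainder; the Pearson
#' correlation of the per-bin mean expression and per-bin mean activity is
#' returned with its p-value.
#'
#' @param expression per-record mean RPM (named or parallel to `activity`).
#' @param activity per-record enhancer activity fold change.
#' @param n_bins number of bins (default 8).
#' @return list (r, p, bins data.frame).
#' @export
binned_activity_correlation <- function(expression, activity, n_bins = 8) {
  stopifnot(length(expression) == length(activity))
  n <- length(expression)
  if (n < n_bins) stop("need at least n_bins records")
  ord <- order(expression, decreasing = TRUE)
  base <- n %/% n_bins
  sizes <- rep(base, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- base + 1
  bin <- rep(seq_len(n_bins), times = sizes)
  e <- tapply(expression[ord], bin, mean)
  a <- tapply(activity[ord], bin, mean)
  ct <- stats::cor.test(e, a, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       bins = data.frame(bin = seq_len(n_bins), mean_expression = as.numeric(e),
                         mean_activity = as.numeric(a)))
}

#' Label transcribed vs non-transcribed enhancers
#'
#' An enhancer is a transcribed enhancer (TEn) when its interval contains at
#' least one eRNA center point (half-open: a center equal to the exclusive
#' end does not count), and non-TEn otherwise.
#'
#' @param enhancers interval data.frame with `id`.
#' @param erna_records output of \code{define_erna_regions} (uses `chrom` and
#'   `center`).
#' @return data.frame (id, label) partitioning the enhancer set.
#' @export
label_transcribed_enhancers <- function(enhancers, erna_records) {
  validate_intervals(enhancers)
  if (nrow(erna_records) == 0) {
    return(data.frame(id = enhancers$id, label = "non-TEn",
                      stringsAsFactors = FALSE))
  }
  centers <- data.frame(chrom = erna_records$chrom,
                        start = erna_records$center,
                        end = erna_records$center + 1)
  data.frame(id = enhancers$id,
             label = ifelse(overlaps_any(enhancers, centers),
                            "TEn", "non-TEn"),
             stringsAsFactors = FALSE)
}
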