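#' Quantify enhancer activity from IP and INPUT read counts
#'
#' Activity is measured over the +/- 1 kb window around each enhancer center:
#' reads-per-million in the immunoprecipitated (IP) H3K27ac library divided by
#' reads-per-million in the INPUT (chromatin background) library. The fold
#' change IP_RPM / INPUT_RPM is the per-enhancer activity score.
#'
#' @param enhancers interval data.frame with an `id` column.
#' @param counts data.frame with columns `id`, `ip_count`, `input_count`
#'   (reads falling in the center +/- 1 kb window).
#' @param lib_sizes list or named vector with elements `ip` and `input`:
#'   total mapped reads per library (> 0).
#' @return data.frame (id, ip_rpm, input_rpm, fold_change). `fold_change` is
#'   `NA` where `input_rpm` is zero (a warning is emitted).
#' @export
quantify_activity <- function(enhancers, counts, lib_sizes) {
  lib_sizes <- as.list(lib_sizes)
  stopifnot(lib_sizes$ip > 0, lib_sizes$input > 0)
  missing <- setdiff(enhancers$id, counts$id)
  if (length(missing))
    stop("missing counts for enhancer id(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  m <- counts[match(enhancers$id, counts$id), ]
  if (any(m$ip_count < 0 | m$input_count < 0)) stop("negative counts")
  out <- data.frame(id = enhancers$id,
                    ip_rpm = m$ip_count / lib_sizes$ip * 1e6,
                    input_rpm = m$input_count / lib_sizes$input * 1e6,
                    stringsAsFactors = FALSE)
  out$fold_change <- ifelse(out$input_rpm > 0, out$ip_rpm / out$input_rpm, NA)
  if (anyNA(out$fold_change))
    warning(sum(is.na(out$fold_change)),
            " enhancer(s) with zero INPUT signal: fold_change undefined")
  out
}

#' Call super-enhancers by stitching and rank-curve tangent cutoff
#'
#' Enhancers within `stitch_distance` of each other are stitched into one
#' region; stitched regions are ranked by ascending total signal; both the
#' rank axis and the signal axis are min-max scaled to [0, 1]; the cutoff is
#' the first rank at which the slope of the scaled signal curve (centered
#' finite difference, one-sided at the ends) exceeds 1; regions strictly above
#' the cutoff rank are flagged as super-enhancers. With fewer than three
#' stitched regions the curve is undefined and everything is flagged
#' non-super with a warning. Calls are invariant to uniform rescaling of the
#' signal vector.
#'
#' @param enhancers interval data.frame with `id`.
#' @param signal numeric vector of non-negative per-enhancer signal, parallel
#'   to `enhancers` rows (e.g. IP - INPUT rpm difference floored at 0).
#' @param stitch_distance maximum gap (bp) joined when stitching.
#' @return data.frame of stitched regions: chrom, start, end, id, members
#'   (comma-joined enhancer ids), total_signal, rank, is_super.
#' @export
call_super_enhancers <- function(enhancers, signal, stitch_distance = 12500) {
  stopifnot(length(signal) == nrow(enhancers), all(signal >= 0))
  validate_intervals(enhancers)
  gr <- as_gr(enhancers); GenomicRanges::strand(gr) <- "*"
  stitched <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1)
  hit <- GenomicRanges::findOverlaps(gr, stitched)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  out <- gr_to_gi(stitched)
  out$id <- sprintf("se_%05d", seq_len(nrow(out)))
  out$members <- vapply(seq_len(nrow(out)), function(i)
    paste(enhancers$id[grp == i], collapse = ","), "")
  out$total_signal <- vapply(seq_len(nrow(out)), function(i)
    sum(signal[grp == i]), 0)
  ord <- order(out$total_signal)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  n <- nrow(out)
  if (n < 3) {
    warning("fewer than 3 stitched regions: rank curve undefined, ",
            "no super-enhancers called")
    out$is_super <- FALSE
    rownames(out) <- NULL
    return(out)
  }
  x <- (out$rank - 1) / (n - 1)
  rng <- range(out$total_signal)
  y <- if (diff(rng) > 0) (out$total_signal - rng[1]) / diff(rng) else
    rep(0, n)
  slope <- numeric(n)
  slope[1] <- (y[2] - y[1]) / (x[2] - x[1])
  slope[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    slope[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  cut <- which(slope > 1)
  out$is_super <- if (length(cut)) out$rank > min(cut) else rep(FALSE, n)
  rownames(out) <- NULL
  out
}
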