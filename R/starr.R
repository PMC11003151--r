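#' Screen candidate SNPs by population allele frequencies
#'
#' A SNP is a STARR-seq candidate when it lies inside an eRNA region, the
#' absolute difference between the eastern and western population minor
#' allele frequencies strictly exceeds `dmaf`, and the MAF in the mixed pool
#' strictly exceeds `mixed_min`.
#'
#' @param freqs data.frame (id, chrom, pos, east_maf, west_maf, mixed_maf);
#'   MAFs in [0, 0.5].
#' @param erna_regions interval data.frame.
#' @param dmaf minimum east-west MAF difference (strict, default 0.3).
#' @param mixed_min minimum mixed-pool MAF (strict, default 0.05).
#' @return character vector of candidate SNP ids.
#' @export
screen_candidate_snps <- function(freqs, erna_regions, dmaf = 0.3,
                                  mixed_min = 0.05) {
  mafs <- c(freqs$east_maf, freqs$west_maf, freqs$mixed_maf)
  if (any(mafs < 0 | mafs > 0.5)) stop("MAF outside [0, 0.5]")
  pts <- data.frame(chrom = freqs$chrom, start = freqs$pos,
                    end = freqs$pos + 1)
  inside <- overlaps_any(pts, erna_regions)
  keep <- inside & abs(freqs$east_maf - freqs$west_maf) > dmaf &
    freqs$mixed_maf > mixed_min
  freqs$id[keep]
}

#' Collapse output sequencing libraries into biological replicates
#'
#' Each biological replicate contributes two output libraries; their allele
#' counts are summed per SNP to give one count table per replicate.
#'
#' @param libs list of data.frames (id, ref_count, alt_count), one per
#'   library, in replicate order (libraries 1-2 are replicate 1, 3-4
#'   replicate 2, and so on pairwise).
#' @return list of per-replicate count data.frames.
#' @export
collapse_output_libraries <- function(libs) {
  if (length(libs) %% 2 != 0) stop("expected an even number of libraries")
  lapply(seq_len(length(libs) / 2), function(r) {
    a <- libs[[2 * r - 1]]; b <- libs[[2 * r]]
    if (!setequal(a$id, b$id)) stop("SNP sets differ between libraries")
    b <- b[match(a$id, b$id), ]
    data.frame(id = a$id, ref_count = a$ref_count + b$ref_count,
               alt_count = a$alt_count + b$alt_count,
               stringsAsFactors = FALSE)
  })
}

#' Merge output replicates with a correlation QC
#'
#' Sums allele counts across the two biological replicates and reports the
#' Pearson correlation of per-SNP total counts between them; a warning is
#' raised when the replicates are not highly correlated (r < 0.8) or when
#' the correlation is undefined.
#'
#' @param rep1,rep2 data.frames (id, ref_count, alt_count) over the same SNPs.
#' @return list (counts, correlation).
#' @export
merge_output_replicates <- function(rep1, rep2) {
  if (!setequal(rep1$id, rep2$id)) stop("SNP sets differ between replicates")
  rep2 <- rep2[match(rep1$id, rep2$id), ]
  t1 <- rep1$ref_count + rep1$alt_count
  t2 <- rep2$ref_count + rep2$alt_count
  r <- if (stats::sd(t1) == 0 || stats::sd(t2) == 0) NA_real_ else
    stats::cor(t1, t2)
  if (is.na(r)) warning("replicate correlation undefined (constant totals)")
  else if (r < 0.8)
    warning("replicate totals poorly correlated (r = ", round(r, 3), ")")
  list(counts = data.frame(id = rep1$id,
                           ref_count = rep1$ref_count + rep2$ref_count,
                           alt_count = rep1$alt_count + rep2$alt_count,
                           stringsAsFactors = FALSE),
       correlation = r)
}

#' Allelic activity test for STARR-seq SNPs
#'
#' SNPs whose total allele coverage is not strictly greater than
#' `min_coverage` in both the input and the output library are excluded. For
#' the rest, the effect size is the output alt/ref ratio divided by the input
#' alt/ref ratio (undefined when any cell is zero), significance comes from a
#' two-tailed Fisher's exact test on [[input_ref, input_alt], [output_ref,
#' output_alt]], q-values are Benjamini-Hochberg across the tested SNPs, and
#' a SNP is called regulatory when q < `q_cutoff`.
#'
#' @param input,output data.frames (id, ref_count, alt_count) over the same
#'   SNP set (output typically replicate-merged).
#' @param min_coverage strict coverage cutoff per library (default 20).
#' @param q_cutoff regulatory-call FDR threshold (default 0.05).
#' @return data.frame (id, input_ref, input_alt, output_ref, output_alt,
#'   effect_size, p, q, is_regulatory, tested). Excluded SNPs carry
#'   `tested = FALSE` and `NA` statistics.
#' @export
allelic_activity_test <- function(input, output, min_coverage = 20,
                                  q_cutoff = 0.05) {
  if (!setequal(input$id, output$id)) stop("SNP sets differ")
  output <- output[match(input$id, output$id), ]
  cnt <- cbind(input$ref_count, input$alt_count,
               output$ref_count, output$alt_count)
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    stop("counts must be non-negative integers")
  out <- data.frame(id = input$id,
                    input_ref = input$ref_count, input_alt = input$alt_count,
                    output_ref = output$ref_count,
                    output_alt = output$alt_count,
                    stringsAsFactors = FALSE)
  out$tested <- (out$input_ref + out$input_alt) > min_coverage &
    (out$output_ref + out$output_alt) > min_coverage
  out$effect_size <- ifelse(
    out$tested & out$input_ref > 0 & out$input_alt > 0 &
      out$output_ref > 0 & out$output_alt > 0,
    (out$output_alt / out$output_ref) / (out$input_alt / out$input_ref), NA)
  out$p <- NA_real_
  if (any(out$tested))
    out$p[out$tested] <- fisher_two_sided(
      out$input_ref[out$tested], out$input_alt[out$tested],
      out$output_ref[out$tested], out$output_alt[out$tested])
  out$q <- NA_real_
  out$q[out$tested] <- bh_fdr(out$p[out$tested])
  out$is_regulatory <- !is.na(out$q) & out$q < q_cutoff
  out
}
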