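#' Tissue-specificity index (tau-style)
#'
#' For a non-negative per-tissue expression vector, each entry is first
#' normalized by the maximum across tissues (x_i = expr_i / max_j expr_j) and
#' the index is sum_i (1 - x_i) / (N - 1). The index is 0 for a perfectly
#' uniform vector, 1 for expression confined to a single tissue, and is
#' invariant to uniform rescaling. All-zero vectors have no defined index and
#' return `NA`.
#'
#' @param expr numeric vector of per-tissue expression (one replicate).
#' @return TSI in [0, 1], or `NA` for an all-zero vector.
#' @export
tsi <- function(expr) {
  stopifnot(length(expr) >= 2, all(expr >= 0))
  m <- max(expr)
  if (m == 0) return(NA_real_)
  sum(1 - expr / m) / (length(expr) - 1)
}

#' Call tissue-specific features within one breed
#'
#' The specificity index is computed separately for biological replicates 1
#' and 2. A feature is tissue-specific when its index strictly exceeds
#' `threshold` in both replicates and both replicates agree on the
#' maximally-expressing tissue; the feature is then assigned to that tissue.
#'
#' @param mat features x samples expression matrix (RPM or TPM) for one
#'   breed; row names are feature ids.
#' @param samples data.frame (sample, tissue, replicate) matching the
#'   columns of `mat`; both replicates must cover the same tissue set.
#' @param threshold strict specificity cutoff (default 0.8).
#' @return data.frame (feature, tsi_rep1, tsi_rep2, tissue_rep1, tissue_rep2,
#'   is_specific, tissue). `tissue` is `NA` for non-specific features.
#' @export
call_tissue_specific <- function(mat, samples, threshold = 0.8) {
  reps <- sort(unique(samples$replicate))
  if (length(reps) != 2) stop("expected exactly two replicates")
  t1 <- sort(samples$tissue[samples$replicate == reps[1]])
  t2 <- sort(samples$tissue[samples$replicate == reps[2]])
  if (!identical(t1, t2)) stop("replicate tissue sets differ")
  per_rep <- lapply(reps, function(r) {
    sel <- samples[samples$replicate == r, ]
    sub <- mat[, sel$sample, drop = FALSE]
    colnames(sub) <- sel$tissue
    v <- apply(sub, 1, function(x) if (max(x) == 0) NA_real_ else tsi(x))
    amax <- colnames(sub)[apply(sub, 1, which.max)]
    amax[is.na(v)] <- NA_character_
    list(tsi = v, tissue = amax)
  })
  out <- data.frame(feature = rownames(mat),
                    tsi_rep1 = per_rep[[1]]$tsi,
                    tsi_rep2 = per_rep[[2]]$tsi,
                    tissue_rep1 = per_rep[[1]]$tissue,
                    tissue_rep2 = per_rep[[2]]$tissue,
                    stringsAsFactors = FALSE)
  out$is_specific <- !is.na(out$tsi_rep1) & !is.na(out$tsi_rep2) &
    out$tsi_rep1 > threshold & out$tsi_rep2 > threshold &
    out$tissue_rep1 == out$tissue_rep2
  out$tissue <- ifelse(out$is_specific, out$tissue_rep1, NA_character_)
  rownames(out) <- NULL
  out
}

#' Detectable genes in a breed-tissue group
#'
#' A gene is detectable when its mean TPM across the group's replicates is
#' at least `threshold`, mirroring the eRNA detectability rule.
#'
#' @param tpm genes x samples TPM matrix.
#' @param samples sample metadata (sample, breed, tissue, replicate).
#' @param tissue,breed group selectors.
#' @param threshold TPM cutoff.
#' @return character vector of detectable gene ids.
#' @export
detectable_genes <- function(tpm, samples, tissue, breed, threshold = 1) {
  sel <- samples$tissue == tissue & samples$breed == breed
  mu <- rowMeans(tpm[, samples$sample[sel], drop = FALSE])
  rownames(tpm)[mu >= threshold]
}
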