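#' Genomic permutation enrichment test
#'
#' The observed statistic is the number of query elements overlapping at
#' least one feature (an element overlapping several features counts once).
#' Each null draw re-places every query element uniformly at random on the
#' genome: a chromosome is sampled with probability proportional to its
#' length among the chromosomes the element fits on, and the start is drawn
#' uniformly from [0, chrom_len - len], so element lengths are preserved and
#' no clipping occurs. The p-value uses the add-one Monte-Carlo estimator
#' (1 + #\{null >= observed\}) / (R + 1), which never returns zero.
#'
#' @param query interval data.frame (elements being tested).
#' @param features interval data.frame (annotation being tested against).
#' @param layout \code{genome_layout}.
#' @param R number of permutations (default 1000).
#' @param seed integer seed for the placement RNG.
#' @return list of class `permutation_result`: observed, null (length R),
#'   p, R, seed.
#' @export
permutation_enrichment <- function(query, features, layout, R = 1000,
                                   seed = 1) {
  stopifnot(R >= 1)
  validate_intervals(query, layout)
  validate_intervals(features, layout)
  lens <- query$end - query$start
  chr_len <- layout$lengths
  if (any(lens > max(chr_len)))
    stop("query element longer than every chromosome")
  observed <- sum(overlaps_any(query, features))
  feat <- split(features, features$chrom)
  feat <- lapply(feat, function(f) {
    g <- gr_to_gi(GenomicRanges::reduce(as_gr(f)))
    g[order(g$start), , drop = FALSE]
  })
  nq <- nrow(query)
  null <- integer(R)
  if (nq > 0) {
    state <- local_rng(seed)
    on.exit(restore_rng(state))
    fits_all <- all(lens <= min(chr_len))
    total <- nq * R
    if (fits_all) {
      ci <- sample.int(length(chr_len), total, replace = TRUE,
                       prob = chr_len)
    } else {
      ## elements that do not fit everywhere sample only eligible chromosomes
      ci <- integer(total)
      for (j in seq_len(nq)) {
        ok <- which(chr_len >= lens[j])
        idx <- seq(j, total, by = nq)
        ci[idx] <- if (length(ok) == 1) ok else
          sample(ok, R, replace = TRUE, prob = chr_len[ok])
      }
    }
    el <- rep(lens, times = R)
    start <- floor(stats::runif(total) * (chr_len[ci] - el + 1))
    hit <- logical(total)
    for (k in seq_along(chr_len)) {
      sel <- which(ci == k)
      if (!length(sel)) next
      f <- feat[[names(chr_len)[k]]]
      if (is.null(f) || nrow(f) == 0) next
      s <- start[sel]; e <- s + el[sel]
      ## overlap iff some feature has f.start < e and f.end > s
      i0 <- findInterval(s, f$start)           # last feature starting <= s
      h <- (i0 >= 1 & f$end[pmax(i0, 1)] > s) |
           (i0 < nrow(f) & f$start[i0 + 1] < e)
      hit[sel] <- h
    }
    null <- colSums(matrix(hit, nrow = nq))
  }
  p <- (1 + sum(null >= observed)) / (R + 1)
  structure(list(observed = observed, null = null, p = p, R = R,
                 seed = seed), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result: observed =", x$observed,
      " null mean =", round(mean(x$null), 2),
      " p =", signif(x$p, 4), " (R =", x$R, ")\n")
  invisible(x)
}

## RNG scoping: run a block under a private seed without disturbing the
## caller's stream.
local_rng <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  state
}
restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Transposon insertion and family enrichment in transcribed enhancers
#'
#' Compares transposon content between transcribed (TEn) and non-transcribed
#' (non-TEn) enhancers: (i) a two-sided Fisher test on the 2x2 table of
#' enhancers with / without any transposon overlap by group; (ii) per-class
#' base fractions (transposon bases over enhancer bases within each group);
#' (iii) per-family permutation enrichment run separately on the two groups,
#' with Benjamini-Hochberg correction across all family x group tests.
#'
#' @param enhancers interval data.frame with `id`.
#' @param labels data.frame (id, label) with label in \{TEn, non-TEn\}.
#' @param repeats interval data.frame with `class` and `family` columns.
#' @param layout \code{genome_layout}.
#' @param R permutations per family test.
#' @param seed base seed; each family x group test uses an offset seed.
#' @return list: fisher_p, insertion_table, class_fractions, family_enrichment
#'   (data.frame family, group, observed, p, q).
#' @export
transposon_insertion_test <- function(enhancers, labels, repeats, layout,
                                      R = 1000, seed = 1) {
  stopifnot(setequal(labels$label, intersect(labels$label,
                                             c("TEn", "non-TEn"))))
  lab <- labels$label[match(enhancers$id, labels$id)]
  if (anyNA(lab)) stop("labels do not cover the enhancer set")
  groups <- list(TEn = enhancers[lab == "TEn", , drop = FALSE],
                 `non-TEn` = enhancers[lab == "non-TEn", , drop = FALSE])
  if (any(vapply(groups, nrow, 0L) == 0)) stop("empty label group")
  has <- lapply(groups, function(g) overlaps_any(g, repeats))
  tab <- rbind(TEn = c(with = sum(has$TEn), without = sum(!has$TEn)),
               `non-TEn` = c(with = sum(has$`non-TEn`),
                             without = sum(!has$`non-TEn`)))
  fisher_p <- fisher_two_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  classes <- sort(unique(repeats$class))
  class_fractions <- do.call(rbind, lapply(names(groups), function(gn) {
    g <- groups[[gn]]
    gbases <- sum(g$end - g$start)
    data.frame(group = gn, class = classes,
               fraction = vapply(classes, function(cl) {
                 r <- repeats[repeats$class == cl, , drop = FALSE]
                 ov <- GenomicRanges::intersect(
                   GenomicRanges::reduce(as_gr(g)),
                   GenomicRanges::reduce(as_gr(r)))
                 sum(GenomicRanges::width(ov)) / gbases
               }, 0),
               stringsAsFactors = FALSE)
  }))
  families <- sort(unique(repeats$family))
  fam <- expand.grid(family = families, group = names(groups),
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(fam)), function(i) {
    r <- repeats[repeats$family == fam$family[i], , drop = FALSE]
    permutation_enrichment(groups[[fam$group[i]]], r, layout, R = R,
                           seed = seed + i)
  })
  fam$observed <- vapply(res, `[[`, 0, "observed")
  fam$p <- vapply(res, `[[`, 0, "p")
  fam$q <- bh_fdr(fam$p)
  list(fisher_p = fisher_p, insertion_table = tab,
       class_fractions = class_fractions, family_enrichment = fam)
}

#' Read RepeatMasker .out annotation
#'
#' Parses the whitespace-aligned RepeatMasker output table (two header lines
#' then one row per hit), extracting genomic coordinates (converted to
#' 0-based half-open) and the repeat class/family column, which is split at
#' the first "/" into class and family. A BED file with `id` encoding
#' "class/family" in column 4 is accepted as a fallback.
#'
#' @param path `.out` file or BED fallback.
#' @return interval data.frame with `class` and `family` columns.
#' @export
read_repeatmasker <- function(path) {
  ln <- readLines(path)
  if (length(ln) && grepl("^\\s*SW", ln[1])) {
    ln <- ln[-(1:2)]
    ln <- ln[nzchar(trimws(ln))]
    f <- strsplit(trimws(ln), "\\s+")
    df <- data.frame(chrom = vapply(f, `[`, "", 5),
                     start = as.numeric(vapply(f, `[`, "", 6)) - 1,
                     end = as.numeric(vapply(f, `[`, "", 7)),
                     id = vapply(f, `[`, "", 11),
                     stringsAsFactors = FALSE)
  } else {
    df <- read_bed(path)
  }
  cf <- strsplit(df$id, "/", fixed = TRUE)
  df$class <- vapply(cf, `[`, "", 1)
  df$family <- vapply(cf, function(v)
    if (length(v) > 1) v[2] else v[1], "")
  df$family <- paste(df$class, df$family, sep = "/")
  validate_intervals(df)
  df
}
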