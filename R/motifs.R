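#' Parse a HOMER-format motif file
#'
#' Format: a header line `>consensus<TAB>name<TAB>threshold` followed by one
#' row per motif position with four whitespace-separated base probabilities
#' (A, C, G, T). Probabilities are floored at 1e-3 and renormalized so every
#' position can be log-scored; the detection threshold (natural-log odds
#' units) is stored as given. Rows that do not have four columns or do not
#' sum to ~1 raise a parse error naming the line.
#'
#' @param path file path, or a character vector of lines.
#' @return list of motifs, each a list (name, consensus, threshold, pwm)
#'   where `pwm` is an L x 4 matrix with columns A, C, G, T.
#' @export
parse_homer_motifs <- function(path) {
  ln <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  ln <- ln[nzchar(trimws(ln))]
  motifs <- list()
  i <- 1
  while (i <= length(ln)) {
    if (!startsWith(ln[i], ">"))
      stop("line ", i, ": expected motif header starting with '>'")
    hdr <- strsplit(sub("^>", "", ln[i]), "\t", fixed = TRUE)[[1]]
    if (length(hdr) < 3 || is.na(suppressWarnings(as.numeric(hdr[3]))))
      stop("line ", i, ": header must be consensus<TAB>name<TAB>threshold")
    j <- i + 1
    rows <- list()
    while (j <= length(ln) && !startsWith(ln[j], ">")) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln[j]), "\\s+")[[1]]))
      if (length(v) != 4 || anyNA(v))
        stop("line ", j, ": expected 4 numeric base probabilities")
      if (abs(sum(v) - 1) > 1e-3)
        stop("line ", j, ": probabilities sum to ", sum(v), ", not 1")
      rows[[length(rows) + 1]] <- v
      j <- j + 1
    }
    if (!length(rows)) stop("line ", i, ": motif has no probability rows")
    pwm <- do.call(rbind, rows)
    pwm <- pmax(pwm, 1e-3)
    pwm <- pwm / rowSums(pwm)
    colnames(pwm) <- c("A", "C", "G", "T")
    motifs[[length(motifs) + 1]] <-
      list(name = hdr[2], consensus = hdr[1],
           threshold = as.numeric(hdr[3]), pwm = pwm)
    i <- j
  }
  motifs
}

#' Write motifs in HOMER format
#' @param motifs list as returned by \code{parse_homer_motifs}.
#' @param path output file.
#' @export
write_homer_motifs <- function(motifs, path) {
  out <- unlist(lapply(motifs, function(m) {
    c(sprintf(">%s\t%s\t%s", m$consensus, m$name,
              format(m$threshold, trim = TRUE)),
      apply(m$pwm, 1, function(r) paste(format(r, trim = TRUE),
                                        collapse = "\t")))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Scan a sequence with a PWM (both strands)
#'
#' At every offset the log-odds score is sum over positions of
#' ln(p_base / 0.25) against a uniform background; any window containing an
#' N is unscoreable (score -Inf). A hit is emitted when the score reaches
#' the motif's threshold. Reverse-strand hits (the reverse complement of the
#' motif matching the forward sequence) are reported at the forward-strand
#' offset of the site's leftmost base.
#'
#' @param pwm a motif from \code{parse_homer_motifs}.
#' @param sequence a character string or \code{DNAString} over A, C, G, T, N.
#' @param seq_id optional id recorded in the output.
#' @return data.frame (motif, seq_id, offset, strand, score); offsets are
#'   0-based. Sequences shorter than the motif yield zero rows.
#' @export
scan_sequence <- function(pwm, sequence, seq_id = NA_character_) {
  s <- toupper(as.character(sequence))
  code <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  L <- nrow(pwm$pwm)
  n <- length(code)
  empty <- data.frame(motif = character(0), seq_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < L) return(empty)
  lo_f <- log(pwm$pwm / 0.25)
  ## reverse complement motif: reverse positions, swap A<->T, C<->G
  lo_r <- lo_f[L:1, c("T", "G", "C", "A"), drop = FALSE]
  noff <- n - L + 1
  score_strand <- function(lo) {
    sc <- numeric(noff)
    for (j in seq_len(L)) {
      b <- code[j:(j + noff - 1)]
      v <- lo[j, ][b]
      v[is.na(v)] <- -Inf          # N (or unknown base) kills the window
      sc <- sc + v
    }
    sc
  }
  sf <- score_strand(lo_f)
  sr <- score_strand(lo_r)
  hf <- which(sf >= pwm$threshold)
  hr <- which(sr >= pwm$threshold)
  nh <- length(hf) + length(hr)
  out <- data.frame(
    motif = rep(pwm$name, nh),
    seq_id = rep(seq_id, nh),
    offset = c(hf, hr) - 1L,
    strand = rep(c("+", "-"), c(length(hf), length(hr))),
    score = c(sf[hf], sr[hr]),
    stringsAsFactors = FALSE)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Scan a set of sequences with a set of motifs
#'
#' @param motifs list of motifs.
#' @param seqs named character vector or \code{DNAStringSet}.
#' @return combined hit data.frame (see \code{scan_sequence}).
#' @export
scan_set <- function(motifs, seqs) {
  seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  out <- do.call(rbind, unlist(lapply(motifs, function(m)
    lapply(seq_along(seqs), function(i)
      scan_sequence(m, seqs[[i]], ids[i]))), recursive = FALSE))
  if (is.null(out))
    out <- data.frame(motif = character(0), seq_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Known-motif enrichment of a foreground sequence set
#'
#' For each motif, counts the sequences carrying at least one hit in the
#' foreground and background sets, tests enrichment with a one-sided Fisher
#' test, and corrects across motifs with Benjamini-Hochberg. This is a
#' hit-count enrichment against a caller-supplied background (for example
#' non-specific eRNA enhancers), reported with the conventional Q < 0.01
#' significance flag.
#'
#' @param fg_seqs,bg_seqs named character vectors or \code{DNAStringSet}s.
#' @param motifs list of motifs.
#' @param q_cutoff significance threshold on the q-value.
#' @return data.frame (motif, fg_hits, fg_n, bg_hits, bg_n, p, q,
#'   significant), sorted by p.
#' @export
known_motif_enrichment <- function(fg_seqs, bg_seqs, motifs,
                                   q_cutoff = 0.01) {
  stopifnot(length(fg_seqs) > 0, length(bg_seqs) > 0)
  nf <- length(fg_seqs); nb <- length(bg_seqs)
  count_hits <- function(seqs) {
    hits <- scan_set(motifs, seqs)
    vapply(motifs, function(m)
      length(unique(hits$seq_id[hits$motif == m$name])), 0L)
  }
  fg <- count_hits(fg_seqs)
  bg <- count_hits(bg_seqs)
  p <- fisher_one_sided(fg, nf - fg, bg, nb - bg)
  out <- data.frame(motif = vapply(motifs, `[[`, "", "name"),
                    fg_hits = fg, fg_n = nf, bg_hits = bg, bg_n = nb,
                    p = p, q = bh_fdr(p), stringsAsFactors = FALSE)
  out$significant <- out$q < q_cutoff
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
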