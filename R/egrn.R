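## TAD membership: smallest TAD interval strictly containing each point
## (0-based: start <= pos < end). Returns the TAD id or NA.
tad_of <- function(chrom, pos, tads) {
  if (is.null(tads$id)) tads$id <- sprintf("tad_%05d", seq_len(nrow(tads)))
  pts <- data.frame(chrom = chrom, start = pos, end = pos + 1)
  hits <- GenomicRanges::findOverlaps(as_gr(pts), as_gr(tads),
                                      type = "within")
  out <- rep(NA_character_, length(chrom))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    w <- tads$end[sh] - tads$start[sh]
    ord <- order(qh, w)
    first <- !duplicated(qh[ord])
    out[qh[ord][first]] <- tads$id[sh[ord][first]]
  }
  out
}

#' Link transcription factors to eRNAs (TF -> eRNA edges)
#'
#' A directed TF -> eRNA edge requires all of: at least one hit of the TF's
#' binding motif in the eRNA's enhancer sequence; the TF expressed in the
#' eRNA's tissue; and Spearman rho > `rho_min` (strict) with q < `fdr`
#' across the samples. All motif-supported candidate pairs form one
#' multiple-testing batch.
#'
#' @param tf_expr TFs x samples expression matrix (TPM).
#' @param erna_expr eRNAs x samples expression matrix (RPM), same columns.
#' @param motif_hits data.frame with columns `motif` (= TF id) and `seq_id`
#'   (= eRNA id): motif hits over each eRNA's enhancer sequence.
#' @param erna_tissue named character vector: the tissue each eRNA is
#'   assigned to.
#' @param tf_expressed logical matrix TFs x tissues: is the TF expressed
#'   (mean TPM >= 1) in that tissue.
#' @param rho_min,fdr thresholds (defaults 0.5 and 0.05).
#' @return edge data.frame (source, target, type, rho, q, motif_hit).
#' @export
link_tf_to_erna <- function(tf_expr, erna_expr, motif_hits, erna_tissue,
                            tf_expressed, rho_min = 0.5, fdr = 0.05) {
  cand <- unique(data.frame(a = motif_hits$motif, b = motif_hits$seq_id,
                            stringsAsFactors = FALSE))
  cand <- cand[cand$a %in% rownames(tf_expr) &
               cand$b %in% rownames(erna_expr), , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(source = character(0), target = character(0),
                      type = character(0), rho = numeric(0), q = numeric(0),
                      motif_hit = logical(0)))
  cr <- spearman_fdr(tf_expr, erna_expr, cand)
  tis <- erna_tissue[cr$b]
  expressed <- mapply(function(tf, ti)
    !is.na(ti) && isTRUE(tf_expressed[tf, ti]), cr$a, tis)
  keep <- cr$rho > rho_min & cr$q < fdr & expressed
  data.frame(source = cr$a, target = cr$b,
             type = rep("TF->eRNA", nrow(cr)), rho = cr$rho, q = cr$q,
             motif_hit = rep(TRUE, nrow(cr)),
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

#' Link eRNAs to target genes (eRNA -> gene edges)
#'
#' Candidate pairs are all eRNA-gene combinations whose anchors (enhancer
#' center and gene TSS) lie within `max_distance` of each other on the same
#' chromosome; these form the multiple-testing batch. An edge additionally
#' requires Spearman rho > `rho_min`, q < `fdr`, and both anchors inside the
#' same TAD interval (candidates with an anchor outside every TAD are
#' dropped and counted).
#'
#' @param erna_expr eRNAs x samples RPM matrix.
#' @param gene_expr genes x samples TPM matrix, same columns.
#' @param erna_anchors data.frame (id, chrom, center).
#' @param gene_anchors data.frame (id, chrom, tss).
#' @param tads interval data.frame (with optional `id`).
#' @param rho_min,fdr,max_distance thresholds (0.3, 0.05, 1 Mb).
#' @return list: `edges` (source, target, type, rho, q, distance, tad) and
#'   `n_no_tad`, the number of candidates dropped for lacking a shared TAD
#'   assignment.
#' @export
link_erna_to_genes <- function(erna_expr, gene_expr, erna_anchors,
                               gene_anchors, tads, rho_min = 0.3,
                               fdr = 0.05, max_distance = 1e6) {
  ea <- erna_anchors[erna_anchors$id %in% rownames(erna_expr), ]
  ga <- gene_anchors[gene_anchors$id %in% rownames(gene_expr), ]
  cand <- do.call(rbind, lapply(seq_len(nrow(ea)), function(i) {
    sel <- ga$chrom == ea$chrom[i] &
      abs(ga$tss - ea$center[i]) <= max_distance
    if (!any(sel)) return(NULL)
    data.frame(a = ea$id[i], b = ga$id[sel],
               distance = abs(ga$tss[sel] - ea$center[i]),
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(source = character(0), target = character(0),
                      type = character(0), rho = numeric(0), q = numeric(0),
                      distance = numeric(0), tad = character(0))
  if (is.null(cand) || nrow(cand) == 0)
    return(list(edges = empty, n_no_tad = 0L))
  cr <- spearman_fdr(erna_expr, gene_expr, cand[c("a", "b")])
  cand <- cand[paste(cand$a, cand$b) %in% paste(cr$a, cr$b), , drop = FALSE]
  etad <- tad_of(ea$chrom[match(cr$a, ea$id)],
                 ea$center[match(cr$a, ea$id)], tads)
  gtad <- tad_of(ga$chrom[match(cr$b, ga$id)],
                 ga$tss[match(cr$b, ga$id)], tads)
  no_tad <- is.na(etad) | is.na(gtad)
  same_tad <- !no_tad & etad == gtad
  keep <- cr$rho > rho_min & cr$q < fdr & same_tad
  edges <- data.frame(source = cr$a, target = cr$b,
                      type = rep("eRNA->gene", nrow(cr)), rho = cr$rho,
                      q = cr$q, distance = cand$distance, tad = etad,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, n_no_tad = sum(no_tad))
}

#' Keep eRNAs near GWAS hits
#'
#' Retains the eRNAs whose region overlaps any GWAS hit expanded by
#' +/- `flank` (linkage-disequilibrium window).
#'
#' @param ernas interval data.frame with `id` (eRNA regions).
#' @param gwas_hits data.frame with `chrom` and `pos` (or `start`/`end`).
#' @param flank expansion in bp (default 20 kb).
#' @param layout \code{genome_layout}.
#' @return character vector of retained eRNA ids.
#' @export
filter_by_gwas <- function(ernas, gwas_hits, flank = 20000, layout) {
  if (nrow(gwas_hits) == 0) return(character(0))
  windows <- expand_points(gwas_hits, flank, layout)
  ernas$id[overlaps_any(ernas, windows)]
}

#' Assemble a directed eRNA-mediated regulatory network
#'
#' Deduplicates edges, derives the TF / eRNA / gene node sets from the edge
#' list, orders everything deterministically and attaches provenance
#' (thresholds, seed, timestampless input digests) for reproducibility.
#'
#' @param tf_edges,gene_edges edge data.frames from the two linking steps.
#' @param erna_regions interval data.frame with `id` covering every eRNA
#'   node (used later for SNP containment).
#' @param provenance named list recorded as-is (thresholds, seed, digests).
#' @return object of class `egrn`: list (nodes, edges, erna_regions,
#'   provenance).
#' @export
assemble_egrn <- function(tf_edges, gene_edges, erna_regions,
                          provenance = list()) {
  need <- function(df, cols) {
    for (cl in setdiff(cols, names(df))) df[[cl]] <- rep(NA, nrow(df))
    df[cols]
  }
  cols <- c("source", "target", "type", "rho", "q", "distance", "tad",
            "motif_hit")
  edges <- rbind(need(tf_edges, cols), need(gene_edges, cols))
  edges <- edges[!duplicated(edges[c("source", "target", "type")]), ,
                 drop = FALSE]
  edges <- edges[order(edges$type, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  ernas <- sort(unique(c(edges$target[edges$type == "TF->eRNA"],
                         edges$source[edges$type == "eRNA->gene"])))
  missing <- setdiff(ernas, erna_regions$id)
  if (length(missing))
    stop("edge endpoint(s) without an eRNA region: ",
         paste(utils::head(missing, 5), collapse = ", "))
  nodes <- list(
    tfs = sort(unique(edges$source[edges$type == "TF->eRNA"])),
    ernas = ernas,
    genes = sort(unique(edges$target[edges$type == "eRNA->gene"])))
  structure(list(nodes = nodes, edges = edges,
                 erna_regions =
                   erna_regions[erna_regions$id %in% ernas, , drop = FALSE],
                 provenance = provenance),
            class = "egrn")
}

#' @export
print.egrn <- function(x, ...) {
  cat("egrn:", length(x$nodes$tfs), "TFs ->", length(x$nodes$ernas),
      "eRNAs ->", length(x$nodes$genes), "genes;",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Refine a network by regulatory SNPs (STARR-seq)
#'
#' Drops every eRNA node whose region contains no regulatory SNP, all edges
#' incident to dropped eRNAs, and TF / gene nodes left without edges. The
#' surviving eRNAs are the hub eRNAs. Pruning is monotone: no node or edge
#' is ever added.
#'
#' @param egrn an `egrn` object.
#' @param regulatory data.frame from \code{allelic_activity_test}; only rows
#'   with `is_regulatory = TRUE` are used.
#' @param snp_positions data.frame (id, chrom, pos) for the SNPs.
#' @return refined `egrn`.
#' @export
refine_by_starr <- function(egrn, regulatory, snp_positions) {
  reg_ids <- regulatory$id[regulatory$is_regulatory]
  snps <- snp_positions[snp_positions$id %in% reg_ids, , drop = FALSE]
  keep_erna <- if (nrow(snps)) {
    pts <- data.frame(chrom = snps$chrom, start = snps$pos,
                      end = snps$pos + 1)
    egrn$erna_regions$id[overlaps_any(egrn$erna_regions, pts)]
  } else character(0)
  e <- egrn$edges
  keep <- (e$type == "TF->eRNA" & e$target %in% keep_erna) |
    (e$type == "eRNA->gene" & e$source %in% keep_erna)
  out <- egrn
  out$edges <- e[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out$nodes <- list(
    tfs = sort(unique(out$edges$source[out$edges$type == "TF->eRNA"])),
    ernas = sort(unique(c(
      out$edges$target[out$edges$type == "TF->eRNA"],
      out$edges$source[out$edges$type == "eRNA->gene"]))),
    genes = sort(unique(out$edges$target[out$edges$type == "eRNA->gene"])))
  out$erna_regions <-
    egrn$erna_regions[egrn$erna_regions$id %in% out$nodes$ernas, ,
                      drop = FALSE]
  out$provenance$starr_refined <- TRUE
  out
}

#' Export a network (edge TSV, SIF, GraphML, provenance JSON)
#'
#' @param egrn an `egrn` object.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_egrn <- function(egrn, dir, prefix = "egrn") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".edges.tsv", ".sif", ".graphml",
                                           ".provenance.json")))
  utils::write.table(egrn$edges, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sif <- sprintf("%s\t%s\t%s", egrn$edges$source,
                 ifelse(egrn$edges$type == "TF->eRNA", "binds", "targets"),
                 egrn$edges$target)
  writeLines(sif, paths[2])
  nodes <- data.frame(
    name = c(egrn$nodes$tfs, egrn$nodes$ernas, egrn$nodes$genes),
    kind = rep(c("TF", "eRNA", "gene"),
               c(length(egrn$nodes$tfs), length(egrn$nodes$ernas),
                 length(egrn$nodes$genes))))
  if (nrow(egrn$edges)) {
    g <- igraph::graph_from_data_frame(egrn$edges, directed = TRUE,
                                       vertices = nodes)
  } else {
    g <- igraph::make_empty_graph(directed = TRUE)
  }
  igraph::write_graph(g, paths[3], format = "graphml")
  jsonlite::write_json(egrn$provenance, paths[4], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Independently validate an assembled network against raw inputs
#'
#' Re-checks every emitted edge from the raw expression matrices and
#' annotations using independent primitives (\code{stats::cor.test} with the
#' t approximation, \code{stats::p.adjust} over re-derived candidate
#' batches, direct arithmetic for distance, direct containment for TADs,
#' a fresh motif re-scan, and SNP containment for refined networks).
#'
#' @param egrn an `egrn` object.
#' @param tf_expr,erna_expr,gene_expr raw expression matrices.
#' @param motifs motif list (TF ids as motif names).
#' @param enhancer_seqs named sequences of each eRNA's enhancer.
#' @param erna_anchors,gene_anchors anchor tables as in the link steps.
#' @param tads TAD intervals.
#' @param erna_tissue,tf_expressed as in \code{link_tf_to_erna}.
#' @param thresholds list with rho_tf, rho_gene, fdr, max_distance.
#' @return list (n_checked, violations): `violations` is a character vector
#'   describing every failed condition (empty when the network is valid).
#' @export
validate_egrn <- function(egrn, tf_expr, erna_expr, gene_expr, motifs,
                          enhancer_seqs, erna_anchors, gene_anchors, tads,
                          erna_tissue, tf_expressed,
                          thresholds = list(rho_tf = 0.5, rho_gene = 0.3,
                                            fdr = 0.05, max_distance = 1e6)) {
  viol <- character(0)
  e <- egrn$edges
  sp <- function(x, y) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    unname(ct$estimate)
  }
  tp <- function(rho, n) {
    tt <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  n <- ncol(erna_expr)
  te <- e[e$type == "TF->eRNA", , drop = FALSE]
  if (nrow(te)) {
    ## rebuild the candidate batch: motif-supported TF-eRNA pairs
    hits <- scan_set(motifs, enhancer_seqs)
    cand <- unique(paste(hits$motif, hits$seq_id))
    allp <- vapply(cand, function(k) {
      v <- strsplit(k, " ")[[1]]
      tp(sp(tf_expr[v[1], ], erna_expr[v[2], ]), n)
    }, 0)
    q <- stats::setNames(stats::p.adjust(allp, "BH"), cand)
    for (i in seq_len(nrow(te))) {
      key <- paste(te$source[i], te$target[i])
      rho <- sp(tf_expr[te$source[i], ], erna_expr[te$target[i], ])
      if (!key %in% cand)
        viol <- c(viol, paste("no motif hit:", key))
      if (!(rho > thresholds$rho_tf))
        viol <- c(viol, paste("TF edge rho too low:", key))
      if (!is.na(q[key]) && !(q[key] < thresholds$fdr))
        viol <- c(viol, paste("TF edge q too high:", key))
      ti <- erna_tissue[te$target[i]]
      if (is.na(ti) || !isTRUE(tf_expressed[te$source[i], ti]))
        viol <- c(viol, paste("TF not expressed in tissue:", key))
    }
  }
  ge <- e[e$type == "eRNA->gene", , drop = FALSE]
  if (nrow(ge)) {
    ## rebuild the within-distance candidate batch
    cand <- list()
    for (i in seq_len(nrow(erna_anchors))) {
      sel <- gene_anchors$chrom == erna_anchors$chrom[i] &
        abs(gene_anchors$tss - erna_anchors$center[i]) <=
          thresholds$max_distance &
        gene_anchors$id %in% rownames(gene_expr)
      if (any(sel))
        cand[[length(cand) + 1]] <-
          paste(erna_anchors$id[i], gene_anchors$id[sel])
    }
    cand <- unlist(cand)
    allp <- vapply(cand, function(k) {
      v <- strsplit(k, " ")[[1]]
      tp(sp(erna_expr[v[1], ], gene_expr[v[2], ]), n)
    }, 0)
    q <- stats::setNames(stats::p.adjust(allp, "BH"), cand)
    for (i in seq_len(nrow(ge))) {
      key <- paste(ge$source[i], ge$target[i])
      ei <- match(ge$source[i], erna_anchors$id)
      gj <- match(ge$target[i], gene_anchors$id)
      d <- abs(gene_anchors$tss[gj] - erna_anchors$center[ei])
      if (!(gene_anchors$chrom[gj] == erna_anchors$chrom[ei] &&
            d <= thresholds$max_distance))
        viol <- c(viol, paste("gene edge beyond distance:", key))
      rho <- sp(erna_expr[ge$source[i], ], gene_expr[ge$target[i], ])
      if (!(rho > thresholds$rho_gene))
        viol <- c(viol, paste("gene edge rho too low:", key))
      if (!is.na(q[key]) && !(q[key] < thresholds$fdr))
        viol <- c(viol, paste("gene edge q too high:", key))
      t_e <- tad_of(erna_anchors$chrom[ei], erna_anchors$center[ei], tads)
      t_g <- tad_of(gene_anchors$chrom[gj], gene_anchors$tss[gj], tads)
      if (is.na(t_e) || is.na(t_g) || t_e != t_g)
        viol <- c(viol, paste("gene edge not in a shared TAD:", key))
    }
  }
  list(n_checked = nrow(e), violations = viol)
}
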