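#' Default analysis thresholds
#'
#' One frozen block with every cutoff the pipeline applies: eRNA
#' detectability (mean RPM >= 1), bidirectionality bounds (5-95 percent,
#' inclusive), tissue-specificity index (> 0.8, both replicates),
#' correlation cutoffs for TF and target-gene links (Spearman > 0.5 / > 0.3
#' with FDR < 0.05), the 1 Mb target-gene distance, the +/- 20 kb GWAS
#' linkage window, the +/- 3 kb eRNA region and +/- 1 kb annotation
#' exclusion flanks, STARR coverage (> 20) and MAF screening cutoffs, the
#' super-enhancer stitch distance, the motif-enrichment Q cutoff, and the
#' permutation count R = 1000.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(detectable_rpm = 1, direction_lo = 0.05, direction_hi = 0.95,
       tsi = 0.8, rho_tf = 0.5, rho_gene = 0.3, fdr = 0.05,
       link_distance = 1e6, gwas_flank = 20000, erna_flank = 3000,
       annot_flank = 1000, tss_flank = 1000, min_coverage = 20,
       dmaf = 0.3, mixed_maf = 0.05, n_perm = 1000, motif_q = 0.01,
       stitch = 12500)
}

#' Read a pipeline run configuration from YAML
#'
#' The file may carry `seed`, `bundle_dir`, `out_dir` and a `thresholds`
#' block; thresholds not named keep their defaults and every deviation from
#' the defaults is reported via message.
#'
#' @param path YAML file.
#' @return list (seed, bundle_dir, out_dir, thresholds).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- default_thresholds()
  if (!is.null(y$thresholds)) {
    unknown <- setdiff(names(y$thresholds), names(th))
    if (length(unknown)) stop("unknown threshold(s): ",
                              paste(unknown, collapse = ", "))
    for (k in names(y$thresholds)) {
      if (!identical(as.numeric(th[[k]]), as.numeric(y$thresholds[[k]])))
        message("threshold override: ", k, " = ", y$thresholds[[k]])
      th[[k]] <- as.numeric(y$thresholds[[k]])
    }
  }
  list(seed = if (is.null(y$seed)) 1L else as.integer(y$seed),
       bundle_dir = y$bundle_dir, out_dir = y$out_dir, thresholds = th)
}

## restrict a network to a set of eRNA nodes, pruning edges and orphans
prune_egrn_to_ernas <- function(egrn, keep_ids) {
  e <- egrn$edges
  keep <- (e$type == "TF->eRNA" & e$target %in% keep_ids) |
    (e$type == "eRNA->gene" & e$source %in% keep_ids)
  out <- egrn
  out$edges <- e[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out$nodes <- list(
    tfs = sort(unique(out$edges$source[out$edges$type == "TF->eRNA"])),
    ernas = sort(unique(c(out$edges$target[out$edges$type == "TF->eRNA"],
                          out$edges$source[out$edges$type == "eRNA->gene"]))),
    genes = sort(unique(out$edges$target[out$edges$type == "eRNA->gene"])))
  out$erna_regions <-
    egrn$erna_regions[egrn$erna_regions$id %in% out$nodes$ernas, ,
                      drop = FALSE]
  out
}

#' Run the full eRNA analysis pipeline on a bundle
#'
#' Stages: enhancer catalog (replicate intersection, TSS exclusion, union
#' across conditions), activity quantification and super-enhancer calls per
#' condition, eRNA region definition and strand-specific quantification,
#' detectability and direction calls, tissue-specificity per breed (eRNAs
#' and genes), enrichment statistics (super-enhancer and gene-proximity
#' hypergeometric tests, GWAS/QTL permutation tests, transposon tests),
#' motif enrichment, TF -> eRNA -> gene network assembly per assayed tissue
#' with GWAS filtering, STARR-seq SNP screening / allelic testing and
#' network refinement, and a final independent edge validation. All
#' randomized stages draw their seeds deterministically from `seed`.
#'
#' @param bundle a `synthetic_bundle` (from \code{simulate_bundle} or
#'   \code{read_bundle}); equivalent real data assembled into the same
#'   structure works identically.
#' @param thresholds list from \code{default_thresholds} (possibly edited).
#' @param seed integer seed for the permutation stages.
#' @param out_dir optional directory: when given, per-stage tables and the
#'   networks are written as plain text.
#' @return list of class `erna_pipeline_report` with per-stage results and
#'   survivor counts.
#' @export
run_pipeline <- function(bundle, thresholds = default_thresholds(),
                         seed = 1, out_dir = NULL) {
  th <- thresholds
  layout <- bundle$layout
  ann <- bundle$annotation
  samples <- bundle$samples
  counts_log <- list()

  ## 1. enhancer catalog
  tss <- data.frame(chrom = c(ann$genes$chrom, ann$ncrnas$chrom),
                    pos = c(ann$genes$tss, ann$ncrnas$tss))
  per_cond <- lapply(bundle$peaks, function(pr) {
    merged <- intersect_then_merge(pr$rep1, pr$rep2, layout)
    list(merged = merged,
         kept = exclude_near_features(merged, tss, th$tss_flank))
  })
  counts_log$peaks_input <- sum(vapply(bundle$peaks, function(p)
    nrow(p$rep1), 0L))
  counts_log$replicate_consistent <- sum(vapply(per_cond, function(x)
    nrow(x$merged), 0L))
  counts_log$after_tss_exclusion <- sum(vapply(per_cond, function(x)
    nrow(x$kept), 0L))
  catalog <- merge_intervals(do.call(rbind, lapply(per_cond, `[[`, "kept")))
  catalog$id <- sprintf("enh_%04d", seq_len(nrow(catalog)))
  counts_log$enhancers <- nrow(catalog)

  ## 2. activity + super-enhancers per condition
  activity <- lapply(bundle$chip, function(ch)
    quantify_activity(catalog, ch$counts, ch$lib_sizes))
  super <- lapply(activity, function(a)
    call_super_enhancers(catalog, pmax(a$ip_rpm - a$input_rpm, 0),
                         th$stitch))

  ## 3. eRNA records and quantification
  records <- define_erna_regions(catalog, ann, layout, th$erna_flank,
                                 th$annot_flank)
  counts_log$erna_records <- nrow(records)
  q <- quantify_rpm(records, bundle$stranded_counts, bundle$lib_sizes,
                    samples)
  groups <- unique(paste(samples$breed, samples$tissue, sep = "."))
  detectable <- lapply(stats::setNames(groups, groups), function(g) {
    v <- strsplit(g, ".", fixed = TRUE)[[1]]
    call_detectable(q$rpm, samples, v[2], v[1], th$detectable_rpm)
  })
  detectable_any <- sort(unique(unlist(detectable)))
  counts_log$detectable_ernas <- length(detectable_any)
  direction <- global_direction(q$rpm, q$plus_fraction, samples,
                                th$detectable_rpm)
  gc <- data.frame(erna_id = records$erna_id,
                   gc_fraction = gc_fraction(interval_seqs(
                     data.frame(records[c("chrom", "start", "end")],
                                id = records$erna_id), layout)))
  ten <- label_transcribed_enhancers(
    catalog, records[records$erna_id %in% detectable_any, , drop = FALSE])

  ## per-condition expression-activity coupling
  act_cor <- lapply(stats::setNames(names(activity), names(activity)),
                    function(cond) {
    v <- strsplit(cond, ".", fixed = TRUE)[[1]]
    det <- detectable[[cond]]
    if (length(det) < 8) return(NULL)
    sel <- samples$breed == v[1] & samples$tissue == v[2]
    expr <- rowMeans(q$rpm[det, samples$sample[sel], drop = FALSE])
    enh_id <- records$enhancer_id[match(det, records$erna_id)]
    fc <- activity[[cond]]$fold_change[match(enh_id, activity[[cond]]$id)]
    ok <- !is.na(fc)
    binned_activity_correlation(expr[ok], fc[ok])
  })

  ## 4. tissue specificity per breed
  tsi_erna <- lapply(stats::setNames(unique(samples$breed),
                                     unique(samples$breed)), function(b) {
    sel <- samples[samples$breed == b, ]
    call_tissue_specific(q$rpm[, sel$sample, drop = FALSE], sel, th$tsi)
  })
  tsi_gene <- lapply(stats::setNames(unique(samples$breed),
                                     unique(samples$breed)), function(b) {
    sel <- samples[samples$breed == b, ]
    call_tissue_specific(bundle$tpm[, sel$sample, drop = FALSE], sel,
                         th$tsi)
  })
  specific_union <- function(tsis) {
    sp <- do.call(rbind, lapply(names(tsis), function(b) {
      s <- tsis[[b]][tsis[[b]]$is_specific, c("feature", "tissue")]
      if (nrow(s)) s$breed <- b
      s
    }))
    sp[!duplicated(sp$feature), , drop = FALSE]
  }
  spec_erna <- specific_union(tsi_erna)
  spec_gene <- specific_union(tsi_gene)
  counts_log$specific_ernas <- nrow(spec_erna)

  ## 5. enrichment statistics
  se_enrich <- do.call(rbind, lapply(names(super), function(cond) {
    v <- strsplit(cond, ".", fixed = TRUE)[[1]]
    se <- super[[cond]][super[[cond]]$is_super, , drop = FALSE]
    det <- detectable[[cond]]
    det_rec <- records[records$erna_id %in% det, , drop = FALSE]
    in_se <- det[overlaps_any(det_rec[c("chrom", "start", "end")], se)]
    spec <- intersect(det, spec_erna$feature[spec_erna$tissue == v[2] &
                                             spec_erna$breed == v[1]])
    m <- length(intersect(spec, in_se))
    data.frame(condition = cond, T = length(det), M = length(in_se),
               t = length(spec), m = m,
               p = if (length(det) && m <= min(length(in_se), length(spec)))
                 hypergeom_enrichment(length(det), length(in_se),
                                      length(spec), m) else NA)
  }))
  gene_near <- do.call(rbind, lapply(names(bundle$chip), function(cond) {
    v <- strsplit(cond, ".", fixed = TRUE)[[1]]
    det_g <- detectable_genes(bundle$tpm, samples, v[2], v[1],
                              th$detectable_rpm)
    spec_e <- spec_erna$feature[spec_erna$tissue == v[2]]
    er <- records[records$erna_id %in% spec_e, c("chrom", "start", "end")]
    if (nrow(er) == 0) return(NULL)
    win <- expand_points(er, 1e6, layout)
    gpos <- ann$genes[ann$genes$id %in% det_g, ]
    near <- gpos$id[overlaps_any(
      data.frame(chrom = gpos$chrom, start = gpos$tss,
                 end = gpos$tss + 1), win)]
    spec_g <- intersect(det_g,
                        spec_gene$feature[spec_gene$tissue == v[2]])
    y <- length(intersect(spec_g, near))
    data.frame(condition = cond, X = length(det_g), Y = length(near),
               x = length(spec_g), y = y,
               p = hypergeom_enrichment(length(det_g), length(near),
                                        length(spec_g), y))
  }))
  perm_block <- function(feature_tab, expand, seed0) {
    combos <- expand.grid(tissue = c("muscle", "fat"),
                          trait_class = unique(feature_tab$trait_class),
                          stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(combos)), function(i) {
      qy <- records[records$erna_id %in%
        spec_erna$feature[spec_erna$tissue == combos$tissue[i]],
        c("chrom", "start", "end")]
      ft <- feature_tab[feature_tab$trait_class == combos$trait_class[i], ]
      ft <- if (expand) expand_points(ft, th$gwas_flank, layout) else
        ft[c("chrom", "start", "end")]
      permutation_enrichment(qy, ft, layout, R = th$n_perm,
                             seed = seed0 + i)
    })
    combos$observed <- vapply(res, `[[`, 0, "observed")
    combos$p <- vapply(res, `[[`, 0, "p")
    combos$q <- bh_fdr(combos$p)
    combos
  }
  gwas_enrich <- perm_block(bundle$gwas, TRUE, seed * 1000L)
  qtl_enrich <- perm_block(bundle$qtl, FALSE, seed * 1000L + 100L)
  transposons <- transposon_insertion_test(catalog, ten, bundle$repeats,
                                           layout, R = th$n_perm,
                                           seed = seed * 1000L + 200L)

  ## 6. motif enrichment: specific vs non-specific detectable enhancers
  enh_of <- function(erna_ids) {
    eid <- records$enhancer_id[match(erna_ids, records$erna_id)]
    s <- interval_seqs(catalog[match(eid, catalog$id), ], layout)
    names(s) <- erna_ids
    s
  }
  spec_mf <- spec_erna$feature[spec_erna$tissue %in% c("muscle", "fat")]
  bg_ids <- setdiff(detectable_any, spec_erna$feature)
  bg_ids <- bg_ids[seq_len(min(150, length(bg_ids)))]
  motif_enrich <- known_motif_enrichment(enh_of(spec_mf), enh_of(bg_ids),
                                         bundle$motifs, th$motif_q)

  ## 7. networks per assayed tissue
  tf_ids <- intersect(vapply(bundle$motifs, `[[`, "", "name"),
                      rownames(bundle$tpm))
  tissues <- unique(samples$tissue)
  tf_expressed <- t(vapply(tf_ids, function(tf)
    vapply(tissues, function(ti)
      mean(bundle$tpm[tf, samples$sample[samples$tissue == ti]]) >=
        th$detectable_rpm, TRUE), logical(length(tissues))))
  colnames(tf_expressed) <- tissues
  gene_anchors <- data.frame(id = ann$genes$id, chrom = ann$genes$chrom,
                             tss = ann$genes$tss, stringsAsFactors = FALSE)
  trait_of <- c(muscle = "Meat and Carcass", fat = "Production")
  networks <- lapply(stats::setNames(c("muscle", "fat"),
                                     c("muscle", "fat")), function(ti) {
    ids <- spec_erna$feature[spec_erna$tissue == ti]
    ids <- intersect(ids, records$erna_id)
    if (!length(ids)) return(NULL)
    seqs <- enh_of(ids)
    hits <- scan_set(bundle$motifs, seqs)
    erna_expr <- q$rpm[ids, , drop = FALSE]
    tf_edges <- link_tf_to_erna(
      bundle$tpm[tf_ids, , drop = FALSE], erna_expr, hits,
      stats::setNames(rep(ti, length(ids)), ids), tf_expressed,
      th$rho_tf, th$fdr)
    erna_anchors <- data.frame(
      id = ids, chrom = records$chrom[match(ids, records$erna_id)],
      center = records$center[match(ids, records$erna_id)],
      stringsAsFactors = FALSE)
    ge <- link_erna_to_genes(erna_expr, bundle$tpm, erna_anchors,
                             gene_anchors, bundle$tads, th$rho_gene,
                             th$fdr, th$link_distance)
    regions <- data.frame(records[match(ids, records$erna_id),
                                  c("chrom", "start", "end")], id = ids)
    net <- assemble_egrn(tf_edges, ge$edges, regions,
                         provenance = list(tissue = ti, seed = seed,
                                           thresholds = th))
    hits_tab <- bundle$gwas[bundle$gwas$trait_class == trait_of[[ti]], ]
    keep <- filter_by_gwas(regions, hits_tab, th$gwas_flank, layout)
    prune_egrn_to_ernas(net, keep)
  })
  counts_log$egrn_edges <- sum(vapply(networks, function(n)
    if (is.null(n)) 0L else nrow(n$edges), 0L))

  ## 8. STARR screening, allelic testing, fat-network refinement
  cand <- screen_candidate_snps(bundle$starr$freqs,
                                records[c("chrom", "start", "end")],
                                th$dmaf, th$mixed_maf)
  counts_log$candidate_snps <- length(cand)
  reps <- collapse_output_libraries(bundle$starr$output_libs)
  merged <- merge_output_replicates(reps[[1]], reps[[2]])
  assayed <- intersect(bundle$starr$input_counts$id,
                       c(cand, "snp_lowcov", "snp_zerocell"))
  starr_res <- allelic_activity_test(
    bundle$starr$input_counts[
      bundle$starr$input_counts$id %in% assayed, , drop = FALSE],
    merged$counts[merged$counts$id %in% assayed, , drop = FALSE],
    th$min_coverage, th$fdr)
  counts_log$regulatory_snps <- sum(starr_res$is_regulatory)
  refined_fat <- if (!is.null(networks$fat))
    refine_by_starr(networks$fat, starr_res, bundle$starr$snp_positions)
  else NULL
  if (!is.null(refined_fat))
    counts_log$refined_fat_edges <- nrow(refined_fat$edges)

  ## 9. independent validation of the emitted networks
  net_tissue <- c(muscle = "muscle", fat = "fat", refined_fat = "fat")
  validation <- lapply(stats::setNames(names(net_tissue), names(net_tissue)),
                       function(nm) {
    net <- if (nm == "refined_fat") refined_fat else networks[[nm]]
    if (is.null(net) || nrow(net$edges) == 0)
      return(list(n_checked = 0L, violations = character(0)))
    ## candidate scope = the tissue-specific eRNA set the network was
    ## built from, so the re-derived multiple-testing family matches
    all_ids <- spec_erna$feature[spec_erna$tissue == net_tissue[[nm]]]
    all_ids <- intersect(all_ids, records$erna_id)
    erna_anchors <- data.frame(
      id = all_ids, chrom = records$chrom[match(all_ids, records$erna_id)],
      center = records$center[match(all_ids, records$erna_id)])
    ti <- spec_erna$tissue[match(all_ids, spec_erna$feature)]
    validate_egrn(net, bundle$tpm[tf_ids, , drop = FALSE],
                  q$rpm[all_ids, , drop = FALSE], bundle$tpm,
                  bundle$motifs, enh_of(all_ids), erna_anchors,
                  gene_anchors, bundle$tads,
                  stats::setNames(ti, all_ids), tf_expressed,
                  list(rho_tf = th$rho_tf, rho_gene = th$rho_gene,
                       fdr = th$fdr, max_distance = th$link_distance))
  })

  report <- structure(list(
    thresholds = th, seed = seed, counts = counts_log,
    catalog = catalog, activity = activity, super = super,
    records = records, rpm = q$rpm, plus_fraction = q$plus_fraction,
    detectable = detectable, direction = direction, gc = gc, ten = ten,
    activity_correlation = act_cor,
    tsi_erna = tsi_erna, tsi_gene = tsi_gene,
    specific_erna = spec_erna, specific_gene = spec_gene,
    se_enrichment = se_enrich, gene_near_enrichment = gene_near,
    gwas_enrichment = gwas_enrich, qtl_enrichment = qtl_enrich,
    transposons = transposons, motif_enrichment = motif_enrich,
    networks = networks, starr = starr_res, refined_fat = refined_fat,
    validation = validation), class = "erna_pipeline_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.erna_pipeline_report <- function(x, ...) {
  cat("erna_pipeline_report (seed", x$seed, ")\n")
  for (k in names(x$counts)) cat(sprintf("  %-24s %d\n", k, x$counts[[k]]))
  invisible(x)
}

#' Write the pipeline report as plain-text tables
#'
#' @param report an `erna_pipeline_report`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(x) {  # fixed 10-digit formatting keeps output byte-stable
    if (is.data.frame(x)) {
      for (j in seq_along(x)) if (is.numeric(x[[j]]))
        x[[j]] <- formatC(x[[j]], digits = 10, format = "g")
    }
    x
  }
  w <- function(x, f) if (!is.null(x) && nrow(x))
    write_tsv(num(x), file.path(dir, f))
  w(report$catalog, "enhancers.bed.tsv")
  w(data.frame(erna_id = rownames(report$rpm), report$rpm,
               check.names = FALSE), "erna_rpm.tsv")
  w(report$direction, "direction.tsv")
  w(report$gc, "gc.tsv")
  w(report$ten, "ten_labels.tsv")
  w(do.call(rbind, lapply(names(report$tsi_erna), function(b)
    data.frame(breed = b, report$tsi_erna[[b]]))), "tsi_erna.tsv")
  w(report$specific_erna, "specific_erna.tsv")
  w(report$specific_gene, "specific_gene.tsv")
  w(report$se_enrichment, "se_enrichment.tsv")
  w(report$gene_near_enrichment, "gene_near_enrichment.tsv")
  w(report$gwas_enrichment, "gwas_enrichment.tsv")
  w(report$qtl_enrichment, "qtl_enrichment.tsv")
  w(report$transposons$family_enrichment, "transposon_families.tsv")
  w(report$motif_enrichment, "motif_enrichment.tsv")
  w(report$starr, "starr_results.tsv")
  for (ti in names(report$networks))
    if (!is.null(report$networks[[ti]]))
      write_egrn(report$networks[[ti]], dir, paste0("egrn_", ti))
  if (!is.null(report$refined_fat))
    write_egrn(report$refined_fat, dir, "egrn_fat_refined")
  jsonlite::write_json(
    list(seed = report$seed, counts = report$counts,
         validation = lapply(report$validation, function(v)
           list(n_checked = v$n_checked,
                n_violations = length(v$violations)))),
    file.path(dir, "run_report.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
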