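#' Configuration for the synthetic multi-omics bundle
#'
#' Defaults describe a desk-scale study emulating the real design: two
#' breeds x five tissues x two replicates (20 expression samples), H3K27ac
#' peaks with replicate jitter for the four breed x assayed-tissue
#' conditions, ~260 enhancers on a two-chromosome genome partitioned into
#' 80 kb TADs, 50 planted TF -> eRNA -> gene chains (target pairwise
#' Spearman ~0.9), tissue-specific features planted at 20-fold over
#' baseline, log-normal baseline expression (meanlog 1, sdlog 0.7), GWAS
#' hits inside every chain eRNA plus background hits outside, and STARR-seq
#' allele counts with a planted 3x skew at ~500x depth for 40 of 100
#' candidate SNPs.
#'
#' @param seed integer master seed; a fixed seed reproduces the bundle
#'   exactly.
#' @param ... named overrides of any default listed below.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    chrom_lengths = c(chr1 = 3200000, chr2 = 2400000),
    tad_size = 80000,
    tissues = c("muscle", "fat", "heart", "liver", "spleen"),
    breeds = c("DU", "ES"),
    chip_tissues = c("muscle", "fat"),
    n_chains = 50,
    n_specific_extra_erna = 60,
    n_specific_extra_gene = 40,
    n_other_gene = 60,
    n_ncrna = 30,
    fold = 20,
    rho_target = 0.9,
    meanlog = 1,
    sdlog = 0.7,
    sample_sdlog = 0.35,
    lib_size_rna = 2e7,
    lib_size_chip = 1e7,
    unidirectional_fraction = 0.25,
    peak_jitter = 200,
    motif_length = 12,
    n_gwas_outside = 100,
    n_qtl = 20,
    n_repeats = 800,
    starr_depth = 500,
    starr_effect = 3,
    n_snp_true = 40,
    n_snp_null = 60)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$rho_target > -1, cfg$rho_target < 1,
            cfg$n_snp_true + cfg$n_snp_null <= 2 * cfg$n_chains)
  structure(cfg, class = c("synthetic_config", "list"))
}

## deterministic genomic layout: TAD roles and planted feature coordinates
plan_layout <- function(cfg) {
  starts <- unlist(lapply(names(cfg$chrom_lengths), function(ch)
    stats::setNames(seq(0, cfg$chrom_lengths[[ch]] - cfg$tad_size,
                        by = cfg$tad_size),
                    rep(ch, cfg$chrom_lengths[[ch]] %/% cfg$tad_size))))
  tads <- data.frame(chrom = names(starts), start = as.numeric(starts),
                     end = as.numeric(starts) + cfg$tad_size,
                     stringsAsFactors = FALSE)
  tads$id <- sprintf("tad_%03d", seq_len(nrow(tads)))
  n_tf_tads <- ceiling(cfg$n_chains / 10)
  n_ee_tads <- ceiling(cfg$n_specific_extra_erna / 10)
  n_ge_tads <- ceiling(cfg$n_specific_extra_gene / 10)
  need <- cfg$n_chains + n_tf_tads + n_ee_tads + n_ge_tads
  if (need + 1 > nrow(tads))
    stop("infeasible packing: genome too small for the requested features")
  role <- rep("misc", nrow(tads))
  role[seq_len(cfg$n_chains)] <- "chain"
  role[cfg$n_chains + seq_len(n_tf_tads)] <- "tf"
  role[cfg$n_chains + n_tf_tads + seq_len(n_ee_tads)] <- "erna_extra"
  role[cfg$n_chains + n_tf_tads + n_ee_tads + seq_len(n_ge_tads)] <-
    "gene_extra"
  tads$role <- role
  chain_tissue <- rep(c("muscle", "fat"), length.out = cfg$n_chains)

  chain_tads <- tads[tads$role == "chain", ]
  enh <- data.frame(chrom = chain_tads$chrom,
                    start = chain_tads$start + 18000,
                    end = chain_tads$start + 20000,
                    role = "chain", chain = seq_len(cfg$n_chains),
                    tissue = chain_tissue, stringsAsFactors = FALSE)
  dk <- do.call(rbind, lapply(c(2000, 62000, 70000), function(off)
    data.frame(chrom = chain_tads$chrom, start = chain_tads$start + off,
               end = chain_tads$start + off + 1600, role = "decoy",
               chain = NA, tissue = NA, stringsAsFactors = FALSE)))
  ee_tads <- tads[tads$role == "erna_extra", ]
  ee <- do.call(rbind, lapply(seq_len(nrow(ee_tads)), function(i)
    data.frame(chrom = ee_tads$chrom[i],
               start = ee_tads$start[i] + 4000 + (0:9) * 7600,
               end = ee_tads$start[i] + 4000 + (0:9) * 7600 + 1800,
               role = "specific", chain = NA, tissue = NA,
               stringsAsFactors = FALSE)))
  ee <- ee[seq_len(cfg$n_specific_extra_erna), ]
  ee$tissue <- rep(cfg$tissues, length.out = nrow(ee))
  enhancers <- rbind(enh, dk, ee)
  enhancers <- enhancers[order(enhancers$chrom, enhancers$start), ]
  rownames(enhancers) <- NULL

  tf_tads <- tads[tads$role == "tf", ]
  tf <- do.call(rbind, lapply(seq_len(nrow(tf_tads)), function(i)
    data.frame(chrom = tf_tads$chrom[i],
               start = tf_tads$start[i] + 4000 + (0:9) * 7600,
               end = tf_tads$start[i] + 4000 + (0:9) * 7600 + 3000,
               stringsAsFactors = FALSE)))
  tf <- tf[seq_len(cfg$n_chains), ]
  tf$id <- sprintf("tf_%03d", seq_len(cfg$n_chains))
  tf$role <- "tf"; tf$chain <- seq_len(cfg$n_chains)
  tf$tissue <- chain_tissue

  tg <- data.frame(chrom = chain_tads$chrom,
                   start = chain_tads$start + 48000,
                   end = chain_tads$start + 52000,
                   id = sprintf("tg_%03d", seq_len(cfg$n_chains)),
                   role = "target", chain = seq_len(cfg$n_chains),
                   tissue = chain_tissue, stringsAsFactors = FALSE)

  ge_tads <- tads[tads$role == "gene_extra", ]
  sg <- do.call(rbind, lapply(seq_len(nrow(ge_tads)), function(i)
    data.frame(chrom = ge_tads$chrom[i],
               start = ge_tads$start[i] + 4000 + (0:9) * 7600,
               end = ge_tads$start[i] + 4000 + (0:9) * 7600 + 3000,
               stringsAsFactors = FALSE)))
  sg <- sg[seq_len(cfg$n_specific_extra_gene), ]
  sg$id <- sprintf("sg_%03d", nrow(sg) |> seq_len())
  sg$role <- "specific_gene"; sg$chain <- NA
  sg$tissue <- rep(cfg$tissues, length.out = nrow(sg))

  misc_tads <- tads[tads$role == "misc", ]
  n_misc <- cfg$n_other_gene + cfg$n_ncrna + 1
  slots <- do.call(rbind, lapply(seq_len(nrow(misc_tads)), function(i)
    data.frame(chrom = misc_tads$chrom[i],
               start = misc_tads$start[i] + 2000 + (0:18) * 4100,
               end = misc_tads$start[i] + 2000 + (0:18) * 4100 + 2000,
               stringsAsFactors = FALSE)))
  if (n_misc > nrow(slots))
    stop("infeasible packing: not enough slots for background genes")
  slots <- slots[seq_len(n_misc), ]
  og <- slots[seq_len(cfg$n_other_gene), ]
  og$id <- sprintf("og_%03d", seq_len(cfg$n_other_gene))
  og$role <- "other"; og$chain <- NA; og$tissue <- NA
  gz <- slots[cfg$n_other_gene + 1, ]
  gz$id <- "gene_zero"; gz$role <- "zero"; gz$chain <- NA; gz$tissue <- NA
  nc <- slots[cfg$n_other_gene + 1 + seq_len(cfg$n_ncrna), ]
  nc$id <- sprintf("nc_%03d", seq_len(cfg$n_ncrna))
  genes <- rbind(tf, tg, sg, og, gz)
  genes$strand <- rep(c("+", "-"), length.out = nrow(genes))
  genes$strand[genes$role %in% c("tf", "target")] <- "+"
  genes$biotype <- "protein_coding"
  nc$strand <- "+"
  nc$biotype <- rep(c("miRNA", "misc_RNA", "rRNA", "snoRNA", "snRNA",
                      "tRNA", "lncRNA"), length.out = nrow(nc))
  list(tads = tads[c("chrom", "start", "end", "id")],
       tad_roles = tads, enhancers = enhancers, genes = genes, ncrnas = nc,
       chain_tissue = chain_tissue)
}

#' Generate the synthetic reference: genome, annotation, peaks, TADs,
#' repeats and motif file
#'
#' Chromosome sequences are i.i.d. uniform bases; gene and ncRNA models are
#' non-overlapping; each breed x ChIP-tissue condition gets two replicate
#' peak sets whose boundaries jitter by at most the configured amount so
#' replicate intersection retains every planted peak; TADs partition each
#' chromosome; one PWM per chain TF is embedded (exact consensus) in that
#' chain's enhancer and, by construction, matches above threshold nowhere
#' else among the enhancer sequences.
#'
#' @param cfg a \code{synthetic_config}.
#' @return list: layout (with sequence), annotation, peaks (nested list
#'   condition -> replicate), tads, repeats, motifs, planted (planted
#'   feature tables).
#' @export
generate_reference <- function(cfg) {
  state <- local_rng(cfg$seed)
  on.exit(restore_rng(state))
  plan <- plan_layout(cfg)
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(cfg$chrom_lengths, function(L)
    sample(bases, L, replace = TRUE))

  ## one motif per chain TF, embedded at enhancer start + 300
  L <- cfg$motif_length
  consensi <- character(0)
  while (length(consensi) < cfg$n_chains) {
    cand <- paste(sample(bases, L, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cand)))
    if (!cand %in% consensi && !rc %in% consensi && cand != rc)
      consensi <- c(consensi, cand)
  }
  chain_enh <- plan$enhancers[plan$enhancers$role == "chain", ]
  chain_enh <- chain_enh[order(chain_enh$chain), ]
  for (i in seq_len(cfg$n_chains)) {
    pos <- chain_enh$start[i] + 300
    seqs[[chain_enh$chrom[i]]][(pos + 1):(pos + L)] <-
      strsplit(consensi[i], "")[[1]]
  }
  per_site <- log(0.997 / 0.25)
  motifs <- lapply(seq_len(cfg$n_chains), function(i) {
    pwm <- matrix(0.001, nrow = L, ncol = 4,
                  dimnames = list(NULL, bases))
    pwm[cbind(seq_len(L), match(strsplit(consensi[i], "")[[1]], bases))] <-
      0.997
    list(name = sprintf("tf_%03d", i), consensus = consensi[i],
         threshold = round(0.9 * L * per_site, 4), pwm = pwm)
  })

  ## scrub chance matches: any exact occurrence of a consensus (either
  ## strand) outside its planted site is destroyed by a point change.
  ## Scan the planted intervals expanded by the replicate jitter so the
  ## derived (jitter-widened) catalog is covered too.
  enh <- plan$enhancers
  enh$start <- pmax(0, enh$start - cfg$peak_jitter - L)
  enh$end <- pmin(cfg$chrom_lengths[enh$chrom] + 0,
                  enh$end + cfg$peak_jitter + L)
  planted_at <- stats::setNames(chain_enh$start + 300,
                                paste0(chain_enh$chrom, ":",
                                       chain_enh$start + 300))
  for (iter in 1:8) {
    enh_seq <- Biostrings::DNAStringSet(vapply(seq_len(nrow(enh)),
      function(i) paste(seqs[[enh$chrom[i]]][(enh$start[i] + 1):enh$end[i]],
                        collapse = ""), ""))
    dirty <- FALSE
    for (i in seq_len(cfg$n_chains)) {
      for (pat in c(consensi[i], as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(consensi[i]))))) {
        m <- Biostrings::vmatchPattern(pat, enh_seq)
        for (j in seq_along(m)) {
          st <- Biostrings::startIndex(m)[[j]]
          if (is.null(st)) next
          for (s0 in st) {
            gpos <- enh$start[j] + s0 - 1      # 0-based genomic match start
            if (paste0(enh$chrom[j], ":", gpos) %in% names(planted_at) &&
                pat == consensi[i]) next       # the planted site itself
            flip <- gpos + ceiling(L / 2)      # mutate the middle base
            cur <- seqs[[enh$chrom[j]]][flip + 1]
            seqs[[enh$chrom[j]]][flip + 1] <- setdiff(bases, cur)[1]
            dirty <- TRUE
          }
        }
      }
    }
    if (!dirty) break
  }

  layout <- genome_layout(
    cfg$chrom_lengths,
    Biostrings::DNAStringSet(stats::setNames(
      vapply(seqs, paste, "", collapse = ""), names(cfg$chrom_lengths))))

  annotation <- annotation_set(
    genes = plan$genes[c("chrom", "start", "end", "id", "strand",
                         "biotype")],
    ncrnas = plan$ncrnas[c("chrom", "start", "end", "id", "strand",
                           "biotype")])

  conditions <- as.vector(outer(cfg$breeds, cfg$chip_tissues, paste,
                                sep = "."))
  peaks <- lapply(stats::setNames(conditions, conditions), function(cond)
    lapply(stats::setNames(1:2, c("rep1", "rep2")), function(r) {
      n <- nrow(enh)
      data.frame(chrom = enh$chrom,
                 start = pmax(0, enh$start +
                                sample(-cfg$peak_jitter:cfg$peak_jitter, n,
                                       replace = TRUE)),
                 end = pmin(layout$lengths[enh$chrom], enh$end +
                              sample(-cfg$peak_jitter:cfg$peak_jitter, n,
                                     replace = TRUE)),
               stringsAsFactors = FALSE)
    }))

  rep_families <- c("LINE/L1", "LINE/L2", "SINE/PRE1", "SINE/MIR",
                    "LTR/ERV1", "LTR/ERVL", "LTR/ERVK", "DNA/hAT",
                    "DNA/TcMar")
  rlen <- sample(200:2000, cfg$n_repeats, replace = TRUE)
  rchr <- sample(names(cfg$chrom_lengths), cfg$n_repeats, replace = TRUE,
                 prob = cfg$chrom_lengths)
  rstart <- floor(stats::runif(cfg$n_repeats) *
                    (cfg$chrom_lengths[rchr] - rlen))
  fam <- sample(rep_families, cfg$n_repeats, replace = TRUE)
  repeats <- data.frame(chrom = rchr, start = rstart, end = rstart + rlen,
                        id = fam,
                        class = vapply(strsplit(fam, "/"), `[`, "", 1),
                        family = fam, stringsAsFactors = FALSE)
  repeats <- sort_intervals(repeats)

  list(layout = layout, annotation = annotation, peaks = peaks,
       tads = plan$tads, repeats = repeats, motifs = motifs, planted = plan)
}

## latent-factor loading that targets a pairwise Spearman for joint normals
spearman_loading <- function(rho_s) sqrt(2 * sin(pi * rho_s / 6))

#' Generate the synthetic expression data
#'
#' Derives the enhancer catalog and eRNA records exactly as the analysis
#' does (replicate intersection, TSS exclusion, center +/- 3 kb regions,
#' annotation masking), then simulates: a gene TPM matrix and strand-specific
#' eRNA read counts over 20 samples with log-normal baseline, a per-chain
#' latent factor mixing TF, eRNA and target gene to the target pairwise
#' Spearman, a multiplicative tissue boost for planted tissue-specific
#' features in both breeds, Poisson sampling of totals at the configured
#' library size, and a Beta-distributed plus-strand fraction (Beta(8,1) for
#' the unidirectional-designated fraction, Beta(5,5) otherwise). ChIP IP /
#' INPUT counts per condition track expected expression so activity and
#' expression correlate. Includes deliberately degenerate records: one
#' all-zero eRNA, one all-zero gene row, one zero-INPUT enhancer.
#'
#' @param cfg a \code{synthetic_config}.
#' @param reference output of \code{generate_reference}.
#' @return list: samples, catalog (derived enhancers), records (eRNA
#'   regions), stranded_counts, lib_sizes, tpm, chip (per condition),
#'   role_map, truth tables for specific features and chain edges.
#' @export
generate_expression <- function(cfg, reference) {
  state <- local_rng(cfg$seed + 1)
  on.exit(restore_rng(state))
  layout <- reference$layout
  ann <- reference$annotation

  ## derived catalog: replicate intersection per condition, TSS exclusion,
  ## union across conditions
  tss <- data.frame(chrom = c(ann$genes$chrom, ann$ncrnas$chrom),
                    pos = c(ann$genes$tss, ann$ncrnas$tss))
  per_cond <- lapply(reference$peaks, function(pr) {
    m <- intersect_then_merge(pr$rep1, pr$rep2, layout)
    exclude_near_features(m, tss, 1000)
  })
  catalog <- merge_intervals(do.call(rbind, per_cond))
  catalog$id <- sprintf("enh_%04d", seq_len(nrow(catalog)))

  ## match planted enhancers to derived ids via center containment
  planted <- reference$planted$enhancers
  pc <- data.frame(chrom = planted$chrom,
                   start = floor((planted$start + planted$end) / 2),
                   end = floor((planted$start + planted$end) / 2) + 1)
  hit <- GenomicRanges::findOverlaps(as_gr(pc), as_gr(catalog))
  planted$derived_id <- NA_character_
  planted$derived_id[S4Vectors::queryHits(hit)] <-
    catalog$id[S4Vectors::subjectHits(hit)]

  records <- define_erna_regions(catalog, ann, layout)
  role_map <- planted[!is.na(planted$derived_id),
                      c("derived_id", "role", "chain", "tissue")]
  role_map$erna_id <- paste0("erna_", role_map$derived_id)

  samples <- expand.grid(replicate = 1:2, tissue = cfg$tissues,
                         breed = cfg$breeds, stringsAsFactors = FALSE)
  samples <- samples[c("breed", "tissue", "replicate")]
  samples$sample <- sprintf("%s_%s_r%d", samples$breed, samples$tissue,
                            samples$replicate)
  ns <- nrow(samples)

  ## expression model: a per-feature baseline level (log-normal across
  ## features, meanlog/sdlog) plus smaller per-sample variation
  ## (sample_sdlog) that carries the per-chain latent factor; planted
  ## tissue-specific features are multiplied by `fold` in their tissue in
  ## both breeds. Spearman between chain members depends only on the latent
  ## mixing, not on the variance scales.
  lam <- spearman_loading(cfg$rho_target)
  z <- matrix(stats::rnorm(cfg$n_chains * ns), cfg$n_chains, ns)
  logexpr <- function(chain, tissue) {
    e <- stats::rnorm(ns)
    core <- if (!is.na(chain)) lam * z[chain, ] + sqrt(1 - lam^2) * e else e
    x <- cfg$meanlog + cfg$sdlog * stats::rnorm(1) +
      cfg$sample_sdlog * core
    if (!is.na(tissue)) x <- x + log(cfg$fold) * (samples$tissue == tissue)
    x
  }

  ## gene TPM
  g <- reference$planted$genes
  tpm <- t(vapply(seq_len(nrow(g)), function(i)
    if (g$role[i] == "zero") rep(0, ns) else
      exp(logexpr(g$chain[i], g$tissue[i])), numeric(ns)))
  dimnames(tpm) <- list(g$id, samples$sample)

  ## eRNA stranded counts
  ids <- records$erna_id
  info <- role_map[match(ids, role_map$erna_id), ]
  uni <- stats::runif(length(ids)) < cfg$unidirectional_fraction
  plus_prob <- ifelse(uni, stats::rbeta(length(ids), 8, 1),
                      stats::rbeta(length(ids), 5, 5))
  zero_id <- utils::tail(ids[!is.na(info$role) & info$role == "decoy"], 1)
  lib_sizes <- stats::setNames(rep(cfg$lib_size_rna, ns), samples$sample)
  sc <- do.call(rbind, lapply(seq_along(ids), function(i) {
    if (length(zero_id) && ids[i] == zero_id) {
      total <- rep(0L, ns)
    } else {
      mu <- exp(logexpr(info$chain[i], info$tissue[i]))
      total <- stats::rpois(ns, mu * cfg$lib_size_rna / 1e6)
    }
    plus <- stats::rbinom(ns, total, plus_prob[i])
    data.frame(erna_id = ids[i], sample = samples$sample,
               plus_count = plus, minus_count = total - plus,
               stringsAsFactors = FALSE)
  }))

  ## ChIP counts per condition: IP tracks expression, INPUT is flat
  rpm_mat <- quantify_rpm(records, sc, lib_sizes, samples)$rpm
  chip <- lapply(stats::setNames(names(reference$peaks),
                                 names(reference$peaks)), function(cond) {
    parts <- strsplit(cond, ".", fixed = TRUE)[[1]]
    sel <- samples$breed == parts[1] & samples$tissue == parts[2]
    mean_rpm <- rowMeans(rpm_mat[, samples$sample[sel], drop = FALSE])
    mean_rpm <- mean_rpm[paste0("erna_", catalog$id)]
    ip_mu <- (1 + 2 * mean_rpm) * cfg$lib_size_chip / 1e6
    counts <- data.frame(id = catalog$id,
                         ip_count = stats::rpois(nrow(catalog), ip_mu),
                         input_count = stats::rpois(nrow(catalog),
                                                    cfg$lib_size_chip / 1e6),
                         stringsAsFactors = FALSE)
    list(counts = counts,
         lib_sizes = list(ip = cfg$lib_size_chip,
                          input = cfg$lib_size_chip))
  })
  ## degenerate path: one enhancer with zero INPUT signal in one condition
  dec <- role_map$derived_id[role_map$role == "decoy"][1]
  if (!is.na(dec))
    chip[[1]]$counts$input_count[chip[[1]]$counts$id == dec] <- 0L

  truth_specific_erna <- stats::na.omit(data.frame(
    erna_id = role_map$erna_id, tissue = role_map$tissue,
    role = role_map$role, stringsAsFactors = FALSE))
  truth_specific_gene <- g[g$role %in% c("tf", "target", "specific_gene"),
                           c("id", "tissue", "role")]
  chains <- role_map[role_map$role == "chain" & !is.na(role_map$chain), ]
  chains <- chains[order(chains$chain), ]
  truth_edges <- rbind(
    data.frame(source = sprintf("tf_%03d", chains$chain),
               target = chains$erna_id, type = "TF->eRNA",
               stringsAsFactors = FALSE),
    data.frame(source = chains$erna_id,
               target = sprintf("tg_%03d", chains$chain),
               type = "eRNA->gene", stringsAsFactors = FALSE))

  list(samples = samples, catalog = catalog, records = records,
       stranded_counts = sc, lib_sizes = lib_sizes, tpm = tpm, chip = chip,
       role_map = role_map,
       truth = list(specific_erna = truth_specific_erna,
                    specific_gene = truth_specific_gene,
                    edges = truth_edges,
                    chains = chains))
}

#' Generate GWAS hits and QTL intervals
#'
#' One hit is planted inside every chain eRNA region (trait class matching
#' the chain tissue); background hits are rejection-sampled to fall outside
#' every eRNA region expanded by 20 kb; QTL are long random intervals.
#'
#' @param cfg config; @param reference,expression upstream stages.
#' @return list (gwas, qtl).
#' @export
generate_gwas <- function(cfg, reference, expression) {
  state <- local_rng(cfg$seed + 2)
  on.exit(restore_rng(state))
  layout <- reference$layout
  classes <- c("Meat and Carcass", "Health", "Production", "Reproduction",
               "Exterior")
  chains <- expression$truth$chains
  rec <- expression$records
  ctr <- rec$center[match(chains$erna_id, rec$erna_id)]
  inside <- data.frame(chrom = rec$chrom[match(chains$erna_id, rec$erna_id)],
                       pos = ctr + 500,
                       trait_class = ifelse(chains$tissue == "muscle",
                                            "Meat and Carcass", "Production"),
                       stringsAsFactors = FALSE)
  windows <- expand_points(rec[c("chrom", "start", "end")], 20000, layout)
  out <- data.frame(chrom = character(0), pos = numeric(0))
  while (nrow(out) < cfg$n_gwas_outside) {
    k <- cfg$n_gwas_outside * 2
    ch <- sample(names(layout$lengths), k, replace = TRUE,
                 prob = layout$lengths)
    pos <- floor(stats::runif(k) * (layout$lengths[ch] - 1))
    cand <- data.frame(chrom = ch, pos = pos)
    pts <- data.frame(chrom = ch, start = pos, end = pos + 1)
    out <- rbind(out, cand[!overlaps_any(pts, windows), ])
  }
  out <- out[seq_len(cfg$n_gwas_outside), ]
  out$trait_class <- sample(classes, nrow(out), replace = TRUE)
  gwas <- rbind(inside, out)
  rownames(gwas) <- NULL
  qlen <- sample(100000:300000, cfg$n_qtl, replace = TRUE)
  qch <- sample(names(layout$lengths), cfg$n_qtl, replace = TRUE,
                prob = layout$lengths)
  qstart <- floor(stats::runif(cfg$n_qtl) * (layout$lengths[qch] - qlen))
  qtl <- data.frame(chrom = qch, start = qstart, end = qstart + qlen,
                    trait_class = sample(classes, cfg$n_qtl, replace = TRUE),
                    stringsAsFactors = FALSE)
  list(gwas = gwas, qtl = sort_intervals(qtl))
}

#' Generate STARR-seq candidate SNPs and allele count tables
#'
#' Two SNPs are placed inside every chain eRNA region; the first
#' `n_snp_true + n_snp_null` of them are the assayed candidates, all passing
#' the population-frequency screen (east-west MAF difference > 0.3, mixed
#' MAF > 0.05); additional SNPs failing the screen (small frequency
#' difference, low mixed MAF, or outside eRNAs) are included as negatives.
#' Input allele counts are symmetric binomial at the configured depth;
#' output counts come from four libraries (two per biological replicate) at
#' half depth each, with alt-allele probability e/(1+e) for the planted
#' regulatory SNPs and 1/2 for nulls. Two degenerate SNPs exercise the
#' coverage filter and the zero-cell path.
#'
#' @param cfg config; @param reference,expression upstream stages.
#' @return list: freqs, input_counts, output_libs (4), truth (true/null
#'   ids).
#' @export
generate_starr_counts <- function(cfg, reference, expression) {
  state <- local_rng(cfg$seed + 3)
  on.exit(restore_rng(state))
  rec <- expression$records
  chains <- expression$truth$chains
  ctr <- rec$center[match(chains$erna_id, rec$erna_id)]
  chrom <- rec$chrom[match(chains$erna_id, rec$erna_id)]
  pos <- c(rbind(ctr - 1200, ctr + 1300))
  chrom2 <- rep(chrom, each = 2)
  n_cand <- cfg$n_snp_true + cfg$n_snp_null
  if (n_cand > length(pos)) stop("not enough chain SNP slots")
  cand <- data.frame(id = sprintf("snp_%03d", seq_len(n_cand)),
                     chrom = chrom2[seq_len(n_cand)],
                     pos = pos[seq_len(n_cand)],
                     east_maf = stats::runif(n_cand, 0.38, 0.5),
                     west_maf = stats::runif(n_cand, 0, 0.07),
                     mixed_maf = stats::runif(n_cand, 0.06, 0.45),
                     stringsAsFactors = FALSE)
  ## screen-failing negatives: small delta, low mixed pool, outside eRNAs
  neg_in <- data.frame(id = sprintf("snpneg_%03d", 1:20),
                       chrom = chrom2[1:20],
                       pos = pos[1:20] + 13,
                       east_maf = stats::runif(20, 0.2, 0.3),
                       west_maf = stats::runif(20, 0.1, 0.2),
                       mixed_maf = stats::runif(20, 0.06, 0.45),
                       stringsAsFactors = FALSE)
  layout <- reference$layout
  og <- reference$planted$genes[
    match(sprintf("og_%03d", 1:20), reference$planted$genes$id), ]
  far <- data.frame(id = sprintf("snpneg_%03d", 21:40),
                    chrom = og$chrom,
                    east_maf = stats::runif(20, 0.38, 0.5),
                    west_maf = stats::runif(20, 0, 0.07),
                    mixed_maf = stats::runif(20, 0.06, 0.45),
                    stringsAsFactors = FALSE)
  far$pos <- og$start + 100
  freqs <- rbind(cand, neg_in[names(cand)], far[names(cand)])
  truth_true <- cand$id[seq_len(cfg$n_snp_true)]
  truth_null <- cand$id[cfg$n_snp_true + seq_len(cfg$n_snp_null)]

  assay <- rbind(cand[c("id", "chrom", "pos")],
                 data.frame(id = c("snp_lowcov", "snp_zerocell"),
                            chrom = chrom2[1:2],
                            pos = pos[1:2] + c(333, 444)))
  depth <- cfg$starr_depth
  e <- cfg$starr_effect
  n_in <- stats::rpois(nrow(assay), depth)
  n_in[assay$id == "snp_lowcov"] <- 10L
  alt_in <- stats::rbinom(nrow(assay), n_in, 0.5)
  alt_in[assay$id == "snp_zerocell"] <- 0L
  input_counts <- data.frame(id = assay$id, ref_count = n_in - alt_in,
                             alt_count = alt_in, stringsAsFactors = FALSE)
  p_alt <- ifelse(assay$id %in% truth_true, e / (1 + e), 0.5)
  output_libs <- lapply(1:4, function(l) {
    n <- stats::rpois(nrow(assay), depth / 2)
    n[assay$id == "snp_lowcov"] <- 4L
    alt <- stats::rbinom(nrow(assay), n, p_alt)
    alt[assay$id == "snp_zerocell"] <- 0L
    data.frame(id = assay$id, ref_count = n - alt, alt_count = alt,
               stringsAsFactors = FALSE)
  })
  list(freqs = freqs, snp_positions = assay, input_counts = input_counts,
       output_libs = output_libs,
       truth = list(regulatory = truth_true, null = truth_null))
}

#' Generate the complete synthetic bundle
#'
#' Runs reference, expression, GWAS/QTL and STARR generation under one
#' master seed. A fixed seed yields an identical bundle.
#'
#' @param cfg a \code{synthetic_config}.
#' @return list of class `synthetic_bundle` combining all stages plus the
#'   config.
#' @export
simulate_bundle <- function(cfg = synthetic_config()) {
  reference <- generate_reference(cfg)
  expression <- generate_expression(cfg, reference)
  gq <- generate_gwas(cfg, reference, expression)
  starr <- generate_starr_counts(cfg, reference, expression)
  structure(c(list(config = cfg), reference, expression,
              gq, list(starr = starr)),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle: seed", x$config$seed, "-",
      nrow(x$catalog), "enhancers,", nrow(x$records), "eRNA records,",
      nrow(x$tpm), "genes,", nrow(x$samples), "samples\n")
  invisible(x)
}
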