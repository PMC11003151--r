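## plain-text serialization of a synthetic bundle: every file goes through
## the package's own readers on the way back in.

write_tsv <- function(x, path, col.names = TRUE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}

write_gtf <- function(annotation, path) {
  fmt <- function(df, feature) {
    if (nrow(df) == 0) return(character(0))
    sprintf('%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
            df$chrom, df$start + 1, df$end, df$strand, df$id, df$biotype)
  }
  writeLines(c(fmt(annotation$genes, "gene"), fmt(annotation$ncrnas, "gene")),
             path)
  invisible(path)
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Emits FASTA, chromosome sizes, per-condition replicate peak BEDs, GTF
#' annotation, TAD/repeat BEDs, HOMER motif text, expression and count TSVs,
#' GWAS/QTL tables, STARR-seq tables, ground-truth tables, and a manifest
#' JSON listing every file with its md5 digest.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created).
#' @return invisibly, the manifest path.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "chip"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$layout$seqs,
                              file.path(dir, "genome.fa"))
  write_tsv(data.frame(chrom = names(bundle$layout$lengths),
                       length = as.numeric(bundle$layout$lengths)),
            file.path(dir, "chrom.sizes"), col.names = FALSE)
  for (cond in names(bundle$peaks))
    for (r in names(bundle$peaks[[cond]]))
      write_bed(bundle$peaks[[cond]][[r]],
                file.path(dir, "peaks", paste0(cond, ".", r, ".bed")))
  write_gtf(bundle$annotation, file.path(dir, "annotation.gtf"))
  write_bed(bundle$tads, file.path(dir, "tads.bed"))
  write_bed(bundle$repeats[c("chrom", "start", "end", "id")],
            file.path(dir, "repeats.bed"))
  write_homer_motifs(bundle$motifs, file.path(dir, "custom.motifs"))
  write_tsv(bundle$samples, file.path(dir, "samples.tsv"))
  write_tsv(bundle$stranded_counts, file.path(dir, "stranded_counts.tsv"))
  write_tsv(data.frame(sample = names(bundle$lib_sizes),
                       lib_size = as.numeric(bundle$lib_sizes)),
            file.path(dir, "lib_sizes.tsv"))
  write_tsv(data.frame(gene = rownames(bundle$tpm), bundle$tpm,
                       check.names = FALSE),
            file.path(dir, "tpm.tsv"))
  for (cond in names(bundle$chip)) {
    write_tsv(bundle$chip[[cond]]$counts,
              file.path(dir, "chip", paste0(cond, ".counts.tsv")))
  }
  write_tsv(data.frame(
    condition = names(bundle$chip),
    ip = vapply(bundle$chip, function(x) x$lib_sizes$ip, 0),
    input = vapply(bundle$chip, function(x) x$lib_sizes$input, 0)),
    file.path(dir, "chip", "lib_sizes.tsv"))
  write_tsv(bundle$gwas, file.path(dir, "gwas.tsv"))
  write_tsv(bundle$qtl, file.path(dir, "qtl.tsv"))
  write_tsv(bundle$starr$freqs, file.path(dir, "snp_freqs.tsv"))
  write_tsv(bundle$starr$snp_positions, file.path(dir, "snp_positions.tsv"))
  write_tsv(bundle$starr$input_counts, file.path(dir, "starr_input.tsv"))
  for (l in seq_along(bundle$starr$output_libs))
    write_tsv(bundle$starr$output_libs[[l]],
              file.path(dir, sprintf("starr_output_lib%d.tsv", l)))
  write_tsv(bundle$truth$specific_erna,
            file.path(dir, "truth", "specific_erna.tsv"))
  write_tsv(bundle$truth$specific_gene,
            file.path(dir, "truth", "specific_gene.tsv"))
  write_tsv(bundle$truth$edges, file.path(dir, "truth", "edges.tsv"))
  write_tsv(data.frame(id = bundle$starr$truth$regulatory),
            file.path(dir, "truth", "regulatory_snps.tsv"))
  files <- list.files(dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    seed = bundle$config$seed,
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(dir, f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Read a bundle directory back into memory
#'
#' Every file is parsed through the package's standard readers; the result
#' holds the same analysis-facing components as \code{simulate_bundle}
#' (derived tables such as the enhancer catalog are recomputed by
#' \code{run_pipeline}, not stored).
#'
#' @param dir bundle directory.
#' @return list of class `synthetic_bundle`.
#' @export
read_bundle <- function(dir) {
  layout <- read_genome_fasta(file.path(dir, "genome.fa"))
  peak_files <- list.files(file.path(dir, "peaks"), full.names = FALSE)
  conds <- unique(sub("\\.rep[12]\\.bed$", "", peak_files))
  peaks <- lapply(stats::setNames(conds, conds), function(cond)
    lapply(stats::setNames(c("rep1", "rep2"), c("rep1", "rep2")),
           function(r) read_bed(file.path(dir, "peaks",
                                          paste0(cond, ".", r, ".bed")))))
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  lib <- read_tsv(file.path(dir, "lib_sizes.tsv"))
  tpm_df <- read_tsv(file.path(dir, "tpm.tsv"))
  tpm <- as.matrix(tpm_df[, -1, drop = FALSE])
  rownames(tpm) <- tpm_df[[1]]
  chip_lib <- read_tsv(file.path(dir, "chip", "lib_sizes.tsv"))
  chip <- lapply(stats::setNames(chip_lib$condition, chip_lib$condition),
                 function(cond) {
    i <- match(cond, chip_lib$condition)
    list(counts = read_tsv(file.path(dir, "chip",
                                     paste0(cond, ".counts.tsv"))),
         lib_sizes = list(ip = chip_lib$ip[i], input = chip_lib$input[i]))
  })
  starr <- list(
    freqs = read_tsv(file.path(dir, "snp_freqs.tsv")),
    snp_positions = read_tsv(file.path(dir, "snp_positions.tsv")),
    input_counts = read_tsv(file.path(dir, "starr_input.tsv")),
    output_libs = lapply(list.files(dir, "^starr_output_lib",
                                    full.names = TRUE), read_tsv))
  truth <- list(
    specific_erna = read_tsv(file.path(dir, "truth", "specific_erna.tsv")),
    specific_gene = read_tsv(file.path(dir, "truth", "specific_gene.tsv")),
    edges = read_tsv(file.path(dir, "truth", "edges.tsv")))
  starr$truth <- list(
    regulatory = read_tsv(file.path(dir, "truth",
                                    "regulatory_snps.tsv"))$id)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structure(list(
    config = synthetic_config(seed = manifest$seed),
    layout = layout,
    annotation = read_gtf_annotation(file.path(dir, "annotation.gtf")),
    peaks = peaks,
    tads = read_bed(file.path(dir, "tads.bed")),
    repeats = read_repeatmasker(file.path(dir, "repeats.bed")),
    motifs = parse_homer_motifs(file.path(dir, "custom.motifs")),
    samples = samples,
    stranded_counts = read_tsv(file.path(dir, "stranded_counts.tsv")),
    lib_sizes = stats::setNames(lib$lib_size, lib$sample),
    tpm = tpm, chip = chip,
    gwas = read_tsv(file.path(dir, "gwas.tsv")),
    qtl = read_tsv(file.path(dir, "qtl.tsv")),
    starr = starr, truth = truth), class = "synthetic_bundle")
}
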