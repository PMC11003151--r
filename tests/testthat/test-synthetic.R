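test_that("a fixed seed reproduces the bundle exactly", {
  cfg <- small_config(seed = 42)
  a <- simulate_bundle(cfg)
  b <- simulate_bundle(cfg)
  expect_identical(as.character(a$layout$seqs), as.character(b$layout$seqs))
  expect_identical(a$stranded_counts, b$stranded_counts)
  expect_identical(a$tpm, b$tpm)
  expect_identical(a$starr, b$starr)
  expect_identical(a$peaks, b$peaks)
  c <- simulate_bundle(small_config(seed = 43))
  expect_false(identical(as.character(a$layout$seqs),
                         as.character(c$layout$seqs)))
})

test_that("replicate jitter keeps at least 95 percent of planted peaks", {
  b <- small_bundle()
  for (cond in names(b$peaks)) {
    m <- intersect_then_merge(b$peaks[[cond]]$rep1, b$peaks[[cond]]$rep2,
                              b$layout)
    expect_gte(nrow(m), 0.95 * nrow(b$planted$enhancers))
  }
})

test_that("planted motifs hit exactly the chain-linked enhancers", {
  b <- small_bundle()
  seqs <- interval_seqs(b$catalog, b$layout)
  hits <- scan_set(b$motifs, seqs)
  chains <- b$truth$chains
  for (i in seq_len(nrow(chains))) {
    tf <- sprintf("tf_%03d", chains$chain[i])
    expect_equal(unique(hits$seq_id[hits$motif == tf]),
                 chains$derived_id[i])
  }
})

test_that("bundle files round-trip through the package readers", {
  b <- small_bundle()
  d <- withr::local_tempdir()
  write_bundle(b, d)
  r <- read_bundle(d)
  expect_identical(as.character(r$layout$seqs), as.character(b$layout$seqs))
  expect_equal(r$tpm, b$tpm)
  expect_equal(r$stranded_counts, b$stranded_counts)
  expect_equal(r$samples, b$samples)
  for (cond in names(b$peaks))
    expect_equal(r$peaks[[cond]]$rep1[c("chrom", "start", "end")],
                 b$peaks[[cond]]$rep1[c("chrom", "start", "end")])
  expect_equal(r$tads[c("chrom", "start", "end")],
               b$tads[c("chrom", "start", "end")])
  expect_setequal(r$annotation$genes$id, b$annotation$genes$id)
  expect_equal(sort(r$annotation$ncrnas$biotype),
               sort(b$annotation$ncrnas$biotype))
  expect_equal(length(r$motifs), length(b$motifs))
  expect_equal(r$motifs[[1]]$pwm, b$motifs[[1]]$pwm, tolerance = 1e-9)
  expect_equal(r$starr$input_counts, b$starr$input_counts)
  # manifest digests match the files on disk
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  for (f in names(man$files))
    expect_equal(unname(tools::md5sum(file.path(d, f))),
                 man$files[[f]])
})

test_that("planted chain pairs reach the target correlation and GWAS hits sit inside eRNAs", {
  b <- small_bundle()
  q <- quantify_rpm(b$records, b$stranded_counts, b$lib_sizes, b$samples)
  ch <- b$truth$chains
  rho <- vapply(seq_len(nrow(ch)), function(i)
    cor(rank(b$tpm[sprintf("tf_%03d", ch$chain[i]), ]),
        rank(q$rpm[ch$erna_id[i], ])), 0)
  expect_lt(abs(median(rho) - b$config$rho_target), 0.1)
  expect_true(all(rho > 0.5))
  # decoy pairs stay near zero
  dec <- b$role_map$erna_id[b$role_map$role == "decoy"]
  dec <- dec[apply(q$rpm[dec, ], 1, sd) > 0]
  set.seed(1)
  null_rho <- replicate(200, {
    i <- sample(dec, 2)
    cor(rank(q$rpm[i[1], ]), rank(q$rpm[i[2], ]))
  })
  expect_gte(mean(abs(null_rho) < 0.5), 0.95)
  # one planted GWAS hit inside every chain eRNA region
  rec <- b$records[match(ch$erna_id, b$records$erna_id), ]
  hits <- b$gwas[seq_len(nrow(ch)), ]
  expect_true(all(hits$pos >= rec$start & hits$pos < rec$end))
})

test_that("degenerate records exercise the error paths downstream", {
  b <- small_bundle()
  # an all-zero eRNA row and an all-zero gene row exist
  q <- quantify_rpm(b$records, b$stranded_counts, b$lib_sizes, b$samples)
  expect_true(any(rowSums(q$rpm) == 0))
  expect_true("gene_zero" %in% rownames(b$tpm))
  expect_true(all(b$tpm["gene_zero", ] == 0))
  # low-coverage and zero-cell SNPs are flagged, not fatal
  reps <- collapse_output_libraries(b$starr$output_libs)
  merged <- merge_output_replicates(reps[[1]], reps[[2]])
  res <- allelic_activity_test(b$starr$input_counts, merged$counts)
  expect_false(res$tested[res$id == "snp_lowcov"])
  expect_true(is.na(res$effect_size[res$id == "snp_zerocell"]))
  expect_false(res$is_regulatory[res$id == "snp_zerocell"])
})

test_that("unknown config fields are rejected and packing limits are enforced", {
  expect_error(synthetic_config(bogus = 1), "unknown config")
  expect_error(generate_reference(synthetic_config(
    chrom_lengths = c(chr1 = 200000), n_chains = 50)), "infeasible")
})
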