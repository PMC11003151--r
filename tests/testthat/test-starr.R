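test_that("SNP screening needs eRNA overlap, MAF difference and mixed-pool MAF", {
  regions <- gi("chrA", 1000, 7000)
  freqs <- data.frame(
    id = c("in_pass", "in_small_delta", "out_pass", "in_low_mixed"),
    chrom = "chrA", pos = c(2000, 2100, 50000, 2200),
    east_maf = c(0.45, 0.30, 0.45, 0.45),
    west_maf = c(0.10, 0.10, 0.05, 0.10),
    mixed_maf = c(0.28, 0.28, 0.28, 0.04))
  expect_equal(screen_candidate_snps(freqs, regions), "in_pass")
  freqs$east_maf[1] <- 0.6
  expect_error(screen_candidate_snps(freqs, regions), "MAF")
})

test_that("output libraries collapse pairwise and replicates merge with a QC correlation", {
  libs <- lapply(list(c(5, 2), c(5, 3), c(9, 7), c(11, 8)), function(v)
    data.frame(id = c("s1", "s2"), ref_count = v[1], alt_count = v[2]))
  reps <- collapse_output_libraries(libs)
  expect_equal(reps[[1]]$ref_count, c(10, 10))
  expect_equal(reps[[1]]$alt_count, c(5, 5))
  expect_error(collapse_output_libraries(libs[1:3]), "even number")

  r1 <- data.frame(id = c("s1", "s2"), ref_count = c(10, 30),
                   alt_count = c(5, 10))
  r2 <- data.frame(id = c("s2", "s1"), ref_count = c(60, 20),
                   alt_count = c(20, 15))
  m <- merge_output_replicates(r1, r2)
  expect_equal(m$counts$ref_count, c(30, 90))   # aligned by id
  expect_equal(m$counts$alt_count, c(20, 30))
  expect_equal(m$correlation, 1)                # totals (15,40) vs (35,80)

  expect_warning(m0 <- merge_output_replicates(
    r1, transform(r1, ref_count = 0, alt_count = 0)), "undefined")
  expect_equal(m0$counts$ref_count, r1$ref_count)
  expect_error(merge_output_replicates(r1, r2[1, ]), "SNP sets")
})

test_that("allelic activity testing applies the strict coverage filter and Fisher test", {
  input <- data.frame(id = c("a", "b", "c"),
                      ref_count = c(100, 50, 10),
                      alt_count = c(100, 50, 5))
  output <- data.frame(id = c("a", "b", "c"),
                       ref_count = c(100, 50, 300),
                       alt_count = c(300, 50, 300))
  res <- allelic_activity_test(input, output)
  expect_equal(res$effect_size[res$id == "a"], 3)
  expect_equal(res$p[res$id == "a"],
               fisher.test(matrix(c(100, 100, 100, 300), 2,
                                  byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_equal(res$effect_size[res$id == "b"], 1)
  expect_equal(res$p[res$id == "b"], 1)
  expect_false(res$tested[res$id == "c"])       # input total 15 <= 20
  expect_true(is.na(res$p[res$id == "c"]))
  # a zero cell keeps the Fisher test but loses the effect size
  z <- allelic_activity_test(
    data.frame(id = "z", ref_count = 50, alt_count = 0),
    data.frame(id = "z", ref_count = 40, alt_count = 30))
  expect_true(is.na(z$effect_size))
  expect_false(is.na(z$p))
  # coverage of exactly 20+20 is excluded ("exceeding" is strict)
  res20 <- allelic_activity_test(
    data.frame(id = "e", ref_count = 10, alt_count = 10),
    data.frame(id = "e", ref_count = 100, alt_count = 100))
  expect_false(res20$tested)
})

test_that("swapping ref and alt labels inverts effect sizes and keeps p", {
  set.seed(13)
  input <- data.frame(id = paste0("s", 1:30),
                      ref_count = rpois(30, 200), alt_count = rpois(30, 200))
  output <- data.frame(id = input$id,
                       ref_count = rpois(30, 200),
                       alt_count = rpois(30, 400))
  a <- allelic_activity_test(input, output)
  b <- allelic_activity_test(
    data.frame(id = input$id, ref_count = input$alt_count,
               alt_count = input$ref_count),
    data.frame(id = output$id, ref_count = output$alt_count,
               alt_count = output$ref_count))
  expect_equal(b$effect_size, 1 / a$effect_size, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})
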