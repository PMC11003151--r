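test_that("permutation enrichment handles saturation and empty features exactly", {
  lay <- tiny_layout(c(chrA = 100000, chrB = 50000))
  query <- gi(rep("chrA", 5), (0:4) * 10000, (0:4) * 10000 + 500)
  whole <- gi(c("chrA", "chrB"), c(0, 0), c(100000, 50000))
  res <- permutation_enrichment(query, whole, lay, R = 200, seed = 3)
  expect_equal(res$observed, 5)
  expect_true(all(res$null == 5))
  expect_equal(res$p, 1)

  none <- gi(character(0), numeric(0), numeric(0))
  none <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0))
  res <- permutation_enrichment(query, none, lay, R = 50, seed = 3)
  expect_equal(res$observed, 0)
  expect_equal(res$p, 1)

  # an element that fits only on the larger chromosome is placed there
  long <- gi("chrA", 0, 90000)
  res <- permutation_enrichment(long, gi("chrB", 0, 50000), lay,
                                R = 100, seed = 2)
  expect_true(all(res$null == 0))   # never lands on chrB
})

test_that("an element longer than every chromosome is rejected", {
  lay <- tiny_layout(c(chrA = 1000))
  expect_error(
    permutation_enrichment(data.frame(chrom = "chrA", start = 0, end = 1000),
                           data.frame(chrom = "chrA", start = 0, end = 10),
                           genome_layout(c(chrA = 999)), R = 2, seed = 1))
})

test_that("the add-one estimator never returns zero and detects planted enrichment", {
  # features cover ~1% of the genome; the query sits fully inside them
  lay <- tiny_layout(c(chrA = 3000000, chrB = 3000000))
  set.seed(77)
  fs <- sample(0:2900, 60) * 1000
  features <- data.frame(chrom = rep(c("chrA", "chrB"), each = 30),
                         start = fs, end = fs + 500)
  query <- features[sample(60, 50), ]
  query$start <- query$start + 100
  query$end <- query$start + 200
  res <- permutation_enrichment(query, features, lay, R = 1000, seed = 7)
  expect_equal(res$observed, 50)
  expect_equal(res$p, 1 / 1001)
})

test_that("null placement is reproducible under a fixed seed", {
  lay <- tiny_layout()
  q <- gi("chrA", c(0, 5000), c(1000, 5600))
  f <- gi("chrA", 20000, 30000)
  a <- permutation_enrichment(q, f, lay, R = 100, seed = 5)
  b <- permutation_enrichment(q, f, lay, R = 100, seed = 5)
  expect_identical(a$null, b$null)
  c <- permutation_enrichment(q, f, lay, R = 100, seed = 6)
  expect_false(identical(a$null, c$null))
})

test_that("transposon tests compare insertion rates and find a planted family", {
  lay <- tiny_layout(c(chrA = 2000000))
  n <- 60
  s <- (0:(n - 1)) * 30000
  enh <- gi("chrA", s, s + 1000, id = sprintf("e%02d", 1:n))
  labels <- data.frame(id = enh$id,
                       label = rep(c("TEn", "non-TEn"), each = n / 2))
  # family LTR/ERV1 covers every TEn enhancer, nothing else; a second
  # family is scattered uniformly
  ten <- enh[labels$label == "TEn", ]
  planted <- data.frame(chrom = ten$chrom, start = ten$start + 100,
                        end = ten$start + 900, class = "LTR",
                        family = "LTR/ERV1")
  set.seed(10)
  bs <- sample(0:1990, 40) * 1000
  background <- data.frame(chrom = "chrA", start = bs, end = bs + 300,
                           class = "SINE", family = "SINE/PRE1")
  res <- transposon_insertion_test(enh, labels, rbind(planted, background),
                                   lay, R = 500, seed = 2)
  fam <- res$family_enrichment
  q_ten <- fam$q[fam$family == "LTR/ERV1" & fam$group == "TEn"]
  q_non <- fam$q[fam$family == "LTR/ERV1" & fam$group == "non-TEn"]
  expect_lt(q_ten, 0.05)
  expect_gt(q_non, 0.5)
  expect_lt(res$fisher_p, 0.01)   # all TEn hit, non-TEn mostly miss
  # base fractions: LTR bases cover 800/1000 of TEn, none of non-TEn
  cf <- res$class_fractions
  expect_equal(cf$fraction[cf$group == "TEn" & cf$class == "LTR"], 0.8)
  expect_equal(cf$fraction[cf$group == "non-TEn" & cf$class == "LTR"], 0)
})

test_that("identical overlap patterns give a Fisher p of 1 and empty groups error", {
  lay <- tiny_layout(c(chrA = 1000000))
  enh <- gi("chrA", (0:19) * 40000, (0:19) * 40000 + 1000,
            id = sprintf("e%02d", 1:20))
  labels <- data.frame(id = enh$id, label = rep(c("TEn", "non-TEn"), 10))
  cover_all <- data.frame(chrom = "chrA", start = 0, end = 1000000,
                          class = "LINE", family = "LINE/L1")
  res <- transposon_insertion_test(enh, labels, cover_all, lay, R = 10,
                                   seed = 1)
  expect_equal(res$fisher_p, 1)
  labels$label <- "TEn"
  expect_error(transposon_insertion_test(enh, labels, cover_all, lay,
                                         R = 10, seed = 1), "empty")
})

test_that("RepeatMasker .out tables parse with class/family split", {
  txt <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat       position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family begin end (left) ID",
    "  463   1.3  0.6  1.7  chr1      1001  1500  (8500) + L1PA2     LINE/L1      1   500 (0)   1",
    "  239   9.4  0.0  0.0  chr2      2001  2300  (7700) C MIR3      SINE/MIR     1   300 (0)   2")
  f <- withr::local_tempfile()
  writeLines(txt, f)
  rep <- read_repeatmasker(f)
  expect_equal(rep$start, c(1000, 2000))
  expect_equal(rep$end, c(1500, 2300))
  expect_equal(rep$class, c("LINE", "SINE"))
  expect_equal(rep$family, c("LINE/L1", "SINE/MIR"))
})
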