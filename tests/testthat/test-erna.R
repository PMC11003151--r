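mk_samples <- function() data.frame(
  breed = rep(c("DU", "ES"), each = 2), tissue = "muscle",
  replicate = rep(1:2, 2),
  sample = c("DU_r1", "DU_r2", "ES_r1", "ES_r2"))

test_that("eRNA regions are center +/- 3 kb minus annotation +/- 1 kb", {
  lay <- tiny_layout(c(chrA = 100000))
  enh <- gi("chrA", 10000, 12000, id = "e1")
  empty_ann <- annotation_set(data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    id = character(0), strand = character(0), biotype = character(0)))
  rec <- define_erna_regions(enh, empty_ann, lay)
  expect_equal(c(rec$start, rec$end), c(8000, 14000))
  expect_equal(rec$windows[[1]],
               data.frame(chrom = "chrA", start = 8000, end = 14000))

  gene <- annotation_set(data.frame(chrom = "chrA", start = 13000,
                                    end = 20000, id = "g", strand = "+",
                                    biotype = "protein_coding"))
  rec <- define_erna_regions(enh, gene, lay)
  expect_equal(rec$windows[[1]],
               data.frame(chrom = "chrA", start = 8000, end = 12000))

  blanket <- annotation_set(data.frame(chrom = "chrA", start = 7000,
                                       end = 15000, id = "g", strand = "+",
                                       biotype = "protein_coding"))
  expect_equal(nrow(define_erna_regions(enh, blanket, lay)), 0)
  # windows never exceed the 6 kb region
  expect_lte(sum(rec$windows[[1]]$end - rec$windows[[1]]$start), 6000)
})

test_that("RPM and plus-strand fractions follow the counting rule", {
  rec <- data.frame(erna_id = c("x", "y"), enhancer_id = c("e1", "e2"),
                    chrom = "chrA", start = c(0, 10000),
                    end = c(6000, 16000), center = c(3000, 13000))
  sam <- mk_samples()
  sc <- expand.grid(erna_id = c("x", "y"), sample = sam$sample,
                    stringsAsFactors = FALSE)
  sc$plus_count <- ifelse(sc$erna_id == "x", 3, 0)
  sc$minus_count <- ifelse(sc$erna_id == "x", 7, 0)
  libs <- setNames(rep(1e6, 4), sam$sample)
  q <- quantify_rpm(rec, sc, libs, sam)
  expect_equal(unname(q$rpm["x", ]), rep(10, 4))
  expect_equal(unname(q$rpm["y", ]), rep(0, 4))
  expect_equal(unname(q$plus_fraction["x", "DU.muscle"]), 0.3)
  expect_true(all(is.na(q$plus_fraction["y", ])))
  sc$plus_count[1] <- -1
  expect_error(quantify_rpm(rec, sc, libs, sam), "negative")
})

test_that("detectability uses the replicate mean with an inclusive threshold", {
  sam <- mk_samples()
  rpm <- matrix(c(1.5, 0.6, 0.9, 0.9,
                  0.9, 0.9, 2.0, 1.0,
                  1.0, 1.0, 0.0, 0.0), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), sam$sample))
  det <- call_detectable(rpm, sam, "muscle", "DU")
  expect_setequal(det, c("a", "c"))      # means 1.05 and 1.0 (boundary in)
  expect_false("b" %in% det)             # mean 0.9
  # detectability is monotone in any replicate's rpm
  rpm2 <- rpm; rpm2["b", "DU_r1"] <- 5
  expect_true("b" %in% call_detectable(rpm2, sam, "muscle", "DU"))
  expect_true(all(det %in% call_detectable(rpm2, sam, "muscle", "DU")))
})

test_that("direction bounds are inclusive and strand-symmetric", {
  expect_equal(classify_direction(0.5), "bidirectional")
  expect_equal(classify_direction(0.96), "unidirectional")
  expect_equal(classify_direction(0.05), "bidirectional")
  expect_equal(classify_direction(0.95), "bidirectional")
  expect_true(is.na(classify_direction(NA)))
  p <- runif(200)
  expect_equal(classify_direction(p), classify_direction(1 - p))
})

test_that("reads planted on one strand only give unidirectional calls", {
  rec <- data.frame(erna_id = "x", enhancer_id = "e1", chrom = "chrA",
                    start = 0, end = 6000, center = 3000)
  sam <- mk_samples()
  sc <- data.frame(erna_id = "x", sample = sam$sample,
                   plus_count = c(40, 55, 38, 61), minus_count = 0)
  q <- quantify_rpm(rec, sc, setNames(rep(1e6, 4), sam$sample), sam)
  expect_true(all(classify_direction(q$plus_fraction["x", ]) ==
                    "unidirectional"))
})

test_that("GC fraction counts G+C over the full length including N", {
  expect_equal(gc_fraction("ACGC"), 0.75)
  expect_equal(gc_fraction("AAAA"), 0)
  expect_equal(gc_fraction("ACGTN"), 0.4)
  expect_equal(gc_fraction("acgc"), 0.75)
  expect_error(gc_fraction(""), "empty sequence")
})

test_that("binned activity correlation matches a brute-force binning oracle", {
  x <- 1:16
  expect_equal(binned_activity_correlation(x, x, 8)$r, 1)
  expect_equal(binned_activity_correlation(x, -x, 8)$r, -1)
  set.seed(5)
  expr <- rlnorm(80); act <- rlnorm(80)
  got <- binned_activity_correlation(expr, act, 8)
  # oracle: explicit sort, fixed bin sizes, means, Pearson by formula
  ord <- order(expr, decreasing = TRUE)
  bins <- split(ord, rep(1:8, each = 10))
  e <- vapply(bins, function(i) mean(expr[i]), 0)
  a <- vapply(bins, function(i) mean(act[i]), 0)
  r <- sum((e - mean(e)) * (a - mean(a))) /
    sqrt(sum((e - mean(e))^2) * sum((a - mean(a))^2))
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_error(binned_activity_correlation(1:5, 1:5, 8), "n_bins")
})

test_that("transcribed-enhancer labels use half-open center containment", {
  enh <- gi("chrA", 100, 200, id = "e1")
  rec <- function(ctr) data.frame(erna_id = "x", enhancer_id = "e1",
                                  chrom = "chrA", start = ctr - 50,
                                  end = ctr + 50, center = ctr)
  expect_equal(label_transcribed_enhancers(enh, rec(150))$label, "TEn")
  expect_equal(label_transcribed_enhancers(enh, rec(200))$label, "non-TEn")
  expect_equal(label_transcribed_enhancers(enh, rec(100))$label, "TEn")
  none <- label_transcribed_enhancers(enh, rec(150)[0, ])
  expect_equal(none$label, "non-TEn")
})
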