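test_that("intersect_then_merge matches hand-evaluated cases", {
  lay <- tiny_layout()
  r1 <- gi("chrA", 100, 200)
  r2 <- gi("chrA", 150, 250)
  out <- intersect_then_merge(r1, r2, lay)
  expect_equal(out$start, 150)
  expect_equal(out$end, 200)

  # identical replicates come back merged but otherwise unchanged
  x <- gi("chrA", c(10, 50, 45), c(40, 70, 55))
  out <- intersect_then_merge(x, x, lay)
  expect_equal(out, data.frame(chrom = "chrA", start = c(10, 45),
                               end = c(40, 70)))

  # disjoint replicates support nothing
  expect_equal(nrow(intersect_then_merge(gi("chrA", 0, 100),
                                         gi("chrA", 200, 300), lay)), 0)
  expect_error(intersect_then_merge(gi("chrZ", 0, 10), r2, lay),
               "unknown chromosome")
})

test_that("intersect_then_merge is commutative, idempotent, and agrees with a brute-force overlap oracle", {
  lay <- tiny_layout(c(chrA = 100000, chrB = 100000))
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    mk <- function(n) {
      s <- sample(0:9000, n) * 10
      gi(sample(c("chrA", "chrB"), n, replace = TRUE), s,
         s + sample(50:2000, n, replace = TRUE))
    }
    a <- mk(n1); b <- mk(n2)
    ab <- intersect_then_merge(a, b, lay)
    ba <- intersect_then_merge(b, a, lay)
    expect_equal(ab, ba)
    expect_equal(intersect_then_merge(ab, ab, lay), ab)
    # oracle: union of all pairwise O(n*m) intersections, compared by base set
    pieces <- list()
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
      if (s < e) pieces[[length(pieces) + 1]] <-
          data.frame(chrom = a$chrom[i], start = s, end = e)
    }
    oracle <- if (length(pieces)) do.call(rbind, pieces) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    expect_setequal(covered_bases(ab), unique(covered_bases(oracle)))
    # output is sorted and non-overlapping
    if (nrow(ab) > 1) {
      same <- ab$chrom[-1] == ab$chrom[-nrow(ab)]
      expect_true(all(ab$start[-1][same] >= ab$end[-nrow(ab)][same]))
    }
  }
})

test_that("exclude_near_features removes regions within the flank window", {
  lay <- tiny_layout()
  reg <- gi("chrA", 1000, 2000)
  expect_equal(nrow(exclude_near_features(
    reg, data.frame(chrom = "chrA", pos = 1500), 1000)), 0)
  expect_equal(nrow(exclude_near_features(
    reg, data.frame(chrom = "chrA", pos = 3500), 1000)), 1)
  # flank 0 masks just the anchor base
  expect_equal(nrow(exclude_near_features(
    gi("chrA", 10, 20), data.frame(chrom = "chrA", pos = 20), 0)), 1)
  expect_equal(nrow(exclude_near_features(
    gi("chrA", 10, 20), data.frame(chrom = "chrA", pos = 19), 0)), 0)
})

test_that("center_window clips to chromosome bounds and drops empty windows", {
  lay <- tiny_layout(c(chrA = 100000, chrB = 100))
  w <- center_window(gi("chrA", 1000, 2000), 3000, lay)
  expect_equal(c(w$start, w$end), c(0, 4500))
  expect_warning(w0 <- center_window(gi("chrA", 1000, 2000), 0, lay),
                 "empty window")
  expect_equal(nrow(w0), 0)
  w <- center_window(gi("chrB", 0, 10), 5, lay)
  expect_equal(c(w$start, w$end), c(0, 10))
})

test_that("expand_points widens hits symmetrically with clipping", {
  lay <- tiny_layout(c(chrA = 1e6))
  e <- expand_points(data.frame(chrom = "chrA", pos = 100000), 20000, lay)
  expect_equal(c(e$start, e$end), c(80000, 120001))
  e <- expand_points(data.frame(chrom = "chrA", pos = 5000), 20000, lay)
  expect_equal(c(e$start, e$end), c(0, 25001))
  e <- expand_points(data.frame(chrom = "chrA", pos = 42), 0, lay)
  expect_equal(c(e$start, e$end), c(42, 43))
  # interval hits are expanded from both ends
  e <- expand_points(gi("chrA", 1000, 2000), 500, lay)
  expect_equal(c(e$start, e$end), c(500, 2500))
})

test_that("BED round-trip is byte-stable for canonical six-column records", {
  txt <- c("chr1\t0\t100\tr1\t5\t+", "chr1\t150\t300\tr2\t0\t-",
           "chr2\t7\t9\tr3\t1\t.")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeLines(txt, f1)
  df <- read_bed(f1)
  write_bed(df, f2)
  expect_identical(readLines(f2), txt)
  expect_equal(df$start, c(0, 150, 7))
})

test_that("interval validation rejects malformed records", {
  expect_error(gi("chrA", 10, 10), "0 <= start < end")
  expect_error(gi("", 0, 10), "empty chromosome")
  expect_error(validate_intervals(gi("chrA", 0, 10), tiny_layout(c(x = 5))),
               "unknown chromosome")
  expect_error(validate_intervals(gi("chrA", 0, 1e9), tiny_layout()),
               "exceed chromosome bounds")
})

test_that("annotation TSS sits at start for + strand and end-1 for - strand", {
  ann <- annotation_set(data.frame(
    chrom = "chrA", start = c(100, 200), end = c(150, 260),
    id = c("g1", "g2"), strand = c("+", "-"), biotype = "protein_coding"))
  expect_equal(ann$genes$tss, c(100, 259))
})
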