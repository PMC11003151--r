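test_that("TAD membership requires containment and picks the smallest TAD", {
  tads <- data.frame(chrom = "chrA", start = c(0, 100, 1000),
                     end = c(1000, 400, 2000),
                     id = c("big", "small", "right"))
  expect_equal(ernanet:::tad_of("chrA", 200, tads), "small")
  expect_equal(ernanet:::tad_of("chrA", 500, tads), "big")
  expect_equal(ernanet:::tad_of("chrA", 1500, tads), "right")
  expect_true(is.na(ernanet:::tad_of("chrA", 5000, tads)))
  expect_equal(ernanet:::tad_of("chrA", 1000, tads), "right")  # half-open
})

# expression fixture: one perfectly tracking TF/eRNA/gene triple plus noise
mk_link_fixture <- function() {
  n <- 20
  set.seed(31)
  sig <- exp(seq(0, 3, length.out = n)) + 0.01 * rnorm(n)
  tf <- rbind(tfA = sig + 0.001 * rnorm(n), tfB = rnorm(n)^2 + 5)
  er <- rbind(e1 = sig * 2 + 0.001 * rnorm(n), e2 = rlnorm(n))
  ge <- rbind(g1 = sig + 0.002 * rnorm(n), g2 = rlnorm(n))
  list(tf = tf, er = er, ge = ge)
}

test_that("TF links need motif evidence, expression and the strict rho cutoff", {
  fx <- mk_link_fixture()
  expressed <- matrix(TRUE, 2, 1, dimnames = list(c("tfA", "tfB"), "muscle"))
  tissue <- c(e1 = "muscle", e2 = "muscle")
  hits <- data.frame(motif = c("tfA", "tfB"), seq_id = c("e1", "e2"))
  edges <- link_tf_to_erna(fx$tf, fx$er, hits, tissue, expressed)
  expect_equal(edges$source, "tfA")
  expect_equal(edges$target, "e1")
  expect_gt(edges$rho, 0.5)
  # no motif hit: correlated pair is not linked
  edges <- link_tf_to_erna(fx$tf, fx$er,
                           data.frame(motif = "tfB", seq_id = "e2"),
                           tissue, expressed)
  expect_equal(nrow(edges), 0)
  # not expressed in the tissue: no link despite motif and correlation
  off <- expressed; off["tfA", "muscle"] <- FALSE
  edges <- link_tf_to_erna(fx$tf, fx$er, hits, tissue, off)
  expect_equal(nrow(edges), 0)
})

test_that("a Spearman of exactly the cutoff is rejected (strict inequality)", {
  # ranks chosen so rho = 0.5 exactly: n = 5, sum d^2 = 10
  a <- matrix(c(1, 2, 3, 4, 5), 1, dimnames = list("tfA", NULL))
  b <- matrix(c(1, 4, 2, 5, 3), 1, dimnames = list("e1", NULL))
  res <- spearman_fdr(a, b, data.frame(a = "tfA", b = "e1"))
  expect_equal(res$rho, 0.5, tolerance = 1e-12)
  edges <- link_tf_to_erna(a, b, data.frame(motif = "tfA", seq_id = "e1"),
                           c(e1 = "muscle"),
                           matrix(TRUE, 1, 1,
                                  dimnames = list("tfA", "muscle")))
  expect_equal(nrow(edges), 0)
})

test_that("gene links respect distance, TAD sharing and the rho cutoff", {
  fx <- mk_link_fixture()
  tads <- data.frame(chrom = "chrA", start = c(0, 2000000),
                     end = c(2000000, 4000000), id = c("t1", "t2"))
  ea <- data.frame(id = c("e1", "e2"), chrom = "chrA",
                   center = c(100000, 3000000))
  # g1 within 0.5 Mb of e1 in the same TAD; g2 in the other TAD
  ga <- data.frame(id = c("g1", "g2"), chrom = "chrA",
                   tss = c(600000, 2500000))
  res <- link_erna_to_genes(fx$er, fx$ge, ea, ga, tads)
  expect_equal(res$edges$source, "e1")
  expect_equal(res$edges$target, "g1")
  expect_equal(res$edges$distance, 500000)
  expect_equal(res$edges$tad, "t1")
  # beyond 1 Mb: candidate never forms
  ga2 <- transform(ga, tss = c(1600000, 2500000))
  res2 <- link_erna_to_genes(fx$er, fx$ge, ea, ga2, tads)
  expect_false(any(res2$edges$target == "g1"))
  # same stats but anchors in different TADs: no edge
  tads3 <- data.frame(chrom = "chrA", start = c(0, 300000, 2000000),
                      end = c(300000, 2000000, 4000000),
                      id = c("t1", "t1b", "t2"))
  res3 <- link_erna_to_genes(fx$er, fx$ge, ea, ga, tads3)
  expect_equal(nrow(res3$edges), 0)
})

test_that("GWAS filtering keeps eRNAs within the expanded windows", {
  lay <- tiny_layout(c(chrA = 1000000))
  ernas <- gi("chrA", 100000, 106000, id = "e1")
  expect_equal(filter_by_gwas(ernas, data.frame(chrom = "chrA", pos = 110000),
                              20000, lay), "e1")
  expect_length(filter_by_gwas(ernas, data.frame(chrom = "chrA",
                                                 pos = 130000),
                               20000, lay), 0)
  expect_length(filter_by_gwas(ernas, data.frame(chrom = character(0),
                                                 pos = numeric(0)),
                               20000, lay), 0)
})

mk_net <- function() {
  tf_edges <- data.frame(source = c("tfA", "tfB"), target = c("e1", "e1"),
                         type = "TF->eRNA", rho = 0.9, q = 1e-4,
                         motif_hit = TRUE)
  gene_edges <- data.frame(source = "e1", target = c("g1", "g2", "g3"),
                           type = "eRNA->gene", rho = 0.8, q = 1e-4,
                           distance = 1e5, tad = "t1")
  regions <- gi("chrA", c(1000, 50000), c(7000, 56000), id = c("e1", "e2"))
  assemble_egrn(tf_edges, gene_edges, regions)
}

test_that("network assembly deduplicates and derives node sets", {
  net <- mk_net()
  expect_equal(length(net$nodes$tfs), 2)
  expect_equal(length(net$nodes$ernas), 1)
  expect_equal(length(net$nodes$genes), 3)
  expect_equal(nrow(net$edges), 5)
  # duplicate submission is idempotent
  dup <- assemble_egrn(rbind(net$edges[net$edges$type == "TF->eRNA", ],
                             net$edges[net$edges$type == "TF->eRNA", ]),
                       net$edges[net$edges$type == "eRNA->gene", ],
                       gi("chrA", 1000, 7000, id = "e1"))
  expect_equal(nrow(dup$edges), 5)
  # empty network is valid and writable
  none <- assemble_egrn(net$edges[0, ], net$edges[0, ],
                        gi("chrA", 1, 2, id = "x")[0, ])
  d <- withr::local_tempdir()
  paths <- write_egrn(none, d, "empty")
  expect_true(all(file.exists(paths)))
  expect_error(assemble_egrn(net$edges[net$edges$type == "TF->eRNA", ],
                             net$edges[0, ],
                             gi("chrA", 1, 2, id = "other")),
               "without an eRNA region")
})

test_that("STARR refinement prunes eRNAs without regulatory SNPs and never adds", {
  net <- mk_net()
  reg <- data.frame(id = c("s1", "s2"), is_regulatory = c(TRUE, FALSE))
  pos <- data.frame(id = c("s1", "s2"), chrom = "chrA", pos = c(2000, 51000))
  kept <- refine_by_starr(net, reg, pos)     # s1 inside e1
  expect_equal(kept$nodes$ernas, "e1")
  expect_equal(nrow(kept$edges), 5)
  reg$is_regulatory <- c(FALSE, TRUE)        # only s2 (inside e2, no edges)
  dropped <- refine_by_starr(net, reg, pos)
  expect_equal(nrow(dropped$edges), 0)
  expect_length(dropped$nodes$tfs, 0)
  none <- refine_by_starr(net, reg[0, ], pos)
  expect_equal(nrow(none$edges), 0)
  # monotone: refined edge sets are subsets of the original
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(kept$edges) %in% key(net$edges)))
})

test_that("network exports are written and GraphML loads back", {
  net <- mk_net()
  d <- withr::local_tempdir()
  paths <- write_egrn(net, d)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[3], format = "graphml")
  expect_equal(igraph::gorder(g), 6)
  expect_equal(igraph::gsize(g), 5)
  sif <- readLines(paths[2])
  expect_length(sif, 5)
  expect_true(any(grepl("\tbinds\t", sif)))
})
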