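test_that("consensus keeps exactly the shared intron chains", {
  a1 <- tx("a1", "chr1", "+", c(100, 200, 300, 400))
  a2 <- tx("a2", "chr1", "+", c(1000, 1100, 1300, 1400))
  a3 <- tx("a3", "chr1", "+", c(5000, 6000))            # single exon
  b1 <- tx("b1", "chr1", "+", c(90, 200, 300, 420))     # same chain as a1
  b3 <- tx("b3", "chr1", "+", c(5000, 6000))
  route_a <- tx_set(a1, a2, a3)
  route_b <- tx_set(b1, b3)
  cons <- consensus(route_a, route_b)
  expect_equal(names(cons$transcripts), "a1")
  # identical sets: all multi-exon transcripts retained
  cons2 <- consensus(route_a, route_a)
  expect_setequal(names(cons2$transcripts), c("a1", "a2"))
  # chain must match strand
  b1m <- tx("b1m", "chr1", "-", c(90, 200, 300, 420))
  expect_length(consensus(route_a, tx_set(b1m))$transcripts, 0)
  # membership decision is symmetric under route swap
  shared_a <- names(consensus(route_a, route_b)$transcripts)
  shared_b <- names(consensus(route_b, route_a)$transcripts)
  key <- function(set, ids) vapply(set$transcripts[ids],
                                   ctximmune:::chain_key, character(1))
  expect_setequal(unname(key(route_a, shared_a)), unname(key(route_b, shared_b)))
})

test_that("filter cascade enforces the printed boundaries", {
  mk <- function(id, len1, len2, prob, nexon = 2) {
    ex <- if (nexon == 2) c(1000, 1000 + len1, 5000, 5000 + len2)
          else c(1000, 1000 + len1)
    t1 <- tx(id, "chrX", "+", ex)
    t1$noncoding_probability <- prob
    t1
  }
  empty <- tx_set()
  # spliced length 199 removed, 200 survives
  res <- filter_cascade(list(mk("len199", 100, 99, 0.999),
                             mk("len200", 100, 100, 0.999)),
                        empty, empty)
  expect_equal(vapply(res$kept, `[[`, character(1), "id"), "len200")
  expect_equal(unname(res$counts["short"]), 1L)
  # single exon removed regardless of length
  expect_warning(
    res2 <- filter_cascade(list(mk("single", 5000, 0, 0.999, nexon = 1)),
                           empty, empty),
    "every candidate")
  expect_length(res2$kept, 0)
  expect_equal(unname(res2$counts["single_exon"]), 1L)
  # probability exactly 0.99 removed (strict >)
  res3 <- filter_cascade(list(mk("p990", 150, 150, 0.99),
                              mk("p991", 150, 150, 0.991)),
                         empty, empty)
  expect_equal(vapply(res3$kept, `[[`, character(1), "id"), "p991")
  expect_equal(unname(res3$counts["low_probability"]), 1L)
})

test_that("filter cascade matches a brute-force oracle on random fixtures", {
  withr::with_seed(80, {
    normal <- tx_set(tx("n1", "chr1", "+", c(2000, 2500)),
                     tx("n2", "chr2", "-", c(100, 900)))
    known <- tx_set(tx("k1", "chr1", "-", c(7000, 7600)))
    cands <- lapply(1:40, function(i) {
      chrom <- sample(c("chr1", "chr2"), 1)
      strand <- sample(c("+", "-"), 1)
      s1 <- sample(100:8000, 1); l1 <- sample(50:200, 1)
      nexon <- sample(1:2, 1)
      ex <- if (nexon == 2) c(s1, s1 + l1, s1 + l1 + 300, s1 + l1 + 300 + sample(50:200, 1))
            else c(s1, s1 + l1)
      t1 <- tx(sprintf("c%02d", i), chrom, strand, ex)
      t1$noncoding_probability <- sample(c(0.5, 0.99, 0.995, 1), 1)
      t1
    })
    res <- filter_cascade(cands, normal, known)
    overlap1 <- function(t1, set) {
      any(vapply(set$transcripts, function(t2) {
        if (t2$chrom != t1$chrom || t2$strand != t1$strand) return(FALSE)
        for (i in seq_len(nrow(t1$exons))) for (j in seq_len(nrow(t2$exons)))
          if (t1$exons[i, 1] < t2$exons[j, 2] && t2$exons[j, 1] < t1$exons[i, 2])
            return(TRUE)
        FALSE
      }, logical(1)))
    }
    expected <- Filter(function(t1)
      sum(t1$exons[, 2] - t1$exons[, 1]) >= 200 && nrow(t1$exons) >= 2 &&
        !overlap1(t1, normal) && !overlap1(t1, known) &&
        t1$noncoding_probability > 0.99, cands)
    expect_equal(vapply(res$kept, `[[`, character(1), "id"),
                 vapply(expected, `[[`, character(1), "id"))
    expect_equal(sum(res$counts), 40L - length(res$kept))
  })
})

test_that("context classes match the precedence rules on hand-built cases", {
  genes <- data.frame(
    id = c("PITPNM1_like", "SYT17_like", "FAR1"),
    chrom = c("chr11", "chr16", "chr9"),
    start = c(10000, 20000, 2900), end = c(14000, 28000, 3900),
    strand = c("-", "+", "+"),
    biotype = "protein_coding", stringsAsFactors = FALSE)
  host <- tx("SYT17_t1", "chr16", "+", c(20000, 21000, 27000, 28000), "SYT17_like")
  ann <- annotation_set(genes, list(host))
  # + strand transcript over a - strand gene span: antisense
  anti <- tx("T_anti", "chr11", "+", c(11000, 11200, 12000, 12300))
  cc <- classify_context(anti, ann)
  expect_equal(cc$class, "antisense")
  expect_equal(cc$nearest_gene, "PITPNM1_like")
  expect_equal(cc$nearest_distance, 0)
  # + strand transcript fully inside the intron of a + strand gene
  intr <- tx("T_intr", "chr16", "+", c(22000, 22400, 25000, 25300))
  cc2 <- classify_context(intr, ann)
  expect_equal(cc2$class, "sense_intronic")
  expect_equal(cc2$nearest_gene, "SYT17_like")
  # exonic same-strand overlap wins over everything
  sov <- tx("T_sov", "chr16", "+", c(20500, 20800, 25000, 25300))
  expect_equal(classify_context(sov, ann)$class, "sense_overlapping")
  # head-to-head promoter proximity within the window
  bid <- tx("T_bid", "chr9", "-", c(2100, 2300, 2600, 2800))
  expect_equal(classify_context(bid, ann, bidir_window = 1000)$class,
               "bidirectional")
  expect_equal(classify_context(bid, ann, bidir_window = 50)$class,
               "intergenic")
  # far transcript on an empty chromosome: intergenic, nearest gene blank
  far <- tx("T_far", "chr_empty", "+", c(5000, 5300, 6000, 6400))
  cc3 <- classify_context(far, ann)
  expect_equal(cc3$class, "intergenic")
  expect_true(is.na(cc3$nearest_gene))
})

test_that("classifier recovers the generator truth for all five classes", {
  sim <- simulate_annotation(seed = 81, n_per_class = 4)
  calls <- classify_contexts(sim$annotation)
  merged <- merge(calls, sim$truth, by = "transcript_id")
  expect_equal(nrow(merged), 20)
  expect_equal(merged$class.x, merged$class.y)
  # classes are mutually exclusive and exhaustive
  expect_true(all(merged$class.x %in% c("antisense", "sense_overlapping",
                                        "sense_intronic", "bidirectional",
                                        "intergenic")))
})

test_that("target prioritization keeps at most three, flags first, then
           ascending energy", {
  cands <- data.frame(
    target = sprintf("T%d", 1:5),
    cancer_pathway = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    immune_pathway = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    score = c(-12, -30, -8, -25, -15))
  kept <- prioritize_targets(cands)
  expect_equal(kept$target, c("T3", "T5", "T1"))  # 2 flags, then energy asc
  two <- prioritize_targets(cands[1:2, ])
  expect_equal(nrow(two), 2)
  # equal flags: pure ascending energy, cross-checked with order()
  eq <- data.frame(target = sprintf("E%d", 1:4),
                   cancer_pathway = TRUE, immune_pathway = FALSE,
                   score = c(-5, -20, -1, -11))
  expect_equal(prioritize_targets(eq)$target,
               eq$target[order(eq$score)][1:3])
  expect_warning(out <- prioritize_targets(eq[0, ]), "no candidate")
  expect_equal(nrow(out), 0)
})
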