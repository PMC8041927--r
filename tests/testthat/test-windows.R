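test_that("window grid covers the transcript with a right-anchored tail", {
  g <- window_grid(300)
  expect_equal(nrow(g), 21)            # starts 0..200
  expect_equal(g$start, seq(0, 200, 10))
  g2 <- window_grid(305)
  expect_equal(tail(g2$end, 1), 305)   # extra window [205, 305)
  expect_equal(tail(g2$start, 1), 205)
  g3 <- window_grid(60)
  expect_equal(g3, data.frame(start = 0, end = 60))  # short transcript
})

test_that("fragments count in every window they overlap by >= 1 nt", {
  m <- gene_model("G", "T", "chr1", "+", 0, 300)
  ip <- data.frame(start = 0, end = 150)
  rec <- count_windows(m, ip, ip[0, ])
  expect_equal(rec$a, as.integer(rec$start <= 140))
  expect_true(all(rec$c == 0))  # no fragments -> all-zero counts
  # single-base overlap at both edges
  m2 <- gene_model("G", "T", "chr1", "+", 0, 400)
  frag <- data.frame(start = 99, end = 100)
  rec2 <- count_windows(m2, frag, frag)
  expect_equal(rec2$a[rec2$start == 0], 1)    # window [0,100) catches base 99
  expect_equal(rec2$a[rec2$start == 100], 0)  # [100,200) does not
})

test_that("low-window filter excludes only windows low in both libraries", {
  rec <- data.frame(gene_id = "G", start = 0, end = 100,
                    a = c(100, 4, 4, 40), c = c(40, 3, 1, 2))
  rec$start <- c(0, 10, 20, 30); rec$end <- rec$start + 100
  out <- filter_low_windows(rec)
  # top a = 100 -> cut 5; top c = 40 -> cut 2
  expect_equal(out$retained, c(TRUE, TRUE, FALSE, TRUE))
  zero <- data.frame(gene_id = "Z", start = 0, end = 100, a = 0, c = 0)
  expect_false(filter_low_windows(zero)$retained)
})

test_that("the low-window filter never changes counts of retained windows", {
  set.seed(5)
  rec <- data.frame(gene_id = rep(c("A", "B"), each = 30),
                    start = rep(seq(0, 290, 10), 2))
  rec$end <- rec$start + 100
  rec$a <- rpois(60, 20); rec$c <- rpois(60, 15)
  with_f <- filter_low_windows(rec)
  expect_equal(with_f$a, rec$a)
  expect_equal(with_f$c, rec$c)
  # removing the filter (min_frac = 0 keeps everything) only adds windows
  no_f <- filter_low_windows(rec, min_frac = 0)
  expect_true(all(no_f$retained[with_f$retained]))
  expect_gte(sum(no_f$retained), sum(with_f$retained))
})

test_that("gene-median normalization and its pseudocount path", {
  rec <- data.frame(gene_id = "G", start = c(0, 10, 20),
                    end = c(100, 110, 120), a = c(2, 4, 6), c = c(5, 5, 5),
                    retained = TRUE)
  out <- normalize_by_gene_median(rec)
  expect_equal(out$norm_ip, c(0.5, 1, 1.5))
  expect_equal(out$norm_input, c(1, 1, 1))
  # even count: mean of the middle pair
  rec2 <- rec[c(1, 2, 2, 3), ]; rec2$a <- c(1, 2, 4, 8)
  expect_equal(normalize_by_gene_median(rec2)$b[1], 3)
  # zero median with one nonzero window stays finite
  rec3 <- data.frame(gene_id = "G", start = c(0, 10, 20),
                     end = c(100, 110, 120), a = c(0, 0, 9), c = 1,
                     retained = TRUE)
  out3 <- normalize_by_gene_median(rec3)
  expect_true(all(is.finite(out3$norm_ip)))
  expect_equal(out3$norm_ip, c(1, 1, 10))  # (x + 1) / (0 + 1)
})

test_that("enrichment score follows (a d)/(b c) with the pseudocount rule", {
  expect_equal(enrichment_score(20, 5, 4, 5), 5)
  expect_equal(enrichment_score(7, 7, 3, 3), 1)   # window at gene median
  expect_equal(enrichment_score(10, 5, 0, 5), 11) # (11*6)/(6*1)
  expect_equal(enrichment_score(0, 5, 4, 5), (1 * 6) / (6 * 5))
  expect_error(enrichment_score(-1, 5, 4, 5), "negative")
  # strictly increasing in a for fixed b, c, d
  a <- 0:50
  es <- enrichment_score(a, 5, 4, 5)
  expect_true(all(diff(es) > 0))
})

test_that("Fisher window test matches enumeration and fisher.test", {
  expect_equal(fisher_window_test(5, 50, 10, 100), 1)  # proportional table
  expect_equal(fisher_window_test(0, 0, 0, 0), 1)
  # [[8,2],[1,9]] vs exhaustive enumeration
  expect_equal(fisher_window_test(8, 10, 1, 10), oracle_fisher_p(8, 10, 1, 10),
               tolerance = 1e-12)
  expect_equal(fisher_window_test(8, 10, 1, 10),
               fisher.test(matrix(c(8, 2, 1, 9), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
  set.seed(1)
  for (i in 1:60) {
    A <- sample(0:60, 1); C <- sample(0:60, 1)
    a <- if (A) sample(0:A, 1) else 0
    c <- if (C) sample(0:C, 1) else 0
    p <- fisher_window_test(a, A, c, C)
    expect_equal(p, oracle_fisher_p(a, A, c, C), tolerance = 1e-12)
    if (A + C > 0)
      expect_equal(p, stats::fisher.test(
        matrix(c(a, A - a, c, C - c), 2, byrow = TRUE))$p.value,
        tolerance = 1e-7)
  }
  expect_error(fisher_window_test(5, 4, 0, 10), "a <= A")
})

test_that("BH adjustment matches its definition and is idempotent", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_length(adjust_fdr(numeric(0)), 0)
  set.seed(2)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- adjust_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))             # fdr_i >= p_i
    expect_true(!is.unsorted(q[order(p)]))       # monotone in sorted p
  }
})

test_that("score_windows flags positives at the stated thresholds", {
  m <- gene_model("G", "T", "chr1", "+", 0, 1000)
  set.seed(3)
  bg_ip <- data.frame(start = sort(sample(0:999, 300, TRUE)))
  bg_ip$end <- pmin(bg_ip$start + 150, 1000)
  bg_in <- data.frame(start = sort(sample(0:999, 300, TRUE)))
  bg_in$end <- pmin(bg_in$start + 150, 1000)
  # pile extra IP fragments on [400, 500)
  extra <- data.frame(start = sample(400:480, 250, TRUE))
  extra$end <- pmin(extra$start + 150, 1000)
  rec <- count_windows(m, rbind(bg_ip, extra), bg_in)
  out <- score_windows(rec)
  expect_true(any(out$positive))
  hot <- out[out$positive, ]
  expect_true(all(hot$fdr < 0.01 & log2(hot$es) >= 1))
  expect_true(all(hot$end > 400 & hot$start < 650))
  # the medians-table variant runs and stays consistent on the nulls
  out2 <- score_windows(rec, fisher_table = "medians")
  expect_true(any(out2$positive))
})
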