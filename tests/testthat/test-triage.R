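mk_tables <- function() {
  list(
    evidence_table(c("NEDD4L", "GSN", "GINS4", "ONLYM6A"), "unique_m6a"),
    evidence_table(data.frame(gene = c("NEDD4L", "GSN", "GINS4", "WEAK"),
                              effect = c(-1.2, -0.8, 0.9, 0.3)),
                   "rnaseq_ast_vs_control"),
    evidence_table(data.frame(gene = c("NEDD4L", "GSN", "GINS4", "WEAK"),
                              effect = c(-0.9, -1.1, 1.4, 2.0),
                              p = c(0.01, 0.02, 0.001, 0.2)),
                   "rnaseq_mouse_cuSCC"),
    evidence_table(data.frame(gene = c("NEDD4L", "GSN", "GINS4", "WEAK"),
                              effect = c(-0.7, 0.9, 0.8, 1.0),
                              p = c(0.03, 0.04, 0.04, 0.01)),
                   "rnaseq_human_cuSCC"))
}

test_that("cutoffs are strict and label-specific", {
  tb <- evidence_table(data.frame(gene = c("A", "B", "C", "D"),
                                  effect = c(0.5, -0.6, 1.2, 0.51),
                                  p = c(0.01, 0.04, 0.2, 0.04)),
                       "rnaseq_human_cuSCC")
  got <- apply_cutoffs(tb)
  expect_false("A" %in% got$gene)            # 0.5 exactly: excluded
  expect_true(all(c("B", "D") %in% got$gene))
  expect_false("C" %in% got$gene)            # p = 0.2 fails
  expect_equal(got$direction[got$gene == "B"], -1)
  # As-T table: no p rule
  tb2 <- evidence_table(data.frame(gene = c("A", "B"),
                                   effect = c(0.6, -0.4)),
                        "rnaseq_ast_vs_control")
  expect_equal(apply_cutoffs(tb2)$gene, "A")
  # missing p where required is an error naming the table
  tb3 <- evidence_table(data.frame(gene = "A", effect = 1),
                        "rnaseq_mouse_cuSCC")
  expect_error(apply_cutoffs(tb3), "rnaseq_mouse_cuSCC")
  # unique_m6a passes as given, direction-free
  expect_equal(apply_cutoffs(evidence_table("x1", "unique_m6a"))$direction, 0L)
})

test_that("evidence tables validate labels, duplicates and effects", {
  expect_error(evidence_table("A", "bogus_label"), "unknown")
  expect_error(evidence_table(c("A", "a "), "unique_m6a"), "duplicate")
  expect_error(evidence_table(data.frame(gene = "A", effect = NA_real_),
                              "rnaseq_ast_vs_control"), "finite")
})

test_that("four-way intersection calls concordant directions", {
  res <- triage(mk_tables())
  expect_equal(res$shared_down, "NEDD4L")
  expect_equal(res$shared_up, "GINS4")
  expect_equal(res$discordant, "GSN")   # human direction flips
  expect_equal(sum(res$venn), length(unique(res$genes$gene)))
  # order invariance
  res2 <- triage(rev(mk_tables()))
  expect_identical(res$genes, res2$genes)
  # errors: wrong count, duplicate labels
  expect_error(triage(mk_tables()[1:3]), "four")
  expect_error(triage(mk_tables()[c(1, 1, 2, 3)]), "duplicate|cover")
})

test_that("an empty table empties the intersection", {
  tabs <- mk_tables()
  tabs[[1]] <- evidence_table(character(0), "unique_m6a")
  res <- triage(tabs)
  expect_length(res$shared_down, 0)
  expect_length(res$shared_up, 0)
  expect_length(res$discordant, 0)
})

test_that("identical four tables reduce to apply_cutoffs of one", {
  tb <- evidence_table(data.frame(gene = c("A", "B", "C"),
                                  effect = c(-1, 0.7, 0.2),
                                  p = c(0.01, 0.02, 0.01)),
                       "rnaseq_mouse_cuSCC")
  tabs <- list(
    evidence_table(tb$gene, "unique_m6a"),
    evidence_table(data.frame(gene = tb$gene, effect = tb$effect),
                   "rnaseq_ast_vs_control"),
    tb,
    evidence_table(data.frame(gene = tb$gene, effect = tb$effect, p = tb$p),
                   "rnaseq_human_cuSCC"))
  res <- triage(tabs)
  passed <- apply_cutoffs(tb)
  expect_setequal(c(res$shared_down, res$shared_up), passed$gene_key)
})

test_that("random tables agree with the brute-force set-algebra oracle", {
  cfg <- sim_config(seed = 11)
  for (s in 1:5) {
    cfg$seed <- s * 13L
    sim <- simulate_deg_tables(cfg, n_down = sample(0:6, 1),
                               n_up = sample(0:4, 1),
                               n_discordant = sample(0:10, 1),
                               n_background = 100 - 20)
    res <- triage(sim$tables)
    orc <- oracle_triage(sim$tables)
    expect_equal(res$shared_down, orc$down)
    expect_equal(res$shared_up, orc$up)
    expect_equal(sort(res$discordant), orc$discordant)
  }
})

test_that("relaxing a cutoff never removes a called gene", {
  cfg <- sim_config(seed = 21)
  sim <- simulate_deg_tables(cfg)
  strict <- triage(sim$tables)
  lax <- triage(sim$tables, lfc_cutoff = 0.2, p_cutoff = 0.2)
  expect_true(all(strict$shared_down %in% lax$shared_down))
  expect_true(all(strict$shared_up %in% lax$shared_up))
})

test_that("gene symbols match case-insensitively after trimming", {
  tabs <- mk_tables()
  tabs[[1]] <- evidence_table(c(" nedd4l", "Gins4"), "unique_m6a")
  res <- triage(tabs)
  expect_equal(res$shared_down, "NEDD4L")
  expect_equal(res$shared_up, "GINS4")
})

test_that("evidence tables read from TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = c("A", "B"), effect = c(-1, 2),
                         p = c(0.01, 0.2)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  tb <- read_evidence_table(f, "rnaseq_human_cuSCC")
  expect_s3_class(tb, "evidence_table")
  expect_equal(apply_cutoffs(tb)$gene, "A")
  expect_error(read_evidence_table("no/such/file.tsv", "unique_m6a"),
               "not found")
})
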