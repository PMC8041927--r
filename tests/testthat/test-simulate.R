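test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(planted_enrichment = 0.5), "planted_enrichment")
  expect_error(sim_config(mrna_length_range = c(50, 60), peak_width = 200),
               "too short")
  expect_error(sim_config(background_mean = -1), "positive")
})

test_that("gene-model simulation is reproducible and respects invariants", {
  cfg <- sim_config(seed = 1, n_genes = 50)
  a <- simulate_gene_models(cfg)
  b <- simulate_gene_models(cfg)
  expect_length(a$models, 50)
  expect_identical(a, b)
  for (m in a$models) {
    expect_equal(m$mrna_length, sum(m$exon_end - m$exon_start))
    expect_true(m$cds_start > 0 && m$cds_end < m$mrna_length)
  }
  # planted intervals lie within the transcript
  len <- vapply(a$models[a$truth$gene_id], `[[`, 0, "mrna_length")
  expect_true(all(a$truth$start >= 0 & a$truth$end <= len))
  # single-exon option
  cfg1 <- sim_config(seed = 2, n_genes = 5, exon_count_range = c(1, 1))
  m1 <- simulate_gene_models(cfg1)
  expect_true(all(vapply(m1$models, function(m) length(m$exon_start), 0L) == 1))
})

test_that("fragment simulation is seed-deterministic and strand-consistent", {
  cfg <- sim_config(seed = 4, n_genes = 5)
  gm <- simulate_gene_models(cfg)
  f1 <- simulate_fragments(gm$models, gm$truth, cfg)
  f2 <- simulate_fragments(gm$models, gm$truth, cfg)
  expect_identical(f1, f2)
  strands <- vapply(gm$models, `[[`, "", "strand")
  chroms <- vapply(gm$models, `[[`, "", "chrom")
  expect_true(all(f1$ip$strand %in% strands[match(f1$ip$chrom, chroms)] |
                    f1$ip$chrom %in% chroms[duplicated(chroms)]))
  # fragments round-trip through the package's own readers
  p <- withr::local_tempfile(fileext = ".bed")
  write_fragments_bed(f1$ip, p)
  expect_silent(back <- read_fragments_bed(p))
  expect_equal(nrow(back), nrow(f1$ip))
})

test_that("null simulation has equal IP/input window means up to depth", {
  cfg <- sim_config(seed = 5, n_genes = 10, planted_enrichment = 1,
                    library_ratio = 1.5)
  gm <- simulate_gene_models(cfg)
  fr <- simulate_fragments(gm$models, gm$truth, cfg)
  recs <- do.call(rbind, lapply(gm$models, function(m)
    count_windows(m, project_fragments(fr$ip, m),
                  project_fragments(fr$input, m))))
  expect_gt(nrow(recs), 200)
  ratio <- mean(recs$a) / mean(recs$c)
  # expected ratio is the library depth ratio; sampling error on these
  # totals (~4e3 fragments/library) is ~2%, so 10% is a >3 SE band
  expect_lt(abs(ratio - 1.5) / 1.5, 0.10)
})

test_that("planted windows are enriched by the configured fold", {
  cfg <- sim_config(seed = 6, n_genes = 20, peak_width = 300,
                    background_mean = 50)
  gm <- simulate_gene_models(cfg)
  fr <- simulate_fragments(gm$models, gm$truth, cfg)
  in_r <- out_r <- c(0, 0)  # ip, input sums
  for (g in names(gm$models)) {
    m <- gm$models[[g]]
    rec <- count_windows(m, project_fragments(fr$ip, m),
                         project_fragments(fr$input, m))
    tr <- gm$truth[gm$truth$gene_id == g, ]
    inside <- rec$start >= tr$start & rec$end <= tr$end
    far <- rec$end < tr$start - 250 | rec$start > tr$end + 250
    in_r <- in_r + c(sum(rec$a[inside]), sum(rec$c[inside]))
    out_r <- out_r + c(sum(rec$a[far]), sum(rec$c[far]))
  }
  fold <- (in_r[1] / in_r[2]) / (out_r[1] / out_r[2])
  expect_lt(abs(fold - 8) / 8, 0.2)
})

test_that("DEG tables plant exactly the intended four-way structure", {
  cfg <- sim_config(seed = 7)
  sim <- simulate_deg_tables(cfg)
  res <- triage(sim$tables)
  expect_equal(res$shared_down, sort(toupper(sim$truth$down)))
  expect_equal(res$shared_up, sort(toupper(sim$truth$up)))
  expect_equal(length(res$discordant), 27)
  expect_equal(length(res$shared_down), 10)
  expect_equal(length(res$shared_up), 3)
  # empty planting gives an empty intersection
  sim0 <- simulate_deg_tables(cfg, n_down = 0, n_up = 0, n_discordant = 0)
  res0 <- triage(sim0$tables)
  expect_length(res0$shared_down, 0)
  expect_length(res0$shared_up, 0)
})

test_that("decay simulation matches the closed form and is seeded", {
  s <- simulate_decay(1, c(0, 1, 2), cv = 0)
  expect_equal(s$value, c(1, 0.5, 0.25))
  a <- simulate_decay(4, c(0, 2, 4, 8), cv = 0.1, seed = 3)
  b <- simulate_decay(4, c(0, 2, 4, 8), cv = 0.1, seed = 3)
  expect_identical(a, b)
  expect_equal(a$value[1], 1)  # renormalized at t = 0
  expect_error(simulate_decay(4, c(1, 2)), "0")
})

test_that("half-life refits recover the simulated truth (calibration)", {
  set.seed(123)
  t <- c(0, 1, 2, 4, 6, 8)
  rel_err <- replicate(500, {
    f <- fit_half_life(simulate_decay(4, t, cv = 0.05))
    abs(f$t_half - 4) / 4
  })
  expect_gte(mean(rel_err < 0.10), 0.95)
})
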