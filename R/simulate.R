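#' Simulation configuration
#'
#' Parameters of the synthetic MeRIP-seq generator. The defaults describe
#' the desk-scale test conditions used throughout the package: 50
#' multi-exon genes of 1-3 kb, negative-binomial background coverage with
#' a mean of 50 fragments per 100-nt window, and one planted 150-nt,
#' 8-fold-enriched methylation site per gene.
#'
#' @param seed Integer seed; every generator is fully deterministic given
#'   it.
#' @param n_genes Number of genes.
#' @param exon_count_range Inclusive range of exons per gene.
#' @param mrna_length_range Inclusive range of spliced mRNA lengths (nt).
#' @param background_mean Expected fragments overlapping a 100-nt window
#'   in the input library.
#' @param dispersion Negative-binomial size parameter of the tile-level
#'   coverage noise (smaller = more overdispersed).
#' @param peak_width Width of planted methylation sites (nt).
#' @param planted_enrichment IP-over-input fold enrichment of fragments
#'   touching a planted site (>= 1; 1 = null data).
#' @param peaks_per_gene Planted sites per gene.
#' @param fragment_length Fragment size in nt (default 150, matching the
#'   read-extension length used in peak calling).
#' @param library_ratio Global IP / input depth ratio.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, n_genes = 50, exon_count_range = c(1, 8),
                       mrna_length_range = c(1000, 3000),
                       background_mean = 50, dispersion = 10,
                       peak_width = 150, planted_enrichment = 8,
                       peaks_per_gene = 1, fragment_length = 150,
                       library_ratio = 1) {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              exon_count_range = exon_count_range,
              mrna_length_range = mrna_length_range,
              background_mean = background_mean, dispersion = dispersion,
              peak_width = peak_width,
              planted_enrichment = planted_enrichment,
              peaks_per_gene = peaks_per_gene,
              fragment_length = fragment_length,
              library_ratio = library_ratio)
  num <- unlist(cfg[c("n_genes", "background_mean", "dispersion",
                      "peak_width", "peaks_per_gene", "fragment_length",
                      "library_ratio")])
  if (any(!is.finite(num)) || any(num[names(num) != "peaks_per_gene"] <= 0) ||
      cfg$peaks_per_gene < 0)
    stop("sim_config: parameters must be positive (peaks_per_gene >= 0)")
  if (cfg$planted_enrichment < 1)
    stop("sim_config: planted_enrichment must be >= 1")
  if (any(exon_count_range < 1) || exon_count_range[1] > exon_count_range[2])
    stop("sim_config: bad exon_count_range")
  if (mrna_length_range[1] > mrna_length_range[2] || mrna_length_range[1] < 1)
    stop("sim_config: bad mrna_length_range")
  if (cfg$peaks_per_gene > 0 &&
      mrna_length_range[1] < cfg$peak_width * cfg$peaks_per_gene)
    stop("sim_config: mrna_length_range too short to host ",
         cfg$peaks_per_gene, " planted site(s) of ", cfg$peak_width, " nt")
  structure(cfg, class = "sim_config")
}

#' Simulate gene models with planted methylation sites
#'
#' Draws `n_genes` random multi-exon gene models (exon structure, strand
#' and intron sizes random; genes laid out without overlap across five
#' chromosomes) and plants `peaks_per_gene` non-overlapping methylation
#' sites of `peak_width` nt per gene, uniformly on the isoform. UTR/CDS
#' boundaries follow a 10%/60%/30% split of the mRNA.
#'
#' @param config A [sim_config()].
#' @return List with `models` (named list of [gene_model()], keyed by gene
#'   id) and `truth` (`data.frame`: `gene_id`, `start`, `end`,
#'   `enrichment` in isoform coordinates).
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cursor <- stats::setNames(rep(10000, 5), paste0("chr", 1:5))
  models <- vector("list", config$n_genes)
  truth <- list()
  for (i in seq_len(config$n_genes)) {
    L <- sample(config$mrna_length_range[1]:config$mrna_length_range[2], 1)
    k <- sample(config$exon_count_range[1]:config$exon_count_range[2], 1)
    k <- min(k, L)
    cuts <- if (k > 1) sort(sample(seq_len(L - 1), k - 1)) else integer(0)
    widths <- diff(c(0, cuts, L))
    introns <- if (k > 1) sample(100:5000, k - 1, replace = TRUE) else integer(0)
    chrom <- sample(names(cursor), 1)
    strand <- sample(c("+", "-"), 1)
    ex_start <- cursor[[chrom]] + cumsum(c(0, widths[-k] + introns))
    ex_end <- ex_start + widths
    cursor[[chrom]] <- ex_end[k] + sample(2000:10000, 1)
    cds_start <- round(0.1 * L)
    cds_end <- round(0.7 * L)
    gid <- sprintf("G%03d", i)
    models[[i]] <- gene_model(gid, sprintf("T%03d.1", i), chrom, strand,
                              ex_start, ex_end, cds_start, cds_end)
    if (config$peaks_per_gene > 0) {
      starts <- numeric(0)
      while (length(starts) < config$peaks_per_gene) {
        s <- sample(0:(L - config$peak_width), 1)
        if (!any(s < starts + config$peak_width &
                 s + config$peak_width > starts))
          starts <- c(starts, s)
      }
      truth[[length(truth) + 1L]] <-
        data.frame(gene_id = gid, start = sort(starts),
                   end = sort(starts) + config$peak_width,
                   enrichment = config$planted_enrichment)
    }
  }
  names(models) <- vapply(models, `[[`, "", "gene_id")
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(gene_id = character(0), start = numeric(0),
                           end = numeric(0), enrichment = numeric(0))
  list(models = models, truth = truth)
}

# expected 5'-start rate per nt giving `background_mean` fragments per
# 100-nt window under the >=1-nt-overlap counting rule
.start_rate <- function(config) {
  config$background_mean / (100 + config$fragment_length - 1)
}

#' Simulate IP and input fragment libraries
#'
#' Coverage is generated in isoform space and projected to the genome, so
#' splice junctions are exercised automatically. Fragment 5' starts are
#' drawn per nucleotide as Poisson counts whose rates carry a per-100-nt
#' tile Gamma multiplier (mean 1, shape = `dispersion`) describing the
#' coverage propensity of the shared fragmented mRNA pool: the multiplier
#' is common to IP and input, so each library's tile counts are
#' marginally negative-binomial while the IP/input allocation at fixed
#' coverage remains exchangeable under the null. The input library sees
#' the background rate; the IP library multiplies it by `library_ratio`
#' globally and by `planted_enrichment` for every start whose fragment
#' would overlap a planted site — so window-level IP/input ratios inside
#' planted sites exceed those outside by the planted fold.
#'
#' @param models,truth Output of [simulate_gene_models()].
#' @param config The same [sim_config()].
#' @return List with fragment tables `ip` and `input` (see
#'   [fragments()]).
#' @export
simulate_fragments <- function(models, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  r <- .start_rate(config)
  fl <- config$fragment_length
  one_lib <- function(model, rate) {
    L <- model$mrna_length
    counts <- stats::rpois(L, rate)
    starts <- rep.int(0:(L - 1), counts)
    if (!length(starts))
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0)))
    ends <- pmin(starts + fl, L)
    g1 <- .iso_to_genome_pos(starts, model)
    g2 <- .iso_to_genome_pos(ends - 1, model)
    data.frame(chrom = model$chrom, start = pmin(g1, g2),
               end = pmax(g1, g2) + 1, strand = model$strand)
  }
  ip <- list(); input <- list()
  for (g in names(models)) {
    model <- models[[g]]
    L <- model$mrna_length
    # coverage propensity: per-100-nt-tile Gamma effect of the shared
    # fragmented mRNA pool, identical in IP and input, so each library's
    # tile counts are negative-binomial while the IP/input split at fixed
    # total stays binomial (the Fisher test's conditional null)
    tile <- rep(seq_len(ceiling(L / 100)), each = 100)[seq_len(L)]
    gam <- stats::rgamma(max(tile), shape = config$dispersion,
                         rate = config$dispersion)
    base <- r * gam[tile]
    mult_ip <- rep(config$library_ratio, L)
    tg <- truth[truth$gene_id == g, , drop = FALSE]
    for (j in seq_len(nrow(tg))) {
      lo <- max(0, tg$start[j] - fl + 1)
      sel <- seq.int(lo, tg$end[j] - 1) + 1L
      mult_ip[sel] <- mult_ip[sel] * tg$enrichment[j]
    }
    input[[g]] <- one_lib(model, base)
    ip[[g]] <- one_lib(model, base * mult_ip)
  }
  bind <- function(lst) {
    df <- do.call(rbind, lst)
    rownames(df) <- NULL
    fragments(df$chrom, df$start, df$end, df$strand)
  }
  list(ip = bind(ip), input = bind(input))
}

#' Simulate the four evidence tables with planted shared genes
#'
#' Builds a condition-unique methylation gene list plus three expression
#' tables (cell-line log2 TPM difference; mouse and human tumor log2 fold
#' changes with p-values) such that exactly the planted genes pass all
#' four published cutoffs: `n_down` concordant-down and `n_up`
#' concordant-up genes, plus `n_discordant` genes present in all four
#' sets whose expression directions disagree (the study's four-way
#' overlap has this structure: 40 members, 10 concordant down, 3
#' concordant up). Background genes receive effects or p-values failing
#' at least one cutoff.
#'
#' @param config A [sim_config()] (seed source).
#' @param genes Optional gene-symbol universe; defaults to
#'   `sprintf("GENE%03d", ...)` symbols covering all planted and
#'   background genes.
#' @param n_down,n_up,n_discordant Planted four-way members (defaults 10,
#'   3, 27).
#' @param n_background Additional genes failing the intersection
#'   (default 150).
#' @return List with `tables` (named list of four [evidence_table()]s)
#'   and `truth` (list of `down`, `up`, `discordant` gene vectors).
#' @export
simulate_deg_tables <- function(config, genes = NULL, n_down = 10,
                                n_up = 3, n_discordant = 27,
                                n_background = 150) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n_planted <- n_down + n_up + n_discordant
  n_total <- n_planted + n_background
  if (is.null(genes)) genes <- sprintf("GENE%03d", seq_len(n_total))
  if (length(genes) < n_total)
    stop("gene universe too small: need ", n_total, " genes")
  genes <- genes[seq_len(n_total)]
  down <- genes[seq_len(n_down)]
  up <- genes[n_down + seq_len(n_up)]
  disc <- genes[n_down + n_up + seq_len(n_discordant)]
  bg <- genes[n_planted + seq_len(n_background)]

  eff <- function(n, dir) dir * stats::runif(n, 0.8, 2.5)
  sig_p <- function(n) stats::runif(n, 1e-5, 0.049)
  # direction per gene per expression table (ast, mouse, human)
  dirs <- rbind(
    matrix(-1, n_down, 3), matrix(1, n_up, 3),
    t(vapply(seq_len(n_discordant), function(i) {
      d <- sample(c(-1, 1), 1) * c(1, 1, 1)
      d[sample(3, 1)] <- -d[1]  # flip one set so directions disagree
      d
    }, numeric(3))))
  planted <- c(down, up, disc)

  # background genes: pass everywhere except a chosen subset of tables
  fail_m6a <- stats::runif(n_background) < 0.5
  fail_ast <- stats::runif(n_background) < 0.5
  fail_mouse <- stats::runif(n_background) < 0.5
  fail_human <- stats::runif(n_background) < 0.5
  none <- !(fail_m6a | fail_ast | fail_mouse | fail_human)
  fail_m6a[none] <- TRUE
  bg_dir <- sample(c(-1, 1), n_background, replace = TRUE)
  weak <- function(n) stats::runif(n, 0, 0.5)   # |effect| <= 0.5 fails
  big_p <- function(n) stats::runif(n, 0.10, 0.9)

  m6a_genes <- c(planted, bg[!fail_m6a])

  ast <- data.frame(
    gene = c(planted, bg),
    effect = c(eff(n_planted, 1) * dirs[, 1],
               ifelse(fail_ast, weak(n_background),
                      stats::runif(n_background, 0.8, 2.5)) * bg_dir))

  mk_cuscc <- function(col, fail) data.frame(
    gene = c(planted, bg),
    effect = c(eff(n_planted, 1) * dirs[, col],
               stats::runif(n_background, 0.8, 2.5) * bg_dir),
    p = c(sig_p(n_planted),
          ifelse(fail, big_p(n_background), sig_p(n_background))))

  tables <- list(
    unique_m6a = evidence_table(m6a_genes, "unique_m6a"),
    rnaseq_ast_vs_control = evidence_table(ast, "rnaseq_ast_vs_control"),
    rnaseq_mouse_cuSCC = evidence_table(mk_cuscc(2, fail_mouse),
                                        "rnaseq_mouse_cuSCC"),
    rnaseq_human_cuSCC = evidence_table(mk_cuscc(3, fail_human),
                                        "rnaseq_human_cuSCC"))
  list(tables = tables,
       truth = list(down = down, up = up, discordant = disc))
}

#' Simulate an mRNA (or protein) decay time course
#'
#' `y(t) = 2^(-t / t_half)` with multiplicative lognormal noise of
#' coefficient of variation `cv`, renormalized so the t = 0 point is
#' exactly 1 (the convention of chase experiments, where every series is
#' expressed relative to its own start).
#'
#' @param t_half True half-life (hours, > 0).
#' @param timepoints Hours; must include 0.
#' @param cv Noise coefficient of variation (0 = exact decay).
#' @param seed Optional seed (`NULL` leaves the RNG state alone).
#' @return `data.frame` with columns `time`, `value`.
#' @examples
#' simulate_decay(1, c(0, 1, 2), cv = 0)$value  # 1, 0.5, 0.25
#' @export
simulate_decay <- function(t_half, timepoints, cv = 0.05, seed = NULL) {
  stopifnot(t_half > 0, 0 %in% timepoints, cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log1p(cv^2))
  noise <- stats::rlnorm(length(timepoints), meanlog = -sdlog^2 / 2,
                         sdlog = sdlog)
  y <- 2^(-timepoints / t_half) * noise
  y <- y / y[match(0, timepoints)]
  data.frame(time = timepoints, value = y)
}

#' Simulate a complete two-condition dataset and optionally write it out
#'
#' Orchestrates the generators into the full test surface: gene models
#' with planted methylation sites, IP/input fragment libraries for a
#' control condition (all sites present) and a treated condition (sites
#' lost on the genes planted as methylation-changed), and the four
#' evidence tables whose planted four-way members are drawn from those
#' same genes. With `dir` given, everything is written as plain-text
#' files (BED12 models, BED6 fragments, TSV tables and ground truth).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @param n_down,n_up,n_discordant,n_background Forwarded to
#'   [simulate_deg_tables()]; the planted four-way members are the first
#'   genes of the universe, which here starts with the simulated gene
#'   ids, so methylation-changed genes lose their planted peaks in the
#'   treated condition.
#' @return List: `models`, `truth`, `control` / `treated` (fragment
#'   libraries), `deg` (tables + truth), and `paths` when written.
#' @export
simulate_dataset <- function(config, dir = NULL, n_down = 10, n_up = 3,
                             n_discordant = 27, n_background = 150) {
  gm <- simulate_gene_models(config)
  n_planted <- n_down + n_up + n_discordant
  if (length(gm$models) < n_planted)
    stop("n_genes (", length(gm$models), ") smaller than planted four-way ",
         "membership (", n_planted, ")")
  universe <- c(names(gm$models),
                sprintf("GENE%03d", seq_len(max(0, n_planted + n_background -
                                                  length(gm$models)))))
  deg <- simulate_deg_tables(config, genes = universe, n_down = n_down,
                             n_up = n_up, n_discordant = n_discordant,
                             n_background = n_background)
  changed <- unlist(deg$truth, use.names = FALSE)
  control <- simulate_fragments(gm$models, gm$truth, config)
  cfg_t <- config
  cfg_t$seed <- config$seed + 1000L
  truth_t <- gm$truth[!gm$truth$gene_id %in% changed, , drop = FALSE]
  treated <- simulate_fragments(gm$models, truth_t, cfg_t)
  out <- list(models = gm$models, truth = gm$truth,
              truth_treated = truth_t, control = control,
              treated = treated, deg = deg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(models = file.path(dir, "models.bed12"))
    write_gene_models_bed12(gm$models, paths$models)
    for (cond in c("control", "treated")) for (lib in c("ip", "input")) {
      p <- file.path(dir, paste0(cond, "_", lib, ".bed"))
      write_fragments_bed(out[[cond]][[lib]], p)
      paths[[paste0(cond, "_", lib)]] <- p
    }
    for (lb in names(deg$tables)) {
      p <- file.path(dir, paste0(lb, ".tsv"))
      tb <- deg$tables[[lb]]
      utils::write.table(tb[setdiff(names(tb), "gene_key")], p,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      paths[[lb]] <- p
    }
    paths$truth_peaks <- file.path(dir, "truth_peaks.tsv")
    utils::write.table(gm$truth, paths$truth_peaks, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$truth_genes <- file.path(dir, "truth_genes.tsv")
    utils::write.table(
      data.frame(gene = changed,
                 role = rep(c("down", "up", "discordant"),
                            c(n_down, n_up, n_discordant))),
      paths$truth_genes, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}
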