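#' Merge positive windows into peaks
#'
#' Positive windows (FDR below threshold and log2 enrichment score at or
#' above threshold) are merged per gene whenever their isoform intervals
#' overlap by at least one nucleotide. Each merged peak's enrichment score
#' is recomputed from the counts over the merged interval with the same
#' four-number formula used for windows (gene medians unchanged); the
#' minimum window FDR is kept for ranking. When gene models are supplied
#' the peak is also projected back to genome intervals.
#'
#' @param records Scored window records ([score_windows()]).
#' @param ip,input Named lists (by gene id) of projected fragment tables,
#'   used to recount the merged intervals. Genes absent from the lists get
#'   zero recounts (the pseudocount rule keeps scores finite); interval
#'   structure is unaffected.
#' @param models Optional named list of [gene_model()]s (by gene id) for
#'   genome projection.
#' @param fdr_threshold,log2es_threshold Positivity thresholds (defaults
#'   0.01 and 1); only used if `records` lacks a `positive` column.
#' @return `data.frame` of peaks: `gene_id`, `start`, `end`, `n_windows`,
#'   `min_fdr`, `a`, `c`, `b`, `d`, `es`, `log2_es`, and (with `models`)
#'   `chrom`, `strand`, `genome_blocks` (comma-separated `start-end`
#'   pairs).
#' @export
call_and_merge <- function(records, ip = list(), input = list(),
                           models = NULL, fdr_threshold = 0.01,
                           log2es_threshold = 1) {
  if (is.null(records$positive))
    records$positive <- records$retained & !is.na(records$fdr) &
      records$fdr < fdr_threshold & log2(records$es) >= log2es_threshold
  pos <- records[records$positive %in% TRUE, , drop = FALSE]
  out <- list()
  for (g in unique(pos$gene_id)) {
    pg <- pos[pos$gene_id == g, , drop = FALSE]
    pg <- pg[order(pg$start), , drop = FALSE]
    run_id <- cumsum(c(1, pg$start[-1] >= cummax(pg$end)[-nrow(pg)]))
    b <- pg$b[1]; d <- pg$d[1]
    ipg <- ip[[g]]; ing <- input[[g]]
    for (r in unique(run_id)) {
      w <- pg[run_id == r, , drop = FALSE]
      s <- min(w$start); e <- max(w$end)
      a <- if (!is.null(ipg)) .count_overlaps(ipg$start, ipg$end, s, e) else 0
      cc <- if (!is.null(ing)) .count_overlaps(ing$start, ing$end, s, e) else 0
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, start = s, end = e, n_windows = nrow(w),
        min_fdr = min(w$fdr), a = a, c = cc, b = b, d = d,
        es = enrichment_score(a, b, cc, d))
    }
  }
  peaks <- if (length(out)) do.call(rbind, out)
           else data.frame(gene_id = character(0), start = numeric(0),
                           end = numeric(0), n_windows = integer(0),
                           min_fdr = numeric(0), a = numeric(0),
                           c = numeric(0), b = numeric(0), d = numeric(0),
                           es = numeric(0))
  peaks$log2_es <- log2(peaks$es)
  if (!is.null(models) && nrow(peaks)) {
    peaks$chrom <- NA_character_
    peaks$strand <- NA_character_
    peaks$genome_blocks <- NA_character_
    for (i in seq_len(nrow(peaks))) {
      m <- models[[peaks$gene_id[i]]]
      if (is.null(m)) next
      gb <- project_to_genome(peaks$start[i], peaks$end[i], m)
      peaks$chrom[i] <- m$chrom
      peaks$strand[i] <- m$strand
      peaks$genome_blocks[i] <- paste(sprintf("%d-%d", as.integer(gb$start),
                                              as.integer(gb$end)),
                                      collapse = ",")
    }
  }
  rownames(peaks) <- NULL
  peaks
}

#' Call m6A peaks from IP and input fragments
#'
#' The full window pipeline on isoform coordinates: pick the longest
#' isoform per gene, project and extend fragments, count 100-nt windows
#' every 10 nt, drop windows below 1/20 of the gene's top window in both
#' libraries, normalize counts by the per-gene median, score each window
#' with the `(a d)/(b c)` enrichment score and a two-sided Fisher exact
#' test, adjust p-values by Benjamini-Hochberg across all retained
#' windows, and merge overlapping positive windows (FDR < `fdr_threshold`,
#' log2 ES >= `log2es_threshold`) into peaks.
#'
#' @param models List of [gene_model()]s (isoform selection is applied if
#'   several isoforms per gene are present).
#' @param ip,input Genome fragment tables ([fragments()] /
#'   [read_fragments_bed()]).
#' @param window,step Window geometry in nt (defaults 100 / 10).
#' @param min_frac Low-window fraction (default 1/20).
#' @param fdr_threshold,log2es_threshold Positive-window thresholds
#'   (defaults 0.01 and 1).
#' @param fragment_length Read extension in nt (default 150, the average
#'   MeRIP fragment size).
#' @param stranded Drop antisense fragments during projection (default
#'   `TRUE`).
#' @param fisher_table See [score_windows()].
#' @return Object of class `"m6a_peaks"`: list with elements `peaks`
#'   (merged peak table), `windows` (all window records with statistics)
#'   and `params`.
#' @export
call_peaks <- function(models, ip, input, window = 100, step = 10,
                       min_frac = 1 / 20, fdr_threshold = 0.01,
                       log2es_threshold = 1, fragment_length = 150,
                       stranded = TRUE,
                       fisher_table = c("totals", "medians")) {
  fisher_table <- match.arg(fisher_table)
  models <- select_longest_isoform(models)
  ip_iso <- lapply(models, project_fragments, frags = ip,
                   fragment_length = fragment_length, stranded = stranded)
  input_iso <- lapply(models, project_fragments, frags = input,
                      fragment_length = fragment_length, stranded = stranded)
  recs <- do.call(rbind, lapply(names(models), function(g)
    count_windows(models[[g]], ip_iso[[g]], input_iso[[g]], window, step)))
  recs <- filter_low_windows(recs, min_frac)
  recs <- score_windows(recs, fdr_threshold, log2es_threshold, min_frac,
                        fisher_table)
  peaks <- call_and_merge(recs, ip_iso, input_iso, models,
                          fdr_threshold, log2es_threshold)
  structure(list(peaks = peaks, windows = recs,
                 params = list(window = window, step = step,
                               min_frac = min_frac,
                               fdr_threshold = fdr_threshold,
                               log2es_threshold = log2es_threshold,
                               fragment_length = fragment_length,
                               stranded = stranded,
                               fisher_table = fisher_table,
                               n_genes = length(models))),
            class = "m6a_peaks")
}

#' @export
print.m6a_peaks <- function(x, ...) {
  cat(sprintf(
    "<m6a_peaks> %d peak(s) on %d gene(s); %d/%d windows tested (%d positive)\n",
    nrow(x$peaks), length(unique(x$peaks$gene_id)),
    sum(x$windows$retained), nrow(x$windows),
    sum(x$windows$positive, na.rm = TRUE)))
  cat(sprintf("  thresholds: FDR < %g, log2 ES >= %g; window %d/step %d nt\n",
              x$params$fdr_threshold, x$params$log2es_threshold,
              x$params$window, x$params$step))
  invisible(x)
}

#' @export
summary.m6a_peaks <- function(object, ...) {
  p <- object$peaks
  print(object)
  if (nrow(p)) {
    cat(sprintf("  peak width: median %.0f nt (range %.0f-%.0f)\n",
                stats::median(p$end - p$start), min(p$end - p$start),
                max(p$end - p$start)))
    cat(sprintf("  log2 ES: median %.2f (range %.2f-%.2f)\n",
                stats::median(p$log2_es), min(p$log2_es), max(p$log2_es)))
  }
  invisible(object)
}

.peak_table <- function(x) {
  if (inherits(x, "m6a_peaks")) x$peaks else x
}

#' Compare peak sets between two conditions
#'
#' A peak is *shared* when some peak on the same gene in the other set
#' overlaps it by at least one nucleotide in isoform coordinates, and
#' *unique* otherwise — condition-unique methylation is the evidence that
#' feeds the four-dataset target triage. Gene-level unique lists (genes
#' with at least one unique peak) are also returned.
#'
#' @param peaks_a,peaks_b Peak tables or `"m6a_peaks"` objects from two
#'   conditions called on the same annotation.
#' @param models Named list of [gene_model()]s; every peak's gene must be
#'   present.
#' @return Object of class `"peak_comparison"`: list with `unique_a`,
#'   `unique_b`, `shared_a`, `shared_b` (peak tables) and `genes_unique_a`,
#'   `genes_unique_b` (character vectors).
#' @export
unique_peaks <- function(peaks_a, peaks_b, models) {
  pa <- .peak_table(peaks_a)
  pb <- .peak_table(peaks_b)
  missing <- setdiff(unique(c(pa$gene_id, pb$gene_id)), names(models))
  if (length(missing))
    stop("peak gene(s) absent from gene models: ",
         paste(missing, collapse = ", "))
  overlaps_other <- function(p, q) {
    if (nrow(p) == 0L) return(logical(0))
    vapply(seq_len(nrow(p)), function(i) {
      qq <- q[q$gene_id == p$gene_id[i], , drop = FALSE]
      any(qq$start < p$end[i] & qq$end > p$start[i])
    }, TRUE)
  }
  sa <- overlaps_other(pa, pb)
  sb <- overlaps_other(pb, pa)
  structure(list(
    unique_a = pa[!sa, , drop = FALSE],
    unique_b = pb[!sb, , drop = FALSE],
    shared_a = pa[sa, , drop = FALSE],
    shared_b = pb[sb, , drop = FALSE],
    genes_unique_a = sort(unique(pa$gene_id[!sa])),
    genes_unique_b = sort(unique(pb$gene_id[!sb]))),
    class = "peak_comparison")
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat(sprintf(
    "<peak_comparison> A: %d unique / %d shared peaks (%d genes with unique)\n",
    nrow(x$unique_a), nrow(x$shared_a), length(x$genes_unique_a)))
  cat(sprintf(
    "                  B: %d unique / %d shared peaks (%d genes with unique)\n",
    nrow(x$unique_b), nrow(x$shared_b), length(x$genes_unique_b)))
  invisible(x)
}

#' Metagene distribution of peaks along the mRNA
#'
#' Each peak contributes its isoform midpoint, rescaled within the
#' transcript region it falls in (5'UTR, CDS or 3'UTR), to a fixed block
#' of bins per region, yielding the familiar normalized metagene profile
#' of methylation along the message. Peaks on non-coding models are
#' skipped and counted.
#'
#' @param peaks Peak table or `"m6a_peaks"` object.
#' @param models Named list of [gene_model()]s with CDS boundaries.
#' @param bins_per_region Bins for 5'UTR / CDS / 3'UTR (default
#'   `c(30, 40, 30)`).
#' @return Object of class `"metagene_profile"`: `density` (sums to 1
#'   unless no coding peaks, then all zero with a warning), `counts`,
#'   `region` (bin labels), `n_used`, `n_skipped_noncoding`.
#' @export
metagene_distribution <- function(peaks, models,
                                  bins_per_region = c(30, 40, 30)) {
  p <- .peak_table(peaks)
  stopifnot(length(bins_per_region) == 3L, all(bins_per_region > 0))
  nb <- sum(bins_per_region)
  counts <- numeric(nb)
  region <- factor(rep(c("5'UTR", "CDS", "3'UTR"), bins_per_region),
                   levels = c("5'UTR", "CDS", "3'UTR"))
  offset <- cumsum(c(0, bins_per_region))[1:3]
  n_skip <- 0L
  n_used <- 0L
  for (i in seq_len(nrow(p))) {
    m <- models[[p$gene_id[i]]]
    if (is.null(m)) stop("peak gene absent from models: ", p$gene_id[i])
    if (is.na(m$cds_start)) { n_skip <- n_skip + 1L; next }
    mid <- (p$start[i] + p$end[i]) / 2
    bounds <- c(0, m$cds_start, m$cds_end, m$mrna_length)
    reg <- findInterval(mid, bounds[2:3]) + 1L  # 1=5'UTR, 2=CDS, 3=3'UTR
    rlen <- bounds[reg + 1L] - bounds[reg]
    rel <- if (rlen > 0) (mid - bounds[reg]) / rlen else 0
    bin <- offset[reg] + min(floor(rel * bins_per_region[reg]),
                             bins_per_region[reg] - 1L) + 1L
    counts[bin] <- counts[bin] + 1
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    warning("no peaks on coding models; metagene density is all zero")
    dens <- counts
  } else dens <- counts / sum(counts)
  structure(list(density = dens, counts = counts, region = region,
                 bins_per_region = bins_per_region, n_used = n_used,
                 n_skipped_noncoding = n_skip),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  mass <- tapply(x$density, x$region, sum)
  cat(sprintf("<metagene_profile> %d peaks binned (%d non-coding skipped)\n",
              x$n_used, x$n_skipped_noncoding))
  cat(sprintf("  mass: 5'UTR %.3f | CDS %.3f | 3'UTR %.3f\n",
              mass[1], mass[2], mass[3]))
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  cols <- c("5'UTR" = "grey55", "CDS" = "steelblue", "3'UTR" = "grey55")
  graphics::barplot(x$density, border = NA, space = 0,
                    col = cols[as.character(x$region)],
                    xlab = "normalized mRNA position",
                    ylab = "peak density", ...)
  at <- cumsum(c(0, x$bins_per_region))
  graphics::axis(1, at = at[1:3] + x$bins_per_region / 2, tick = FALSE,
                 labels = levels(x$region))
  graphics::abline(v = at[2:3], lty = 2)
  invisible(x)
}

#' Write peaks as BED6 plus a full window table
#'
#' Emits one BED6 line per peak genome block (score = `round(100 *
#' log2 ES)`, name = `gene:peakIndex`) and, alongside, the complete
#' window-record table as TSV.
#'
#' @param x An `"m6a_peaks"` object with genome-projected peaks.
#' @param bed_path,tsv_path Output paths (`NULL` to skip either).
#' @return Invisibly, the peak table.
#' @export
write_peaks <- function(x, bed_path = NULL, tsv_path = NULL) {
  p <- x$peaks
  if (!is.null(bed_path)) {
    lines <- character(0)
    if (nrow(p) && !is.null(p$genome_blocks)) {
      for (i in seq_len(nrow(p))) {
        blocks <- strsplit(p$genome_blocks[i], ",", fixed = TRUE)[[1]]
        se <- do.call(rbind, strsplit(blocks, "-", fixed = TRUE))
        lines <- c(lines, paste(p$chrom[i], se[, 1], se[, 2],
                                paste0(p$gene_id[i], ":", i),
                                round(100 * p$log2_es[i]), p$strand[i],
                                sep = "\t"))
      }
    }
    writeLines(lines, bed_path)
  }
  if (!is.null(tsv_path))
    utils::write.table(x$windows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(p)
}
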