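#' Load gene models from BED12 or GTF
#'
#' Reads transcript structures into [gene_model()] objects. BED12 blocks
#' are already 0-based half-open; GTF exons are 1-based closed and are
#' converted on read so that a single coordinate convention is used
#' everywhere downstream. The BED12 `name` field may be either a plain
#' transcript id (the gene id then equals it) or `"transcript|gene"`.
#' `thickStart`/`thickEnd` (BED) or `CDS` features (GTF) define the CDS,
#' which is stored in isoform coordinates.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed12"` or `"gtf"`.
#' @return A named list of [gene_model()] objects, keyed by transcript id.
#'   Transcripts with zero exons are dropped with a warning; duplicated
#'   transcript ids are an error.
#' @export
load_gene_models <- function(path, dialect = c("bed12", "gtf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  models <- switch(dialect,
                   bed12 = .load_bed12(path),
                   gtf = .load_gtf(path))
  ids <- vapply(models, `[[`, "", "transcript_id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate transcript_id in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  names(models) <- ids
  models
}

.split_bed_name <- function(name) {
  parts <- strsplit(name, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 2L) list(transcript = parts[1], gene = parts[2])
  else list(transcript = name, gene = name)
}

.load_bed12 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stop("malformed BED12 at line ", i, " of ", path,
           ": expected 12 fields, got ", length(f))
    chrom <- f[1]
    chrom_start <- suppressWarnings(as.numeric(f[2]))
    thick_start <- suppressWarnings(as.numeric(f[7]))
    thick_end <- suppressWarnings(as.numeric(f[8]))
    n_block <- suppressWarnings(as.integer(f[10]))
    if (is.na(chrom_start) || is.na(n_block))
      stop("malformed BED12 at line ", i, " of ", path,
           ": non-numeric coordinate fields")
    nm <- .split_bed_name(f[4])
    if (n_block == 0L) {
      warning("transcript ", nm$transcript, " (line ", i,
              ") has zero exons; skipped")
      next
    }
    sizes <- as.numeric(strsplit(f[11], ",")[[1]])
    starts <- as.numeric(strsplit(f[12], ",")[[1]])
    if (length(sizes) != n_block || length(starts) != n_block ||
        anyNA(sizes) || anyNA(starts))
      stop("malformed BED12 at line ", i, " of ", path,
           ": blockCount does not match blockSizes/blockStarts")
    exon_start <- chrom_start + starts
    exon_end <- exon_start + sizes
    strand <- f[6]
    cds_start <- cds_end <- NA
    if (!is.na(thick_start) && !is.na(thick_end) && thick_end > thick_start) {
      m_tmp <- gene_model(nm$gene, nm$transcript, chrom, strand,
                          exon_start, exon_end)
      lo <- project_to_isoform(thick_start, m_tmp)
      hi <- project_to_isoform(thick_end - 1, m_tmp)
      if (!is.na(lo) && !is.na(hi)) {
        cds_start <- min(lo, hi)
        cds_end <- max(lo, hi) + 1
      }
    }
    j <- j + 1L
    out[[j]] <- gene_model(nm$gene, nm$transcript, chrom, strand,
                           exon_start, exon_end, cds_start, cds_end)
  }
  out[seq_len(j)]
}

.load_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF needs the rtracklayer package; ",
         "BED12 input has no extra dependency")
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  if (!all(c("type", "transcript_id") %in% names(md)))
    stop("GTF ", path, " lacks type/transcript_id attributes")
  ex <- md[md$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop("no exon features in ", path)
  cds <- md[md$type == "CDS", , drop = FALSE]
  out <- lapply(split(ex, ex$transcript_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    gene <- if ("gene_id" %in% names(e) && !is.na(e$gene_id[1]))
      e$gene_id[1] else e$transcript_id[1]
    # GenomicRanges start is 1-based closed; convert to 0-based half-open
    m <- gene_model(gene, e$transcript_id[1], as.character(e$seqnames[1]),
                    as.character(e$strand[1]), e$start - 1, e$end)
    cc <- cds[cds$transcript_id == e$transcript_id[1], , drop = FALSE]
    if (nrow(cc)) {
      g_lo <- min(cc$start) - 1
      g_hi <- max(cc$end)
      lo <- project_to_isoform(g_lo, m)
      hi <- project_to_isoform(g_hi - 1, m)
      if (!is.na(lo) && !is.na(hi))
        m <- gene_model(gene, m$transcript_id, m$chrom, m$strand,
                        m$exon_start, m$exon_end,
                        min(lo, hi), max(lo, hi) + 1)
    }
    m
  })
  unname(out)
}

#' Write gene models as BED12
#'
#' The `name` field is written as `"transcript|gene"` and round-trips
#' through [load_gene_models()]. `thickStart`/`thickEnd` carry the CDS
#' (equal to `chromStart` for non-coding isoforms, the BED convention).
#'
#' @param models List of [gene_model()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(models, path) {
  rows <- vapply(models, function(m) {
    cs <- m$exon_start[1]
    ce <- m$exon_end[length(m$exon_end)]
    if (!is.na(m$cds_start)) {
      g <- project_to_genome(m$cds_start, m$cds_end, m)
      thick <- c(min(g$start), max(g$end))
    } else thick <- c(cs, cs)
    paste(m$chrom, format(cs, scientific = FALSE),
          format(ce, scientific = FALSE),
          paste0(m$transcript_id, "|", m$gene_id), 0, m$strand,
          format(thick[1], scientific = FALSE),
          format(thick[2], scientific = FALSE), "0",
          length(m$exon_start),
          paste0(paste(m$exon_end - m$exon_start, collapse = ","), ","),
          paste0(paste(m$exon_start - cs, collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Read aligned fragments from BED
#'
#' Fragments are aligned-read intervals; only their strand-aware 5' start
#' is used downstream (the pipeline re-extends every read to the average
#' fragment size in isoform coordinates, as in stranded MeRIP-seq
#' processing). Requires at least 6 BED columns (strand is needed).
#'
#' @param path BED file (>= 6 columns).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand` and
#'   the derived `pos5` (genome coordinate of the 5' base).
#' @export
read_fragments_bed <- function(path) {
  if (!file.exists(path)) stop("fragment BED not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "numeric", "numeric",
                                        "character", "character", "character"))
  if (any(!df$strand %in% c("+", "-")))
    stop("fragment BED ", path, " has entries without +/- strand")
  fragments(df$chrom, df$start, df$end, df$strand)
}

#' Construct a fragment table
#'
#' @param chrom,start,end,strand Parallel vectors describing genome
#'   intervals of aligned fragments (0-based half-open).
#' @return `data.frame` with a `pos5` column giving the strand-aware 5'
#'   base of each fragment.
#' @export
fragments <- function(chrom, start, end, strand) {
  stopifnot(all(end > start), all(start >= 0), all(strand %in% c("+", "-")))
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), strand = as.character(strand),
             pos5 = ifelse(strand == "+", as.numeric(start),
                           as.numeric(end) - 1))
}

#' Write fragments as BED6
#'
#' @param frags Fragment table from [fragments()] / [read_fragments_bed()].
#' @param path Output file.
#' @param name Optional name column (recycled).
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(frags, path, name = "frag") {
  df <- data.frame(frags$chrom, format(frags$start, scientific = FALSE, trim = TRUE),
                   format(frags$end, scientific = FALSE, trim = TRUE),
                   name, 0, frags$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Project fragments onto a gene model and extend to fragment length
#'
#' Each fragment's 5' start is projected onto the isoform; fragments whose
#' 5' base is intronic/intergenic for this model are dropped, as are
#' fragments on the opposite strand when `stranded = TRUE` (the default;
#' stranded library preparation). The projected start is extended by
#' `fragment_length` nucleotides 3'-wards in isoform space (clipped at the
#' transcript end), mirroring the read-extension step of MeRIP-seq peak
#' calling.
#'
#' @param frags Fragment table ([fragments()]).
#' @param model A [gene_model()].
#' @param fragment_length Extension length in nt (average fragment size;
#'   default 150).
#' @param stranded Drop fragments on the strand opposite the gene
#'   (default `TRUE`).
#' @return `data.frame` with isoform-interval columns `start`, `end`.
#' @export
project_fragments <- function(frags, model, fragment_length = 150,
                              stranded = TRUE) {
  sel <- frags$chrom == model$chrom
  if (stranded) sel <- sel & frags$strand == model$strand
  s <- project_to_isoform(frags$pos5[sel], model)
  s <- s[!is.na(s)]
  data.frame(start = s, end = pmin(s + fragment_length, model$mrna_length))
}
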