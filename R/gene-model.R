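#' Construct a gene model
#'
#' A gene model holds one isoform of a gene: its exon structure on the
#' genome and, when the isoform is coding, the CDS boundaries expressed in
#' isoform (spliced-mRNA) coordinates. The isoform coordinate frame is the
#' one on which all window scanning is performed, so that windows never
#' straddle introns.
#'
#' All coordinates are 0-based half-open. Exons must be non-overlapping and
#' sorted by genome position; the mRNA length is the sum of exon widths.
#' Isoform coordinate 0 is the transcript 5' end, which for minus-strand
#' genes corresponds to the highest genome coordinate.
#'
#' @param gene_id Gene identifier.
#' @param transcript_id Transcript identifier (unique per model).
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end Integer vectors of genome exon boundaries,
#'   0-based half-open, sorted by genome position, non-overlapping.
#' @param cds_start,cds_end CDS boundaries in isoform coordinates
#'   (0-based half-open), or `NA` for a non-coding isoform.
#' @return An object of class `"gene_model"`.
#' @examples
#' m <- gene_model("G1", "T1", "chr1", "+", c(0L, 200L), c(100L, 300L),
#'                 cds_start = 20, cds_end = 150)
#' m$mrna_length
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand,
                       exon_start, exon_end, cds_start = NA, cds_end = NA) {
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  exon_start <- as.numeric(exon_start)
  exon_end <- as.numeric(exon_end)
  if (length(exon_start) == 0L)
    stop("gene model '", transcript_id, "' has zero exons")
  if (length(exon_start) != length(exon_end))
    stop("exon_start and exon_end differ in length")
  if (any(exon_end <= exon_start))
    stop("empty or inverted exon in '", transcript_id, "'")
  if (is.unsorted(exon_start, strictly = TRUE) ||
      any(exon_start[-1] < exon_end[-length(exon_end)]))
    stop("exons of '", transcript_id,
         "' must be sorted by genome position and non-overlapping")
  mrna_length <- sum(exon_end - exon_start)
  if (!is.na(cds_start) || !is.na(cds_end)) {
    if (is.na(cds_start) || is.na(cds_end))
      stop("cds_start and cds_end must both be given or both NA")
    if (cds_start < 0 || cds_end > mrna_length || cds_start >= cds_end)
      stop("CDS boundaries of '", transcript_id,
           "' outside [0, mrna_length) or inverted")
  }
  structure(
    list(gene_id = as.character(gene_id),
         transcript_id = as.character(transcript_id),
         chrom = as.character(chrom), strand = strand,
         exon_start = exon_start, exon_end = exon_end,
         cds_start = if (is.na(cds_start)) NA_real_ else as.numeric(cds_start),
         cds_end = if (is.na(cds_end)) NA_real_ else as.numeric(cds_end),
         mrna_length = mrna_length),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "non-coding"
         else sprintf("CDS [%d, %d)", as.integer(x$cds_start), as.integer(x$cds_end))
  cat(sprintf("<gene_model> %s / %s  %s:%s  %d exon(s), %d nt, %s\n",
              x$gene_id, x$transcript_id, x$chrom, x$strand,
              length(x$exon_start), as.integer(x$mrna_length), cds))
  invisible(x)
}

# exons in transcript (5'->3') order with cumulative isoform offsets
.tx_exons <- function(model) {
  k <- length(model$exon_start)
  ord <- if (model$strand == "+") seq_len(k) else rev(seq_len(k))
  w <- (model$exon_end - model$exon_start)[ord]
  list(start = model$exon_start[ord], end = model$exon_end[ord],
       width = w, offset = cumsum(c(0, w))[seq_len(k)])
}

#' Project genome positions onto isoform coordinates
#'
#' Maps genome positions to positions along the spliced mRNA of a gene
#' model. The isoform coordinate of a position is the number of exonic
#' nucleotides 5' of it in transcript orientation, so minus-strand
#' transcripts are counted from their (genome-rightmost) 5' end. Intronic
#' and intergenic positions map to `NA` ("outside"), which is an ordinary
#' value, not an error.
#'
#' @param pos Numeric vector of genome positions (0-based).
#' @param model A [gene_model()].
#' @return Numeric vector of isoform coordinates, `NA` where outside the
#'   exons.
#' @examples
#' m <- gene_model("G1", "T1", "chr1", "+", c(0L, 200L), c(100L, 300L))
#' project_to_isoform(c(50, 150, 250), m)  # 50, NA, 150
#' @seealso [project_to_genome()] for the inverse mapping of intervals.
#' @export
project_to_isoform <- function(pos, model) {
  tx <- .tx_exons(model)
  out <- rep(NA_real_, length(pos))
  for (i in seq_along(tx$start)) {
    hit <- !is.na(pos) & pos >= tx$start[i] & pos < tx$end[i]
    if (any(hit)) {
      out[hit] <- tx$offset[i] +
        if (model$strand == "+") pos[hit] - tx$start[i]
        else tx$end[i] - 1 - pos[hit]
    }
  }
  out
}

# genome position of single isoform coordinates (vectorized)
.iso_to_genome_pos <- function(pos, model) {
  tx <- .tx_exons(model)
  out <- rep(NA_real_, length(pos))
  for (i in seq_along(tx$start)) {
    hit <- !is.na(pos) & pos >= tx$offset[i] & pos < tx$offset[i] + tx$width[i]
    if (any(hit)) {
      out[hit] <-
        if (model$strand == "+") tx$start[i] + pos[hit] - tx$offset[i]
        else tx$end[i] - 1 - (pos[hit] - tx$offset[i])
    }
  }
  out
}

#' Project an isoform interval back to genome intervals
#'
#' Maps a half-open interval in isoform coordinates to the ordered list of
#' genome intervals (exon pieces) it covers. The mapping is the exact
#' inverse of [project_to_isoform()]: the union of the returned intervals
#' contains precisely the genome positions whose isoform coordinates fall
#' in `[start, end)`.
#'
#' @param start,end Isoform interval, 0-based half-open,
#'   `0 <= start <= end <= mrna_length`.
#' @param model A [gene_model()].
#' @return A `data.frame` with columns `start`, `end` (genome coordinates,
#'   sorted by genome position). Zero rows for an empty interval.
#' @examples
#' m <- gene_model("G1", "T1", "chr1", "+", c(0L, 200L), c(100L, 300L))
#' project_to_genome(50, 150, m)  # [50,100) and [200,250)
#' @export
project_to_genome <- function(start, end, model) {
  if (start < 0 || end > model$mrna_length || start > end)
    stop("isoform interval [", start, ", ", end, ") outside [0, ",
         model$mrna_length, ")")
  tx <- .tx_exons(model)
  gs <- ge <- numeric(0)
  for (i in seq_along(tx$start)) {
    s <- max(start, tx$offset[i])
    e <- min(end, tx$offset[i] + tx$width[i])
    if (s < e) {
      if (model$strand == "+") {
        g0 <- tx$start[i] + (s - tx$offset[i])
        gs <- c(gs, g0); ge <- c(ge, g0 + (e - s))
      } else {
        g1 <- tx$end[i] - (s - tx$offset[i])
        gs <- c(gs, g1 - (e - s)); ge <- c(ge, g1)
      }
    }
  }
  ord <- order(gs)
  data.frame(start = gs[ord], end = ge[ord])
}

#' Pick the analysis isoform for each gene
#'
#' When a gene has several isoforms, the longest spliced mRNA is used as
#' the single coordinate frame for window scanning. Ties are broken by the
#' lexicographically smallest transcript id so repeated runs pick the same
#' isoform; tie-breaks are reported with a message.
#'
#' @param models A list of [gene_model()] objects (any order, possibly
#'   several per gene).
#' @return A named list of gene models, one per `gene_id` (names are gene
#'   ids, sorted).
#' @export
select_longest_isoform <- function(models) {
  if (length(models) == 0L) stop("no gene models supplied")
  if (!is.null(names(models)) && anyDuplicated(names(models)) == 0L &&
      all(vapply(models, inherits, TRUE, "gene_model")) &&
      identical(names(models), vapply(models, `[[`, "", "gene_id")))
    return(models)  # already one model per gene, keyed by gene id
  gene_ids <- vapply(models, `[[`, "", "gene_id")
  out <- lapply(split(models, gene_ids), function(ms) {
    len <- vapply(ms, `[[`, 0, "mrna_length")
    best <- which(len == max(len))
    if (length(best) > 1L) {
      tid <- vapply(ms[best], `[[`, "", "transcript_id")
      pick <- best[order(tid)[1L]]
      message("gene ", ms[[1]]$gene_id, ": length tie, keeping transcript ",
              ms[[pick]]$transcript_id)
      ms[[pick]]
    } else ms[[best]]
  })
  out[order(names(out))]
}
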