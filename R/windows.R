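#' Sliding-window grid over an isoform
#'
#' Windows of `window` nt advance by `step` nt along the spliced mRNA:
#' starts 0, 10, 20, ... while `start + window <= mrna_length`. If the
#' final regular window stops short of the transcript end, one extra
#' right-anchored window ending exactly at `mrna_length` is added.
#' Transcripts shorter than `window` get a single full-length window.
#'
#' @param mrna_length Transcript length in nt.
#' @param window Window width in nt (default 100).
#' @param step Step in nt (default 10).
#' @return `data.frame` with columns `start`, `end`.
#' @examples
#' nrow(window_grid(300))  # 21 windows: starts 0..200
#' @export
window_grid <- function(mrna_length, window = 100, step = 10) {
  if (mrna_length <= window)
    return(data.frame(start = 0, end = mrna_length))
  starts <- seq.int(0, mrna_length - window, by = step)
  if (starts[length(starts)] + window < mrna_length)
    starts <- c(starts, mrna_length - window)
  data.frame(start = starts, end = starts + window)
}

# counts of intervals overlapping each window by >= 1 nt
.count_overlaps <- function(iv_start, iv_end, w_start, w_end) {
  ss <- sort(iv_start)
  ee <- sort(iv_end)
  findInterval(w_end - 0.5, ss) - findInterval(w_start + 0.5, ee)
}

#' Count IP and input fragments in sliding windows
#'
#' A fragment is counted in every window its isoform interval overlaps by
#' at least one nucleotide. Fragments must already be projected onto the
#' model's isoform coordinates (see [project_fragments()]).
#'
#' @param model A [gene_model()].
#' @param ip,input Projected fragment tables (`start`, `end` isoform
#'   intervals); may be empty.
#' @param window,step Window geometry in nt (defaults 100 / 10).
#' @return `data.frame` of window records: `gene_id`, `start`, `end`,
#'   `a` (IP count), `c` (input count).
#' @export
count_windows <- function(model, ip, input, window = 100, step = 10) {
  w <- window_grid(model$mrna_length, window, step)
  data.frame(gene_id = model$gene_id, start = w$start, end = w$end,
             a = .count_overlaps(ip$start, ip$end, w$start, w$end),
             c = .count_overlaps(input$start, input$end, w$start, w$end))
}

#' Flag low-coverage windows
#'
#' A window is excluded when its count is below `min_frac` of the gene's
#' top window in *both* the IP and the input library (default 1/20); this
#' guards against inaccurate isoform annotation dominating the tails of a
#' transcript. Excluded windows take no part in testing, in the per-gene
#' normalization medians, or in the FDR multiplicity. A gene whose windows
#' are all zero in a library counts as "low" in that library, so all-zero
#' genes are excluded entirely.
#'
#' @param records Window records ([count_windows()]), possibly several
#'   genes.
#' @param min_frac Fraction of the top window (default `1/20`).
#' @return `records` with a logical `retained` column added.
#' @export
filter_low_windows <- function(records, min_frac = 1 / 20) {
  amax <- stats::ave(records$a, records$gene_id, FUN = max)
  cmax <- stats::ave(records$c, records$gene_id, FUN = max)
  low_ip <- amax == 0 | records$a < amax * min_frac
  low_input <- cmax == 0 | records$c < cmax * min_frac
  records$retained <- !(low_ip & low_input)
  records
}

#' Normalize window counts by the gene median
#'
#' Each gene's window counts are divided by the median count over that
#' gene's retained windows (`b` for IP, `d` for input; the median of an
#' even number of windows is the mean of the middle pair). A zero median
#' takes the pseudocount path, `(x + 1) / (median + 1)`, so outputs stay
#' finite.
#'
#' @param records Window records carrying a `retained` column
#'   ([filter_low_windows()]).
#' @return `records` with columns `b`, `d`, `norm_ip`, `norm_input` added.
#' @export
normalize_by_gene_median <- function(records) {
  if (is.null(records$retained)) records$retained <- TRUE
  med <- function(x, keep) if (any(keep)) stats::median(x[keep]) else NA_real_
  spl <- split(seq_len(nrow(records)), records$gene_id)
  records$b <- records$d <- NA_real_
  for (idx in spl) {
    keep <- records$retained[idx]
    records$b[idx] <- med(records$a[idx], keep)
    records$d[idx] <- med(records$c[idx], keep)
  }
  div <- function(x, m) ifelse(is.na(m), NA_real_,
                               ifelse(m == 0, (x + 1) / (m + 1), x / m))
  records$norm_ip <- div(records$a, records$b)
  records$norm_input <- div(records$c, records$d)
  records
}

#' Window/peak enrichment score
#'
#' The IP-over-input enrichment of a window or peak is
#' `es = (a * d) / (b * c)`, with `a`/`c` the IP/input counts in the
#' window and `b`/`d` the per-gene median IP/input window counts. When
#' either product is zero, 1 is added to all four terms before evaluating,
#' which keeps `log2(es)` finite; the rule is symmetric so a zero numerator
#' is damped the same way as a zero denominator.
#'
#' @param a,b,c,d Non-negative numerics (vectorized).
#' @return Numeric vector of enrichment scores (always finite, positive).
#' @examples
#' enrichment_score(20, 5, 4, 5)   # 5
#' enrichment_score(10, 5, 0, 5)   # (11*6)/(6*1) = 11 via pseudocount
#' @export
enrichment_score <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0, na.rm = TRUE))
    stop("enrichment_score: negative counts")
  num <- a * d
  den <- b * c
  es <- num / den
  ps <- !is.na(num) & !is.na(den) & (num == 0 | den == 0)
  es[ps] <- ((a + 1) * (d + 1))[ps] / ((b + 1) * (c + 1))[ps]
  es
}

#' Two-sided Fisher exact test for a window against its gene
#'
#' Tests the 2x2 table `[[a, A - a], [c, C - c]]` — window versus
#' rest-of-gene counts, IP versus input — where `A` and `C` are the gene's
#' total retained IP and input counts. The two-sided p-value sums the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (with the customary 1e-7
#' relative tolerance for ties). Vectorized; tables sharing margins are
#' evaluated as a group so transcriptome-scale calls stay fast.
#'
#' @param a,A,c,C Non-negative integers (vectorized), `a <= A`, `c <= C`.
#' @return p-values in `(0, 1]`; `A = C = 0` gives 1 by convention.
#' @export
fisher_window_test <- function(a, A, c, C) {
  n <- length(a)
  stopifnot(length(A) %in% c(1L, n), length(C) %in% c(1L, n),
            length(c) == n)
  A <- rep_len(A, n); C <- rep_len(C, n)
  if (any(a < 0 | c < 0 | a > A | c > C))
    stop("fisher_window_test: need 0 <= a <= A and 0 <= c <= C")
  p <- rep(1, n)
  k <- a + c
  todo <- which(A + C > 0)
  if (!length(todo)) return(p)
  # group queries sharing hypergeometric margins (A, C, k)
  o <- order(A[todo], C[todo], k[todo])
  ot <- todo[o]
  new_grp <- c(TRUE, diff(A[ot]) != 0 | diff(C[ot]) != 0 | diff(k[ot]) != 0)
  gid <- integer(n)
  gid[ot] <- cumsum(new_grp)
  first <- ot[new_grp]
  Au <- A[first]; Cu <- C[first]; ku <- k[first]
  # expand each margin set's full support once
  lo <- pmax(0, ku - Cu)
  len <- pmin(ku, Au) - lo + 1
  goff <- cumsum(c(0, len))
  gs <- rep(seq_along(len), len)
  a_sup <- sequence(len) + rep(lo, len) - 1
  pr <- stats::dhyper(a_sup, Au[gs], Cu[gs], ku[gs])
  # per-group ascending probabilities; p(a) = cumulative mass of the
  # support up to a's tie class (relative tie tolerance 1e-7)
  m <- length(pr)
  os <- order(gs, pr)
  prs <- pr[os]
  gss <- gs[os]
  cs <- cumsum(prs)
  grp_end <- c(gss[-1] != gss[-m], TRUE)
  grp_mass_end <- cs[grp_end]
  offset <- c(0, grp_mass_end[-length(grp_mass_end)])
  new_cls <- c(TRUE, gss[-1] != gss[-m] | prs[-1] > prs[-m] * (1 + 1e-7))
  cls <- cumsum(new_cls)
  cls_end <- c(cls[-1] != cls[-m], TRUE)
  p_sorted <- cs[cls_end][cls] - offset[gss]
  p_sup <- numeric(m)
  p_sup[os] <- p_sorted
  gq <- gid[todo]
  p[todo] <- p_sup[goff[gq] + a[todo] - lo[gq] + 1]
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment over the supplied p-values
#' (delegating to [stats::p.adjust()]); the multiplicity is the number of
#' values passed in, so excluded windows must be left out by the caller.
#'
#' @param p Numeric vector of p-values (may be empty).
#' @return Adjusted values, same length and order.
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Score windows: normalization, enrichment score, Fisher test, FDR
#'
#' Convenience wrapper running [normalize_by_gene_median()],
#' [enrichment_score()], [fisher_window_test()] and [adjust_fdr()] over a
#' multi-gene window-record table, and flagging positive windows at the
#' given thresholds. The FDR multiplicity spans all retained windows in
#' `records` (transcriptome-wide when called on a full run).
#'
#' @param records Output of [count_windows()] (+ optionally
#'   [filter_low_windows()]; applied here if the `retained` column is
#'   missing).
#' @param fdr_threshold Positive-window FDR cutoff (default 0.01).
#' @param log2es_threshold Positive-window log2 enrichment-score cutoff
#'   (default 1).
#' @param min_frac Low-window fraction if filtering still has to be
#'   applied (default 1/20).
#' @param fisher_table `"totals"` (default) builds the window versus
#'   rest-of-gene table on raw counts with gene-total margins;
#'   `"medians"` builds `[[a, round(b)], [c, round(d)]]` against the
#'   per-gene median counts, for sensitivity checks.
#' @return `records` with columns `b`, `d`, `norm_ip`, `norm_input`,
#'   `es`, `p`, `fdr`, `positive` added (`NA` statistics on excluded
#'   windows).
#' @export
score_windows <- function(records, fdr_threshold = 0.01,
                          log2es_threshold = 1, min_frac = 1 / 20,
                          fisher_table = c("totals", "medians")) {
  fisher_table <- match.arg(fisher_table)
  if (is.null(records$retained))
    records <- filter_low_windows(records, min_frac)
  records <- normalize_by_gene_median(records)
  records$es <- NA_real_
  records$p <- NA_real_
  ret <- which(records$retained)
  if (length(ret)) {
    records$es[ret] <- enrichment_score(records$a[ret], records$b[ret],
                                        records$c[ret], records$d[ret])
    if (fisher_table == "totals") {
      Atot <- stats::ave(records$a * records$retained, records$gene_id,
                         FUN = sum)
      Ctot <- stats::ave(records$c * records$retained, records$gene_id,
                         FUN = sum)
      records$p[ret] <- fisher_window_test(records$a[ret], Atot[ret],
                                           records$c[ret], Ctot[ret])
    } else {
      rb <- round(records$b[ret]); rd <- round(records$d[ret])
      records$p[ret] <- fisher_window_test(records$a[ret],
                                           records$a[ret] + rb,
                                           records$c[ret],
                                           records$c[ret] + rd)
    }
  }
  records$fdr <- NA_real_
  records$fdr[ret] <- adjust_fdr(records$p[ret])
  records$positive <- records$retained & !is.na(records$fdr) &
    records$fdr < fdr_threshold & log2(records$es) >= log2es_threshold
  records
}
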