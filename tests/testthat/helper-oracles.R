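# Independent oracles used across tests. These deliberately avoid the
# code paths of the implementations they check.

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from binomial coefficients
oracle_fisher_p <- function(a, A, c, C) {
  n <- A + C
  if (n == 0) return(1)
  k <- a + c
  sup <- max(0, k - C):min(k, A)
  pr <- exp(lchoose(A, sup) + lchoose(C, k - sup) - lchoose(n, k))
  obs <- pr[sup == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# grouped variant for exhaustive sweeps: takes vectors of margin sets
# (A_i, C_i, k_i), enumerates every support value of each, and returns the
# two-sided p for all of them as total group mass minus the mass of
# strictly more probable tables (descending enumeration, binomial
# coefficients via lchoose -- independent of the dhyper/ascending-cumsum
# route of the implementation)
oracle_fisher_chunk <- function(A, C, k) {
  lo <- pmax(0, k - C)
  len <- pmin(k, A) - lo + 1
  g <- rep(seq_along(len), len)
  a <- sequence(len) + rep(lo, len) - 1
  pr <- exp(lchoose(A[g], a) + lchoose(C[g], k[g] - a) -
              lchoose(A[g] + C[g], k[g]))
  m <- length(pr)
  od <- order(g, -pr)
  prd <- pr[od]
  gd <- g[od]
  cs <- cumsum(prd)
  gstart <- c(TRUE, gd[-1] != gd[-m])
  gidx <- cumsum(gstart)
  before <- cs - prd                       # mass preceding each element
  heavier <- before - before[gstart][gidx] # ... within its own group
  gend <- c(gd[-1] != gd[-m], TRUE)
  tot <- (cs[gend] - before[gstart])[gidx] # total group mass
  newc <- c(TRUE, gd[-1] != gd[-m] | prd[-1] < prd[-m] * (1 - 1e-7))
  cls <- cumsum(newc)
  pd <- tot - heavier[newc][cls]           # ties share their class tail
  p <- numeric(m)
  p[od] <- pd
  list(g = g, a = a, p = pmin(p, 1))
}

# Benjamini-Hochberg straight from the definition:
# sort ascending, q_i = p_(i) * m / i, cumulative minimum from the top
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# genome<->isoform projection by brute force: enumerate exonic genome
# positions in transcript order and look positions up
oracle_exonic_positions <- function(model) {
  pos <- unlist(Map(function(s, e) seq(s, e - 1), model$exon_start,
                    model$exon_end))
  if (model$strand == "-") pos <- rev(pos)
  pos
}

oracle_project <- function(p, model) {
  i <- match(p, oracle_exonic_positions(model))
  if (is.na(i)) NA_real_ else i - 1
}

# random multi-exon gene model
random_model <- function(id, n_exons_max = 10, coding = TRUE) {
  k <- sample(1:n_exons_max, 1)
  w <- sample(20:300, k, replace = TRUE)
  gaps <- if (k > 1) sample(50:500, k - 1, replace = TRUE) else integer(0)
  start0 <- sample(0:10000, 1)
  ex_start <- start0 + cumsum(c(0, w[-k] + gaps))
  L <- sum(w)
  cs <- if (coding && L >= 10) round(0.1 * L) else NA
  ce <- if (coding && L >= 10) round(0.7 * L) else NA
  gene_model(paste0("G", id), paste0("T", id), "chr1",
             sample(c("+", "-"), 1), ex_start, ex_start + w, cs, ce)
}

# brute-force four-set intersection with cutoffs applied independently
oracle_triage <- function(tables, lfc = 0.5, p_cut = 0.05) {
  pass <- function(tb) {
    lb <- attr(tb, "label")
    if (lb == "unique_m6a") return(tb$gene_key)
    keep <- abs(tb$effect) > lfc
    if (lb != "rnaseq_ast_vs_control") keep <- keep & tb$p < p_cut
    tb$gene_key[keep]
  }
  sets <- lapply(tables, pass)
  in_all <- Reduce(intersect, sets)
  dir_of <- function(tb, g) sign(tb$effect[match(g, tb$gene_key)])
  expr <- tables[vapply(tables, function(t) attr(t, "label") != "unique_m6a",
                        TRUE)]
  dirs <- vapply(expr, dir_of, numeric(length(in_all)), g = in_all)
  dirs <- matrix(dirs, nrow = length(in_all))
  same <- apply(dirs, 1, function(d) length(unique(d)) == 1)
  list(down = sort(in_all[same & dirs[, 1] == -1]),
       up = sort(in_all[same & dirs[, 1] == 1]),
       discordant = sort(in_all[!same]))
}

# small deterministic two-exon model used in several files
two_exon_model <- function(strand = "+")
  gene_model("Gx", "Tx", "chr1", strand, c(0, 200), c(100, 300))
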