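#' Evidence-table labels used by the four-dataset triage
#' @export
TRIAGE_LABELS <- c("unique_m6a", "rnaseq_ast_vs_control",
                   "rnaseq_mouse_cuSCC", "rnaseq_human_cuSCC")

#' Construct an evidence table
#'
#' One of the four evidence sets intersected during target triage:
#' a condition-unique methylation gene list (`unique_m6a`, no effect or
#' p-value), the cell-line expression contrast (`rnaseq_ast_vs_control`,
#' log2 TPM difference, no p-value rule), or one of the two tumor
#' expression contrasts (`rnaseq_mouse_cuSCC`, `rnaseq_human_cuSCC`,
#' log2 fold change plus the source's adjusted p-value, which is consumed
#' as-is and never re-adjusted here). Gene symbols are matched
#' case-insensitively after whitespace stripping; cross-species symbol
#' harmonization is the caller's responsibility.
#'
#' @param genes Character vector of gene symbols, or a `data.frame` with
#'   columns `gene`, `effect` and (where required) `p`.
#' @param label One of [TRIAGE_LABELS].
#' @param effect,p Optional vectors when `genes` is a character vector.
#' @return `data.frame` of class `"evidence_table"` with attribute
#'   `label`; columns `gene`, `gene_key` (canonical symbol), and for
#'   expression tables `effect` (+ `p`).
#' @export
evidence_table <- function(genes, label, effect = NULL, p = NULL) {
  if (!label %in% TRIAGE_LABELS)
    stop("unknown evidence label '", label, "'; expected one of: ",
         paste(TRIAGE_LABELS, collapse = ", "))
  if (is.data.frame(genes)) {
    df <- genes
    if (!"gene" %in% names(df)) stop("evidence table needs a 'gene' column")
  } else {
    df <- data.frame(gene = as.character(genes))
    if (!is.null(effect)) df$effect <- effect
    if (!is.null(p)) df$p <- p
  }
  df$gene_key <- toupper(trimws(df$gene))
  dup <- df$gene_key[duplicated(df$gene_key)]
  if (length(dup))
    stop("duplicate gene id(s) in ", label, " table: ",
         paste(unique(dup), collapse = ", "))
  if (label != "unique_m6a") {
    if (!"effect" %in% names(df))
      stop(label, " table needs an 'effect' column")
    if (any(!is.finite(df$effect)))
      stop(label, " table has non-finite effects")
  }
  structure(df, class = c("evidence_table", "data.frame"), label = label)
}

#' Read an evidence table from TSV
#'
#' Expects a header; `unique_m6a` tables need a `gene` column only, the
#' expression tables need `gene` and `effect` (and `p` for the cuSCC
#' contrasts).
#'
#' @param path TSV path.
#' @param label One of [TRIAGE_LABELS].
#' @return An [evidence_table()].
#' @export
read_evidence_table <- function(path, label) {
  if (!file.exists(path)) stop("evidence table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  evidence_table(df, label)
}

#' Apply the published cutoffs to one evidence table
#'
#' Tumor contrasts (mouse/human cuSCC) pass genes with `p < 0.05` in
#' combination with `|log2 fold change| > 0.5`; the cell-line contrast
#' passes `|log2 TPM difference| > 0.5` with no p-value rule; the
#' condition-unique methylation list passes as given. All inequalities
#' are strict, so boundary genes (effect exactly 0.5) are excluded.
#'
#' @param table An [evidence_table()].
#' @param lfc_cutoff Absolute effect cutoff (default 0.5).
#' @param p_cutoff p-value cutoff for the cuSCC tables (default 0.05).
#' @return `data.frame` with `gene`, `gene_key` and `direction`
#'   (+1 up, -1 down, 0 for the direction-free methylation list).
#' @export
apply_cutoffs <- function(table, lfc_cutoff = 0.5, p_cutoff = 0.05) {
  label <- attr(table, "label")
  if (is.null(label)) stop("not an evidence_table (missing label)")
  if (label == "unique_m6a") {
    keep <- rep(TRUE, nrow(table))
    dir <- rep(0L, nrow(table))
  } else {
    dir <- as.integer(sign(table$effect))
    keep <- abs(table$effect) > lfc_cutoff
    if (label %in% c("rnaseq_mouse_cuSCC", "rnaseq_human_cuSCC")) {
      if (!"p" %in% names(table))
        stop(label, " table needs a 'p' column for the p < ", p_cutoff,
             " rule")
      keep <- keep & table$p < p_cutoff
    }
  }
  data.frame(gene = table$gene[keep], gene_key = table$gene_key[keep],
             direction = dir[keep])
}

#' Four-dataset target triage
#'
#' Intersects the four evidence sets after applying their cutoffs. A gene
#' is called `shared_down` / `shared_up` when it is a member of all four
#' sets and the three expression directions agree; members of all four
#' with discordant directions are reported as `discordant`. The result is
#' invariant under table input order, and the full 4-set overlap (all 15
#' Venn regions) is tabulated.
#'
#' @param tables List of the four [evidence_table()]s (any order; labels
#'   must be distinct and cover [TRIAGE_LABELS]).
#' @param lfc_cutoff,p_cutoff Cutoffs forwarded to [apply_cutoffs()].
#' @return Object of class `"triage_result"`: `genes` (per-gene
#'   membership flags, directions and `call`), `venn` (named counts of
#'   the 15 non-empty membership patterns), and the shared gene vectors
#'   `shared_down`, `shared_up`, `discordant`.
#' @export
triage <- function(tables, lfc_cutoff = 0.5, p_cutoff = 0.05) {
  if (length(tables) != 4L)
    stop("triage needs exactly four evidence tables, got ", length(tables))
  labels <- vapply(tables, function(t) attr(t, "label") %||% NA_character_, "")
  if (anyNA(labels)) stop("all inputs must be evidence_table objects")
  if (anyDuplicated(labels))
    stop("duplicate evidence label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (!setequal(labels, TRIAGE_LABELS))
    stop("labels must cover: ", paste(TRIAGE_LABELS, collapse = ", "))
  names(tables) <- labels
  passed <- lapply(tables[TRIAGE_LABELS], apply_cutoffs,
                   lfc_cutoff = lfc_cutoff, p_cutoff = p_cutoff)
  all_keys <- sort(unique(unlist(lapply(passed, `[[`, "gene_key"))))
  member <- vapply(passed, function(p) all_keys %in% p$gene_key,
                   logical(length(all_keys)))
  member <- matrix(member, nrow = length(all_keys),
                   dimnames = list(all_keys, TRIAGE_LABELS))
  dirs <- vapply(TRIAGE_LABELS[-1], function(lb) {
    d <- rep(NA_integer_, length(all_keys))
    d[match(passed[[lb]]$gene_key, all_keys)] <- passed[[lb]]$direction
    d
  }, integer(length(all_keys)))
  dirs <- matrix(dirs, nrow = length(all_keys),
                 dimnames = list(NULL, TRIAGE_LABELS[-1]))
  in_all <- rowSums(member) == 4L
  concord <- in_all & !is.na(dirs[, 1]) & !is.na(dirs[, 2]) &
    !is.na(dirs[, 3]) & dirs[, 1] == dirs[, 2] & dirs[, 2] == dirs[, 3]
  call <- rep("none", length(all_keys))
  call[in_all] <- "discordant"
  call[concord & dirs[, 1] == 1L] <- "shared_up"
  call[concord & dirs[, 1] == -1L] <- "shared_down"
  genes <- data.frame(gene = all_keys,
                      in_unique_m6a = member[, 1], in_ast = member[, 2],
                      in_mouse = member[, 3], in_human = member[, 4],
                      dir_ast = dirs[, 1], dir_mouse = dirs[, 2],
                      dir_human = dirs[, 3], call = call,
                      row.names = NULL)
  pattern <- apply(member, 1L, function(m)
    paste(ifelse(m, c("M", "A", "Ms", "H"), ""), collapse = ""))
  venn <- table(factor(pattern))
  structure(list(genes = genes,
                 venn = stats::setNames(as.integer(venn), names(venn)),
                 shared_down = genes$gene[genes$call == "shared_down"],
                 shared_up = genes$gene[genes$call == "shared_up"],
                 discordant = genes$gene[genes$call == "discordant"],
                 cutoffs = list(lfc = lfc_cutoff, p = p_cutoff)),
            class = "triage_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.triage_result <- function(x, ...) {
  n4 <- sum(x$genes$in_unique_m6a & x$genes$in_ast & x$genes$in_mouse &
              x$genes$in_human)
  cat(sprintf("<triage_result> %d genes in all four sets: %d shared down, %d shared up, %d discordant\n",
              n4, length(x$shared_down), length(x$shared_up),
              length(x$discordant)))
  if (length(x$shared_down))
    cat("  down:", paste(x$shared_down, collapse = ", "), "\n")
  if (length(x$shared_up))
    cat("  up:  ", paste(x$shared_up, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.triage_result <- function(object, ...) {
  print(object)
  cat("  Venn regions (M = unique m6A, A = As-T/control, Ms = mouse cuSCC, H = human cuSCC):\n")
  v <- object$venn
  for (nm in names(v)) cat(sprintf("    %-5s %d\n", nm, v[[nm]]))
  invisible(object)
}
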