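#' Confusion counts over unordered gene pairs
#'
#' Both networks are undirected, so the universe is the N(N-1)/2 unordered
#' pairs: TP = predicted and true, FP = predicted only, FN = true only,
#' TN = the remainder. Counts always partition the pair universe.
#'
#' @param pred,gold [grn_network()] objects over the same ordered panel.
#' @return List of class `grn_confusion`: `tp`, `fp`, `tn`, `fn`,
#'   `n_genes`.
#' @export
confusion <- function(pred, gold) {
  if (!identical(pred$gene_ids, gold$gene_ids)) {
    diff <- union(setdiff(pred$gene_ids, gold$gene_ids),
                  setdiff(gold$gene_ids, pred$gene_ids))
    stop("gene panels differ (symmetric difference: ",
         paste(diff, collapse = ", "), ")")
  }
  n <- length(pred$gene_ids)
  key <- function(e) if (nrow(e)) paste(e[, 1L], e[, 2L]) else character(0)
  p <- key(pred$edges)
  g <- key(gold$edges)
  tp <- length(intersect(p, g))
  fp <- length(setdiff(p, g))
  fn <- length(setdiff(g, p))
  total <- (n * (n - 1L)) %/% 2L
  structure(list(tp = tp, fp = fp, fn = fn,
                 tn = as.integer(total - tp - fp - fn), n_genes = n),
            class = "grn_confusion")
}

#' Confusion counts from printed totals
#'
#' Builds the count object directly from a benchmark table row: the true
#' positives and false positives a method reported, plus the gold-standard
#' edge count and panel size. `FN = gold_edges - TP`;
#' `TN = C(N,2) - gold_edges - FP`.
#'
#' @param tp,fp Reported counts.
#' @param gold_edges Number of edges in the gold standard.
#' @param n_genes Panel size.
#' @return A `grn_confusion`.
#' @export
confusion_from_counts <- function(tp, fp, gold_edges, n_genes) {
  total <- (n_genes * (n_genes - 1)) %/% 2
  fn <- gold_edges - tp
  tn <- total - gold_edges - fp
  stopifnot(fn >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n_genes = as.integer(n_genes)),
            class = "grn_confusion")
}

#' @export
print.grn_confusion <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d (%d genes, %d pairs)\n",
              x$tp, x$fp, x$tn, x$fn, x$n_genes,
              x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

# round-half-up at k decimals (base round() is banker's rounding)
round_half_up <- function(x, k = 3L) floor(x * 10^k + 0.5) / 10^k

#' Standard benchmark metrics from confusion counts
#'
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), PPV = TP/(TP+FP),
#' ACC = (TP+TN)/total. A zero denominator gives 0 (never NaN) and sets
#' the `undefined` flag for that metric.
#'
#' @param counts A `grn_confusion`.
#' @return List of class `grn_metrics`: `tpr`, `fpr`, `ppv`, `acc` at full
#'   precision, `rounded` (3 decimals, half-up), `undefined` (character
#'   vector of metrics with zero denominator), `counts`.
#' @export
network_metrics <- function(counts) {
  stopifnot(inherits(counts, "grn_confusion"))
  safe <- function(num, den) if (den == 0) 0 else num / den
  undef <- character(0)
  if (counts$tp + counts$fn == 0) undef <- c(undef, "tpr")
  if (counts$fp + counts$tn == 0) undef <- c(undef, "fpr")
  if (counts$tp + counts$fp == 0) undef <- c(undef, "ppv")
  tot <- counts$tp + counts$fp + counts$tn + counts$fn
  if (tot == 0) undef <- c(undef, "acc")
  out <- list(
    tpr = safe(counts$tp, counts$tp + counts$fn),
    fpr = safe(counts$fp, counts$fp + counts$tn),
    ppv = safe(counts$tp, counts$tp + counts$fp),
    acc = safe(counts$tp + counts$tn, tot))
  out$rounded <- lapply(out, round_half_up)
  out$undefined <- undef
  out$counts <- counts
  class(out) <- "grn_metrics"
  out
}

#' @export
print.grn_metrics <- function(x, ...) {
  cat(sprintf("TPR %.3f  FPR %.3f  PPV %.3f  ACC %.3f\n",
              x$rounded$tpr, x$rounded$fpr, x$rounded$ppv, x$rounded$acc))
  print(x$counts)
  invisible(x)
}
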