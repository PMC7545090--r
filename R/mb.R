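#' Genes with no edge in an inferred network
#'
#' @param net A [grn_network()].
#' @return Integer vector of degree-0 gene indices, ascending.
#' @export
find_isolated <- function(net) unname(which(degrees(net) == 0L))

#' Parent-child set of a target gene by conditional-independence search
#'
#' Backward elimination in the IPC-MB style, restricted to the
#' parent-child (PC) set: start from all other genes as candidates; for
#' conditioning-set sizes s = 0, 1, ..., `max_cond`, remove any candidate
#' X for which some size-s subset S of the remaining candidates (excluding
#' X) makes `estimate_cmi(target, X | S) < ci_eps`, recording S as the
#' separating set. Scan order is deterministic: candidates ascending,
#' subsets in lexicographic order. Spouse discovery is deliberately
#' omitted — only direct neighbours are wanted.
#'
#' @param expr Genes x samples expression matrix.
#' @param target Target gene index.
#' @param ci_eps Conditional-independence threshold in nats (default 0.03).
#' @param max_cond Largest conditioning-set size tried (default 3).
#' @param opts [mi_options()] for the CMI estimator.
#' @return List of class `pc_result`: `target`, `pc` (ascending indices),
#'   `sepsets` (named list, names are removed gene indices).
#' @export
recognize_pc <- function(expr, target, ci_eps = 0.03, max_cond = 3L,
                         opts = mi_options()) {
  n <- nrow(expr)
  stopifnot(n >= 2L, target >= 1L, target <= n)
  candidates <- setdiff(seq_len(n), target)
  sepsets <- list()
  for (s in 0:max_cond) {
    if (length(candidates) - 1L < s) break
    repeat {
      removed <- FALSE
      for (x in candidates) {
        pool <- setdiff(candidates, x)
        # combn over positions: combn(x, s) with scalar x would expand to
        # seq_len(x) and condition on the candidate itself
        subsets <- if (s == 0L) list(integer(0))
                   else if (length(pool) < s) list()
                   else lapply(utils::combn(seq_along(pool), s,
                                            simplify = FALSE),
                               function(ix) pool[ix])
        for (S in subsets) {
          if (estimate_cmi(expr, target, x, S, opts) < ci_eps) {
            candidates <- setdiff(candidates, x)
            sepsets[[as.character(x)]] <- S
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
      if (!removed) break
    }
  }
  structure(list(target = target, pc = candidates, sepsets = sepsets),
            class = "pc_result")
}

#' Reconnect isolated genes via their parent-child sets
#'
#' Every degree-0 gene is linked to each member of its PC set discovered
#' from the expression data. A gene whose PC comes back empty gets one
#' fallback edge to its strongest-MI partner, so the repaired network has
#' no isolated gene. Existing edges are never removed.
#'
#' @param net A [grn_network()].
#' @param expr Genes x samples expression matrix.
#' @param ci_eps,max_cond,opts Passed to [recognize_pc()].
#' @param mi Optional precomputed MI matrix (for the fallback edge); if
#'   missing it is computed from `expr`.
#' @param symmetric If `TRUE`, keep only PC members whose own PC contains
#'   the target (AND correction); default `FALSE`.
#' @return The repaired [grn_network()].
#' @export
repair_network <- function(net, expr, ci_eps = 0.03, max_cond = 3L,
                           opts = mi_options(), mi = NULL,
                           symmetric = FALSE) {
  iso <- find_isolated(net)
  if (!length(iso)) return(net)
  if (is.null(mi)) mi <- estimate_mi_matrix(expr, opts)
  new_edges <- net$edges
  for (g in iso) {
    pc <- recognize_pc(expr, g, ci_eps, max_cond, opts)$pc
    if (symmetric && length(pc)) {
      pc <- Filter(function(x)
        g %in% recognize_pc(expr, x, ci_eps, max_cond, opts)$pc, pc)
    }
    if (!length(pc)) {
      partner <- which.max(replace(mi[g, ], g, -Inf))
      message(sprintf("gene %d: empty PC set, fallback edge to top-MI partner %d",
                      g, partner))
      pc <- partner
    }
    new_edges <- rbind(new_edges, cbind(g, pc))
  }
  grn_network(net$gene_ids, new_edges, votes = net$votes)
}
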