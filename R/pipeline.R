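#' Pipeline configuration
#'
#' Collects every tunable of the inference pipeline with its default.
#' Configs serialise to and from plain-text DCF files
#' ([write_config()] / [read_config()]); unknown keys are rejected.
#'
#' @param mi_method MI estimator, `"gaussian"` or `"histogram"`.
#' @param bins Histogram bin count.
#' @param alpha_min,alpha_max Restart-probability clamp bounds.
#' @param alpha_override If set, skip the commute-time derivation and use
#'   this restart probability directly.
#' @param log_base Base of the log sizing functional modules.
#' @param module_size If set, overrides the `ceiling(log(N))` module size.
#' @param tol,max_iter RWR convergence controls.
#' @param threshold_coef Coefficient on alpha in the adaptive threshold
#'   (default 0.75, i.e. 3/4).
#' @param symmetrize `"or"` or `"and"` vote symmetrisation.
#' @param ci_eps,max_cond Conditional-independence controls of the repair
#'   stage.
#' @param repair Run the isolated-gene repair stage (default TRUE).
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters for synthetic data generation).
#' @param verbose Emit per-stage messages.
#' @return List of class `rwrnet_config`.
#' @export
rwrnet_config <- function(mi_method = "gaussian", bins = 8L,
                          alpha_min = 0.01, alpha_max = 0.99,
                          alpha_override = NA_real_,
                          log_base = exp(1), module_size = NA_integer_,
                          tol = 1e-6, max_iter = 10000L,
                          threshold_coef = 0.75,
                          symmetrize = "or",
                          ci_eps = 0.03, max_cond = 3L,
                          repair = TRUE, seed = 1L, verbose = FALSE) {
  cfg <- list(mi_method = mi_method, bins = as.integer(bins),
              alpha_min = alpha_min, alpha_max = alpha_max,
              alpha_override = alpha_override,
              log_base = log_base,
              module_size = suppressWarnings(as.integer(module_size)),
              tol = tol, max_iter = as.integer(max_iter),
              threshold_coef = threshold_coef,
              symmetrize = match.arg(symmetrize, c("or", "and")),
              ci_eps = ci_eps, max_cond = as.integer(max_cond),
              repair = isTRUE(as.logical(repair)),
              seed = as.integer(seed),
              verbose = isTRUE(as.logical(verbose)))
  stopifnot(cfg$mi_method %in% c("gaussian", "histogram"),
            cfg$threshold_coef >= 0, cfg$tol > 0)
  class(cfg) <- "rwrnet_config"
  cfg
}

#' Write a configuration to a plain-text DCF file
#' @param cfg An [rwrnet_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  flat <- lapply(unclass(cfg), function(v)
    format(v, digits = 17, scientific = FALSE))
  write.dcf(as.data.frame(flat, stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Read a configuration from a DCF file
#'
#' Keys absent from the file keep their defaults; unknown keys are an
#' error.
#' @param path DCF file written by [write_config()] or by hand.
#' @return An [rwrnet_config()].
#' @export
read_config <- function(path) {
  raw <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  known <- names(formals(rwrnet_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  defaults <- formals(rwrnet_config)
  for (k in names(raw)) {
    proto <- eval(defaults[[k]])
    raw[[k]] <- if (is.character(proto)) as.character(raw[[k]])
                else if (is.logical(proto)) as.logical(raw[[k]])
                else if (identical(raw[[k]], "NA")) NA_real_
                else as.numeric(raw[[k]])
  }
  do.call(rwrnet_config, raw)
}

#' Infer a gene regulatory network from an expression matrix
#'
#' Runs the full pipeline in fixed stage order: pairwise MI; restart
#' probability from commute times; roaming network; expression levels,
#' centres and functional modules; per-gene seeded random walks; walk
#' scores and per-gene adaptive thresholds; undirected network assembly;
#' and finally reconnection of isolated genes through their parent-child
#' sets. Deterministic: identical input and config give identical output.
#'
#' @param expr Genes x samples numeric matrix with gene-id row names.
#' @param config An [rwrnet_config()].
#' @return List of class `rwrnet_fit`: `network` (after repair, or the
#'   thresholded network when repair is off), `network_raw` (before
#'   repair), `scores` (`rwr_scores`), `kernel` (`commute_kernel`), `mi`,
#'   `roaming`, `centres`, `modules`, and `log` (named list of per-stage
#'   summaries).
#' @examples
#' fx <- make_fixture("chain4")
#' fit <- rwrnet_infer(fx$expr)
#' fit$network
#' @export
rwrnet_infer <- function(expr, config = rwrnet_config()) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2L, ncol(expr) >= 2L)
  ids <- rownames(expr)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(expr)))
  rownames(expr) <- ids
  n <- nrow(expr)
  note <- function(...) if (config$verbose) message(sprintf(...))
  opts <- mi_options(config$mi_method, config$bins)
  log <- list(n_genes = n, n_samples = ncol(expr))

  mi <- estimate_mi_matrix(expr, opts)
  note("stage 1: MI matrix (%d genes)", n)

  if (is.finite(config$alpha_override) && !is.na(config$alpha_override)) {
    kernel <- list(alpha = config$alpha_override,
                   alpha_raw = config$alpha_override)
    class(kernel) <- "commute_kernel"
  } else {
    kernel <- commute_kernel(mi, config$alpha_min, config$alpha_max)
  }
  log$alpha_raw <- kernel$alpha_raw
  log$alpha <- kernel$alpha
  note("stage 2: restart probability alpha = %.4f (raw %.4f)",
       kernel$alpha, kernel$alpha_raw)

  roam <- build_roaming(mi)
  note("stage 3: roaming network")

  el <- expression_levels(mi)
  centres <- select_centres(el)
  module_size <- if (is.na(config$module_size)) NULL else config$module_size
  modules <- build_modules(mi, centres, module_size, config$log_base)
  log$n_centres <- length(centres)
  log$module_size <- if (length(centres)) length(modules[[centres[1L]]])
                     else 0L
  note("stage 4-5: %d module centres, module size %d",
       log$n_centres, log$module_size)

  scores <- rwr_scores(roam, kernel, centres, modules,
                       tol = config$tol, max_iter = config$max_iter,
                       threshold_coef = config$threshold_coef)
  log$iterations <- scores$iterations
  note("stage 6: RWR per gene (median %d iterations)",
       stats::median(scores$iterations))

  net_raw <- assemble_network(scores$mip, scores$thresholds, ids,
                              mode = config$symmetrize)
  log$edges_before_repair <- n_edges(net_raw)
  note("stage 7: thresholded network, %d edges", n_edges(net_raw))

  if (config$repair) {
    net <- repair_network(net_raw, expr, config$ci_eps, config$max_cond,
                          opts, mi = mi)
  } else {
    net <- net_raw
  }
  log$edges_after_repair <- n_edges(net)
  log$isolated_after <- length(find_isolated(net))
  note("stage 8: repair %s, %d edges final",
       if (config$repair) "on" else "off", n_edges(net))

  structure(list(network = net, network_raw = net_raw, scores = scores,
                 kernel = kernel, mi = mi, roaming = roam,
                 centres = centres, modules = modules, log = log,
                 config = config),
            class = "rwrnet_fit")
}

#' @export
print.rwrnet_fit <- function(x, ...) {
  cat(sprintf(paste0("rwrnet fit: %d genes, alpha %.4f, %d centres, ",
                     "%d edges (%d before repair)\n"),
              x$log$n_genes, x$log$alpha, x$log$n_centres,
              n_edges(x$network), x$log$edges_before_repair))
  invisible(x)
}
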