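#' Estimator options for (conditional) mutual information
#'
#' @param method `"gaussian"` (default) computes MI as `-1/2 * ln(1 - r^2)`
#'   from the sample Pearson correlation `r`, the estimator that is exact
#'   for bivariate normal data; `"histogram"` is the plug-in estimate of
#'   the discrete MI sum on equal-width bins, for data that is clearly
#'   non-Gaussian.
#' @param bins Number of equal-width bins per variable (histogram only).
#' @param correlation_clamp Correlations are clamped to this magnitude
#'   before the log, so duplicated genes give a large finite MI rather
#'   than infinity.
#' @return A list of class `mi_options`.
#' @export
mi_options <- function(method = c("gaussian", "histogram"), bins = 8L,
                       correlation_clamp = 0.99999) {
  method <- match.arg(method)
  stopifnot(bins >= 2L, correlation_clamp > 0, correlation_clamp < 1)
  structure(list(method = method, bins = as.integer(bins),
                 correlation_clamp = correlation_clamp),
            class = "mi_options")
}

# Gaussian MI from a correlation value, with clamping.
.mi_from_r <- function(r, clamp) {
  r <- pmin(pmax(r, -clamp), clamp)
  -0.5 * log(1 - r^2)
}

# equal-width binning of one numeric vector
.bin_equal_width <- function(x, bins) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep.int(1L, length(x)))
  b <- floor((x - rng[1L]) / (rng[2L] - rng[1L]) * bins) + 1L
  pmin(b, bins)
}

# plug-in discrete MI of two integer-binned vectors, in nats
.mi_histogram <- function(bx, by) {
  n <- length(bx)
  joint <- table(bx, by) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  expd <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / expd[nz]))
}

#' Pairwise mutual information matrix
#'
#' Estimates MI between every pair of genes in an expression matrix. The
#' result is symmetric, non-negative, in nats, with a zero diagonal
#' (self-information is never used downstream). Constant genes (zero
#' variance) get MI 0 against every partner, with a warning.
#'
#' @param expr Numeric matrix, genes x samples (e.g. [read_expression()]).
#' @param opts An [mi_options()] bundle.
#' @return Symmetric N x N numeric matrix with the gene ids as dimnames.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), nrow = 4, dimnames = list(paste0("G", 1:4), NULL))
#' estimate_mi_matrix(x)
#' @export
estimate_mi_matrix <- function(expr, opts = mi_options()) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  n <- nrow(expr)
  m <- ncol(expr)
  ids <- rownames(expr)
  if (is.null(ids)) ids <- paste0("g", seq_len(n))
  sds <- apply(expr, 1L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const))
    warning("constant gene(s) set to MI 0: ",
            paste(ids[const], collapse = ", "))
  if (opts$method == "gaussian") {
    if (m < 3L) stop("gaussian MI needs at least 3 samples")
    ok <- !const
    r <- matrix(0, n, n)
    if (sum(ok) >= 2L)
      r[ok, ok] <- stats::cor(t(expr[ok, , drop = FALSE]))
    mi <- .mi_from_r(r, opts$correlation_clamp)
  } else {
    binned <- t(apply(expr, 1L, .bin_equal_width, bins = opts$bins))
    mi <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (const[i] || const[j]) next
        mi[i, j] <- mi[j, i] <- .mi_histogram(binned[i, ], binned[j, ])
      }
    }
  }
  mi[const, ] <- 0
  mi[, const] <- 0
  diag(mi) <- 0
  mi[mi < 0] <- 0
  dimnames(mi) <- list(ids, ids)
  mi
}

#' Conditional mutual information between two genes
#'
#' For the Gaussian method, CMI(i, j | S) = `-1/2 * ln(1 - rho^2)` with
#' `rho` the sample partial correlation of genes `i` and `j` given the
#' conditioning set, obtained by inverting the correlation submatrix. An
#' empty conditioning set reduces exactly to the pairwise MI. A singular
#' conditioning matrix is ridge-regularised (1e-6 on the diagonal) with a
#' warning. For the histogram method the plug-in discrete CMI is computed
#' on the jointly binned variables.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param i,j Gene indices, `i != j`.
#' @param cond Integer vector of conditioning gene indices (may be empty).
#'   If it contains `i` or `j` the CMI is 0 by convention.
#' @param opts An [mi_options()] bundle.
#' @return Non-negative scalar, nats.
#' @export
estimate_cmi <- function(expr, i, j, cond = integer(0), opts = mi_options()) {
  stopifnot(i != j)
  cond <- setdiff(as.integer(cond), c(NA_integer_))
  if (any(cond %in% c(i, j))) return(0)
  if (length(cond) == 0L) {
    mi <- estimate_mi_matrix(expr[c(i, j), , drop = FALSE], opts)
    return(mi[1L, 2L])
  }
  if (opts$method == "histogram") {
    bx <- .bin_equal_width(expr[i, ], opts$bins)
    by <- .bin_equal_width(expr[j, ], opts$bins)
    bz <- apply(expr[cond, , drop = FALSE], 1L, .bin_equal_width,
                bins = opts$bins)
    zkey <- interaction(as.data.frame(bz), drop = TRUE)
    val <- 0
    n <- length(bx)
    for (lev in levels(zkey)) {
      sel <- zkey == lev
      if (sum(sel) < 2L) next
      val <- val + sum(sel) / n * .mi_histogram(bx[sel], by[sel])
    }
    return(max(val, 0))
  }
  vars <- c(i, j, cond)
  sub <- expr[vars, , drop = FALSE]
  if (any(apply(sub, 1L, stats::sd) == 0)) return(0)
  cm <- stats::cor(t(sub))
  prec <- tryCatch(solve(cm), error = function(e) {
    warning("singular conditioning correlation matrix; ",
            "ridge-regularising (1e-6)")
    solve(cm + diag(1e-6, nrow(cm)))
  })
  rho <- -prec[1L, 2L] / sqrt(prec[1L, 1L] * prec[2L, 2L])
  .mi_from_r(rho, opts$correlation_clamp)
}
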