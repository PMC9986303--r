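#' Iteratively prune highly correlated variables
#'
#' While any variable pair correlates beyond the threshold in absolute
#' value, one member of the worst pair is removed: the one with the
#' larger mean absolute correlation to all other variables (ties broken
#' towards the later column).  The removal log records each decision.
#'
#' @param x data.frame or matrix, observations x variables
#' @param r_threshold absolute correlation above which a pair is pruned
#' @return list with `retained` (column names), `data` (pruned table) and
#'   `log` (data.frame of removed variables and the offending pairs)
#' @export
prune_correlated <- function(x, r_threshold = 0.85) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("need at least 2 variables")
  log <- NULL
  repeat {
    R <- stats::cor(x)
    diag(R) <- 0
    if (max(abs(R)) <= r_threshold) break
    idx <- which(abs(R) == max(abs(R)), arr.ind = TRUE)[1L, ]
    mean_abs <- rowMeans(abs(R)) * ncol(R) / (ncol(R) - 1L)
    pair <- sort(c(idx[["row"]], idx[["col"]]))
    drop_i <- if (mean_abs[pair[1L]] > mean_abs[pair[2L]]) pair[1L]
              else pair[2L]                       # tie -> later column
    log <- rbind(log, data.frame(
      removed = colnames(x)[drop_i],
      partner = colnames(x)[setdiff(pair, drop_i)],
      r = R[pair[1L], pair[2L]]))
    x <- x[, -drop_i, drop = FALSE]
    if (ncol(x) < 2L) break
  }
  list(retained = colnames(x), data = x, log = log)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Per-variable and overall KMO from the squared correlations and the
#' squared anti-image partial correlations.  An identity correlation
#' matrix has no common variance: both sums are zero and the 0/0 is
#' resolved to 0 by convention (with a warning).
#'
#' @param corr correlation matrix (positive definite)
#' @return list with `per_variable` (named) and `overall`
#' @export
kmo <- function(corr) {
  corr <- as.matrix(corr)
  p <- ncol(corr)
  inv <- tryCatch(solve(corr), error = function(e)
    stop("correlation matrix is singular; prune correlated variables first"))
  part <- -inv / sqrt(outer(diag(inv), diag(inv)))
  diag(part) <- 0
  r0 <- corr
  diag(r0) <- 0
  num <- colSums(r0^2)
  den <- num + colSums(part^2)
  per <- ifelse(den == 0, 0, num / den)
  if (any(den == 0))
    warning("no common variance for some variables; KMO set to 0")
  overall <- if (sum(den) == 0) 0 else sum(num) / sum(den)
  list(per_variable = stats::setNames(per, colnames(corr)), overall = overall)
}

#' Iterative KMO screening
#'
#' Repeatedly drops the variable with the lowest per-variable KMO while
#' any value falls below the cut-off, recomputing after each removal.
#'
#' @param x observations x variables table
#' @param min_kmo admission threshold (default 0.5)
#' @return list with `retained`, `data`, `log` and the final [kmo()]
#' @export
kmo_screen <- function(x, min_kmo = 0.5) {
  x <- as.data.frame(x)
  log <- NULL
  repeat {
    k <- kmo(stats::cor(x))
    if (all(k$per_variable >= min_kmo) || ncol(x) <= 2L) break
    worst <- which.min(k$per_variable)
    log <- rbind(log, data.frame(removed = colnames(x)[worst],
                                 kmo = unname(k$per_variable[worst])))
    x <- x[, -worst, drop = FALSE]
  }
  list(retained = colnames(x), data = x, log = log, kmo = k)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param corr correlation matrix
#' @param n number of observations behind it (complete cases)
#' @return list with `chi2`, `df`, `p_value`
#' @export
bartlett_sphericity <- function(corr, n) {
  corr <- as.matrix(corr)
  p <- ncol(corr)
  if (n <= p) stop("need more observations than variables")
  d <- det(corr)
  if (d <= 0) stop("non-positive determinant; matrix is not a valid correlation matrix")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Principal component analysis of the correlation matrix
#'
#' Eigendecomposition of the correlation matrix of complete observations.
#' Loadings are the unit-norm eigenvectors; component signs are arbitrary,
#' so PC1 is anchored to load positively on `sign_anchor` and the
#' remaining components are flipped so their largest-magnitude loading is
#' positive.  Components with eigenvalue > 1 are retained by default.
#'
#' @param x observations x variables table, no missing cells
#' @param sign_anchor variable whose PC1 loading is forced positive
#'   (default: first column)
#' @param retain_rule eigenvalue threshold for the retained-component
#'   count (default 1, the Kaiser rule)
#' @return object of class `ovigait_pca` with eigenvalues, percent and
#'   cumulative variance, loadings, `n_components`, and scree data
#' @export
pca_correlation <- function(x, sign_anchor = NULL, retain_rule = 1) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("need at least 2 variables")
  if (nrow(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x)) stop("missing cells are not allowed (no imputation)")
  R <- stats::cor(x)
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors
  rownames(L) <- colnames(x)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  if (is.null(sign_anchor)) sign_anchor <- colnames(x)[1L]
  if (!sign_anchor %in% colnames(x))
    stop("sign_anchor ", sign_anchor, " is not a variable of x")
  if (L[sign_anchor, 1L] < 0) L[, 1L] <- -L[, 1L]
  for (j in 2:ncol(L))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  ev <- e$values
  pct <- ev / ncol(x) * 100
  structure(list(
    eigenvalues = ev,
    pct_variance = pct,
    cumulative_pct = cumsum(pct),
    loadings = L,
    n_components = sum(ev > retain_rule),
    retain_rule = retain_rule,
    sign_anchor = sign_anchor,
    n_obs = nrow(x),
    variables = colnames(x)),
    class = "ovigait_pca")
}

#' @export
print.ovigait_pca <- function(x, digits = 3, ...) {
  cat(sprintf("Correlation PCA of %d variables, %d observations\n",
              length(x$variables), x$n_obs))
  cat(sprintf("  %d component(s) with eigenvalue > %g; cumulative variance %.1f%%\n",
              x$n_components, x$retain_rule,
              x$cumulative_pct[max(1L, x$n_components)]))
  cat("  eigenvalues:", paste(round(x$eigenvalues, digits), collapse = ", "),
      "\n  loadings (retained components):\n")
  print(round(x$loadings[, seq_len(max(1L, x$n_components)), drop = FALSE],
              digits))
  invisible(x)
}

#' Full PCA pipeline: correlation pruning, KMO screening, final PCA
#'
#' Applies [prune_correlated()], then iterative [kmo_screen()], then
#' [bartlett_sphericity()] and [pca_correlation()] on the surviving
#' variables, logging every exclusion.
#'
#' @inheritParams prune_correlated
#' @inheritParams kmo_screen
#' @inheritParams pca_correlation
#' @return list with `pca`, `kmo`, `bartlett`, `pruned`, `screened`
#' @export
pca_pipeline <- function(x, r_threshold = 0.85, min_kmo = 0.5,
                         sign_anchor = NULL) {
  pruned <- prune_correlated(x, r_threshold)
  screened <- kmo_screen(pruned$data, min_kmo)
  dat <- screened$data
  if (!is.null(sign_anchor) && !sign_anchor %in% colnames(dat))
    sign_anchor <- NULL
  list(pca = pca_correlation(dat, sign_anchor = sign_anchor),
       kmo = screened$kmo,
       bartlett = bartlett_sphericity(stats::cor(dat), nrow(dat)),
       pruned = pruned, screened = screened)
}

#' The post-stroke variable table used for the published PCA
#'
#' Twenty animals by eight variables: infarct volume, total neurological
#' score, two global gait measures and four forelimb measures at 3 days
#' post-stroke, shipped verbatim as packaged data.
#'
#' @return data.frame with an `animal` id column and eight numeric columns
#' @export
poststroke_pca_table <- function() {
  path <- system.file("extdata", "poststroke_pca_variables.csv",
                      package = "ovigait", mustWork = TRUE)
  utils::read.csv(path)
}
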