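## Cross-cell, cross-species analysis of accepted parameter ensembles:
## max-normalized heatmap matrix and PCA species separation.

#' Normalized parameter matrix for the degeneracy heatmap
#'
#' Rows are parameters normalized to their row maximum and sorted by
#' descending row mean; columns are individuals grouped by cell
#' (`<cell>:<rank>` column names retain provenance).
#'
#' @param ensembles_per_cell Named list (cell id -> matrix individuals x
#'   parameters, shared parameter names).
#' @return Matrix (parameters x individuals) with attribute `"row_means"`.
#' @export
build_parameter_matrix <- function(ensembles_per_cell) {
  stopifnot(length(ensembles_per_cell) >= 1)
  pnames <- colnames(ensembles_per_cell[[1]])
  cols <- list()
  for (cell in names(ensembles_per_cell)) {
    m <- ensembles_per_cell[[cell]]
    if (!identical(colnames(m), pnames))
      stop("all ensembles must share the parameter naming scheme")
    for (i in seq_len(nrow(m)))
      cols[[paste0(cell, ":", i)]] <- m[i, ]
  }
  M <- do.call(cbind, cols)
  rmax <- apply(M, 1, max)
  zero <- rmax == 0
  if (any(zero)) {
    warning("excluding all-zero parameter row(s): ",
            paste(pnames[zero], collapse = ", "))
    M <- M[!zero, , drop = FALSE]
    rmax <- rmax[!zero]
  }
  M <- M / rmax
  rmeans <- rowMeans(M)
  M <- M[order(rmeans, decreasing = TRUE), , drop = FALSE]
  attr(M, "row_means") <- sort(rmeans, decreasing = TRUE)
  M
}

#' Principal component analysis of pooled individuals
#'
#' PCA on the subset of parameters common to both species, after
#' per-parameter scaling across the pooled individuals.
#'
#' @param individuals Matrix (individuals x parameters), pooled over
#'   species.
#' @param subset Parameter names to analyze; default all columns.
#' @param scaling `"standardize"` (unit variance; default) or `"max"`
#'   (divide by the column maximum).
#' @return List: `eigenvalues` (component variances), `fractions`
#'   (variance fractions, summing to 1), `projections` (scores),
#'   `loadings` (orthonormal rotation).
#' @export
run_pca <- function(individuals, subset = NULL,
                    scaling = c("standardize", "max")) {
  scaling <- match.arg(scaling)
  if (nrow(individuals) < 2) stop("need at least 2 individuals")
  X <- individuals[, if (is.null(subset)) colnames(individuals) else subset,
                   drop = FALSE]
  constant <- apply(X, 2, function(x) var(x) == 0)
  if (any(constant)) {
    warning("dropping constant parameter(s): ",
            paste(colnames(X)[constant], collapse = ", "))
    X <- X[, !constant, drop = FALSE]
  }
  if (!ncol(X)) stop("no non-constant parameters left")
  if (scaling == "max") X <- sweep(X, 2, apply(abs(X), 2, max), "/")
  pc <- prcomp(X, center = TRUE, scale. = scaling == "standardize")
  ev <- pc$sdev^2
  list(eigenvalues = ev, fractions = ev / sum(ev),
       projections = pc$x, loadings = pc$rotation)
}

#' Species separation on one principal component
#'
#' Reports per-species projection ranges, the range-overlap fraction on the
#' chosen component, and the standardized mean difference. The `separated`
#' flag is TRUE when the ranges do not overlap at all.
#'
#' @param projections Score matrix from [run_pca()].
#' @param labels Species label per individual.
#' @param component Component index; default 1.
#' @return List: `ranges`, `overlap_fraction`, `smd`, `separated`.
#' @export
cluster_separation <- function(projections, labels, component = 1) {
  x <- projections[, component]
  gr <- split(x, labels)
  if (length(gr) != 2) stop("exactly two species labels required")
  r1 <- range(gr[[1]])
  r2 <- range(gr[[2]])
  ov <- min(r1[2], r2[2]) - max(r1[1], r2[1])
  shorter <- min(diff(r1), diff(r2))
  overlap_fraction <- if (ov <= 0) 0
    else if (shorter == 0) 1 else min(ov / shorter, 1)
  pooled_sd <- sqrt(((length(gr[[1]]) - 1) * var(gr[[1]]) +
                     (length(gr[[2]]) - 1) * var(gr[[2]])) /
                    (length(gr[[1]]) + length(gr[[2]]) - 2))
  smd <- abs(mean(gr[[1]]) - mean(gr[[2]])) /
    (if (pooled_sd > 0) pooled_sd else 1)
  list(ranges = stats::setNames(list(r1, r2), names(gr)),
       overlap_fraction = overlap_fraction, smd = smd,
       separated = ov <= 0)
}
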