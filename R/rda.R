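#' Redundancy analysis (constrained ordination) from first principles
#'
#' RDA of a multivariate response (here: per-species Gi* Z-scores over
#' grid cells) on environmental covariates: the response matrix is
#' regressed on the constraints, and the fitted values are subjected to a
#' PCA. Eigenvalues of the constrained axes, species scores, site scores
#' and covariate biplot scores are returned in the type-2 (correlation
#' biplot) scaling by default.
#'
#' @param Y cells x species numeric matrix (no missing values after the
#'   common-grid intersection).
#' @param X cells x covariates numeric matrix; must be full column rank.
#' @param standardize_y scale response columns to unit variance
#'   (default TRUE; Z-scores from different species are pooled
#'   differently).
#' @param scaling triplot scaling: 2 (correlation, default) or 1
#'   (distance).
#' @return object of class `rda_result`: `eigenvalues` (descending),
#'   `species_scores`, `site_scores`, `biplot_scores`,
#'   `prop_constrained`, `total_variance`.
#' @export
rda_fit <- function(Y, X, standardize_y = TRUE, scaling = 2) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same rows")
  if (anyNA(Y) || anyNA(X)) stop("missing values; intersect grids first")
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = standardize_y)
  Yc[is.nan(Yc)] <- 0
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    dep <- colnames(Xc)[qrX$pivot[(qrX$rank + 1):ncol(Xc)]]
    stop("X is rank deficient; dependent columns: ", paste(dep, collapse = ", "))
  }
  Yhat <- qr.fitted(qrX, Yc)
  S <- crossprod(Yhat) / (n - 1)
  eg <- eigen(S, symmetric = TRUE)
  rank <- min(qrX$rank, ncol(Yc))
  lambda <- pmax(eg$values[seq_len(rank)], 0)
  U <- eg$vectors[, seq_len(rank), drop = FALSE]
  rownames(U) <- colnames(Y)
  total <- sum(diag(crossprod(Yc) / (n - 1)))
  # site scores as linear combinations of X (the "lc" scores)
  F_ <- Yhat %*% U                       # raw site scores, var = lambda
  if (scaling == 2) {
    species <- U %*% diag(sqrt(lambda), rank)
    sites <- sweep(F_, 2, sqrt(pmax(lambda, 1e-300)), "/")
  } else {
    species <- U
    sites <- F_
  }
  biplot <- suppressWarnings(stats::cor(Xc, sites))
  biplot[is.na(biplot)] <- 0
  colnames(species) <- colnames(sites) <- colnames(biplot) <-
    paste0("RDA", seq_len(rank))
  structure(list(eigenvalues = lambda, species_scores = species,
                 site_scores = sites, biplot_scores = biplot,
                 prop_constrained = if (total > 0) sum(lambda) / total else 0,
                 total_variance = total, scaling = scaling),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("<rda_result> %d constrained axes; %.1f%% of variance constrained\n",
              length(x$eigenvalues), 100 * x$prop_constrained))
  ev <- x$eigenvalues
  cat("  eigenvalues:", paste(sprintf("%.4g", ev[seq_len(min(5, length(ev)))]),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Rank covariate loadings on an RDA axis
#'
#' @param result an `rda_result`.
#' @param axis constrained-axis index (error beyond the rank).
#' @return data.frame of covariates sorted by absolute biplot score on
#'   the axis, with the signed score.
#' @export
rda_axis_interpretation <- function(result, axis) {
  stopifnot(inherits(result, "rda_result"))
  if (axis < 1 || axis > length(result$eigenvalues))
    stop("axis index beyond the number of constrained axes")
  sc <- result$biplot_scores[, axis]
  out <- data.frame(covariate = rownames(result$biplot_scores), score = sc)
  out <- out[order(-abs(out$score)), ]
  rownames(out) <- NULL
  out
}
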