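## Desired-gain multi-trait selection index: trait weights b solve
## G b = d, where G is the covariance matrix of the (z-scored) traits and
## d the desired gain per trait in SD units.  Accessions are scored as the
## weighted sum of their z-scored trait values.

#' Specify a desired-gain selection index
#'
#' The published defaults target a one-SD gain in grain yield, half an SD
#' in spikelet fertility, and hold days to fifty per cent flowering fixed
#' (zero desired gain) to avoid inadvertent selection on phenology.
#'
#' @param traits Ordered character vector of trait names (>= 2).
#' @param d Numeric vector of desired gains in SD units, same length; at
#'   least one entry nonzero.
#' @param scaling Z-score the traits before computing G and scores
#'   (default `TRUE`; when `FALSE`, G is the raw covariance and `d` is in
#'   trait units).
#' @return Object of class `"index_spec"`.
#' @examples
#' index_spec()  # gy/sf/dff with d = (1, 0.5, 0)
#' @export
index_spec <- function(traits = c("gy", "sf", "dff"), d = c(1, 0.5, 0),
                       scaling = TRUE) {
  if (length(traits) != length(d))
    stop("traits and d must have equal length")
  if (length(traits) < 2L) stop("need at least 2 traits")
  if (all(d == 0)) stop("at least one desired gain must be nonzero")
  if (anyDuplicated(traits)) stop("duplicated trait names")
  structure(list(traits = traits, d = as.numeric(d),
                 scaling = isTRUE(scaling)),
            class = "index_spec")
}

#' Compute desired-gain index weights
#'
#' Z-scores the trait columns (when `spec$scaling`), forms the sample
#' covariance `G` of the scaled traits (the trait correlation matrix),
#' and solves `G b = d` by Cholesky factorization (no explicit inverse).
#' The residual `max |G b - d|` is verified below `1e-8`.
#'
#' @param values Matrix/data.frame of trait values, rows = genotypes
#'   (test accessions plus checks, typically multi-environment predicted
#'   values), columns including `spec$traits`.  Rows with any missing
#'   index trait are dropped for estimating G.
#' @param spec An [index_spec()].
#' @return Object of class `"index_weights"`: `b`, `G`, `d`, `residual`,
#'   `center`, `scale`, `spec`.
#' @export
compute_weights <- function(values, spec = index_spec()) {
  stopifnot(inherits(spec, "index_spec"))
  values <- as.data.frame(values)
  missing <- setdiff(spec$traits, names(values))
  if (length(missing))
    stop("trait(s) absent from values: ", paste(missing, collapse = ", "))
  M <- as.matrix(values[, spec$traits, drop = FALSE])
  M <- M[stats::complete.cases(M), , drop = FALSE]
  n <- nrow(M); k <- length(spec$traits)
  if (n < k + 1L)
    stop("need at least ", k + 1L, " complete genotypes, got ", n)

  center <- colMeans(M)
  scl <- apply(M, 2, stats::sd)
  if (any(scl == 0))
    stop("zero-variance trait(s): ",
         paste(spec$traits[scl == 0], collapse = ", "))
  if (spec$scaling) {
    Z <- sweep(sweep(M, 2, center), 2, scl, `/`)
  } else {
    Z <- sweep(M, 2, center)
    scl <- rep(1, k); names(scl) <- spec$traits
  }
  G <- stats::cov(Z)

  ## condition / collinearity diagnostics before solving
  kap <- kappa(G, exact = TRUE)
  if (!is.finite(kap) || kap > 1e10) {
    off <- abs(G / sqrt(tcrossprod(diag(G))))
    diag(off) <- 0
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop("covariance matrix is singular or ill-conditioned ",
         sprintf("(condition number %.3g); most collinear pair: %s ~ %s",
                 kap, spec$traits[worst[1]], spec$traits[worst[2]]))
  }
  R <- chol(G)
  b <- backsolve(R, backsolve(R, spec$d, transpose = TRUE))
  residual <- max(abs(G %*% b - spec$d))
  if (residual >= 1e-8)
    stop("solve residual too large: ", format(residual))
  structure(list(b = stats::setNames(drop(b), spec$traits), G = G,
                 d = spec$d, residual = residual,
                 center = center,
                 scale = scl, spec = spec),
            class = "index_weights")
}

#' @export
print.index_weights <- function(x, ...) {
  cat("Desired-gain index weights (residual ",
      format(x$residual, digits = 3), ")\n", sep = "")
  print(round(x$b, 4))
  invisible(x)
}

#' Score and rank accessions on a selection index
#'
#' Each genotype's score is `sum_j b_j z_gj`, with the z-scoring using
#' the same centering and SD as [compute_weights()].  Ranks are
#' descending by score, exact ties broken by genotype name.
#'
#' @param values Trait values as in [compute_weights()], with genotype
#'   names as row names or a `genotype` column.
#' @param weights An `"index_weights"` object.
#' @return data.frame of class `"index_scores"`: `genotype`, `score`,
#'   `rank`, ordered by rank.  Genotypes with a missing index trait get
#'   no score and are dropped with a message.
#' @export
score_accessions <- function(values, weights) {
  stopifnot(inherits(weights, "index_weights"))
  values <- as.data.frame(values)
  genos <- if ("genotype" %in% names(values)) values$genotype
           else rownames(values)
  if (is.null(genos)) stop("genotype names required (column or rownames)")
  traits <- weights$spec$traits
  M <- as.matrix(values[, traits, drop = FALSE])
  ok <- stats::complete.cases(M)
  if (!all(ok))
    message("dropping ", sum(!ok), " genotype(s) with missing index traits")
  M <- M[ok, , drop = FALSE]; genos <- genos[ok]
  Z <- sweep(sweep(M, 2, weights$center), 2, weights$scale, `/`)
  score <- drop(Z %*% weights$b)
  o <- order(-score, genos)
  out <- data.frame(genotype = genos[o], score = score[o],
                    rank = seq_along(o))
  rownames(out) <- NULL
  structure(out, class = c("index_scores", "data.frame"))
}

#' Accessions scoring above every tolerant check
#'
#' @param scores An `"index_scores"` data.frame.
#' @param tolerant Character vector of tolerant check names; all must be
#'   scored.
#' @return Sorted character vector of genotypes (checks excluded) with
#'   score strictly greater than the best tolerant check's score.
#' @export
beats_all_checks <- function(scores, tolerant) {
  stopifnot(is.data.frame(scores), length(tolerant) > 0)
  missing <- setdiff(tolerant, scores$genotype)
  if (length(missing))
    stop("unscored check(s): ", paste(missing, collapse = ", "))
  thr <- max(scores$score[scores$genotype %in% tolerant])
  sort(setdiff(scores$genotype[scores$score > thr], tolerant))
}
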