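## Core linear mixed-model machinery for models with one categorical fixed
## factor (cell-means coding) and at most one categorical random factor:
##
##   y = X beta + Z u + e,   u ~ N(0, v_random I),  e ~ N(0, v_error I)
##
## Both X and Z are single-factor indicator matrices, so X'X and Z'Z are
## diagonal and every REML likelihood evaluation reduces to O(n) work plus
## a q x q solve (q = number of random levels via Woodbury).  This covers
## the two models needed for augmented-design trials: genotype-fixed /
## block-random (stage-1 BLUEs) and genotype-random / environment-fixed
## (heritability and stage-2 BLUPs).

#' Specify a one-fixed-factor, one-random-factor linear mixed model
#'
#' Builds the model specification consumed by [reml_fit()] and
#' [solve_mme()].  The fixed factor is coded as cell means (one column per
#' level, no intercept), so fixed-effect estimates are adjusted level means
#' on the response scale; the random factor contributes a single variance
#' component.
#'
#' @param response Numeric vector of observations. `NA`s are dropped (with
#'   their factor assignments).
#' @param fixed Factor (or coercible) assigning each observation to a fixed
#'   level. Levels with no remaining observations are dropped with a warning
#'   (they are aliased in augmented designs when plots are lost).
#' @param random Factor assigning each observation to a random level, or
#'   `NULL` for a fixed-effects-only model.
#' @param genotype Which term carries the genotype effect, `"fixed"` or
#'   `"random"`. Metadata only; recorded so downstream code knows where to
#'   read genotype values.
#' @param weights Optional positive observation weights `w`; the residual
#'   variance of observation i is `v_error / w_i` (inverse-variance
#'   weighting of stage-1 estimates). Default: all 1.
#' @return An object of class `"lmm_spec"`.
#' @examples
#' set.seed(1)
#' y <- rnorm(12) + rep(c(0, 1), each = 6)
#' sp <- model_spec(y, fixed = rep(c("a", "b"), each = 6),
#'                  random = rep(1:3, 4))
#' reml_fit(sp)
#' @export
model_spec <- function(response, fixed, random = NULL,
                       genotype = c("fixed", "random"), weights = NULL) {
  genotype <- match.arg(genotype)
  stopifnot(is.numeric(response))
  fixed_levels <- if (is.factor(fixed)) levels(fixed) else
    as.character(sort(unique(fixed)))
  fixed <- factor(fixed, levels = fixed_levels)
  if (!is.null(random)) random <- factor(random)
  if (length(fixed) != length(response))
    stop("`fixed` must have one level assignment per observation")
  if (!is.null(random) && length(random) != length(response))
    stop("`random` must have one level assignment per observation")
  if (!is.null(weights)) {
    if (length(weights) != length(response) || any(!is.finite(weights)) ||
        any(weights <= 0))
      stop("`weights` must be positive and finite, one per observation")
  }

  keep <- is.finite(response)
  if (!all(keep)) {
    response <- response[keep]
    fixed <- fixed[keep]
    if (!is.null(random)) random <- random[keep]
    if (!is.null(weights)) weights <- weights[keep]
  }
  if (length(response) == 0L) stop("no finite observations")

  empty <- setdiff(levels(fixed), unique(as.character(fixed)))
  if (length(empty)) {
    warning("dropping fixed levels with no observations (aliased): ",
            paste(empty, collapse = ", "))
  }
  fixed <- droplevels(fixed)
  if (!is.null(random)) random <- droplevels(random)
  if (nlevels(fixed) < 1L) stop("fixed factor has no levels")
  if (!is.null(random) && nlevels(random) < 2L)
    stop("random factor needs at least 2 levels (got ",
         nlevels(random), ")")

  structure(list(y = as.numeric(response), fixed = fixed, random = random,
                 genotype = genotype, weights = weights),
            class = "lmm_spec")
}

## Dense indicator (one column per level) for a factor.
.indicator <- function(f) {
  m <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

## Sufficient statistics for the one-plus-one factor model.  X and Z are
## indicator matrices, so all (weighted) cross-products are contingency
## tables / grouped sums.  The response is centered first: the constant is
## in the column space of the cell-means X, so REML is unchanged while the
## quadratic forms avoid catastrophic cancellation (and translation
## invariance becomes exact).
.lmm_suffstat <- function(spec) {
  y <- spec$y - mean(spec$y)
  f <- spec$fixed
  r <- spec$random
  w <- if (is.null(spec$weights)) rep(1, length(y)) else spec$weights
  p <- nlevels(f)
  out <- list(
    n = length(y), p = p,
    nf = as.numeric(tapply(w, f, sum)),     # diag of X'WX
    Xty = as.numeric(tapply(w * y, f, sum)),
    yty = sum(w * y * y),
    sumlogw = sum(log(w))
  )
  if (!is.null(r)) {
    out$q <- nlevels(r)
    out$nr <- as.numeric(tapply(w, r, sum)) # diag of Z'WZ
    out$Zty <- as.numeric(tapply(w * y, r, sum))
    out$U <- unclass(stats::xtabs(w ~ f + r))  # X'WZ, p x q
    storage.mode(out$U) <- "double"
    dimnames(out$U) <- NULL
  }
  out
}

## Profiled REML criterion at lambda = v_random / v_error.
## Returns the restricted log-likelihood along with the profiled v_error
## and GLS fixed estimates.  Uses H = I + lambda Z Z' and the Woodbury
## identity twice (Z'Z diagonal; X'X diagonal).
.reml_profile <- function(ss, lambda) {
  n <- ss$n; p <- ss$p
  if (is.null(ss$q) || lambda <= 0) {
    ## (weighted) OLS limit
    beta <- ss$Xty / ss$nf
    rss <- ss$yty - sum(beta * ss$Xty)
    ve <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * ve) + 1) - ss$sumlogw +
                    sum(log(ss$nf)))
    return(list(loglik = ll, ve = max(ve, 0), beta = beta,
                logdetH = -ss$sumlogw, logdetA = sum(log(ss$nf))))
  }
  d <- lambda / (1 + lambda * ss$nr)        # D = diag(d), q-vector
  ## A = X'H^-1 X = Dx - U D U'  with Dx = diag(nf)
  Ud <- sweep(ss$U, 2, d, `*`)              # U %*% D
  a <- ss$Xty - drop(Ud %*% ss$Zty)         # X'H^-1 y
  yy <- ss$yty - sum(d * ss$Zty^2)          # y'H^-1 y
  ## Solve A beta = a and get log det A via Woodbury on Dx:
  ## A^-1 = Dx^-1 + Dx^-1 U (D^-1 - U'Dx^-1 U)^-1 U' Dx^-1
  UtDxU <- crossprod(ss$U / ss$nf, ss$U)    # q x q
  M <- diag(1 / d, nrow = ss$q) - UtDxU     # D^-1 - U'Dx^-1 U
  Mc <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(Mc)) return(list(loglik = -Inf))
  v <- crossprod(ss$U / ss$nf, a)           # U' Dx^-1 a
  z <- backsolve(Mc, backsolve(Mc, v, transpose = TRUE))
  beta <- a / ss$nf + drop(ss$U %*% z) / ss$nf
  rss <- yy - sum(beta * a)
  if (rss <= 0) rss <- .Machine$double.eps * abs(yy)
  ve <- rss / (n - p)
  ## log det A = log det Dx + log det(I - D^{1/2} U' Dx^-1 U D^{1/2})
  ##           = log det Dx + log det(M) + log det(D)
  logdetA <- sum(log(ss$nf)) + 2 * sum(log(diag(Mc))) + sum(log(d))
  logdetH <- sum(log1p(lambda * ss$nr)) - ss$sumlogw
  ll <- -0.5 * ((n - p) * (log(2 * pi * ve) + 1) + logdetH + logdetA)
  list(loglik = ll, ve = ve, beta = beta,
       logdetH = logdetH, logdetA = logdetA)
}

#' REML variance components for a one-random-factor mixed model
#'
#' Maximizes the restricted log-likelihood over the variance ratio
#' `lambda = v_random / v_error` by bounded scalar search on the log scale
#' (the fixed effects and residual variance are profiled out analytically),
#' then back-solves both components.  The non-negativity constraint is
#' enforced by the log parameterization; a maximum on the lower search
#' boundary is reported as `v_random = 0` with `boundary = TRUE`.
#'
#' @param spec An [model_spec()] object with a random factor (a spec
#'   without one returns the OLS residual variance and `v_random = 0`).
#' @param tol Convergence tolerance on the log variance ratio; successive
#'   restricted log-likelihoods at the optimum differ by far less than
#'   `1e-8` at the default.
#' @return List of class `"lmm_vc"` with `v_random`, `v_error`,
#'   `reml_loglik`, `converged`, `n_iter` (likelihood evaluations), and
#'   `boundary`.
#' @seealso [solve_mme()], [heritability()]
#' @export
reml_fit <- function(spec, tol = 1e-10) {
  stopifnot(inherits(spec, "lmm_spec"))
  ss <- .lmm_suffstat(spec)
  if (ss$n <= ss$p)
    stop("no residual degrees of freedom (n = ", ss$n, ", p = ", ss$p, ")")

  if (is.null(spec$random)) {
    pr <- .reml_profile(ss, 0)
    return(structure(list(v_random = 0, v_error = pr$ve,
                          reml_loglik = pr$loglik, converged = TRUE,
                          n_iter = 1L, boundary = FALSE),
                     class = "lmm_vc"))
  }

  ## Degenerate response: zero residual variation
  if (ss$yty - sum((ss$Xty / ss$nf) * ss$Xty) < 1e-12 * max(1, ss$yty)) {
    pr <- .reml_profile(ss, 0)
    return(structure(list(v_random = 0, v_error = max(pr$ve, 0),
                          reml_loglik = pr$loglik, converged = FALSE,
                          n_iter = 1L, boundary = TRUE,
                          note = "degenerate: near-zero residual variance"),
                     class = "lmm_vc"))
  }

  neval <- 0L
  f <- function(t) {
    neval <<- neval + 1L
    .reml_profile(ss, exp(t))$loglik
  }
  lo <- -30; hi <- 30
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE,
                         tol = sqrt(tol))
  t_hat <- opt$maximum
  ## Guard against boundary optima: Brent never samples the endpoints,
  ## and a maximum pressed against either end means the component is not
  ## interior-identified.
  at_lo <- f(lo) >= opt$objective || t_hat < lo + 1
  at_hi <- f(hi) >= opt$objective || t_hat > hi - 1
  boundary <- FALSE
  if (at_lo) { t_hat <- lo; boundary <- TRUE }
  if (at_hi) { t_hat <- hi; boundary <- TRUE }

  pr <- .reml_profile(ss, exp(t_hat))
  lambda <- exp(t_hat)
  ve <- pr$ve
  vu <- if (at_lo) 0 else lambda * ve
  structure(list(v_random = vu, v_error = ve, reml_loglik = pr$loglik,
                 converged = !boundary && neval <= 200L,
                 n_iter = neval, boundary = boundary),
            class = "lmm_vc")
}

#' @export
print.lmm_vc <- function(x, ...) {
  cat("REML variance components\n")
  cat(sprintf("  v_random: %.6g\n  v_error:  %.6g\n  loglik:   %.6f\n",
              x$v_random, x$v_error, x$reml_loglik))
  cat(sprintf("  converged: %s (%d evaluations)\n", x$converged, x$n_iter))
  invisible(x)
}

#' Solve Henderson's mixed-model equations
#'
#' Given variance components, solves
#' \deqn{\begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + kI \end{pmatrix}
#'       \begin{pmatrix} \hat\beta \\ \hat u \end{pmatrix} =
#'       \begin{pmatrix} X'y \\ Z'y \end{pmatrix}, \quad
#'       k = v_e / v_u,}
#' yielding generalized-least-squares fixed estimates (BLUEs under
#' cell-means coding these are adjusted level means) and conditional-mean
#' random predictions (BLUPs).  Standard errors come from the diagonal of
#' `v_error` times the inverse coefficient matrix (prediction-error
#' variance for the random levels).
#'
#' @param spec An [model_spec()] object.
#' @param vc An `"lmm_vc"` object (or list with `v_random`, `v_error`).
#' @return List of class `"lmm_effects"`: `fixed` (data.frame `level`,
#'   `estimate`, `se`), `random` (data.frame `level`, `blup`, `se`, or
#'   `NULL`), `intercept` (mean of fixed-level estimates), and the variance
#'   components used.
#' @export
solve_mme <- function(spec, vc) {
  stopifnot(inherits(spec, "lmm_spec"))
  m0 <- mean(spec$y)   # constant is in span(X); added back to the BLUEs
  y <- spec$y - m0
  X <- .indicator(spec$fixed)
  sw <- if (is.null(spec$weights)) NULL else sqrt(spec$weights)
  if (!is.null(sw)) { X <- X * sw; y <- y * sw }
  ve <- vc$v_error
  vu <- vc$v_random

  if (is.null(spec$random) || vu <= 0 || !is.finite(vu)) {
    ## u = 0; fixed effects by (weighted) OLS
    XtX <- crossprod(X)
    Ci <- tryCatch(solve(XtX), error = function(e)
      stop("singular coefficient matrix: fixed design not full rank"))
    beta <- drop(Ci %*% crossprod(X, y)) + m0
    fixed <- data.frame(level = colnames(X), estimate = beta,
                        se = sqrt(ve * diag(Ci)), row.names = NULL)
    random <- if (is.null(spec$random)) NULL else
      data.frame(level = levels(spec$random),
                 blup = 0, se = 0, row.names = NULL)
    return(structure(list(fixed = fixed, random = random,
                          intercept = mean(beta), vc = vc),
                     class = "lmm_effects"))
  }

  Z <- .indicator(spec$random)
  if (!is.null(sw)) Z <- Z * sw
  k <- ve / vu
  p <- ncol(X); q <- ncol(Z)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(k, q)))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  Ci <- tryCatch(solve(C), error = function(e)
    stop("singular mixed-model coefficient matrix; check for confounded ",
         "fixed and random levels"))
  sol <- drop(Ci %*% rhs)
  se <- sqrt(pmax(ve * diag(Ci), 0))
  fixed <- data.frame(level = colnames(X), estimate = sol[seq_len(p)] + m0,
                      se = se[seq_len(p)], row.names = NULL)
  random <- data.frame(level = colnames(Z), blup = sol[p + seq_len(q)],
                       se = se[p + seq_len(q)], row.names = NULL)
  structure(list(fixed = fixed, random = random,
                 intercept = mean(fixed$estimate), vc = vc),
            class = "lmm_effects")
}

#' Broad-sense heritability from variance components
#'
#' \eqn{H^2 = v_g / (v_g + v_e)}, the fraction of phenotypic variance
#' attributable to genotype, computed from a fit in which the genotype
#' term is the random factor.
#'
#' @param vc An `"lmm_vc"` object or list with `v_random` (the genetic
#'   variance) and `v_error`.
#' @return Numeric in `[0, 1]`.
#' @examples
#' heritability(list(v_random = 3, v_error = 1))  # 0.75
#' @export
heritability <- function(vc) {
  vg <- vc$v_random; ve <- vc$v_error
  if (is.null(vg) || is.null(ve) || vg < 0 || ve < 0)
    stop("variance components must be non-negative")
  if (vg + ve == 0) stop("heritability undefined: both variances are zero")
  vg / (vg + ve)
}
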