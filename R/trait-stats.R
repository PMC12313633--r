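## Descriptive and associative statistics: stress-induced reduction
## metrics, trait and environment correlations on BLUEs/BLUPs, and
## stepwise multiple regression of grain yield on secondary traits.

#' Stress-induced reduction of a trait
#'
#' Two definitions are supported.  `"of-means"` takes the difference and
#' ratio of the two group means: absolute reduction
#' `mean(control) - mean(stress)`, percent reduction
#' `100 * (mean(control) - mean(stress)) / mean(control)`.
#' `"mean-of-per-genotype"` pairs the values by genotype and averages the
#' per-genotype percent reductions (the absolute reduction is then the
#' mean per-genotype difference).  The two disagree in general; both are
#' available because published summaries rarely state which was used.
#'
#' @param control,stress Numeric vectors of trait values (e.g. BLUEs).
#'   For `"mean-of-per-genotype"` they must be paired (same genotype
#'   order); supply `genotype` to pair by name instead.
#' @param mode `"of-means"` (default) or `"mean-of-per-genotype"`.
#' @param genotype Optional list of two character vectors naming the
#'   entries of `control` and `stress` for pairing by genotype.
#' @param trait,control_label,stress_label Labels carried into the report.
#' @return data.frame of class `"reduction_report"` with `trait`,
#'   `control_mean`, `stress_mean`, `absolute`, `percent`, `mode`, `n`.
#' @examples
#' reduction_metrics(87.80, 54.48)  # absolute 33.32, percent ~37.95
#' @export
reduction_metrics <- function(control, stress,
                              mode = c("of-means", "mean-of-per-genotype"),
                              genotype = NULL, trait = NA_character_,
                              control_label = "Control",
                              stress_label = "stress") {
  mode <- match.arg(mode)
  control <- control[is.finite(control)]
  stress <- stress[is.finite(stress)]
  if (!length(control) || !length(stress)) stop("empty input")
  cm <- mean(control); sm <- mean(stress)

  if (mode == "of-means") {
    absolute <- cm - sm
    if (abs(cm) < .Machine$double.eps^0.5)
      stop("control mean is zero; percent reduction undefined")
    percent <- 100 * (cm - sm) / cm
    n <- c(length(control), length(stress))
  } else {
    if (!is.null(genotype)) {
      common <- intersect(genotype[[1]], genotype[[2]])
      control <- control[match(common, genotype[[1]])]
      stress <- stress[match(common, genotype[[2]])]
    }
    if (length(control) != length(stress))
      stop("mean-of-per-genotype mode needs paired values ",
           "(supply `genotype` to pair by name)")
    if (any(abs(control) < .Machine$double.eps^0.5))
      stop("a control value is zero; per-genotype percent undefined")
    absolute <- mean(control - stress)
    percent <- mean(100 * (control - stress) / control)
    n <- rep(length(control), 2)
  }
  structure(data.frame(trait = trait, control_mean = cm, stress_mean = sm,
                       absolute = absolute, percent = percent,
                       mode = mode, n_control = n[1], n_stress = n[2]),
            class = c("reduction_report", "data.frame"))
}

#' Reduction table across traits and stress environments
#'
#' Applies [reduction_metrics()] to every trait x stress-environment pair
#' found in a table of per-genotype values (typically stage-1 BLUEs), in
#' both modes.
#'
#' @param values data.frame with columns `environment`, `trait`,
#'   `genotype` and a value column.
#' @param control Name of the non-stress environment.
#' @param value Name of the value column (default `"blue"`).
#' @return data.frame: one row per trait x stress environment x mode.
#' @export
reduction_table <- function(values, control = "Control", value = "blue") {
  stopifnot(is.data.frame(values),
            all(c("environment", "trait", "genotype") %in% names(values)),
            value %in% names(values))
  envs <- setdiff(unique(values$environment), control)
  if (!control %in% values$environment)
    stop("control environment '", control, "' not found")
  out <- list()
  for (tn in unique(values$trait)) {
    vc_ <- values[values$trait == tn & values$environment == control, ]
    if (nrow(vc_) == 0) next
    for (ev in envs) {
      vs <- values[values$trait == tn & values$environment == ev, ]
      if (nrow(vs) == 0) next
      for (md in c("of-means", "mean-of-per-genotype")) {
        r <- tryCatch(
          reduction_metrics(vc_[[value]], vs[[value]], mode = md,
                            genotype = list(vc_$genotype, vs$genotype),
                            trait = tn, stress_label = ev),
          error = function(e) NULL)
        if (!is.null(r)) {
          r$stress_env <- ev
          out[[length(out) + 1L]] <- r
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations between the columns of a
#' genotype x trait value matrix, with two-sided p-values from the
#' t transform `t = r sqrt(n-2) / sqrt(1-r^2)` and Benjamini-Hochberg
#' adjusted p-values over the upper triangle.
#'
#' @param values Numeric matrix or data.frame, rows = genotypes,
#'   columns = traits (or environments).
#' @param min_n Minimum pairwise-complete observations per cell
#'   (default 3); cells below it are reported missing.
#' @return List of class `"corr_matrix"`: `r`, `p`, `p_adj`, `n`
#'   (matrices) and `labels`.
#' @export
trait_correlations <- function(values, min_n = 3L) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  k <- ncol(values)
  labels <- colnames(values)
  if (is.null(labels)) labels <- paste0("V", seq_len(k))
  r <- p <- diag(1, k)
  n <- matrix(NA_integer_, k, k)
  diag(n) <- colSums(is.finite(values))
  diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- is.finite(values[, i]) & is.finite(values[, j])
    nij <- sum(ok)
    n[i, j] <- n[j, i] <- nij
    if (nij < max(min_n, 3L) ||
        stats::sd(values[ok, i]) == 0 || stats::sd(values[ok, j]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      p[i, j] <- p[j, i] <- NA_real_
      next
    }
    rij <- stats::cor(values[ok, i], values[ok, j])
    r[i, j] <- r[j, i] <- rij
    tt <- rij * sqrt((nij - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = nij - 2)
  }
  up <- upper.tri(p)
  p_adj <- p
  p_adj[up] <- stats::p.adjust(p[up], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  dimnames(r) <- dimnames(p) <- dimnames(p_adj) <- dimnames(n) <-
    list(labels, labels)
  structure(list(r = r, p = p, p_adj = p_adj, n = n, labels = labels),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlations (", nrow(x$r), " x ", ncol(x$r), ")\n",
      sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' Between-environment correlation of one trait
#'
#' Reshapes per-environment genotype values (stage-1 BLUEs) of a single
#' trait to a genotype x environment matrix and correlates the
#' environments.
#'
#' @param blues data.frame with `environment`, `genotype` and a value
#'   column; optionally a `trait` column with `trait` given.
#' @param trait Optional trait filter.
#' @param value Value column name (default `"blue"`).
#' @return A `"corr_matrix"` over environments.
#' @export
env_correlations <- function(blues, trait = NULL, value = "blue") {
  stopifnot(is.data.frame(blues))
  if (!is.null(trait) && "trait" %in% names(blues))
    blues <- blues[blues$trait == trait, , drop = FALSE]
  envs <- unique(blues$environment)
  if (length(envs) < 2L) stop("need >= 2 environments, got ", length(envs))
  genos <- unique(blues$genotype)
  m <- matrix(NA_real_, length(genos), length(envs),
              dimnames = list(genos, envs))
  m[cbind(match(blues$genotype, genos),
          match(blues$environment, envs))] <- blues[[value]]
  trait_correlations(m)
}

#' Stepwise multiple regression of yield on secondary traits
#'
#' Candidates are pre-filtered to those with `|r|` with the response at or
#' above `r_threshold` (the moderately-or-highly-correlated rule), then a
#' bidirectional stepwise search by AIC starts from the intercept-only
#' model (`criterion = "AIC"`), or predictors enter at `p < alpha_enter`
#' and leave at `p > alpha_remove` (`criterion = "p"`).  The selected
#' model is refit by ordinary least squares and the usual summaries
#' reported.
#'
#' @param y Numeric response (e.g. multi-environment grain-yield
#'   predictions).
#' @param X Numeric matrix/data.frame of candidate predictors, one column
#'   per trait.
#' @param criterion `"AIC"` (default) or `"p"`.
#' @param r_threshold Pre-filter on marginal |correlation| with `y`
#'   (default 0.1).
#' @param alpha_enter,alpha_remove Entry/removal p-values for
#'   `criterion = "p"`.
#' @return List of class `"stepwise_result"`: `selected` (predictor
#'   names), `coefficients` (term, estimate, se, t, p), `r_squared`,
#'   `adj_r_squared`, `f_statistic`, `df`, `f_p_value`, `aic`, `model`
#'   (the `lm` fit), `candidates` (post-filter candidate set).
#' @export
stepwise_regression <- function(y, X, criterion = c("AIC", "p"),
                                r_threshold = 0.1, alpha_enter = 0.05,
                                alpha_remove = 0.10) {
  criterion <- match.arg(criterion)
  X <- as.data.frame(X)
  if (any(!vapply(X, is.numeric, logical(1))))
    stop("all candidate columns must be numeric")
  ok <- is.finite(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (length(y) <= ncol(X) + 1L)
    stop("need more observations than candidates (+1)")

  ## drop exactly collinear columns (rank check on the candidate block)
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < ncol(X) + 1L) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    keep <- setdiff(keep, 1L) - 1L
    dropped <- setdiff(names(X), names(X)[keep])
    warning("dropping collinear candidate(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }

  marg <- vapply(X, function(x)
    if (stats::sd(x) == 0) 0 else abs(stats::cor(y, x)), numeric(1))
  cand <- names(X)[marg >= r_threshold]
  dat <- data.frame(.y = y, X[, cand, drop = FALSE], check.names = FALSE)

  if (length(cand) == 0L) {
    fit <- stats::lm(.y ~ 1, data = dat)
  } else if (criterion == "AIC") {
    null_fit <- stats::lm(.y ~ 1, data = dat)
    upper <- stats::reformulate(sprintf("`%s`", cand), response = ".y")
    fit <- stats::step(null_fit, direction = "both",
                       scope = list(lower = ~ 1, upper = upper),
                       trace = 0)
  } else {
    fit <- .stepwise_p(dat, cand, alpha_enter, alpha_remove)
  }

  sel <- setdiff(all.vars(stats::formula(fit)), ".y")
  sm <- summary(fit)
  co <- stats::coef(sm)
  coefficients <- data.frame(term = gsub("`", "", rownames(co)),
                             estimate = co[, 1], se = co[, 2],
                             t_value = co[, 3], p_value = co[, 4],
                             row.names = NULL)
  fs <- sm$fstatistic
  structure(list(
    selected = sel, coefficients = coefficients,
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    f_statistic = if (is.null(fs)) NA_real_ else unname(fs[1]),
    df = if (is.null(fs)) c(0, stats::df.residual(fit))
         else unname(fs[2:3]),
    f_p_value = if (is.null(fs)) NA_real_
                else stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
    aic = stats::AIC(fit), model = fit, candidates = cand,
    criterion = criterion),
    class = "stepwise_result")
}

## p-value-threshold bidirectional stepwise (enter/remove), deterministic.
.stepwise_p <- function(dat, cand, alpha_enter, alpha_remove) {
  current <- character(0)
  repeat {
    changed <- FALSE
    ## forward: best-p candidate below alpha_enter
    pool <- setdiff(cand, current)
    if (length(pool)) {
      pvals <- vapply(pool, function(v) {
        f <- stats::reformulate(sprintf("`%s`", c(current, v)),
                                response = ".y")
        co <- stats::coef(summary(stats::lm(f, data = dat)))
        co[nrow(co), 4]
      }, numeric(1))
      if (min(pvals) < alpha_enter) {
        current <- c(current, pool[which.min(pvals)])
        changed <- TRUE
      }
    }
    ## backward: worst-p included term above alpha_remove
    if (length(current)) {
      f <- stats::reformulate(sprintf("`%s`", current), response = ".y")
      co <- stats::coef(summary(stats::lm(f, data = dat)))[-1, 4,
                                                           drop = TRUE]
      if (length(co) && max(co) > alpha_remove) {
        current <- current[-which.max(co)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  f <- if (length(current))
    stats::reformulate(sprintf("`%s`", current), response = ".y")
  else .y ~ 1
  stats::lm(f, data = dat)
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Stepwise regression (", x$criterion, "): ",
      if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(intercept only)", "\n", sep = "")
  cat(sprintf("  R2 = %.3f, adj. R2 = %.3f, F = %.2f on %d and %d df\n",
              x$r_squared, x$adj_r_squared, x$f_statistic,
              x$df[1], x$df[2]))
  invisible(x)
}
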