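## Stage-2 (multi-trial) analysis: stage-1 BLUEs from all environments are
## combined in a genotype-random / environment-fixed mixed model, giving
## shrinkage predictions (BLUPs) per genotype on the trait scale.

#' Multi-environment analysis of stage-1 BLUEs for one trait
#'
#' Fits `value ~ environment (fixed) + genotype (random)` to the
#' per-environment BLUEs of one trait.  The reported predicted value of a
#' genotype is `grand mean + BLUP deviation`, where the grand mean is the
#' unweighted mean of the fitted environment means, so predictions are on
#' the trait scale.  The fit is unweighted by default; set
#' `weight = "inv_var"` to weight each BLUE by `1/se^2` (rows with missing
#' or zero `se` then get the median weight).
#'
#' @param blues data.frame with columns `environment`, `genotype`, `blue`
#'   and optionally `se` and `is_check` (e.g. the `blues` element of
#'   [run_all_sta()], filtered to one trait, or with a `trait` column and
#'   `trait` given).
#' @param trait Optional trait name to filter on / record.
#' @param weight `"none"` (default) or `"inv_var"`.
#' @return Object of class `"mta_result"`: `trait`, `predictions`
#'   (data.frame `genotype`, `blup` (deviation), `predicted`, `se`,
#'   `is_check`), `grand_mean`, `env_means`, `vc`.
#' @export
fit_mta <- function(blues, trait = NULL, weight = c("none", "inv_var")) {
  weight <- match.arg(weight)
  stopifnot(is.data.frame(blues))
  if (!is.null(trait) && "trait" %in% names(blues))
    blues <- blues[blues$trait == trait, , drop = FALSE]
  if (is.null(trait))
    trait <- if ("trait" %in% names(blues)) unique(blues$trait)[1] else NA
  if (nrow(blues) == 0) stop("no BLUEs for trait ", trait)
  blues <- blues[is.finite(blues$blue), , drop = FALSE]
  n_env <- length(unique(blues$environment))
  if (n_env < 2L) {
    ## genotype and environment mean are confounded: no shrinkage is
    ## identified, so stage-1 BLUEs pass through (centered as deviations)
    warning("only ", n_env, " environment for trait ", trait,
            "; stage-1 BLUEs pass through unshrunk")
    grand <- mean(blues$blue)
    pred <- data.frame(genotype = blues$genotype,
                       blup = blues$blue - grand,
                       predicted = blues$blue,
                       se = if ("se" %in% names(blues)) blues$se
                            else NA_real_)
    pred <- pred[order(pred$genotype), , drop = FALSE]
    rownames(pred) <- NULL
    if ("is_check" %in% names(blues)) {
      chk <- unique(blues$genotype[blues$is_check])
      pred$is_check <- pred$genotype %in% chk
    } else pred$is_check <- FALSE
    vc <- structure(list(v_random = stats::var(blues$blue), v_error = 0,
                         reml_loglik = NA_real_, converged = FALSE,
                         n_iter = 0L, boundary = TRUE),
                    class = "lmm_vc")
    return(structure(list(trait = trait, predictions = pred,
                          grand_mean = grand,
                          env_means = stats::setNames(
                            grand, unique(blues$environment)),
                          vc = vc, weight = weight),
                     class = "mta_result"))
  }

  w <- NULL
  if (weight == "inv_var") {
    if (!"se" %in% names(blues))
      stop("inverse-variance weighting requires an `se` column")
    w <- 1 / blues$se^2
    w[!is.finite(w) | w <= 0] <- stats::median(w[is.finite(w) & w > 0])
    w <- w / mean(w)    # normalized so v_error stays on the trait scale
  }

  sp <- model_spec(blues$blue, fixed = blues$environment,
                   random = blues$genotype, genotype = "random",
                   weights = w)
  vc <- reml_fit(sp)
  eff <- solve_mme(sp, vc)
  env_means <- stats::setNames(eff$fixed$estimate, eff$fixed$level)
  grand <- mean(env_means)
  pred <- data.frame(genotype = eff$random$level, blup = eff$random$blup,
                     predicted = grand + eff$random$blup,
                     se = eff$random$se)
  if ("is_check" %in% names(blues)) {
    chk <- unique(blues$genotype[blues$is_check])
    pred$is_check <- pred$genotype %in% chk
  } else pred$is_check <- FALSE
  structure(list(trait = trait, predictions = pred, grand_mean = grand,
                 env_means = env_means, vc = vc, weight = weight),
            class = "mta_result")
}

#' @export
print.mta_result <- function(x, ...) {
  cat(sprintf("Multi-environment analysis: %s\n", x$trait))
  cat(sprintf("  %d genotypes, predicted grand mean %.4g, v_g = %.4g, v_e = %.4g\n",
              nrow(x$predictions), x$grand_mean, x$vc$v_random, x$vc$v_error))
  invisible(x)
}

#' Rank genotypes by multi-environment predicted value
#'
#' Descending by predicted value; exact ties broken by genotype name
#' (ascending), so the ranking is stable under row permutation.
#'
#' @param mta An `"mta_result"`.
#' @return data.frame `genotype`, `predicted`, `rank` in rank order.
#' @export
rank_by_prediction <- function(mta) {
  stopifnot(inherits(mta, "mta_result"))
  p <- mta$predictions
  o <- order(-p$predicted, p$genotype)
  out <- data.frame(genotype = p$genotype[o], predicted = p$predicted[o],
                    rank = seq_along(o))
  rownames(out) <- NULL
  out
}

#' Fraction of test accessions beating a reference yield level
#'
#' The reference is either the predicted grand mean of the trial
#' (`reference = "mean"`) or the best (maximum) predicted value among a
#' named list of checks.  Checks are excluded from the numerator and
#' denominator.
#'
#' @param mta An `"mta_result"`.
#' @param reference `"mean"`, or a character vector of check genotype
#'   names.
#' @return List with `fraction` (of non-check accessions strictly above
#'   the reference), `threshold`, `members` (genotype names above), `n`.
#' @export
superiority_fraction <- function(mta, reference = "mean") {
  stopifnot(inherits(mta, "mta_result"))
  p <- mta$predictions
  if (identical(reference, "mean")) {
    thr <- mta$grand_mean
  } else {
    missing <- setdiff(reference, p$genotype)
    if (length(missing))
      stop("unknown check(s): ", paste(missing, collapse = ", "))
    thr <- max(p$predicted[p$genotype %in% reference])
  }
  tests <- p[!p$is_check, , drop = FALSE]
  if (nrow(tests) == 0) stop("no non-check accessions to compare")
  above <- tests$genotype[tests$predicted > thr]
  list(fraction = length(above) / nrow(tests), threshold = thr,
       members = sort(above), n = nrow(tests))
}
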