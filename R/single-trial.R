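## Stage-1 (single-trial) analysis of one environment x one trait under the
## augmented design: BLUEs adjusted for block effects from a genotype-fixed
## / block-random fit, plus variance components and broad-sense
## heritability from a companion genotype-random / block-fixed fit.

#' Single-trial analysis of one environment x trait
#'
#' Fits two mixed models to the plot data of one environment and trait:
#' (1) genotype fixed, block random -- the fixed-effect estimates are the
#' design-adjusted genotype means (BLUEs) with standard errors; (2) the
#' companion fit with genotype random and block fixed, whose REML variance
#' components give the broad-sense heritability
#' \eqn{H^2 = v_g / (v_g + v_e)}.  The trial CV (%) is computed on the raw
#' plot values (set `cv_on = "blue"` for the alternative).
#'
#' @param records Plot records (long format). Rows from other
#'   environments/traits are ignored if `environment`/`trait` are given.
#' @param environment,trait Which environment x trait cell to analyse;
#'   may be omitted when `records` contains a single cell.
#' @param cv_on `"raw"` (default) or `"blue"`.
#' @return Object of class `"sta_result"`: `environment`, `trait`,
#'   `blues` (data.frame `genotype`, `blue`, `se`, `is_check`), `vc`
#'   (genotype-random REML components), `h2`, `summary` (mean, min, max,
#'   cv, n on the CV scale chosen).
#' @seealso [run_all_sta()], [fit_mta()]
#' @export
fit_sta <- function(records, environment = NULL, trait = NULL,
                    cv_on = c("raw", "blue")) {
  cv_on <- match.arg(cv_on)
  stopifnot(is.data.frame(records))
  if (!is.null(environment))
    records <- records[records$environment == environment, , drop = FALSE]
  if (!is.null(trait))
    records <- records[records$trait == trait, , drop = FALSE]
  if (nrow(records) == 0)
    stop("no records for environment ", environment, ", trait ", trait)
  if (length(unique(records$environment)) > 1L ||
      length(unique(records$trait)) > 1L)
    stop("fit_sta() analyses one environment x trait; specify both")
  environment <- records$environment[1]
  trait <- records$trait[1]

  records <- records[is.finite(records$value), , drop = FALSE]
  n_blocks <- length(unique(records$block))
  if (n_blocks < 2L) stop("need >= 2 blocks, got ", n_blocks)

  ## checks should appear in every block; warn (and proceed) otherwise
  chk <- unique(records$genotype[records$is_check])
  if (length(chk)) {
    tab <- table(factor(records$genotype[records$is_check], levels = chk),
                 records$block[records$is_check])
    miss <- rowSums(tab == 0)
    if (any(miss > 0))
      warning("check(s) missing from some blocks: ",
              paste(names(miss)[miss > 0], collapse = ", "))
  }

  ## (1) genotype fixed / block random -> BLUEs
  sp_blue <- model_spec(records$value, fixed = records$genotype,
                        random = records$block, genotype = "fixed")
  vc_blue <- reml_fit(sp_blue)
  eff <- solve_mme(sp_blue, vc_blue)
  blues <- data.frame(genotype = eff$fixed$level, blue = eff$fixed$estimate,
                      se = eff$fixed$se)
  blues$is_check <- blues$genotype %in% chk

  ## (2) genotype random / block fixed -> variance components and H2
  sp_h2 <- model_spec(records$value, fixed = records$block,
                      random = records$genotype, genotype = "random")
  vc <- reml_fit(sp_h2)
  h2 <- tryCatch(heritability(vc), error = function(e) NA_real_)

  vals <- if (cv_on == "raw") records$value else blues$blue
  m <- mean(vals)
  summary <- data.frame(
    environment = environment, trait = trait, mean = m,
    min = min(vals), max = max(vals),
    cv = if (abs(m) < .Machine$double.eps^0.5) NA_real_
         else 100 * stats::sd(vals) / m,
    heritability = h2, n = length(vals))

  structure(list(environment = environment, trait = trait, blues = blues,
                 vc = vc, h2 = h2, summary = summary, cv_on = cv_on),
            class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf("Single-trial analysis: %s / %s\n", x$environment, x$trait))
  cat(sprintf("  %d genotypes, H2 = %.3f, v_g = %.4g, v_e = %.4g\n",
              nrow(x$blues), x$h2, x$vc$v_random, x$vc$v_error))
  invisible(x)
}

#' Run single-trial analyses for every environment x trait cell
#'
#' @param records Plot records spanning one or more environments and
#'   traits.
#' @param traits Optional subset of traits to analyse.
#' @param quiet Suppress per-cell progress messages.
#' @return Object of class `"sta_set"`: list with `fits` (named list of
#'   [fit_sta()] results, names `environment.trait`), `summary` (stacked
#'   per-trial summary table with mean, range, heritability and CV), and
#'   `blues` (stacked long table `environment`, `trait`, `genotype`,
#'   `blue`, `se`, `is_check`).
#' @export
run_all_sta <- function(records, traits = NULL, quiet = TRUE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("empty input")
  if (is.null(traits)) traits <- unique(records$trait)
  cells <- unique(records[records$trait %in% traits,
                          c("environment", "trait")])
  if (nrow(cells) == 0) stop("no matching environment x trait cells")
  fits <- vector("list", nrow(cells))
  names(fits) <- paste(cells$environment, cells$trait, sep = ".")
  for (i in seq_len(nrow(cells))) {
    if (!quiet)
      message("STA: ", cells$environment[i], " / ", cells$trait[i])
    fits[[i]] <- fit_sta(records, cells$environment[i], cells$trait[i])
  }
  summary <- do.call(rbind, lapply(fits, `[[`, "summary"))
  rownames(summary) <- NULL
  blues <- do.call(rbind, lapply(fits, function(f)
    data.frame(environment = f$environment, trait = f$trait, f$blues)))
  rownames(blues) <- NULL
  structure(list(fits = fits, summary = summary, blues = blues),
            class = "sta_set")
}
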