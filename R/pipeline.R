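## Orchestration and I/O: schema-validated long-format phenotype CSVs in
## and a full report bundle (CSV tables + run log) out.

.DM_REQUIRED_COLS <- c("environment", "block", "genotype", "is_check",
                       "trait", "value")

#' Read a long-format phenotype CSV
#'
#' Expected header: `environment,block,genotype,is_check,trait,value`
#' (UTF-8, "." decimal, empty field = missing value).  Schema violations
#' -- missing columns, non-numeric values, duplicate
#' (environment, block, genotype, trait) rows -- raise errors naming the
#' offending column or rows.
#'
#' @param path CSV file path.
#' @param quiet Suppress the row-count message.
#' @return data.frame of plot records; `value` is numeric with `NA` for
#'   missing, `is_check` logical.
#' @seealso [write_phenotypes()]
#' @export
read_phenotypes <- function(path, quiet = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing <- setdiff(.DM_REQUIRED_COLS, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, .DM_REQUIRED_COLS]
  if (!is.numeric(df$value)) {
    bad <- which(!is.na(df$value) &
                   is.na(suppressWarnings(as.numeric(df$value))))
    stop("non-numeric value(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (is.character(df$is_check))
    df$is_check <- toupper(df$is_check) %in% c("TRUE", "T", "1", "YES")
  df$is_check <- as.logical(df$is_check)
  key <- paste(df$environment, df$block, df$genotype, df$trait, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (environment, block, genotype, trait) row(s): ",
         paste(utils::head(dup, 10), collapse = ", "))
  if (!quiet) {
    message(nrow(df), " records; per environment: ",
            paste(sprintf("%s=%d", names(table(df$environment)),
                          table(df$environment)), collapse = ", "))
  }
  df
}

#' Write plot records to CSV
#'
#' @param records Plot records data.frame (the [read_phenotypes()]
#'   schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(.DM_REQUIRED_COLS %in% names(records)))
  utils::write.csv(records[, .DM_REQUIRED_COLS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' @param input Path to a phenotype CSV, a plot-records data.frame, or a
#'   [sim_config()] (data are then simulated with the run seed).
#' @param out_dir Output directory for the report bundle.
#' @param traits Optional trait subset to analyse.
#' @param control Name of the non-stress environment.
#' @param stress Names of stress environments for classification; default:
#'   every non-control environment in the data.
#' @param yield_trait Trait used for classification and as the
#'   regression/superiority response.
#' @param checks A [check_config()].
#' @param index An [index_spec()].
#' @param stepwise_criterion `"AIC"` or `"p"`.
#' @param seed Integer seed controlling any simulation.
#' @param verbose Emit per-stage messages.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input, out_dir, traits = NULL,
                            control = "Control", stress = NULL,
                            yield_trait = "gy", checks = check_config(),
                            index = index_spec(),
                            stepwise_criterion = "AIC",
                            seed = 1L, verbose = FALSE) {
  stopifnot(inherits(checks, "check_config"), inherits(index, "index_spec"))
  structure(list(input = input, out_dir = out_dir, traits = traits,
                 control = control, stress = stress,
                 yield_trait = yield_trait, checks = checks, index = index,
                 stepwise_criterion = stepwise_criterion,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: single-trial analyses per environment x trait
#' (summary table and BLUEs), stress-reduction metrics, between-
#' environment correlations per trait, multi-environment BLUPs and yield
#' ranking, trait correlations on predicted values, stepwise regression of
#' yield on secondary traits, per-stress-environment classification on
#' BLUEs, multi-environment classification on predicted values, and the
#' desired-gain selection index.  Every stage's table is written as CSV
#' under `config$out_dir` together with a JSON run log (seed, package
#' version, input hash).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result (`sta`, `reductions`,
#'   `env_corr`, `mta`, `ranking`, `superiority`, `trait_corr`,
#'   `regression`, `classification`, `index`) plus `files` (written
#'   paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message("[droughtmet] ", ...)
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, na = "")
    files <<- c(files, p)
  }
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## input --------------------------------------------------------------
  records <- stage("input", {
    if (inherits(config$input, "sim_config"))
      simulate_met(config$input, seed = config$seed)$records
    else if (is.character(config$input)) read_phenotypes(config$input)
    else if (is.data.frame(config$input)) config$input
    else stop("unsupported input type")
  })
  emit(records, "phenotypes")
  envs <- unique(records$environment)
  if (!config$control %in% envs)
    stop("control environment '", config$control, "' absent from data")
  stress <- config$stress
  if (is.null(stress)) stress <- setdiff(envs, config$control)

  ## stage 1: single-trial analyses -------------------------------------
  sta <- stage("single-trial", run_all_sta(records, traits = config$traits,
                                           quiet = !config$verbose))
  emit(sta$summary, "sta_summary")
  emit(sta$blues, "sta_blues")

  ## reductions ----------------------------------------------------------
  reductions <- stage("reductions",
                      reduction_table(sta$blues, control = config$control))
  emit(reductions, "reductions")

  ## between-environment correlations per trait -------------------------
  env_corr <- stage("env-correlations", {
    lapply(split(sta$blues, sta$blues$trait), function(b) {
      if (length(unique(b$environment)) < 2L) return(NULL)
      env_correlations(b)
    })
  })
  ec_rows <- do.call(rbind, lapply(names(env_corr), function(tn) {
    cm <- env_corr[[tn]]
    if (is.null(cm)) return(NULL)
    idx <- which(upper.tri(cm$r), arr.ind = TRUE)
    data.frame(trait = tn, env1 = cm$labels[idx[, 1]],
               env2 = cm$labels[idx[, 2]], r = cm$r[idx], p = cm$p[idx],
               n = cm$n[idx])
  }))
  emit(ec_rows, "env_correlations")

  ## stage 2: multi-environment BLUPs -----------------------------------
  mta <- stage("multi-trial", {
    lapply(split(sta$blues, sta$blues$trait), fit_mta)
  })
  pred_long <- do.call(rbind, lapply(names(mta), function(tn)
    data.frame(trait = tn, mta[[tn]]$predictions)))
  rownames(pred_long) <- NULL
  emit(pred_long, "mta_predictions")

  ranking <- superiority <- NULL
  if (config$yield_trait %in% names(mta)) {
    ranking <- rank_by_prediction(mta[[config$yield_trait]])
    emit(ranking, "mta_yield_ranking")
    superiority <- superiority_fraction(mta[[config$yield_trait]], "mean")
  }

  ## trait correlations on predicted values -----------------------------
  pv <- stats::reshape(pred_long[, c("genotype", "trait", "predicted")],
                       idvar = "genotype", timevar = "trait",
                       direction = "wide")
  names(pv) <- sub("^predicted\\.", "", names(pv))
  rownames(pv) <- pv$genotype
  trait_corr <- stage("trait-correlations",
                      trait_correlations(pv[, -1, drop = FALSE]))
  idx <- which(upper.tri(trait_corr$r), arr.ind = TRUE)
  emit(data.frame(trait1 = trait_corr$labels[idx[, 1]],
                  trait2 = trait_corr$labels[idx[, 2]],
                  r = trait_corr$r[idx], p = trait_corr$p[idx],
                  p_adj = trait_corr$p_adj[idx], n = trait_corr$n[idx]),
       "trait_correlations")

  ## stepwise regression of yield on secondary traits -------------------
  regression <- NULL
  if (config$yield_trait %in% names(pv)) {
    cand_cols <- setdiff(names(pv), c("genotype", config$yield_trait))
    cc <- stats::complete.cases(pv[, c(config$yield_trait, cand_cols)])
    regression <- stage("stepwise-regression",
      stepwise_regression(pv[cc, config$yield_trait],
                          pv[cc, cand_cols, drop = FALSE],
                          criterion = config$stepwise_criterion))
    emit(regression$coefficients, "regression_coefficients")
    emit(data.frame(r_squared = regression$r_squared,
                    adj_r_squared = regression$adj_r_squared,
                    f_statistic = regression$f_statistic,
                    df1 = regression$df[1], df2 = regression$df[2],
                    f_p_value = regression$f_p_value),
         "regression_summary")
  }

  ## classification ------------------------------------------------------
  classification <- stage("classification", {
    out <- list()
    yb <- sta$blues[sta$blues$trait == config$yield_trait, , drop = FALSE]
    for (ev in stress) {
      b <- yb[yb$environment == ev, , drop = FALSE]
      if (nrow(b) == 0) next
      out[[ev]] <- classify(stats::setNames(b$blue, b$genotype),
                            checks = config$checks, environment = ev)
    }
    if (config$yield_trait %in% names(mta)) {
      p <- mta[[config$yield_trait]]$predictions
      out[["multi"]] <- classify(stats::setNames(p$predicted, p$genotype),
                                 checks = config$checks,
                                 environment = "multi")
    }
    out
  })
  emit(do.call(rbind, classification), "classification")
  emit(do.call(rbind, lapply(names(classification), function(ev)
    data.frame(environment = ev,
               category_summary(classification[[ev]])))),
    "classification_summary")

  ## selection index -----------------------------------------------------
  index <- stage("selection-index", {
    itr <- config$index$traits
    if (!all(itr %in% names(pv))) {
      say("index traits absent (", paste(setdiff(itr, names(pv)),
                                         collapse = ", "), "); skipped")
      NULL
    } else {
      w <- compute_weights(pv, spec = config$index)
      sc <- score_accessions(pv, w)
      winners <- beats_all_checks(sc, config$checks$tolerant)
      sc$beats_all_checks <- sc$genotype %in% winners
      list(weights = w, scores = sc, winners = winners)
    }
  })
  if (!is.null(index)) emit(index$scores, "index_scores")

  ## run log -------------------------------------------------------------
  pheno_path <- file.path(config$out_dir, "phenotypes.csv")
  log <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("droughtmet")),
    r_version = R.version.string,
    timestamp = format(t0, "%Y-%m-%d %H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    input_md5 = unname(tools::md5sum(pheno_path)),
    control = config$control, stress = stress,
    yield_trait = config$yield_trait,
    index = list(traits = config$index$traits, d = config$index$d),
    checks = config$checks[c("tolerant", "susceptible",
                             "upper_anchor", "lower_anchor")],
    stepwise_criterion = config$stepwise_criterion,
    files = basename(files))
  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, log_path)

  say("done: ", length(files), " files in ", config$out_dir)
  invisible(list(records = records, sta = sta, reductions = reductions,
                 env_corr = env_corr, mta = mta, ranking = ranking,
                 superiority = superiority, trait_corr = trait_corr,
                 regression = regression, classification = classification,
                 index = index, files = files))
}
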