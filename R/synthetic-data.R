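## Synthetic plot-level data for an augmented RCBD multi-environment trial:
## unreplicated test accessions plus replicated tolerant/susceptible checks
## in every block, three environments (irrigated control, rainout-shelter
## managed drought, rainfed target population of environments), ten
## agronomic and four physiological traits.  Genetic effects carry both
## between-trait and cross-environment correlation; ground truth is
## returned so downstream estimators can be validated against it.

.DM_ENVS <- c("Control", "ROS", "TPE")

## Per-trait, per-environment trial-level parameters: mean, broad-sense
## heritability and plot-level CV (%).  NA = trait not scored in that
## environment (physiological traits are scored under Control/ROS only;
## drought-reaction scores under ROS only).
.dm_trait_table <- function() {
  tr <- function(name, label, ordinal,
                 mC, hC, cC, mR, hR, cR, mT, hT, cT)
    data.frame(trait = name, label = label, ordinal = ordinal,
               mean_Control = mC, h2_Control = hC, cv_Control = cC,
               mean_ROS = mR, h2_ROS = hR, cv_ROS = cR,
               mean_TPE = mT, h2_TPE = hT, cv_TPE = cT)
  rbind(
    tr("dff", "Days to fifty per cent flowering", FALSE,
       85.26, 0.98, 10.90,  84.78, 0.96, 10.22,  72.89, 0.99, 15.99),
    tr("ph",  "Plant height (cm)", FALSE,
       118.99, 0.90, 16.41, 115.82, 0.95, 22.32, 80.99, 0.85, 17.52),
    tr("tp",  "Tillers per plant", FALSE,
       16.63, 0.79, 29.65,  8.86, 0.65, 32.46,   6.38, 0.75, 30.87),
    tr("npt", "Number of productive tillers per plant", FALSE,
       16.84, 0.80, 29.18,  8.12, 0.74, 34.98,   6.13, 0.76, 30.03),
    tr("pe",  "Panicle exsertion (score)", TRUE,
       7.73, 0.78, 26.59,   3.62, 0.92, 76.58,   6.56, 0.90, 38.12),
    tr("pl",  "Panicle length (cm)", FALSE,
       23.92, 0.51, 10.52,  23.30, 0.66, 13.85,  19.48, 0.67, 12.52),
    tr("pw",  "Panicle weight (g)", FALSE,
       4.28, 0.90, 17.75,   2.16, 0.97, 52.37,   3.29, 0.85, 17.98),
    tr("hsw", "Hundred seed weight (g)", FALSE,
       2.32, 0.92, 14.67,   1.82, 0.95, 24.88,   2.09, 0.91, 18.56),
    tr("sf",  "Spikelet fertility (%)", FALSE,
       87.80, 0.60, 8.52,   54.48, 0.89, 35.52,  76.30, 0.76, 14.78),
    tr("gy",  "Grain yield (t/ha)", FALSE,
       4.57, 0.88, 31.47,   1.55, 0.85, 61.14,   1.37, 0.80, 43.06),
    tr("rwc", "Relative water content (%)", FALSE,
       88.97, 0.55, 6.07,   75.56, 0.73, 10.47,  NA, NA, NA),
    tr("ccm", "Chlorophyll content index", FALSE,
       16.95, 0.69, 24.81,  9.24, 0.79, 37.38,   NA, NA, NA),
    tr("lr",  "Leaf rolling (score)", TRUE,
       NA, NA, NA,          4.67, 0.69, 28.81,   NA, NA, NA),
    tr("ltd", "Leaf tip drying (score)", TRUE,
       NA, NA, NA,          3.15, 0.87, 55.55,   NA, NA, NA)
  )
}

## Cross-environment genetic correlations per trait (Control-ROS,
## Control-TPE, ROS-TPE).  Traits absent from an environment keep the
## identity on the remaining block.
.dm_env_corr <- function() {
  m <- rbind(
    dff = c(0.82, 0.68, 0.60), ph  = c(0.68, 0.74, 0.67),
    tp  = c(0.22, 0.10, 0.21), npt = c(0.21, 0.13, 0.20),
    pe  = c(0.34, 0.53, 0.26), pl  = c(0.62, 0.41, 0.20),
    pw  = c(0.42, 0.64, 0.20), hsw = c(0.65, 0.89, 0.57),
    sf  = c(0.33, 0.88, 0.29), gy  = c(0.26, 0.38, 0.00),
    rwc = c(0.76, NA, NA),     ccm = c(0.45, NA, NA),
    lr  = c(NA, NA, NA),       ltd = c(NA, NA, NA))
  colnames(m) <- c("Control_ROS", "Control_TPE", "ROS_TPE")
  m
}

## Between-trait genetic correlation matrix.  Grain-yield rows follow the
## observed multi-environment associations (panicle weight strongest, then
## spikelet fertility / panicle length / seed weight, weak with tillering,
## negative with flowering time and leaf rolling); selected secondary
## structure (tillers vs productive tillers, rolling vs tip drying) is set
## to field-typical values and everything else left near zero.  Projected
## to the nearest unit-diagonal PSD matrix once, deterministically.
.dm_trait_corr <- function(traits) {
  n <- length(traits)
  C <- diag(n); dimnames(C) <- list(traits, traits)
  set <- function(a, b, v) {
    if (a %in% traits && b %in% traits) C[a, b] <<- C[b, a] <<- v
  }
  set("gy", "pw", 0.50);  set("gy", "sf", 0.34);  set("gy", "pl", 0.30)
  set("gy", "hsw", 0.30); set("gy", "ph", 0.26);  set("gy", "npt", 0.20)
  set("gy", "pe", 0.17);  set("gy", "tp", 0.14);  set("gy", "dff", -0.15)
  set("gy", "lr", -0.15); set("gy", "ltd", 0.18); set("gy", "rwc", 0.15)
  set("gy", "ccm", 0.15)
  set("tp", "npt", 0.90); set("pl", "pw", 0.45);  set("pw", "sf", 0.40)
  set("pw", "hsw", 0.30); set("pl", "hsw", 0.25); set("sf", "hsw", 0.20)
  set("ph", "pl", 0.30);  set("ph", "dff", 0.20); set("lr", "ltd", 0.47)
  set("rwc", "ccm", 0.30); set("lr", "rwc", -0.30); set("sf", "pe", 0.25)
  .dm_nearest_corr(C)
}

## Eigenvalue clipping followed by rescaling to unit diagonal.
.dm_nearest_corr <- function(C, floor = 1e-4) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= floor) return(C)
  v <- pmax(e$values, floor)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  dimnames(M) <- dimnames(C)
  (M + t(M)) / 2
}

## Fixed (non-random) genetic effects of the reference checks, in genetic
## SD units.  Tolerant checks hold yield and spikelet fertility under
## stress, susceptible checks collapse there but perform well irrigated.
.dm_check_effects <- function() {
  list(
    gy = rbind(Control = c(Apo = 0.2, Norungan = 0.2, `CO 53` = 0.2,
                           `Anna (R) 4` = 0.2, `IR 64` = 0.5, Jaya = 0.5,
                           `Pusa 44` = 0.5),
               ROS = c(1.5, 1.2, 0.9, 0.7, -0.8, -1.0, -1.2),
               TPE = c(1.5, 1.2, 0.9, 0.7, -0.8, -1.0, -1.2)),
    sf = rbind(Control = rep(0, 7),
               ROS = c(0.8, 0.7, 0.6, 0.5, -0.6, -0.7, -0.8),
               TPE = c(0.8, 0.7, 0.6, 0.5, -0.6, -0.7, -0.8))
  )
}

#' Build a simulation configuration for an augmented multi-environment trial
#'
#' Returns the full description of the simulated world: trial layout
#' (number of unreplicated test accessions, checks replicated in every
#' block, blocks per environment), per-environment per-trait means,
#' target broad-sense heritabilities and plot CVs, cross-environment and
#' between-trait genetic correlation structure, and the seed.  Variance
#' components are derived from the target heritability and plot CV: with
#' phenotypic variance \eqn{v_p} implied by the CV, the block variance is
#' \eqn{0.01 v_p} and \eqn{v_g = H^2 (v_p - v_{block})},
#' \eqn{v_e = (1 - H^2)(v_p - v_{block})}.
#'
#' @param n_test Number of unreplicated test accessions.
#' @param n_blocks Blocks per environment; every check appears once per
#'   block.
#' @param traits Character vector of trait codes to simulate (subset of
#'   the 14 defaults); useful to speed up simulation studies.
#' @param dropout Probability that a whole plot (all traits of one
#'   environment x block x genotype cell) is lost. Default 0.
#' @param seed Integer seed; simulation is fully deterministic given it.
#' @return Object of class `"sim_config"`.
#' @seealso [default_config()], [simulate_met()]
#' @export
sim_config <- function(n_test = 500L, n_blocks = 10L, traits = NULL,
                       dropout = 0, seed = 20221L) {
  tab <- .dm_trait_table()
  if (!is.null(traits)) {
    bad <- setdiff(traits, tab$trait)
    if (length(bad)) stop("unknown traits: ", paste(bad, collapse = ", "))
    tab <- tab[match(traits, tab$trait), , drop = FALSE]
  }
  trait_names <- tab$trait
  ec_all <- .dm_env_corr()

  mean_m <- as.matrix(tab[, paste0("mean_", .DM_ENVS)])
  h2_m <- as.matrix(tab[, paste0("h2_", .DM_ENVS)])
  cv_m <- as.matrix(tab[, paste0("cv_", .DM_ENVS)])
  dimnames(mean_m) <- dimnames(h2_m) <- dimnames(cv_m) <-
    list(trait_names, .DM_ENVS)

  sigma_p <- abs(mean_m) * cv_m / 100
  v_p <- sigma_p^2
  v_block <- 0.01 * v_p
  v_g <- h2_m * (v_p - v_block)
  v_e <- (1 - h2_m) * (v_p - v_block)

  env_corr <- lapply(trait_names, function(tn) {
    r <- if (tn %in% rownames(ec_all)) ec_all[tn, ] else rep(NA_real_, 3)
    C <- diag(3); dimnames(C) <- list(.DM_ENVS, .DM_ENVS)
    C["Control", "ROS"] <- C["ROS", "Control"] <-
      ifelse(is.na(r[1]), 0, r[1])
    C["Control", "TPE"] <- C["TPE", "Control"] <-
      ifelse(is.na(r[2]), 0, r[2])
    C["ROS", "TPE"] <- C["TPE", "ROS"] <- ifelse(is.na(r[3]), 0, r[3])
    .dm_nearest_corr(C)
  })
  names(env_corr) <- trait_names

  cfg <- structure(list(
    n_test = as.integer(n_test), n_blocks = as.integer(n_blocks),
    environments = data.frame(name = .DM_ENVS,
                              stress = c(FALSE, TRUE, TRUE)),
    checks = data.frame(
      name = c("Apo", "Norungan", "CO 53", "Anna (R) 4",
               "IR 64", "Jaya", "Pusa 44"),
      role = c(rep("tolerant", 4), rep("susceptible", 3))),
    traits = trait_names, trait_labels = tab$label,
    ordinal = tab$trait[tab$ordinal],
    mean = mean_m, h2 = h2_m, cv = cv_m,
    v_g = v_g, v_block = v_block, v_e = v_e,
    env_corr = env_corr, trait_corr = .dm_trait_corr(trait_names),
    check_effects = .dm_check_effects(),
    dropout = dropout, seed = as.integer(seed)),
    class = "sim_config")
  validate_config(cfg)
  cfg
}

#' Default simulation configuration
#'
#' The defaults reproduce the published trial structure: 500 test
#' accessions, 7 checks (4 drought-tolerant, 3 susceptible) replicated in
#' 10 blocks, 3 environments, 14 traits with the reported per-environment
#' means, heritabilities and CVs.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `"sim_config"` object.
#' @examples
#' cfg <- default_config()
#' cfg$mean["gy", "Control"]  # 4.57 t/ha
#' @export
default_config <- function(...) sim_config(...)

#' Validate a simulation configuration
#'
#' Checks layout counts, non-negative variance parameters, and that every
#' correlation matrix is symmetric with unit diagonal and positive
#' semi-definite.
#'
#' @param config A `"sim_config"` object.
#' @return `config`, invisibly; otherwise an error.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_test < 1L) stop("n_test must be >= 1")
  if (config$n_blocks < 2L) stop("n_blocks must be >= 2")
  for (nm in c("v_g", "v_block", "v_e"))
    if (any(config[[nm]] < 0, na.rm = TRUE))
      stop("negative variance parameter in ", nm)
  if (config$dropout < 0 || config$dropout >= 1)
    stop("dropout must be in [0, 1)")
  check_corr <- function(C, what) {
    if (!isTRUE(all.equal(C, t(C), tolerance = 1e-10)))
      stop(what, " correlation matrix not symmetric")
    if (max(abs(diag(C) - 1)) > 1e-10)
      stop(what, " correlation matrix diagonal not 1")
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop(what, " correlation matrix not positive semi-definite")
  }
  check_corr(config$trait_corr, "between-trait")
  for (tn in names(config$env_corr))
    check_corr(config$env_corr[[tn]], paste("cross-environment", tn))
  invisible(config)
}

## Run code with a private RNG stream, restoring global state afterwards.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a multi-environment augmented-RCBD trial
#'
#' Draws correlated genetic effects for the test accessions from a
#' multivariate normal (between-trait correlation within an environment,
#' per-trait cross-environment correlation), assigns fixed role-based
#' genetic effects to the checks (grain yield and spikelet fertility),
#' adds independent block effects and plot residuals, and emits long-format
#' plot records plus the ground truth.  Score-type traits (panicle
#' exsertion, leaf rolling, leaf tip drying) are thresholded from the
#' latent normal onto the 1-9 scale.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer overriding `config$seed`.
#' @return List with `records` (data.frame: `environment`, `block`,
#'   `genotype`, `is_check`, `trait`, `value`) and `truth` (list with
#'   `genetic`: per genotype x environment x trait the genetic effect and
#'   true value on the trait scale, and `components`: per environment x
#'   trait the true `v_g`, `v_block`, `v_e`).
#' @examples
#' sim <- simulate_met(sim_config(n_test = 20, n_blocks = 3,
#'                                traits = c("gy", "sf")), seed = 7)
#' head(sim$records)
#' @export
simulate_met <- function(config, seed = NULL) {
  validate_config(config)
  if (is.null(seed)) seed <- config$seed
  .with_seed(seed, {
    envs <- config$environments$name
    n_env <- length(envs)
    traits <- config$traits
    n_tr <- length(traits)
    checks <- config$checks$name
    genos <- c(sprintf("ACC%03d", seq_len(config$n_test)), checks)
    n_g <- length(genos)
    is_chk <- genos %in% checks

    ## latent genetic effects, unit scale -------------------------------
    Lt <- chol(config$trait_corr + diag(1e-10, n_tr))
    E <- array(0, c(n_g, n_env, n_tr),
               dimnames = list(genos, envs, traits))
    for (e in seq_len(n_env))
      E[, e, ] <- matrix(stats::rnorm(n_g * n_tr), n_g, n_tr) %*% Lt
    G <- array(0, c(n_g, n_env, n_tr),
               dimnames = list(genos, envs, traits))
    for (t in seq_len(n_tr)) {
      Le <- t(chol(config$env_corr[[t]] + diag(1e-10, n_env)))
      G[, , t] <- E[, , t] %*% t(Le)
    }

    ## scale by genetic SD; overwrite checks with fixed role effects ----
    sg <- sqrt(config$v_g)                     # trait x env, NA if absent
    for (t in seq_len(n_tr)) for (e in seq_len(n_env)) {
      s <- sg[traits[t], envs[e]]
      G[, e, t] <- if (is.na(s)) NA_real_ else G[, e, t] * s
      ce <- config$check_effects[[traits[t]]]
      if (!is.null(ce) && !is.na(s))
        G[checks, e, t] <- ce[envs[e], ] * s
    }
    ## checks keep their drawn values for traits without role effects
    ## (they behave as ordinary genotypes for neutral traits)

    ## field layout ------------------------------------------------------
    nb <- config$n_blocks
    test_names <- genos[!is_chk]
    plots <- do.call(rbind, lapply(envs, function(ev) {
      tb <- data.frame(environment = ev,
                       block = sample(rep(seq_len(nb),
                                          length.out = length(test_names))),
                       genotype = test_names, is_check = FALSE)
      cb <- expand.grid(genotype = checks, block = seq_len(nb),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      cb <- data.frame(environment = ev, block = cb$block,
                       genotype = cb$genotype, is_check = TRUE)
      rbind(tb, cb)
    }))

    if (config$dropout > 0) {
      keep <- stats::runif(nrow(plots)) >= config$dropout
      plots <- plots[keep, , drop = FALSE]
    }

    ## observations ------------------------------------------------------
    rec <- vector("list", n_env * n_tr)
    k <- 0L
    for (e in seq_len(n_env)) {
      pe <- plots[plots$environment == envs[e], , drop = FALSE]
      bl_eff <- matrix(stats::rnorm(nb * n_tr), nb, n_tr)
      for (t in seq_len(n_tr)) {
        tn <- traits[t]
        mu <- config$mean[tn, envs[e]]
        if (is.na(mu)) next
        sb <- sqrt(config$v_block[tn, envs[e]])
        se <- sqrt(config$v_e[tn, envs[e]])
        val <- mu + G[pe$genotype, e, t] + sb * bl_eff[pe$block, t] +
          se * stats::rnorm(nrow(pe))
        if (tn %in% config$ordinal) val <- pmin(pmax(round(val), 1), 9)
        k <- k + 1L
        rec[[k]] <- data.frame(pe, trait = tn, value = val,
                               row.names = NULL)
      }
    }
    records <- do.call(rbind, rec[seq_len(k)])
    rownames(records) <- NULL

    ## ground truth ------------------------------------------------------
    gt <- expand.grid(genotype = genos, environment = envs, trait = traits,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gt$genetic_effect <- G[cbind(gt$genotype, gt$environment, gt$trait)]
    gt$true_value <- config$mean[cbind(gt$trait, gt$environment)] +
      gt$genetic_effect
    gt <- gt[!is.na(gt$genetic_effect), , drop = FALSE]
    rownames(gt) <- NULL

    comp <- expand.grid(environment = envs, trait = traits,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    idx <- cbind(comp$trait, comp$environment)
    comp$v_g <- config$v_g[idx]
    comp$v_block <- config$v_block[idx]
    comp$v_e <- config$v_e[idx]
    comp <- comp[!is.na(comp$v_g), , drop = FALSE]
    rownames(comp) <- NULL

    list(records = records,
         truth = list(genetic = gt, components = comp),
         config = config, seed = seed)
  })
}

#' Descriptive summary of plot records
#'
#' Per environment x trait: mean, min, max and plot-level CV
#' (`100 * sd / mean`; reported missing when the mean is zero).
#'
#' @param records Plot records as produced by [simulate_met()] (or read
#'   with [read_phenotypes()]).
#' @return data.frame with `environment`, `trait`, `mean`, `min`, `max`,
#'   `cv`, `n`.
#' @export
realized_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  sp <- split(records$value,
              list(records$environment, records$trait), drop = TRUE)
  out <- do.call(rbind, lapply(names(sp), function(nm) {
    v <- sp[[nm]]; v <- v[is.finite(v)]
    key <- strsplit(nm, ".", fixed = TRUE)[[1]]
    m <- mean(v)
    data.frame(environment = key[1], trait = paste(key[-1], collapse = "."),
               mean = m, min = min(v), max = max(v),
               cv = if (abs(m) < .Machine$double.eps^0.5) NA_real_
                    else 100 * stats::sd(v) / m,
               n = length(v))
  }))
  rownames(out) <- NULL
  out[order(out$trait, out$environment), ]
}
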