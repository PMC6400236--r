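# Orchestration of the three experiments from one seeded configuration:
# (1) raw-data central-tendency vs tail modeling, (2) tail modeling of
# large generated populations (direct + MCMC), (3) the indicator-function
# classification study.

#' Experiment configuration
#'
#' Bundles the study conditions with every tunable the experiments use.
#' All randomness derives from `seed` through stage-name-keyed sub-seeds
#' ([derive_seed()]), so runs are byte-reproducible and adding a stage
#' never perturbs earlier streams.
#'
#' @param study a [study_config()] (default [canonical_config()]).
#' @param n_samples generated population size per condition per sampler
#'   method (default 100000).
#' @param raw_n top-n values for raw-data tail fits (default `c(3, 8)`).
#' @param sampled_n top-n values for generated-population tail fits
#'   (default `c(50, 250)`).
#' @param threshold_T response threshold (default the study's).
#' @param mcmc list of Metropolis-Hastings options: `proposal_sd` (`NULL`
#'   = automatic), `burn_in`, `thin`.
#' @param classifier list of indicator options (`C`, `hidden`, `epochs`).
#' @param n_repeats evaluation repeats per classifier setting.
#' @param train_frac training fraction for the indicator study.
#' @param feature_dim classifier feature dimension (default 22).
#' @param force_paper_families fit Gaussian to the olfaction condition and
#'   Generalized Pareto to the control condition (the pairing the
#'   normality-plus-BIC analysis selects on data of this structure;
#'   default `TRUE`). With `FALSE` each condition's generative family
#'   follows the normality battery and BIC selection, which must then
#'   pick a samplable family (Gaussian, Weibull or GPD).
#' @param seed global seed.
#' @return an object of class `"experiment_config"`.
#' @export
experiment_config <- function(study = canonical_config(), n_samples = 100000L,
                              raw_n = c(3L, 8L), sampled_n = c(50L, 250L),
                              threshold_T = study$threshold_T,
                              mcmc = list(proposal_sd = NULL,
                                          burn_in = 1000L, thin = 10L),
                              classifier = list(C = 4, hidden = 16L,
                                                epochs = 200L),
                              n_repeats = 5L, train_frac = 0.8,
                              feature_dim = 22L,
                              force_paper_families = TRUE, seed = 101L) {
  validate_study_config(study)
  if (length(raw_n) == 0L || length(sampled_n) == 0L)
    stop_domain("experiment_config: n-lists must be non-empty")
  if (!all(vapply(c(raw_n, sampled_n), is_count, logical(1), min = 3L)))
    stop_domain("experiment_config: tail n values must be integers >= 3")
  if (!is_count(n_samples, 1L))
    stop_domain("experiment_config: n_samples must be >= 1")
  structure(list(study = study, n_samples = as.integer(n_samples),
                 raw_n = as.integer(raw_n), sampled_n = as.integer(sampled_n),
                 threshold_T = threshold_T, mcmc = mcmc,
                 classifier = classifier, n_repeats = as.integer(n_repeats),
                 train_frac = train_frac, feature_dim = as.integer(feature_dim),
                 force_paper_families = isTRUE(force_paper_families),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

new_report <- function(id, ...) {
  structure(list(id = id, ...), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment report:", x$id, "\n")
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    tab <- x$tables[[nm]]
    if (is.data.frame(tab) && nrow(tab) > 12L) {
      print(head(tab, 12L), row.names = FALSE, digits = 4)
      cat(sprintf("  ... %d rows\n", nrow(tab)))
    } else print(tab, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

stage_log <- function(stage, seed, n, t0) {
  message(sprintf("[evtgate] stage=%s seed=%s n=%s elapsed=%.2fs", stage,
                  seed, n, as.numeric(Sys.time()) - t0))
}

# fit the per-condition generative distributions from a raw data pair
condition_distributions <- function(cfg, data) {
  if (cfg$force_paper_families) {
    return(list(
      olfaction = dist_spec("gaussian", fit_gaussian(data$olfaction$values)),
      control = dist_spec("generalized pareto",
                          fit_gpd_mle(data$control$values, tau = 0))))
  }
  pick <- function(values) {
    rep <- normality_battery(values)
    if (rep$normal)
      return(dist_spec("gaussian", fit_gaussian(values)))
    sel <- select_distribution(values, catalog_families(FALSE))
    fam <- sel$ranked$family[1L]
    if (!fam %in% c("gaussian", "weibull", "generalized pareto"))
      stop_domain("condition_distributions: BIC selected '", fam,
                  "', which has no generative sampler; use ",
                  "force_paper_families = TRUE")
    p <- sel$fits[[fam]]
    dist_spec(fam, switch(fam,
      weibull = weibull_params(p$shape, p$scale),
      `generalized pareto` = gpd_params(p$shape, p$scale, 0),
      gaussian = gaussian_params(p$mu, p$sigma2)))
  }
  list(olfaction = pick(data$olfaction$values),
       control = pick(data$control$values))
}

#' Experiment 1: central-tendency vs extreme-value modeling of raw data
#'
#' Fits a Gaussian to each full condition series and Weibull tail models
#' to the top-n responses for each `n` in the raw n-list, and tabulates
#' every model's CDF at the response threshold along with full CDF
#' curves on the response axis. With olfactory stimulation the Weibull
#' tail curve should assign markedly higher probability at the threshold
#' than the Gaussian fitted to the same data -- the leftward sensitivity
#' shift.
#'
#' @param cfg an [experiment_config()].
#' @param data list with `olfaction` and `control` [response_series()].
#' @return an `"experiment_report"` with tables `threshold` (model
#'   probabilities at `threshold_T`) and `curves`, plus the fitted
#'   models.
#' @export
run_experiment1 <- function(cfg, data) {
  t0 <- as.numeric(Sys.time())
  conditions <- list(olfaction = data$olfaction, control = data$control)
  if (any(vapply(conditions, function(s) length(s$values),
                 integer(1)) < max(cfg$raw_n)))
    stop_domain("run_experiment1: a series is shorter than max(raw_n)")
  T_ <- cfg$threshold_T
  gaussians <- lapply(conditions, function(s) fit_gaussian(s$values))
  tails <- list()
  rows <- list()
  hi <- max(vapply(conditions, function(s) max(s$values), numeric(1)))
  curves <- list()
  for (cond in names(conditions)) {
    g <- gaussians[[cond]]
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, model = "gaussian", n_top = NA_integer_,
      probability = pnorm(T_, g$mu, sqrt(g$sigma2)))
    grid <- seq(0, hi * 1.1, length.out = 257L)
    curves[[length(curves) + 1L]] <- data.frame(
      condition = cond, model = "gaussian", response = grid,
      probability = pnorm(grid, g$mu, sqrt(g$sigma2)))
    for (n in cfg$raw_n) {
      tm <- fit_tail(conditions[[cond]]$values, n, condition = cond)
      tails[[paste0(cond, "_top", n)]] <- tm
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, model = paste0("weibull_top", n), n_top = n,
        probability = response_probability(tm, T_))
      cv <- tail_cdf_curve(tm, 0, hi * 1.1, 257L)
      curves[[length(curves) + 1L]] <- data.frame(
        condition = cond, model = paste0("weibull_top", n),
        response = cv$response, probability = cv$probability)
    }
  }
  stage_log("experiment1", "-", paste(lengths(lapply(conditions, `[[`,
                                                     "values")),
                                      collapse = "/"), t0)
  new_report("experiment1",
             threshold_T = T_,
             tables = list(threshold = do.call(rbind, rows),
                           curves = do.call(rbind, curves)),
             models = list(gaussian = gaussians, tails = tails))
}

#' Experiment 2: tail modeling of large generated populations
#'
#' Generates `n_samples` non-negative responses per condition with each
#' sampler method (direct and Metropolis-Hastings) from the fitted
#' per-condition distributions, fits Weibull tail models to the top-n
#' samples for each `n` in the sampled n-list, and tabulates the
#' olfaction-minus-control separation of tail probabilities at the
#' threshold per method and `n`.
#'
#' @param cfg an [experiment_config()].
#' @param data raw series pair; `NULL` generates them from `cfg$study`.
#' @param dists optional precomputed [condition_distributions()] result.
#' @return an `"experiment_report"` with tables `separation` and
#'   `curves`, the fitted tail models, and sampler acceptance rates.
#' @export
run_experiment2 <- function(cfg, data = NULL, dists = NULL) {
  t0 <- as.numeric(Sys.time())
  if (is.null(data))
    data <- generate_responses(cfg$study, derive_seed(cfg$seed, "data"))
  if (is.null(dists)) dists <- condition_distributions(cfg, data)
  T_ <- cfg$threshold_T
  tails <- list(); rows <- list(); curves <- list(); acc <- list()
  probs <- list()
  for (method in c("direct", "mcmc")) {
    for (cond in c("olfaction", "control")) {
      s <- derive_seed(cfg$seed, paste("exp2", method, cond))
      scfg <- sampler_config(method, cfg$n_samples, seed = s, nonneg = TRUE,
                             proposal_sd = cfg$mcmc$proposal_sd,
                             burn_in = cfg$mcmc$burn_in,
                             thin = cfg$mcmc$thin)
      ss <- if (method == "direct") draw_direct(dists[[cond]], scfg)
            else draw_mcmc(dists[[cond]], scfg)
      acc[[paste(method, cond, sep = "_")]] <- ss$acceptance_rate
      for (n in cfg$sampled_n) {
        tm <- fit_tail(ss$values, n, condition = cond)
        tails[[paste(method, cond, "top", n, sep = "_")]] <- tm
        probs[[paste(method, cond, n, sep = "_")]] <-
          response_probability(tm, T_)
        cv <- tail_cdf_curve(tm, 0, max(ss$values) * 1.05, 257L)
        curves[[length(curves) + 1L]] <- data.frame(
          method = method, condition = cond,
          model = paste0("weibull_top", n),
          response = cv$response, probability = cv$probability)
      }
    }
    for (n in cfg$sampled_n) {
      p_olf <- probs[[paste(method, "olfaction", n, sep = "_")]]
      p_ctrl <- probs[[paste(method, "control", n, sep = "_")]]
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, n_top = n, p_olfaction = p_olf,
        p_control = p_ctrl, separation = p_olf - p_ctrl)
    }
  }
  stage_log("experiment2", cfg$seed, cfg$n_samples, t0)
  new_report("experiment2",
             threshold_T = T_,
             tables = list(separation = do.call(rbind, rows),
                           curves = do.call(rbind, curves)),
             models = tails, acceptance_rates = acc,
             dists = dists, seed = cfg$seed)
}

#' Experiment 3: the indicator function as a binary classifier
#'
#' Builds labeled datasets of `feature_dim`-dimensional response vectors
#' from generated per-condition populations and evaluates the three
#' classifier settings of the study -- linear SVM on directly sampled
#' data, linear SVM on MCMC-sampled data, and MLP on MCMC-sampled data --
#' with repeated stratified train/test splits.
#'
#' @param cfg an [experiment_config()].
#' @param data raw series pair; `NULL` generates them from `cfg$study`.
#' @param dists optional precomputed [condition_distributions()] result.
#' @return an `"experiment_report"` with an `accuracy` table and the
#'   three `"eval_result"` objects (`svm_direct`, `svm_mcmc`,
#'   `mlp_mcmc`).
#' @export
run_experiment3 <- function(cfg, data = NULL, dists = NULL) {
  t0 <- as.numeric(Sys.time())
  if (is.null(data))
    data <- generate_responses(cfg$study, derive_seed(cfg$seed, "data"))
  if (is.null(dists)) dists <- condition_distributions(cfg, data)
  factory <- function(method) {
    force(method)
    function(seed) {
      draw1 <- function(cond, s) {
        scfg <- sampler_config(method, cfg$n_samples, seed = s,
                               nonneg = TRUE,
                               proposal_sd = cfg$mcmc$proposal_sd,
                               burn_in = cfg$mcmc$burn_in,
                               thin = cfg$mcmc$thin)
        if (method == "direct") draw_direct(dists[[cond]], scfg)
        else draw_mcmc(dists[[cond]], scfg)
      }
      olf <- draw1("olfaction", derive_seed(seed, "olf"))
      ctrl <- draw1("control", derive_seed(seed, "ctrl"))
      suppressMessages(assemble_dataset(olf, ctrl, dim = cfg$feature_dim,
                                        seed = derive_seed(seed, "shuffle")))
    }
  }
  settings <- list(
    svm_direct = list(kind = "linear_svm", method = "direct"),
    svm_mcmc = list(kind = "linear_svm", method = "mcmc"),
    mlp_mcmc = list(kind = "mlp", method = "mcmc"))
  evals <- lapply(names(settings), function(nm) {
    st <- settings[[nm]]
    repeat_eval(factory(st$method), kind = st$kind, config = cfg$classifier,
                n_repeats = cfg$n_repeats,
                base_seed = derive_seed(cfg$seed, paste("exp3", nm)),
                train_frac = cfg$train_frac)
  })
  names(evals) <- names(settings)
  tab <- do.call(rbind, lapply(names(evals), function(nm) data.frame(
    setting = nm, kind = evals[[nm]]$kind,
    mean_accuracy = evals[[nm]]$mean, spread_sd = evals[[nm]]$spread,
    n_repeats = evals[[nm]]$n_repeats)))
  stage_log("experiment3", cfg$seed, cfg$n_samples, t0)
  new_report("experiment3", tables = list(accuracy = tab), evals = evals,
             dists = dists, seed = cfg$seed)
}

#' Run the whole analysis end to end
#'
#' Generates (or accepts) the raw per-condition series, runs the
#' normality battery on each condition and BIC selection on any condition
#' that fails it, then experiments 1-3 in order. Any stage error aborts
#' with the stage identifier. With `output_dir` set, all report tables
#' are written as CSV and report summaries as JSON (byte-identical across
#' runs with the same config).
#'
#' @param cfg an [experiment_config()].
#' @param data raw series pair; `NULL` generates them from `cfg$study`.
#' @param output_dir optional artifact directory.
#' @return a named list of four reports: `selection`, `experiment1`,
#'   `experiment2`, `experiment3`.
#' @export
run_all <- function(cfg, data = NULL, output_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  stage <- function(id, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", id, " failed: ", conditionMessage(e), call. = FALSE))
  }
  t0 <- as.numeric(Sys.time())
  data <- stage("data", {
    if (is.null(data)) generate_responses(cfg$study,
                                          derive_seed(cfg$seed, "data"))
    else data
  })
  selection <- stage("selection", {
    norm <- lapply(list(olfaction = data$olfaction, control = data$control),
                   function(s) normality_battery(s$values))
    sel <- lapply(names(norm), function(cond) {
      if (norm[[cond]]$normal) NULL
      else select_distribution(data[[cond]]$values, catalog_families(FALSE))
    })
    names(sel) <- names(norm)
    nt <- do.call(rbind, lapply(names(norm), function(cond) {
      tab <- norm[[cond]]$tests
      tab$condition <- cond
      tab
    }))
    ranked <- do.call(rbind, lapply(names(sel), function(cond) {
      if (is.null(sel[[cond]])) return(NULL)
      tab <- sel[[cond]]$ranked
      tab$condition <- cond
      tab
    }))
    stage_log("selection", "-", "-", t0)
    new_report("selection",
               tables = list(normality = nt, bic_ranking = ranked),
               normality = norm, selections = sel)
  })
  dists <- stage("distributions", condition_distributions(cfg, data))
  exp1 <- stage("experiment1", run_experiment1(cfg, data))
  exp2 <- stage("experiment2", run_experiment2(cfg, data, dists))
  exp3 <- stage("experiment3", run_experiment3(cfg, data, dists))
  reports <- list(selection = selection, experiment1 = exp1,
                  experiment2 = exp2, experiment3 = exp3)
  if (!is.null(output_dir)) write_reports(reports, cfg, output_dir)
  reports
}

report_to_list <- function(report) {
  out <- list(id = report$id)
  if (!is.null(report$threshold_T)) out$threshold_T <- report$threshold_T
  if (!is.null(report$seed)) out$seed <- report$seed
  out$tables <- lapply(report$tables, function(tab) {
    if (is.null(tab)) NULL else tab
  })
  if (!is.null(report$acceptance_rates))
    out$acceptance_rates <- report$acceptance_rates
  if (!is.null(report$models)) {
    tails <- report$models$tails %||%
      Filter(function(m) inherits(m, "evt_tail"), report$models)
    if (length(tails) > 0L)
      out$tail_models <- lapply(tails, function(m) as.list(coef(m)))
  }
  if (!is.null(report$evals))
    out$evals <- lapply(report$evals, function(ev)
      list(mean = ev$mean, spread = ev$spread,
           accuracies = ev$accuracies, kind = ev$kind))
  out
}

#' Write a set of experiment reports to disk
#'
#' One `<id>.json` summary per report plus one `<id>_<table>.csv` per
#' table. Output contains no timestamps, so repeated runs with the same
#' configuration produce byte-identical artifacts.
#'
#' @param reports named list of `"experiment_report"`s (from
#'   [run_all()]).
#' @param cfg the [experiment_config()] used (serialized alongside).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(reports, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(reports)) {
    rep <- reports[[nm]]
    jsonlite::write_json(report_to_list(rep),
                         file.path(dir, paste0(rep$id, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    for (tab in names(rep$tables)) {
      if (is.null(rep$tables[[tab]])) next
      write.csv(rep$tables[[tab]],
                file.path(dir, paste0(rep$id, "_", tab, ".csv")),
                row.names = FALSE)
    }
  }
  cfg_out <- unclass(cfg)
  cfg_out$study <- {
    s <- unclass(cfg$study)
    s$olf_gaussian <- unclass(s$olf_gaussian)
    s$ctrl_gpd <- unclass(s$ctrl_gpd)
    s
  }
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
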