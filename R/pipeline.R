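#' Load a study from input files
#'
#' Assembles the object the analysis stages consume: MCC tree, posterior
#' ensemble, accession records and variable groups.
#'
#' @param mcc Path to the MCC Newick file.
#' @param posterior Optional path to a multi-tree Newick file.
#' @param accessions Path to the accession-level CSV/TSV.
#' @param groups Optional path to a YAML/JSON variable-group map (default
#'   [default_variable_groups()]).
#' @inheritParams parse_newick
#' @return A study list (`mcc`, `posterior`, `records`, `groups`).
#' @export
load_study <- function(mcc, posterior = NULL, accessions, groups = NULL,
                       ultrametric = "error", rel_tol = 1e-6) {
  ens <- read_tree_ensemble(mcc, posterior, ultrametric = ultrametric,
                            rel_tol = rel_tol)
  records <- read_accessions(accessions)
  g <- if (is.null(groups)) default_variable_groups()
       else read_variable_groups(groups)
  list(mcc = ens$mcc, posterior = ens$posterior, records = records,
       groups = g)
}

# All trees of a study as a named list: "mcc", "post_1", "post_2", ...
.study_trees <- function(study, n_posterior_used = NULL) {
  post <- study$posterior
  if (!is.null(n_posterior_used) && length(post) > n_posterior_used)
    post <- post[seq_len(n_posterior_used)]
  trees <- c(list(mcc = study$mcc), stats::setNames(
    as.list(post), if (length(post)) paste0("post_", seq_along(post))
                   else character(0)))
  trees
}

.study_variables <- function(study, variables = NULL) {
  if (!is.null(variables)) return(variables)
  grep("^bio[0-9]+$", names(study$records), value = TRUE)
}

# Run fun(variable, tree_id, tree) over the grid, quarantining failures so
# one optimizer corner case cannot sink a 19 x 1001 run. Results are bound
# in deterministic (variable, tree) order; errors are collected in the
# "errors" attribute.
.per_variable_tree <- function(study, variables, trees, fun) {
  rows <- list(); errors <- list()
  for (v in variables) {
    for (ti in seq_along(trees)) {
      tid <- names(trees)[ti]
      res <- tryCatch(fun(v, tid, trees[[ti]]),
                      error = function(e)
                        structure(conditionMessage(e), class = "stage_error"))
      if (inherits(res, "stage_error")) {
        errors[[paste(v, tid, sep = "|")]] <- as.character(res)
      } else rows[[paste(v, tid, sep = "|")]] <- res
    }
  }
  if (!length(rows) && length(errors))
    stop("all (variable, tree) analyses failed; first error: ",
         errors[[1]], call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Phylogenetic-signal stage
#'
#' Blomberg's K with pooled sampling error and a tip-randomization p-value
#' for every (variable, tree) combination — the tabular counterpart of a
#' per-variable signal figure over the MCC tree and posterior ensemble.
#'
#' @param study A study list ([load_study()] or [simulate_study()]).
#' @param variables Variables to analyze (default: all bio columns).
#' @param n_rand Randomizations per test (default 1000).
#' @param n_posterior_used Number of posterior trees to use (default all).
#' @param seed Base seed; per-(variable, tree) seeds derive from it.
#' @param se_formula Passed to [trait_summary()].
#' @param use_se Fold pooled sampling errors into K (default TRUE).
#' @param outdir Optional directory; writes `signal.csv`.
#' @return data.frame (variable, tree_id, K, p, n_rand, sigma2_hat), with
#'   any quarantined failures in `attr(, "errors")`.
#' @export
run_signal_stage <- function(study, variables = NULL, n_rand = 1000,
                             n_posterior_used = NULL, seed,
                             se_formula = "sd_over_sqrt_n", use_se = TRUE,
                             outdir = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  variables <- .study_variables(study, variables)
  trees <- .study_trees(study, n_posterior_used)
  summ <- trait_summary(study$records, variables, se_formula = se_formula)
  out <- .per_variable_tree(study, variables, trees, function(v, tid, tree) {
    x <- trait_vector(summ, v, "mean")
    se <- if (use_se) trait_vector(summ, v, "se") else 0
    r <- k_randomization_test(tree, x, se, n_rand = n_rand,
                              seed = derive_seed(seed, "signal", v, tid))
    data.frame(variable = v, tree_id = tid, K = r$K, p = r$p,
               n_rand = r$n_rand, sigma2_hat = r$sigma2_hat,
               stringsAsFactors = FALSE)
  })
  if (!is.null(outdir))
    write_report_csv(out, file.path(outdir, "signal.csv"),
                     meta = list(stage = "signal", seed = seed,
                                 n_rand = n_rand))
  out
}

#' Disparity-through-time stage
#'
#' DTT curves, MDI and its one-sided BM-simulation test per (variable,
#' tree). The MCC curve and envelope per variable are returned (and
#' written) alongside the MDI summary table.
#'
#' @inheritParams run_signal_stage
#' @param n_sim BM simulations per test (default 1000).
#' @return List: `summary` data.frame (variable, tree_id, MDI, p,
#'   one_minus_p, n_sim), `curves` — per-variable data.frames of the MCC
#'   curve and envelope.
#' @export
run_dtt_stage <- function(study, variables = NULL, n_sim = 1000,
                          n_posterior_used = NULL, seed, outdir = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  variables <- .study_variables(study, variables)
  trees <- .study_trees(study, n_posterior_used)
  summ <- trait_summary(study$records, variables)
  curves <- list()
  out <- .per_variable_tree(study, variables, trees, function(v, tid, tree) {
    x <- trait_vector(summ, v, "mean")
    r <- dtt_test(tree, x, n_sim = n_sim,
                  seed = derive_seed(seed, "dtt", v, tid))
    if (tid == "mcc")
      curves[[v]] <<- data.frame(variable = v, rel_time = r$rel_times,
                                 observed = r$observed,
                                 sim_median = r$sim_median,
                                 sim_lo95 = r$sim_lo95,
                                 sim_hi95 = r$sim_hi95)
    data.frame(variable = v, tree_id = tid, MDI = r$MDI, p = r$p,
               one_minus_p = 1 - r$p, n_sim = r$n_sim,
               stringsAsFactors = FALSE)
  })
  if (!is.null(outdir)) {
    write_report_csv(out, file.path(outdir, "dtt_summary.csv"),
                     meta = list(stage = "dtt", seed = seed, n_sim = n_sim))
    write_report_csv(do.call(rbind, curves),
                     file.path(outdir, "dtt_curves.csv"),
                     meta = list(stage = "dtt", seed = seed))
  }
  list(summary = out, curves = curves)
}

#' Model-fitting stage
#'
#' Fits BM, OU and EB with sampling error to every (variable, tree), with
#' AICc weights and a best-model registry for the rates stage.
#'
#' @inheritParams run_signal_stage
#' @param basis Which per-OTU statistic to fit: `"mean"` (default),
#'   `"min"`, or `"max"`.
#' @return List: `fits` data.frame (variable, tree_id, model, sigma2, z0,
#'   alpha, a, lnL, AICc, weight, best), `best` — named list of
#'   `model_fit` objects keyed `variable|tree_id`.
#' @export
run_model_stage <- function(study, variables = NULL,
                            n_posterior_used = NULL, seed = 0,
                            se_formula = "sd_over_sqrt_n", use_se = TRUE,
                            basis = "mean", outdir = NULL) {
  variables <- .study_variables(study, variables)
  trees <- .study_trees(study, n_posterior_used)
  summ <- trait_summary(study$records, variables, se_formula = se_formula)
  registry <- list()
  out <- .per_variable_tree(study, variables, trees, function(v, tid, tree) {
    x <- trait_vector(summ, v, basis)
    se <- if (use_se) trait_vector(summ, v, "se") else 0
    fits <- fit_all_models(tree, x, se)
    best <- attr(fits, "best")
    registry[[paste(v, tid, sep = "|")]] <<- fits[[best]]
    do.call(rbind, lapply(names(fits), function(m) {
      f <- fits[[m]]
      data.frame(variable = v, tree_id = tid, model = m,
                 sigma2 = f$sigma2, z0 = f$z0,
                 alpha = if (is.null(f$alpha)) NA_real_ else f$alpha,
                 a = if (is.null(f$a)) NA_real_ else f$a,
                 lnL = f$lnL, AICc = f$AICc, weight = f$weight,
                 best = (m == best), stringsAsFactors = FALSE)
    }))
  })
  if (!is.null(outdir))
    write_report_csv(out, file.path(outdir,
                                    paste0("model_fits_", basis, ".csv")),
                     meta = list(stage = "models", basis = basis,
                                 seed = seed))
  list(fits = out, best = registry)
}

#' Rates stage
#'
#' Absolute per-tip rates of niche change for the configured variables and
#' bases (per-OTU mean/min/max), with models re-fit per basis and ancestors
#' reconstructed on the best-fit covariance; plus paired diffusion-rate
#' (sigma2) comparisons with HPD summaries across the ensemble.
#'
#' @inheritParams run_signal_stage
#' @param rate_variables Variables for absolute rates (default bio1, bio5,
#'   bio6 — the thermal trio).
#' @param bases Per-OTU statistics to run (default mean, min, max).
#' @param pairs List of 2-vectors of variables for sigma2 comparison
#'   (default BIO5 vs BIO6 and BIO16 vs BIO17).
#' @param model_stage Optional precomputed [run_model_stage()] result for
#'   `basis = "mean"`, reused to avoid refitting.
#' @param hpd_mass HPD mass (default 0.95).
#' @return List: `rates` (variable, basis, tree_id, tip_label, rate),
#'   `rate_summary` (per tip: MCC rate + ensemble HPD), `sigma2_pairs`.
#' @export
run_rates_stage <- function(study, rate_variables = c("bio1", "bio5", "bio6"),
                            bases = c("mean", "min", "max"),
                            pairs = list(c("bio5", "bio6"),
                                         c("bio16", "bio17")),
                            n_posterior_used = NULL, seed = 0,
                            se_formula = "sd_over_sqrt_n", use_se = TRUE,
                            model_stage = NULL, hpd_mass = 0.95,
                            outdir = NULL) {
  trees <- .study_trees(study, n_posterior_used)
  all_vars <- unique(c(rate_variables, unlist(pairs)))
  summ <- trait_summary(study$records, all_vars, se_formula = se_formula)

  stage_for <- function(vars, basis) {
    if (basis == "mean" && !is.null(model_stage)) return(model_stage)
    run_model_stage(study, variables = vars,
                    n_posterior_used = n_posterior_used, seed = seed,
                    se_formula = se_formula, use_se = use_se, basis = basis)
  }

  rate_rows <- list()
  for (basis in bases) {
    ms <- stage_for(rate_variables, basis)
    for (v in rate_variables) {
      x_all <- trait_vector(summ, v, basis)
      se <- if (use_se) trait_vector(summ, v, "se") else 0
      for (tid in names(trees)) {
        fit <- ms$best[[paste(v, tid, sep = "|")]]
        if (is.null(fit)) next
        rt <- absolute_tip_rates(trees[[tid]], x_all, fit, se = se)
        rate_rows[[paste(v, basis, tid, sep = "|")]] <-
          data.frame(variable = v, basis = basis, tree_id = tid,
                     tip_label = rt$tip_label, rate = rt$rate,
                     stringsAsFactors = FALSE)
      }
    }
  }
  rates <- do.call(rbind, rate_rows)
  rownames(rates) <- NULL

  # per-tip summary: MCC value plus HPD across posterior trees
  key <- interaction(rates$variable, rates$basis, rates$tip_label,
                     drop = TRUE)
  rate_summary <- do.call(rbind, lapply(split(rates, key), function(d) {
    mccv <- d$rate[d$tree_id == "mcc"]
    postv <- d$rate[d$tree_id != "mcc"]
    h <- if (sum(is.finite(postv)) >= 2) hpd_interval(postv, hpd_mass)
         else list(lo = NA_real_, hi = NA_real_)
    data.frame(variable = d$variable[1], basis = d$basis[1],
               tip_label = d$tip_label[1],
               rate_mcc = if (length(mccv)) mccv else NA_real_,
               hpd_lo = h$lo, hpd_hi = h$hi, stringsAsFactors = FALSE)
  }))
  rownames(rate_summary) <- NULL

  ms_mean <- stage_for(unique(unlist(pairs)), "mean")
  sigma2_pairs <- do.call(rbind, lapply(pairs, function(pr) {
    pick <- function(v) {
      ids <- names(trees)
      data.frame(tree_id = ids,
                 sigma2 = vapply(ids, function(tid) {
                   f <- ms_mean$best[[paste(v, tid, sep = "|")]]
                   if (is.null(f)) NA_real_ else f$sigma2
                 }, numeric(1)), stringsAsFactors = FALSE)
    }
    cmp <- compare_sigma2(pick(pr[1]), pick(pr[2]), mass = hpd_mass)
    data.frame(var_A = pr[1], var_B = pr[2],
               sigma2_mcc_A = cmp$mcc_A, sigma2_mcc_B = cmp$mcc_B,
               hpd_lo_A = cmp$hpd_A$lo, hpd_hi_A = cmp$hpd_A$hi,
               hpd_lo_B = cmp$hpd_B$lo, hpd_hi_B = cmp$hpd_B$hi,
               frac_A_lt_B = cmp$frac_A_lt_B,
               hpd_overlap = cmp$hpd_overlap, stringsAsFactors = FALSE)
  }))

  if (!is.null(outdir)) {
    write_report_csv(rates, file.path(outdir, "tip_rates.csv"),
                     meta = list(stage = "rates", seed = seed))
    write_report_csv(rate_summary, file.path(outdir, "tip_rate_summary.csv"),
                     meta = list(stage = "rates", seed = seed,
                                 hpd_mass = hpd_mass))
    write_report_csv(sigma2_pairs, file.path(outdir, "sigma2_pairs.csv"),
                     meta = list(stage = "rates", seed = seed))
  }
  list(rates = rates, rate_summary = rate_summary,
       sigma2_pairs = sigma2_pairs)
}

#' Run the full pipeline
#'
#' Signal, DTT, model fitting and rates over a study, writing all tabular
#' reports into `outdir`.
#'
#' @inheritParams run_signal_stage
#' @inheritParams run_dtt_stage
#' @inheritParams run_rates_stage
#' @return List of the four stage results.
#' @export
run_all <- function(study, variables = NULL, n_rand = 1000, n_sim = 1000,
                    n_posterior_used = NULL, seed,
                    rate_variables = c("bio1", "bio5", "bio6"),
                    pairs = list(c("bio5", "bio6"), c("bio16", "bio17")),
                    se_formula = "sd_over_sqrt_n", use_se = TRUE,
                    hpd_mass = 0.95, outdir = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  signal <- run_signal_stage(study, variables, n_rand = n_rand,
                             n_posterior_used = n_posterior_used,
                             seed = seed, se_formula = se_formula,
                             use_se = use_se, outdir = outdir)
  dtt <- run_dtt_stage(study, variables, n_sim = n_sim,
                       n_posterior_used = n_posterior_used, seed = seed,
                       outdir = outdir)
  models <- run_model_stage(study, variables,
                            n_posterior_used = n_posterior_used,
                            seed = seed, se_formula = se_formula,
                            use_se = use_se, outdir = outdir)
  rates <- run_rates_stage(study, rate_variables = rate_variables,
                           pairs = pairs,
                           n_posterior_used = n_posterior_used, seed = seed,
                           se_formula = se_formula, use_se = use_se,
                           model_stage = models, hpd_mass = hpd_mass,
                           outdir = outdir)
  list(signal = signal, dtt = dtt, models = models, rates = rates)
}
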