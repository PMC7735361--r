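MODEL_FORMS <- c("null", "asymptote", "downturn")

#' Classify a tree's best speciation model from three DICs
#'
#' The best model is the one with the smallest DIC; models within
#' `threshold` DIC units (default 4) of the best are statistically
#' indistinguishable from it.  Categories: a single candidate gives
#' `unambiguous_<model>`; candidates `{downturn, asymptote}` give
#' `downturn_or_asymptote`; whenever the null model is among two or more
#' candidates nothing is favoured (`no_model_favoured`) — if the simplest
#' model cannot be told apart from the best, no slowdown signal is
#' claimed.  Exact ties resolve toward the simpler model
#' (null < asymptote < downturn).
#'
#' @param dics named numeric with entries `null`, `asymptote`, `downturn`.
#' @param threshold DIC-difference threshold (default 4).
#' @return one of `"unambiguous_null"`, `"unambiguous_asymptote"`,
#'   `"unambiguous_downturn"`, `"downturn_or_asymptote"`,
#'   `"no_model_favoured"`.
#' @export
classify_dic <- function(dics, threshold = 4) {
  dics <- dics[MODEL_FORMS]
  if (any(is.na(dics)) || any(!is.finite(dics)))
    stop("all three DICs must be finite")
  best <- min(dics)
  cand <- MODEL_FORMS[dics - best < threshold]
  if (length(cand) == 1L) return(paste0("unambiguous_", cand))
  if ("null" %in% cand) return("no_model_favoured")
  "downturn_or_asymptote"
}

#' Enumerate the fits a pipeline run will perform
#'
#' Bookkeeping helper: with `n_topologies` undated topologies each dated
#' `n_datings` times, plus `n_predated` already-dated trees, and
#' `n_models` candidate models under `n_intercept_modes` intercept
#' treatments, reports the dated-tree count and total fit count (both
#' decompositions: trees x models, and per intercept mode).
#'
#' @param n_topologies undated input topologies.
#' @param n_datings dating replicates per topology.
#' @param n_predated pre-dated trees appended to the ensemble.
#' @param n_models candidate model forms (default 3).
#' @param n_intercept_modes intercept treatments (default 1).
#' @return list `dated_trees`, `fits_per_intercept_mode`, `total_fits`.
#' @export
plan_fits <- function(n_topologies, n_datings, n_predated = 0L,
                      n_models = 3L, n_intercept_modes = 1L) {
  dated <- n_topologies * n_datings + n_predated
  per_mode <- dated * n_models
  list(dated_trees = dated,
       fits_per_intercept_mode = per_mode,
       total_fits = per_mode * n_intercept_modes)
}

# Deterministic 31-bit seed for one fit, derived from identifiers.
fit_seed <- function(base_seed, tree_id, form, intercept) {
  s <- paste(tree_id, form, intercept, sep = "|")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer((h + as.numeric(base_seed)) %% 2147483647)
}

#' Fit all candidate models to one dated tree and classify
#'
#' @param tree a dated `"phylo"`.
#' @param tree_id identifier used in outputs and seed derivation.
#' @param intercept intercept treatment (see [model_spec()]).
#' @param priors,settings passed to [fit_nodecount_model()]; each fit's
#'   seed is derived from `settings$seed` and the fit identifiers.
#' @param threshold DIC threshold for [classify_dic()].
#' @return data.frame row: `tree_id`, `intercept_mode`, `dic_null`,
#'   `dic_asymptote`, `dic_downturn`, `category`, `min_mean_ess`.
#' @export
select_model <- function(tree, tree_id = "tree", intercept = "estimated",
                         priors = prior_spec(), settings = mcmc_settings(),
                         threshold = 4) {
  dics <- ess <- setNames(numeric(3), MODEL_FORMS)
  for (form in MODEL_FORMS) {
    st <- settings
    st$seed <- fit_seed(settings$seed, tree_id, form, intercept)
    fit <- fit_nodecount_model(tree, model_spec(form, intercept),
                               priors, st)
    dics[form] <- fit$DIC
    ess[form] <- fit$mean_ess
  }
  data.frame(tree_id = tree_id, intercept_mode = intercept,
             dic_null = dics[["null"]], dic_asymptote = dics[["asymptote"]],
             dic_downturn = dics[["downturn"]],
             category = classify_dic(dics, threshold),
             min_mean_ess = min(ess),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full selection pipeline over tree ensembles
#'
#' Dates each undated topology `config$reps` times, appends any pre-dated
#' trees, fits the three candidate models to every dated tree under each
#' requested intercept mode, classifies each tree with the DIC rule, and
#' summarizes categories per (source tree, intercept mode).  Completed
#' fits are recorded as JSON sidecars under `out_dir/fits/`; re-runs skip
#' any (tree, mode) whose sidecar exists, so interrupted runs resume
#' where they stopped.
#'
#' @param topologies named list of undated `"phylo"` cladograms (may be
#'   empty).
#' @param ranges age-range table covering all topology tips.
#' @param out_dir directory for sidecars and result CSVs.
#' @param config a [dating_config()] (replicates, mbl, dating seeds).
#' @param predated named list of already-dated `"phylo"` trees.
#' @param intercept_modes character vector of intercept treatments.
#' @param priors,settings,threshold passed to [select_model()].
#' @return list `outcomes` (per-tree data.frame), `summary`
#'   (from [summarize_outcomes()]), `n_fitted`, `n_skipped`, `failures`
#'   (tree ids whose fits errored).
#' @export
run_pipeline <- function(topologies, ranges = NULL, out_dir,
                         config = dating_config(), predated = list(),
                         intercept_modes = "estimated",
                         priors = prior_spec(), settings = mcmc_settings(),
                         threshold = 4) {
  fit_dir <- file.path(out_dir, "fits")
  dir.create(fit_dir, recursive = TRUE, showWarnings = FALSE)
  dated <- list()
  for (nm in names(topologies)) {
    ens <- date_ensemble(topologies[[nm]], ranges, config)
    names(ens) <- sprintf("%s_rep%d", nm, seq_along(ens))
    for (k in names(ens)) attr(ens[[k]], "source") <- nm
    dated <- c(dated, ens)
  }
  for (nm in names(predated)) {
    tr <- predated[[nm]]
    attr(tr, "source") <- nm
    dated[[nm]] <- tr
  }
  outcomes <- list(); n_fitted <- 0L; n_skipped <- 0L; failures <- character()
  for (id in names(dated)) {
    for (mode in intercept_modes) {
      sidecar <- file.path(fit_dir, paste0(id, "_", mode, ".json"))
      if (file.exists(sidecar)) {
        row <- as.data.frame(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                             stringsAsFactors = FALSE)
        n_skipped <- n_skipped + 1L
      } else {
        t0 <- proc.time()[["elapsed"]]
        row <- tryCatch(
          select_model(dated[[id]], id, mode, priors, settings, threshold),
          error = function(e) NULL)
        if (is.null(row)) { failures <- c(failures, id); next }
        n_fitted <- n_fitted + 1L
        row$seconds <- round(proc.time()[["elapsed"]] - t0, 2)
        if (row$min_mean_ess < 200)
          message("warning: ", id, " (", mode, "): min mean ESS ",
                  round(row$min_mean_ess, 1), " < 200")
        jsonlite::write_json(as.list(row), sidecar, auto_unbox = TRUE,
                             digits = NA)
      }
      row$source <- attr(dated[[id]], "source")
      outcomes[[paste(id, mode)]] <- row
    }
  }
  outcomes <- do.call(rbind, outcomes)
  rownames(outcomes) <- NULL
  summ <- if (!is.null(outcomes) && nrow(outcomes))
    summarize_outcomes(outcomes) else NULL
  if (!is.null(outcomes))
    write.csv(outcomes, file.path(out_dir, "outcomes.csv"), row.names = FALSE)
  if (!is.null(summ))
    write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  list(outcomes = outcomes, summary = summ,
       n_fitted = n_fitted, n_skipped = n_skipped, failures = failures)
}

#' Summarize selection outcomes over an ensemble
#'
#' Category counts and percentages per group (by default per source tree
#' and intercept mode), in the style of an ensemble summary table.
#'
#' @param outcomes data.frame from [run_pipeline()] or rows from
#'   [select_model()].
#' @param group_by columns to group on; columns absent from `outcomes`
#'   are dropped, and no grouping column at all summarizes the whole set.
#' @return data.frame with one row per (group, category): `category`,
#'   `count`, `percent`, plus the grouping columns.
#' @export
summarize_outcomes <- function(outcomes,
                               group_by = c("source", "intercept_mode")) {
  if (is.null(outcomes) || nrow(outcomes) == 0L) stop("no outcomes")
  group_by <- intersect(group_by, names(outcomes))
  key <- if (length(group_by))
    interaction(outcomes[group_by], drop = TRUE, sep = "|")
  else factor(rep("all", nrow(outcomes)))
  res <- lapply(levels(key), function(g) {
    sub <- outcomes[key == g, , drop = FALSE]
    tab <- table(factor(sub$category, levels = c(
      "unambiguous_null", "unambiguous_asymptote", "unambiguous_downturn",
      "downturn_or_asymptote", "no_model_favoured")))
    out <- data.frame(category = names(tab), count = as.integer(tab),
                      percent = 100 * as.integer(tab) / nrow(sub),
                      stringsAsFactors = FALSE)
    for (col in group_by) out[[col]] <- sub[[col]][1L]
    out
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res[, c(group_by, "category", "count", "percent")]
}
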