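#' Read and validate a person-level dataset
#'
#' Reads a CSV of clustered person-level records and validates it against a
#' column mapping: the outcome and every item must be coercible to
#' 0/1 (missing allowed), weights must be strictly positive, and all mapped
#' columns must exist. Offending rows are reported by index.
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map A named list with elements `outcome`, `items`
#'   (character vector), `fixed_effects`, `concomitants`, `cluster`,
#'   `weights`, `group` — all optional except `cluster`.
#' @return A validated tibble with the column map attached as attribute
#'   `"column_map"`.
#' @export
read_choice_data <- function(path, column_map) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(column_map$cluster)) abort("`column_map$cluster` is required.")
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(data) == 0) abort("input file has no data rows.")
  # prepare_choice_data performs the full validation pass
  prep <- prepare_choice_data(
    data,
    outcome = column_map$outcome,
    items = column_map$items %||% character(0),
    fixed_effects = column_map$fixed_effects %||% character(0),
    concomitants = column_map$concomitants %||% character(0),
    cluster = column_map$cluster,
    weights = column_map$weights
  )
  if (!is.null(column_map$group) && !column_map$group %in% names(data)) {
    abort(sprintf("group column `%s` not found.", column_map$group))
  }
  out <- tibble::as_tibble(data)
  attr(out, "column_map") <- column_map
  attr(out, "n_clusters") <- prep$n_clusters
  message(sprintf("read %d rows in %d clusters from %s",
                  nrow(out), prep$n_clusters, path))
  out
}

#' Run an end-to-end analysis pipeline
#'
#' Ties the stages together reproducibly: `simulate` writes a synthetic
#' dataset (+ truth + config), `fit` estimates the joint model and writes
#' parameter tables, `score` writes empirical-Bayes scores, `validate`
#' aggregates scores by group and correlates them with an external
#' indicator, `lrtest` runs the joint latent-effect test. Every JSON
#' artifact embeds the seed and a hash of the configuration, so re-running
#' with the same config reproduces all outputs.
#'
#' @param config A named list (or path to a JSON file) with elements:
#'   `stage` (one of `"simulate"`, `"fit"`, `"score"`, `"validate"`,
#'   `"lrtest"`), `out_dir`, `seed`, and stage-specific entries — `data`
#'   (CSV path), `column_map`, `sim` (arguments for [sim_config()]),
#'   `quad` (list with `n_z`, `n_u`), `latent_effect`,
#'   `indicator` (CSV path for validate), `indicator_column`, `by`.
#' @return Invisibly, a list with the computed results and the paths of the
#'   written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stage <- config$stage %||% abort("`config$stage` is required.")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  stamp <- list(seed = seed, config_hash = rlang::hash(config))
  quad <- if (!is.null(config$quad)) {
    quad_spec(config$quad$n_z %||% 15, config$quad$n_u %||% 15)
  } else quad_spec()

  load_data <- function() {
    read_choice_data(config$data, config$column_map)
  }
  do_fit <- function(data) {
    cm <- attr(data, "column_map")
    fit_hlc_probit(data, outcome = cm$outcome,
                   items = cm$items %||% character(0),
                   fixed_effects = cm$fixed_effects %||% character(0),
                   concomitants = cm$concomitants %||% character(0),
                   cluster = cm$cluster, weights = cm$weights,
                   latent_effect = config$latent_effect %||% "quadratic",
                   quad = quad)
  }
  write_json <- function(x, file) {
    path <- file.path(out_dir, file)
    jsonlite::write_json(c(x, stamp), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
  }

  artifacts <- character(0)
  result <- switch(
    stage,
    simulate = {
      cfg <- do.call(sim_config, config$sim %||% list())
      sim <- simulate_hlc_data(cfg, seed = seed)
      pd <- file.path(out_dir, "simulated_data.csv")
      pt <- file.path(out_dir, "simulated_truth.csv")
      readr::write_csv(sim$data, pd)
      readr::write_csv(sim$truth, pt)
      artifacts <- c(pd, pt,
                     write_json(unclass(sim$config), "sim_config.json"))
      sim
    },
    fit = {
      fit <- do_fit(load_data())
      pp <- file.path(out_dir, "parameters.csv")
      readr::write_csv(tidy(fit), pp)
      pi <- file.path(out_dir, "item_parameters.csv")
      readr::write_csv(item_parameter_table(fit), pi)
      artifacts <- c(pp, pi,
                     write_json(as.list(glance(fit)), "fit_summary.json"))
      fit
    },
    score = {
      data <- load_data()
      fit <- do_fit(data)
      sc <- eb_scores(fit)
      ps <- file.path(out_dir, "scores.csv")
      readr::write_csv(sc, ps)
      artifacts <- c(ps, write_json(as.list(glance(fit)), "fit_summary.json"))
      sc
    },
    validate = {
      data <- load_data()
      cm <- attr(data, "column_map")
      if (is.null(cm$group)) abort("validate stage needs `column_map$group`.")
      fit <- do_fit(data)
      sc <- eb_scores(fit)
      data$.score <- sc$post_mean
      grp <- if (is.null(cm$weights)) {
        aggregate_scores(data, .data$.score, .data[[cm$group]])
      } else {
        aggregate_scores(data, .data$.score, .data[[cm$group]],
                         weights = .data[[cm$weights]])
      }
      ind <- readr::read_csv(config$indicator, show_col_types = FALSE, na = "")
      val <- external_validation(grp, ind, by = config$by %||% "group",
                                 score = "mean_score",
                                 indicator = config$indicator_column %||% "indicator")
      pg <- file.path(out_dir, "group_scores.csv")
      readr::write_csv(grp, pg)
      artifacts <- c(pg, write_json(list(pearson = val$pearson,
                                         spearman = val$spearman,
                                         n_groups = val$n_groups),
                                    "validation.json"))
      val
    },
    lrtest = {
      fit <- do_fit(load_data())
      lt <- lr_test_latent(fit)
      artifacts <- write_json(as.list(lt), "lr_test.json")
      lt
    },
    abort(sprintf("unknown stage `%s`.", stage))
  )
  invisible(list(result = result, artifacts = artifacts, stamp = stamp))
}
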