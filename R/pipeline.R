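#' Read and validate a cohort table
#'
#' Reads the documented CSV schema (subject metadata, 63 exposure flag
#' columns, \code{trauma_exposed}, 12 symptom and 6 impairment item
#' columns) and validates it: unknown critical columns, scores outside
#' 0-4, and non-logical flags are itemized errors; a missingness summary
#' is attached as the \code{"validation"} attribute.
#'
#' @param path CSV file path.
#' @return validated cohort tibble.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  items <- c(itq_symptom_items(), itq_impairment_items())
  problems <- character()
  for (col in c(items, exposure_flag_columns(), "trauma_exposed", "gender")) {
    if (!col %in% names(raw)) problems <- c(problems, sprintf("missing column '%s'", col))
  }
  if (length(problems) == 0) {
    for (col in items) {
      bad <- which(!is.na(raw[[col]]) & !(raw[[col]] %in% 0:4))
      if (length(bad) > 0) {
        problems <- c(problems, sprintf("column '%s': out-of-range score in row(s) %s",
                                        col, paste(head(bad, 5), collapse = ", ")))
      }
    }
    for (col in exposure_flag_columns()) {
      v <- raw[[col]]
      if (!is.logical(v) && !all(v %in% c(0, 1, NA))) {
        problems <- c(problems, sprintf("column '%s' is not a 0/1 or logical flag", col))
      } else {
        raw[[col]] <- as.logical(v)
      }
    }
  }
  if (length(problems) > 0) {
    stop_input("cohort validation failed:\n  %s", paste(problems, collapse = "\n  "))
  }
  if ("parental_education" %in% names(raw) && !is.ordered(raw$parental_education)) {
    lev <- intersect(c("low", "medium", "high"), unique(raw$parental_education))
    raw$parental_education <- factor(raw$parental_education, levels = lev, ordered = TRUE)
  }
  attr(raw, "validation") <- list(
    n_subjects = nrow(raw),
    missing_item_cells = sum(is.na(raw[items])),
    rows_with_missing_items = sum(rowSums(is.na(raw[items])) > 0)
  )
  raw
}

#' Pipeline configuration
#'
#' @param input path to a cohort CSV, or a \code{\link{sim_config}} to
#'   simulate from.
#' @param stages subset of \code{c("score", "cfa", "network", "epi")}.
#' @param output_dir directory for the output bundle.
#' @param seed seed recorded in all outputs and used for any stochastic
#'   step (bootstrap weights, optimizer restarts).
#' @param cfa_weights weight flavour passed to \code{\link{fit_wls}}.
#' @param network network options (\code{\link{network_config}}).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input, stages = c("score", "cfa", "network", "epi"),
                            output_dir, seed = 1L,
                            cfa_weights = "identity",
                            network = network_config()) {
  if (length(stages) == 0) stop_input("select at least one stage")
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(input = input, stages = stages, output_dir = output_dir,
                 seed = as.integer(seed), cfa_weights = cfa_weights,
                 network = network),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in the fixed order score, CFA, network,
#' epidemiology on a real or simulated cohort, writing one CSV per result
#' table plus a JSON run manifest (seed, options, package version, stage
#' status). Idempotent: the same config and seed regenerate identical
#' outputs. A failing stage is recorded in the manifest and later stages
#' still run where possible.
#'
#' @param config \code{\link{pipeline_config}}.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    package_version = as.character(utils::packageVersion("itqnet")),
    started = "run",
    status = list()
  )
  results <- list()
  cohort <- if (inherits(config$input, "sim_config")) {
    generate_cohort(config$input)
  } else {
    read_cohort_table(config$input)
  }
  readr::write_csv(cohort, file.path(config$output_dir, "cohort.csv"))
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status[[name]] <<- paste("failed:", conditionMessage(res))
      NULL
    } else {
      manifest$status[[name]] <<- "ok"
      res
    }
  }
  scored <- NULL
  if ("score" %in% config$stages) {
    scored <- run_stage("score", {
      sc <- itq_diagnose(itq_subscales(cohort))
      readr::write_csv(
        sc[, c("subject_id", "ptsd_sum", "dso_sum", "diagnosis")],
        file.path(config$output_dir, "diagnoses.csv")
      )
      prev <- dplyr::bind_rows(
        dplyr::mutate(prevalence_ci(sum(sc$diagnosis == "PTSD", na.rm = TRUE),
                                    sum(!is.na(sc$diagnosis))), outcome = "PTSD"),
        dplyr::mutate(prevalence_ci(sum(sc$diagnosis == "cPTSD", na.rm = TRUE),
                                    sum(!is.na(sc$diagnosis))), outcome = "cPTSD")
      )
      readr::write_csv(prev, file.path(config$output_dir, "prevalence.csv"))
      sc
    })
    results$scored <- scored
    results$prevalence <- if (!is.null(scored)) {
      readr::read_csv(file.path(config$output_dir, "prevalence.csv"),
                      show_col_types = FALSE)
    }
  }
  items <- as.matrix(cohort[itq_symptom_items()])
  complete <- stats::complete.cases(items)
  est <- NULL
  if (any(c("cfa", "network") %in% config$stages)) {
    est <- run_stage("polychoric", {
      polychoric_matrix(items[complete, , drop = FALSE],
                        weights = if (config$cfa_weights %in% c("diag", "full"))
                          config$cfa_weights else "none",
                        boot_seed = config$seed)
    })
  }
  if ("cfa" %in% config$stages && !is.null(est)) {
    results$cfa <- run_stage("cfa", {
      specs <- build_standard_models()
      fits <- lapply(specs, function(sp) {
        fit_wls(est, sp, weights = config$cfa_weights, seed = config$seed)
      })
      bl <- fit_baseline(est, weights = config$cfa_weights)
      cmp <- compare_models(fits, baseline = bl)
      readr::write_csv(cmp$table, file.path(config$output_dir, "cfa_fit_indices.csv"))
      cmp
    })
  }
  if ("network" %in% config$stages && !is.null(est)) {
    results$network <- run_stage("network", {
      net <- if (config$network$correlation_input == "polychoric") {
        estimate_network(est$R, config$network, n = est$n)
      } else {
        estimate_network(items[complete, , drop = FALSE], config$network)
      }
      readr::write_csv(tidy(net), file.path(config$output_dir, "network_edges.csv"))
      adj <- tibble::as_tibble(net$weights, rownames = "node")
      readr::write_csv(adj, file.path(config$output_dir, "network_adjacency.csv"))
      cent <- centrality_measures(net)
      readr::write_csv(cent, file.path(config$output_dir, "centrality.csv"))
      list(network = net, centrality = cent)
    })
  }
  if ("epi" %in% config$stages) {
    results$epi <- run_stage("epi", {
      sc <- scored %||% itq_diagnose(cohort)
      tab <- gender_contrast_table(sc)
      readr::write_csv(tab, file.path(config$output_dir, "exposure_gender_table.csv"))
      ok <- !is.na(sc$diagnosis)
      or_tabs <- lapply(c(unadjusted = FALSE, adjusted = TRUE), function(adj) {
        X <- exposure_design(sc[ok, ], adjusted = adj)
        fit <- fit_multinomial(sc$diagnosis[ok], X)
        dplyr::mutate(odds_ratios(fit), model = if (adj) "adjusted" else "unadjusted")
      })
      ors <- dplyr::bind_rows(or_tabs)
      readr::write_csv(ors, file.path(config$output_dir, "odds_ratios.csv"))
      list(gender_table = tab, odds_ratios = ors)
    })
  }
  manifest$outputs <- list.files(config$output_dir)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(results = results, manifest = manifest, cohort = cohort))
}
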