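#' Pipeline run configuration
#'
#' Bundles the inputs and module options for [run_pipeline()]. Exactly one
#' of `input` (a cohort CSV produced by [write_cohort()] or an equivalent
#' long-format table) or the `spec`/`truth` pair (synthetic generation) must
#' be supplied. All randomness downstream flows from `seed` through named
#' per-stage substreams.
#'
#' @param spec a [cohort_spec()] for synthetic input.
#' @param truth a [truth_record()] for synthetic input.
#' @param input path to a cohort CSV for real input.
#' @param out_dir output directory for the report bundle.
#' @param seed master seed.
#' @param en an [en_config()] for the mediator pre-selection stage.
#' @param max_mediators cap on mediators carried into the SEM stage.
#' @param n_starts optimizer starts per SEM fit.
#' @param alpha_level significance level for model selection.
#' @return A `run_config` list.
#' @export
run_config <- function(spec = NULL, truth = NULL, input = NULL,
                       out_dir = tempfile("twinmed_run_"), seed = 1L,
                       en = en_config(alpha_grid = c(0.2, 0.5, 0.8),
                                      k_folds = 5, nlambda = 40),
                       max_mediators = 2, n_starts = 2,
                       alpha_level = 0.05) {
  if (is.null(input) == (is.null(spec) || is.null(truth)))
    stop("supply exactly one of `input` or the spec/truth pair")
  structure(list(spec = spec, truth = truth, input = input,
                 out_dir = out_dir, seed = as.integer(seed), en = en,
                 max_mediators = max_mediators, n_starts = n_starts,
                 alpha_level = alpha_level),
            class = "run_config")
}

#' Validate a cohort table
#'
#' Schema, pedigree-consistency and item-coding checks for a long-format
#' cohort table: required identifier columns, twin pairs sharing family and
#' site with matching zygosity labels, and item entries restricted to 0, 1
#' or missing. Problems are collected into an itemized error.
#'
#' @param table a data.frame or path to a cohort CSV.
#' @return The validated `cohort_table`, invisibly errors otherwise.
#' @export
validate_input <- function(table) {
  if (is.character(table)) table <- read_cohort(table)
  table <- as.data.frame(table)
  errors <- character(0)
  need <- c("person_id", "family_id", "site_id", "relation")
  miss <- setdiff(need, names(table))
  if (length(miss))
    errors <- c(errors, paste("missing columns:", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    bad_rel <- !table$relation %in% c("MZ", "DZ", "SIB", "SINGLETON")
    if (any(bad_rel))
      errors <- c(errors, paste("unknown relation labels for:",
                                paste(utils::head(table$person_id[bad_rel], 5),
                                      collapse = ", ")))
    twins <- table[table$relation %in% c("MZ", "DZ"), , drop = FALSE]
    for (f in unique(twins$family_id)) {
      members <- twins[twins$family_id == f, , drop = FALSE]
      if (nrow(members) != 2) {
        errors <- c(errors, sprintf(
          "family %s has %d twin member(s); complete pairs required (%s)",
          f, nrow(members), paste(members$person_id, collapse = ", ")))
      } else {
        if (length(unique(members$relation)) != 1)
          errors <- c(errors, sprintf(
            "family %s mixes zygosity labels (%s)", f,
            paste(members$person_id, collapse = ", ")))
        if (length(unique(members$site_id)) != 1)
          errors <- c(errors, sprintf(
            "family %s twins are at different sites (%s)", f,
            paste(members$person_id, collapse = ", ")))
      }
    }
  }
  item_cols <- grep("^(te|ptsd)_item_", names(table), value = TRUE)
  for (col in item_cols) {
    bad <- !(table[[col]] %in% c(0, 1, NA))
    if (any(bad))
      errors <- c(errors, sprintf("item column %s has non-binary values (e.g. %s)",
                                  col, table[[col]][which(bad)[1]]))
  }
  if (length(errors))
    stop("cohort validation failed:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  class(table) <- c("cohort_table", "data.frame")
  invisible(table)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> item measurement -> preprocessing ->
#' elastic-net mediator pre-selection -> multilevel SEM fits (uniDir and
#' biDir) -> model comparison, writing a report bundle of TSV tables:
#' model comparisons, indirect effects with intervals, MZ/DZ twin
#' correlations, variance-component proportions, the mediator-selection
#' report, and a JSON run log with the seed and configuration digest.
#'
#' @param config a [run_config()].
#' @return List with the fitted objects and the paths of the written
#'   tables.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  # --- stage: cohort ---------------------------------------------------
  if (!is.null(config$input)) {
    cohort <- validate_input(config$input)
    roi_cols <- grep("^roi_", names(cohort), value = TRUE)
  } else {
    spec <- config$spec
    spec$seed <- config$seed + 1000L   # stage substream
    gen <- generate_cohort(spec, config$truth)
    cohort <- gen$cohort
    roi_cols <- config$truth$mediators
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"),
                 truth = gen$truth, spec = spec)
  }
  validate_input(cohort)
  log$n_persons <- nrow(cohort)

  # --- stage: measurement ---------------------------------------------
  te_cols <- grep("^te_item_", names(cohort), value = TRUE)
  item_fit <- fit_item_factor_model(cohort[te_cols], n_quadrature = 21,
                                    max_iter = 100)
  utils::write.table(item_fit, file.path(config$out_dir, "item_params.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- stage: preprocess ----------------------------------------------
  tab <- preprocess_cohort(cohort, roi_cols = roi_cols)
  std_cols <- paste0(roi_cols, "_std")

  # --- stage: mediator pre-selection ----------------------------------
  sel <- character(0); cv <- NULL
  if (length(roi_cols)) {
    Xsel <- as.matrix(tab[, c("te_score", std_cols)])
    keep <- !is.na(tab$ptsdsx_score) & stats::complete.cases(Xsel)
    cv <- cross_validate(Xsel[keep, , drop = FALSE], tab$ptsdsx_score[keep],
                         config$en, family_id = tab$family_id[keep])
    sel <- setdiff(select_mediators(cv), "te_score")
    sel <- sub("_std$", "", sel)
    sel <- utils::head(sel, config$max_mediators)
    meff <- effective_tests(stats::cor(as.matrix(tab[, std_cols, drop = FALSE]),
                                       use = "pairwise.complete.obs"))
    sel_report <- data.frame(
      alpha = cv$best_alpha, lambda_min = cv$best$lambda_min,
      lambda_1se = cv$best$lambda_1se, n_selected = length(sel),
      selected = paste(sel, collapse = ","), m_eff = meff)
    utils::write.table(sel_report,
                       file.path(config$out_dir, "selection_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    log$m_eff <- meff
  }

  # --- stage: SEM fits -------------------------------------------------
  columns <- c(te = "te_score",
               stats::setNames(paste0(sel, "_std"), sel),
               ptsdsx = "ptsdsx_score")
  fd <- fiml_data(tab, columns)
  uni <- fit_ml(path_model("uniDir", mediators = sel), fd,
                n_starts = config$n_starts, seed = config$seed + 2000L)
  bi <- fit_ml(path_model("biDir", mediators = sel), fd,
               n_starts = config$n_starts, seed = config$seed + 3000L)

  # --- stage: comparison and tables -----------------------------------
  row <- likelihood_ratio_test(bi, uni, labels = c("biDir", "uniDir"))
  chosen <- select_model(list(row), alpha_level = config$alpha_level)
  utils::write.table(row, file.path(config$out_dir, "model_comparison.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  chosen_fit <- if (chosen == "uniDir") uni else bi
  ind <- do.call(rbind, lapply(sel, function(m) {
    ie <- indirect_effect(chosen_fit, m)
    data.frame(mediator = m, estimate = ie$estimate,
               lower = ie$lower %||% NA_real_, upper = ie$upper %||% NA_real_)
  }))
  if (is.null(ind)) ind <- data.frame(mediator = character(),
                                      estimate = numeric(),
                                      lower = numeric(), upper = numeric())
  utils::write.table(ind, file.path(config$out_dir, "indirect_effects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  tw <- twin_saturated_correlations(tab, columns)
  if (!is.null(tw$combined))
    utils::write.table(round(tw$combined, 3),
                       file.path(config$out_dir, "twin_correlations.tsv"),
                       sep = "\t", quote = FALSE)

  vcs <- do.call(rbind, lapply(chosen_fit$model$phenotypes, function(ph) {
    vc <- chosen_fit$params$components[[ph]]
    pr <- standardize_components(vc)
    data.frame(phenotype = ph,
               VA = pr$proportion[1], VC = pr$proportion[2],
               VE = pr$proportion[3], VS = pr$proportion[4])
  }))
  utils::write.table(vcs, file.path(config$out_dir, "variance_proportions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  log$chosen_model <- chosen
  log$config_digest <- config_digest(config)
  log$version <- as.character(utils::packageVersion("twinmed"))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  list(cohort = cohort, analysis = tab, item_fit = item_fit, cv = cv,
       selected = sel, fits = list(uniDir = uni, biDir = bi),
       comparison = row, chosen = chosen,
       indirect = ind, twin_correlations = tw,
       variance_proportions = vcs, out_dir = config$out_dir)
}

# small stable digest of the configuration (no external digest dependency)
config_digest <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}
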