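#' Run a complete study analysis
#'
#' Orchestrates the full pipeline on either a synthetic study (pass a
#' [synth_config()]) or user files (pass a list of paths: `tree`, `survey`,
#' `traits`, `fauna`). Stages: (1) per-site diversity table (observed and
#' SES MPD/MNTD, Rao and CWM per trait); (2) trait-diversity vs
#' phylogenetic-diversity regression; (3) Pearson correlation screen;
#' (4) interaction-model report table over all trait x response
#' combinations; (5) median-split group labels; (6) machine-readable dump
#' of every fitted model. Deterministic given inputs and `seed`.
#'
#' @param config a `pf_synth_config`, or a list with elements `tree`,
#'   `survey`, `traits`, `fauna` (file paths) plus optional `veg_data`
#'   (named 0/1 vector per site).
#' @param outdir optional output directory; when given, all tables are
#'   written as TSV and the model dump as JSON.
#' @param null_replicates,seed null-model settings for the file-input route
#'   (the synthetic route takes them from the config).
#' @return a `pf_run` list: `diversity`, `fauna_summary`, `models`,
#'   `report`, `trait_vs_phylo`, `correlations`, `median_split`, `log`.
#' @export
run_study <- function(config, outdir = NULL, null_replicates = 999L,
                      seed = 1L) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  if (inherits(config, "pf_synth_config")) {
    study <- generate_study(config)
    div <- study$diversity
    fauna <- study$fauna
    traits <- study$traits
    note("stage synth: %d sites, %d-species pool, %d null replicates",
         config$n_sites, config$n_species, config$null_replicates)
  } else {
    for (f in c("tree", "survey", "traits", "fauna"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        pf_stop("pf_stage_error", "stage vegetation: missing input '%s'", f)
    tree <- parse_newick(file = config$tree)
    survey <- read_survey(config$survey)
    traits <- read_traits(config$traits)
    community <- community_matrix(survey)
    pool <- colnames(community)
    missing_tips <- setdiff(pool, tree$tip.label)
    if (length(missing_tips) > 0)
      pf_stop("pf_stage_error", "stage phylo: species not in tree: %s",
              paste(missing_tips, collapse = ", "))
    D <- patristic_matrix(tree, pool)
    div <- community_diversity(community, D, traits,
                               replicates = null_replicates, seed = seed)
    div$veg_data <- (config$veg_data %||%
                       stats::setNames(rep(0L, nrow(div)), div$site))[div$site]
    fauna <- utils::read.table(config$fauna, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    note("stage vegetation: %d sites, %d species", nrow(community),
         ncol(community))
  }

  fs <- fauna_summary(fauna)
  merged <- merge(div, fs, by = "site", sort = FALSE)
  trait_names <- intersect(c("sla", "ldmc"), sub("^rao_", "",
    grep("^rao_", names(div), value = TRUE)))

  responses <- c(grep("^logabund_", names(fs), value = TRUE),
                 grep("^simpson_", names(fs), value = TRUE),
                 "structure_index")
  responses <- responses[vapply(responses, function(r)
    sum(is.finite(merged[[r]])) >= 8 && stats::sd(merged[[r]],
                                                  na.rm = TRUE) > 0,
    logical(1))]

  # a single data source makes VegData constant; drop the term then
  use_veg <- length(unique(merged$veg_data)) > 1L
  if (!use_veg) note("stage inference: VegData constant, term dropped")

  models <- list()
  for (tr in trait_names) {
    for (resp in responses) {
      key <- paste(toupper(tr), resp, sep = "|")
      preds <- list(VegData = "veg_data", PhylDiv = "ses_mpd",
                    meanFunTrait = paste0("cwm_", tr),
                    FunTraitDiv = paste0("rao_", tr))
      if (!use_veg) preds$VegData <- NULL
      m <- tryCatch(
        fit_interaction_model(merged, resp, predictors = preds),
        phylofauna_error = function(e) {
          note("stage inference: model %s skipped (%s)", key,
               conditionMessage(e))
          NULL
        })
      if (!is.null(m)) {
        models[[key]] <- m
        note("stage inference: %s n=%d excluded=%d", key, m$n_used,
             length(m$excluded))
      }
    }
  }

  if (length(models) == 0)
    pf_stop("pf_stage_error",
            "stage inference: no model could be fitted (too few sites?)")
  report <- build_report(models)

  tvp <- lapply(trait_names, function(tr) {
    fit <- stats::lm(merged[[paste0("rao_", tr)]] ~ merged$ses_mpd)
    sm <- summary(fit)
    data.frame(trait = tr, t = sm$coefficients[2, 3],
               p = sm$coefficients[2, 4], r_squared = sm$r.squared,
               n = length(fit$residuals))
  })
  tvp <- do.call(rbind, tvp)

  num_cols <- names(merged)[vapply(merged, is.numeric, logical(1))]
  corr <- pearson_screen(merged[, num_cols, drop = FALSE])
  split <- median_split(merged$ses_mpd)

  out <- structure(list(diversity = div, fauna_summary = fs,
                        models = models, report = report,
                        trait_vs_phylo = tvp, correlations = corr,
                        median_split = data.frame(site = merged$site,
                                                  group = as.character(split)),
                        median_threshold = attr(split, "threshold"),
                        log = log),
                   class = "pf_run")
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

# serializable view of the fitted models (stable field order, no lm objects)
model_dump <- function(models) {
  lapply(models, function(m)
    list(coefficients = m$coefficients,
         r_squared = m$r_squared, adj_r_squared = m$adj_r_squared,
         vif = as.list(m$vif), excluded = as.character(m$excluded),
         n_used = m$n_used, formula = m$formula))
}

#' Write a run's outputs to disk
#'
#' @param run a `pf_run` object.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(outdir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(run$diversity, "diversity.tsv")
  wt(run$fauna_summary, "fauna_summary.tsv")
  wt(run$report, "model_report.tsv")
  wt(run$trait_vs_phylo, "trait_vs_phylo.tsv")
  wt(run$median_split, "median_split.tsv")
  jsonlite::write_json(model_dump(run$models),
                       file.path(outdir, "models.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  writeLines(run$log, file.path(outdir, "run.log"))
  invisible(outdir)
}
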