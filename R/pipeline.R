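#' Pipeline configuration
#'
#' Bundles the stage parameter blocks, input paths (or generator configs when
#' inputs are simulated), the global seed, and the output directory for
#' [run_pipeline()].
#'
#' @param out_dir Output directory (created if absent).
#' @param stages Subset of `c("simulate", "tda", "pca", "modules", "de")` to
#'   run, in pipeline order. Stages that need inputs from a skipped
#'   `simulate` stage read them from `outcomes_path` / `counts_path` /
#'   `groups_path`.
#' @param trial A [trial_sim_config()].
#' @param expression An [expr_sim_config()].
#' @param mapper A [mapper_config()].
#' @param network A [network_params()].
#' @param outcomes_path,counts_path,groups_path Optional input files used
#'   when `simulate` is not among the stages.
#' @param gmt_path Optional GMT file for the enrichment step; when absent,
#'   gene sets are derived from the simulation ground truth (planted modules
#'   and the injury set).
#' @param arm_column,dose_column Metadata columns used by the dose-response
#'   test.
#' @param seed Global seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("simulate", "tda", "pca", "modules", "de"),
                            trial = trial_sim_config(),
                            expression = expr_sim_config(),
                            mapper = mapper_config(),
                            network = network_params(),
                            outcomes_path = NULL,
                            counts_path = NULL,
                            groups_path = NULL,
                            gmt_path = NULL,
                            arm_column = "arm",
                            dose_column = "dose",
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  for (p in c(outcomes_path, counts_path, groups_path, gmt_path))
    if (!is.null(p) && !file.exists(p)) stop(sprintf("input file not found: %s", p))
  seed <- as.integer(seed)
  trial$seed <- seed
  expression$seed <- seed + 1L
  mapper$seed <- seed + 2L
  structure(list(
    out_dir = out_dir, stages = stages, trial = trial,
    expression = expression, mapper = mapper, network = network,
    outcomes_path = outcomes_path, counts_path = counts_path,
    groups_path = groups_path, gmt_path = gmt_path,
    arm_column = arm_column, dose_column = dose_column, seed = seed
  ), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), NA_character_,
           format(v, digits = 10, trim = TRUE, scientific = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order — simulate (trial + expression
#' tables), tda (bootstrap-consensus Mapper graph with severity, recovery and
#' arm-membership overlays), pca (syndromic PCA, retention audit, subject
#' scores, dose-response contrasts within the treated arm), modules
#' (outlier screen, module detection, eigengene merging, kME, module-trait
#' reversion tests), de (normalization, three-group DE, reversal classes,
#' gene-set enrichment) — writing every result as TSV/JSON under `out_dir`
#' plus a `manifest.json` recording package version, seed, parameters, and
#' the MD5 hash of every output file. Identical configs and seeds produce
#' byte-identical outputs and manifests.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  outcomes <- NULL; counts <- NULL; groups <- NULL; truth <- NULL

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      trial <- simulate_trial(config$trial)
      outcomes <<- trial$data
      emit("outcomes.csv", function(p) write_outcome_table(trial$data, p))
      sim <- simulate_expression(config$expression)
      counts <<- sim$counts; groups <<- sim$groups; truth <<- sim$truth
      emit("counts.tsv", function(p) write_counts(sim$counts, p))
      emit("groups.tsv", function(p) write_groups(sim$groups, p))
      emit("simulation_truth.json", function(p) jsonlite::write_json(
        list(module = as.list(sim$truth$module),
             injury = as.list(sim$truth$injury),
             reversal = as.list(sim$truth$reversal)),
        p, auto_unbox = TRUE))
    })
  } else {
    if (any(c("tda", "pca") %in% config$stages)) {
      if (is.null(config$outcomes_path))
        stop("outcomes_path required when the simulate stage is skipped")
      outcomes <- read_outcome_table(config$outcomes_path)
    }
    if (any(c("modules", "de") %in% config$stages)) {
      if (is.null(config$counts_path) || is.null(config$groups_path))
        stop("counts_path and groups_path required when the simulate stage is skipped")
      counts <- read_counts(config$counts_path)
      groups <- read_groups(config$groups_path, counts)
    }
  }

  if ("tda" %in% config$stages) {
    run_stage("tda", function() {
      cons <- bootstrap_consensus(outcomes, config$mapper)
      g <- cons$graph
      g <- add_overlay(g, outcomes, "severity")
      for (v in colnames(outcomes$outcomes)[1:2])
        g <- add_overlay(g, outcomes, v)
      for (a in unique(outcomes$meta$arm))
        g <- add_overlay(g, outcomes, config$arm_column, level = a)
      emit("mapper", function(p) write_mapper_graph(g, p))
      files <<- c(setdiff(files, "mapper"), "mapper.graphml", "mapper.json")
      emit("cooccurrence.tsv", function(p) {
        m <- cons$cooccurrence
        write_counts(round(m, 6), p, id_label = "subject")
      })
    })
  }

  if ("pca" %in% config$stages) {
    run_stage("pca", function() {
      model <- correlation_pca(outcomes)
      model <- retain_components(model)
      model <- score_subjects(model, outcomes)
      emit("pca_loadings.tsv", function(p) write_tsv(
        data.frame(variable = rownames(model$loadings),
                   as.data.frame(model$loadings)), p))
      emit("pca_eigenvalues.tsv", function(p) write_tsv(
        data.frame(component = names(model$eigenvalues),
                   eigenvalue = unname(model$eigenvalues),
                   variance_explained = unname(model$variance_explained)), p))
      emit("pca_retention_audit.tsv", function(p) write_tsv(model$audit, p))
      emit("pca_scores.tsv", function(p) write_tsv(
        data.frame(subject_id = rownames(model$scores),
                   as.data.frame(model$scores)), p))
      if (length(model$retained)) {
        treated <- outcomes$meta[[config$arm_column]] ==
          config$trial$treated_arm
        dr <- test_dose_response(
          model$scores[treated, 1],
          outcomes$meta[[config$dose_column]][treated])
        emit("dose_response.tsv", function(p) write_tsv(cbind(
          data.frame(F = dr$anova$F, p_omnibus = dr$anova$p,
                     inverted_u = dr$inverted_u), dr$contrasts), p))
      }
    })
  }

  moduleset <- NULL
  expr <- NULL
  if (any(c("modules", "de") %in% config$stages))
    expr <- normalize_counts(counts)

  if ("modules" %in% config$stages) {
    run_stage("modules", function() {
      dropped <- flag_outlier_samples(expr)
      keep <- setdiff(colnames(expr), dropped)
      ms <- detect_modules(expr[, keep, drop = FALSE], config$network)
      ms <- merge_modules(ms, expr[, keep, drop = FALSE])
      moduleset <<- ms
      emit("module_assignment.tsv", function(p) {
        own <- vapply(seq_along(ms$labels), function(i) {
          m <- ms$labels[i]
          if (m == "unassigned" || !ncol(ms$kme)) NA_real_ else ms$kme[i, m]
        }, numeric(1))
        write_tsv(data.frame(gene = names(ms$labels),
                             module = unname(ms$labels), kme_own = own), p)
      })
      emit("module_eigengenes.tsv", function(p)
        write_counts(round(ms$eigengenes, 8), p, id_label = "module"))
      emit("module_merge_log.tsv", function(p) write_tsv(ms$merge_log, p))
      emit("excluded_samples.tsv", function(p) write_tsv(
        data.frame(sample = dropped), p))
      if (nrow(ms$eigengenes)) {
        tt <- module_trait_test(ms, groups[keep],
                                levels = unique(unname(groups)))
        emit("module_trait.tsv", function(p) write_tsv(tt, p))
      }
    })
  }

  if ("de" %in% config$stages) {
    run_stage("de", function() {
      lv <- unique(unname(groups))
      degs <- deg_table(expr, groups[colnames(expr)],
                        reference = lv[1], vehicle = lv[2], treated = lv[3])
      for (nm in c("vehicle_vs_reference", "treated_vs_reference",
                   "treated_vs_vehicle"))
        emit(paste0("de_", nm, ".tsv"), function(p) write_tsv(degs[[nm]], p))
      emit("reversal.tsv", function(p) write_tsv(degs$reversal, p))
      collection <- if (!is.null(config$gmt_path)) {
        read_gmt(config$gmt_path, rownames(expr))
      } else if (!is.null(truth)) {
        sets <- split(names(truth$module), truth$module)
        sets <- sets[names(sets) != "none"]
        sets$injury_response <- names(truth$injury)[truth$injury]
        gene_set_collection(sets, rownames(expr))
      } else NULL
      if (!is.null(collection)) {
        sig <- degs$treated_vs_vehicle$gene[degs$treated_vs_vehicle$significant]
        if (length(sig))
          emit("enrichment.tsv", function(p)
            write_tsv(geneset_enrichment(sig, collection), p))
      }
    })
  }

  manifest <- list(
    package = "scimint",
    version = as.character(utils::packageVersion("scimint")),
    seed = config$seed,
    stages = config$stages,
    parameters = list(
      trial = unclass(config$trial)[setdiff(names(config$trial), "arms")],
      arms = config$trial$arms,
      expression = unclass(config$expression),
      mapper = unclass(config$mapper),
      network = unclass(config$network)
    ),
    files = as.list(vapply(sort(files), function(f)
      unname(tools::md5sum(file.path(config$out_dir, f))), character(1)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
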