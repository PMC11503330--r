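#' Default pipeline configuration
#'
#' Nested list of every threshold, grid, and seed the pipeline uses. With
#' \code{simulate$enabled = TRUE} (the default) the pipeline generates a
#' synthetic study; otherwise the four input paths must point at library /
#' intensity / design / ELISA files and \code{contrast} names the design
#' groups of each arm.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    inputs = list(library = NULL, intensity = NULL, design = NULL,
                  elisa = NULL),
    contrast = list(experimental = "disease", control = "control"),
    simulate = list(enabled = TRUE, seed = 1L, n_labeled = 70L,
                    labeled_planted_fraction = 0.5,
                    coupling_slope = 0.6, noise_sd = 0.05, baseline = 0.2,
                    spec = unclass(signal_spec())),
    features = list(propcon_mode = "below_high", fold_floor = 1.0),
    inference = list(effect_grid_size = 15L, var_grid_size = 15L,
                     tol = 1e-8, max_iter = 5000L),
    criteria = list(cor_threshold = 0.6, fold_threshold = 5,
                    p_threshold = 0.1),
    forest = list(n_trees = 500L, min_leaf = 1L, seed = 20L),
    cv = list(enabled = TRUE, n_repeats = 50L, train_fraction = 0.7,
              stratified = TRUE, feature_aucs = FALSE,
              feature_auc_mode = "forest", seed = 30L),
    selection = list(all_exceed_threshold = 0.5,
                     mean_exceeds_threshold = 0.75)
  )
}

## merge user config over defaults, rejecting unknown keys
merge_config <- function(user, defaults = default_config(), path = NULL) {
  if (is.null(user)) return(defaults)
  merge1 <- function(d, u, prefix) {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown) > 0L)
      stop("unknown config key(s): ",
           paste(paste0(prefix, unknown), collapse = ", "))
    for (k in names(u)) {
      if (is.list(d[[k]]) && !is.null(names(d[[k]]))) {
        d[[k]] <- merge1(d[[k]], as.list(u[[k]]), paste0(prefix, k, "."))
      } else {
        d[k] <- u[k]
      }
    }
    d
  }
  merge1(defaults, user, if (is.null(path)) "" else paste0(path, "."))
}

#' Read / write a pipeline configuration (YAML)
#'
#' Reading merges the file over \code{\link{default_config}} and rejects
#' unknown keys.
#'
#' @param path YAML file path.
#' @return \code{read_pipeline_config} returns the merged nested list.
#' @export
read_pipeline_config <- function(path) {
  merge_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config Nested configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full triage pipeline
#'
#' Executes every stage in order — data (simulated or read from the
#' configured paths), array features with empirical-Bayes inference, ELISA
#' labels, cross-validation, model fitting, whole-library prediction,
#' selection under both thresholding rules, modification enrichment — and
#' writes each artifact as TSV (plus a FASTA export of the conservative
#' selection and a run manifest) into \code{out_dir}.
#'
#' @param config Configuration list (see \code{\link{default_config}}).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory results (\code{features},
#'   \code{training}, \code{cv}, \code{model}, \code{probabilities},
#'   \code{selection_all}, \code{selection_mean}, \code{enrichment},
#'   \code{out_dir}).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  config <- merge_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- c()

  data <- run_stage("data", {
    if (isTRUE(config$simulate$enabled)) {
      sc <- config$simulate
      simulate_study(do.call(signal_spec, sc$spec), seed = sc$seed,
                     n_labeled = sc$n_labeled,
                     labeled_planted_fraction = sc$labeled_planted_fraction,
                     coupling_slope = sc$coupling_slope,
                     noise_sd = sc$noise_sd, baseline = sc$baseline)
    } else {
      inp <- config$inputs
      if (any(vapply(inp, is.null, logical(1))))
        stop("simulate.enabled is FALSE but input paths are incomplete")
      library <- read_peptide_library(inp$library)
      experiment <- read_intensity_matrix(inp$intensity, library)
      design <- read_group_design(inp$design,
                                  config$contrast$experimental,
                                  config$contrast$control)
      elisa <- read_elisa_measurements(inp$elisa)
      list(library = library, experiment = experiment, design = design,
           truth = NULL, elisa = elisa,
           training_ids = unique(elisa$peptide_id))
    }
  })
  counts["library_peptides"] <- nrow(data$library$records)
  counts["subjects"] <- length(data$experiment$subjects)

  inference <- run_stage("inference", {
    ic <- config$inference
    peptide_inference(data$experiment, data$design,
                      effect_grid_size = ic$effect_grid_size,
                      var_grid_size = ic$var_grid_size,
                      tol = ic$tol, max_iter = ic$max_iter)
  })
  write_inference(inference, file.path(out_dir, "inference.tsv"))

  features <- run_stage("features", {
    compute_features(data$experiment, data$design, inference,
                     propcon_mode = config$features$propcon_mode,
                     fold_floor = config$features$fold_floor)
  })
  write_feature_table(features, file.path(out_dir, "features.tsv"))
  counts["feature_rows"] <- nrow(features)

  criteria <- criteria_config(config$criteria$cor_threshold,
                              config$criteria$fold_threshold,
                              config$criteria$p_threshold)
  training <- run_stage("labels", {
    make_training_labels(data$elisa, features, data$experiment,
                         data$design, criteria)
  })
  write_tsv(as.data.frame(training), file.path(out_dir, "labels.tsv"),
            comments = sprintf(
              "criteria: cor>%g fold>=%g p<=%g", criteria$cor_threshold,
              criteria$fold_threshold, criteria$p_threshold))
  counts["labeled_peptides"] <- nrow(training)

  cv <- NULL
  if (isTRUE(config$cv$enabled)) {
    cv <- run_stage("cv", {
      cc <- config$cv
      cross_validate(training, n_repeats = cc$n_repeats,
                     train_fraction = cc$train_fraction,
                     stratified = cc$stratified,
                     n_trees = config$forest$n_trees,
                     min_leaf = config$forest$min_leaf,
                     seed = cc$seed, feature_aucs = cc$feature_aucs,
                     feature_auc_mode = cc$feature_auc_mode)
    })
    write_cv_report(cv, file.path(out_dir, "cv_report.tsv"))
  }

  model <- run_stage("train", {
    validation_model(training, n_trees = config$forest$n_trees,
                     min_leaf = config$forest$min_leaf,
                     seed = config$forest$seed)
  })
  probabilities <- run_stage("predict", predict(model, features))
  write_tsv(probabilities, file.path(out_dir, "probabilities.tsv"))
  counts["scored_peptides"] <- nrow(probabilities)

  sel <- run_stage("select", {
    t_all <- config$selection$all_exceed_threshold
    t_mean <- config$selection$mean_exceeds_threshold
    list(all = select_peptides(probabilities,
                               selection_rule("all_exceed", t_all)),
         mean = select_peptides(probabilities,
                                selection_rule("mean_exceeds", t_mean)))
  })
  write_tsv(sel$all, file.path(out_dir, "selection_all_exceed.tsv"),
            comments = sprintf("rule: all_exceed > %g",
                               config$selection$all_exceed_threshold))
  write_tsv(sel$mean, file.path(out_dir, "selection_mean_exceeds.tsv"),
            comments = sprintf("rule: mean_exceeds > %g",
                               config$selection$mean_exceeds_threshold))
  counts["selected_all_exceed"] <- nrow(sel$all)
  counts["selected_mean_exceeds"] <- nrow(sel$mean)
  recs <- data$library$records
  if (nrow(sel$mean) > 0L)
    write_selected_fasta(recs[recs$peptide_id %in% sel$mean$peptide_id, ],
                         file.path(out_dir, "selection_mean_exceeds.fasta"))

  enrichment <- run_stage("enrich",
                          enrichment_report(sel$all, data$library))
  write_tsv(data.frame(metric = names(unclass(enrichment)),
                       value = vapply(unclass(enrichment), function(v)
                         format(v, digits = 10), character(1))),
            file.path(out_dir, "enrichment.tsv"))

  config_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, config_path)
  manifest <- c(
    sprintf("pepforest %s", as.character(utils::packageVersion("pepforest"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("config_md5: %s", unname(tools::md5sum(config_path))),
    sprintf("seeds: simulate=%s forest=%s cv=%s",
            config$simulate$seed, config$forest$seed, config$cv$seed),
    sprintf("%s: %d", names(counts), counts))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(data = data, inference = inference, features = features,
                 training = training, cv = cv, model = model,
                 probabilities = probabilities,
                 selection_all = sel$all, selection_mean = sel$mean,
                 enrichment = enrichment, out_dir = out_dir))
}
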