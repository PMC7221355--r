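#' Default run configuration
#'
#' Returns the full configuration list for [run_pipeline()], with every
#' option at its routine-use default: 1000 rewiring permutations per subject
#' for the null model, 10000 label permutations for the cluster FWE, cell
#' alpha 0.05, edge alpha 0.01, edge filtration values 0.35/0.5/0.75/1.0,
#' AUC domain \[0, 2\].
#'
#' @param output_dir Where stages write their artifacts.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(output_dir = "betticonn_output") {
  structure(list(
    paths = list(
      output_dir = output_dir,
      matrices_dir = file.path(output_dir, "matrices"),
      phenotypes = file.path(output_dir, "phenotypes.csv"),
      partition = file.path(output_dir, "partition.csv"),
      feature_tables = NULL  # named list of CSVs for the concord stage
    ),
    analysis = list(
      eps_list = c(0.35, 0.5, 0.75, 1.0),
      n_perm_null = 1000,
      n_perm_fwe = 10000,
      alpha_cell = 0.05,
      alpha_edge = 0.01,
      case = NULL,
      seed = 1L
    ),
    simulate = list()  # overrides passed to cohort_spec()
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override [default_run_config()]; everything
#' else keeps its default.
#'
#' @param path YAML file.
#' @param output_dir Default output directory when the file names none.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, output_dir = "betticonn_output") {
  usr <- yaml::read_yaml(path)
  cfg <- default_run_config(output_dir)
  for (section in intersect(names(usr), names(cfg))) {
    for (key in names(usr[[section]])) {
      cfg[[section]][[key]] <- usr[[section]][[key]]
    }
  }
  cfg
}

read_cohort_inputs <- function(cfg) {
  files <- sort(list.files(cfg$paths$matrices_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no connectome CSVs in ", cfg$paths$matrices_dir)
  cms <- lapply(files, read_connectome)
  names(cms) <- sub("\\.csv$", "", basename(files))
  phen <- read_phenotypes(cfg$paths$phenotypes)
  if (!setequal(phen$subject_id, names(cms))) {
    stop("subject ids in phenotypes do not match connectome files")
  }
  cms <- cms[phen$subject_id]
  list(cms = cms, phen = phen,
       partition = read_partition(cfg$paths$partition))
}

#' Run one analysis stage or the whole pipeline
#'
#' Stages read the prior stage's CSV artifacts from the configured paths and
#' write their own into `output_dir`:
#' \describe{
#'   \item{simulate}{synthetic cohort: one connectome CSV per subject,
#'     `phenotypes.csv`, `partition.csv`, and a JSON echo of the generator
#'     spec.}
#'   \item{curves}{per-subject Betti-0 curve breakpoints,
#'     `curves/<id>.csv`.}
#'   \item{features}{`features.csv` of per-subject AUC, slope, kurtosis.}
#'   \item{null}{`null_features.csv` (per subject and permutation) and
#'     `null_p.csv` of per-subject empirical p-values, plus pooled ones.}
#'   \item{infer}{`model.csv`, the whole-brain logistic coefficient table.}
#'   \item{scan}{`scan.csv`, the subnetwork grid with cluster FWE
#'     p-values.}
#'   \item{edges}{`edges.csv`, edge-proportion contrasts at the configured
#'     filtration values.}
#'   \item{concord}{`kcc.csv`, pairwise Kendall's W across the configured
#'     feature tables.}
#'   \item{pipeline}{simulate, curves, features, null, infer, scan, edges
#'     in sequence.}
#' }
#' A `manifest.json` in `output_dir` records the configuration, seed,
#' package version and per-stage completion status.
#'
#' @param stage Stage name.
#' @param config A `run_config` (see [default_run_config()]).
#' @return Invisibly, the stage's main result object.
#' @export
run_stage <- function(stage = c("simulate", "curves", "features", "null",
                                "infer", "scan", "edges", "concord",
                                "pipeline"),
                      config = default_run_config()) {
  stage <- match.arg(stage)
  cfg <- config
  dir.create(cfg$paths$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "pipeline") return(run_pipeline(cfg))

  res <- switch(stage,
    simulate = {
      spec <- do.call(cohort_spec,
                      c(cfg$simulate,
                        if (is.null(cfg$simulate$seed))
                          list(seed = cfg$analysis$seed)))
      cohort <- simulate_cohort(spec)
      dir.create(cfg$paths$matrices_dir, showWarnings = FALSE,
                 recursive = TRUE)
      for (id in names(cohort$connectomes)) {
        write_connectome(cohort$connectomes[[id]],
                         file.path(cfg$paths$matrices_dir,
                                   paste0(id, ".csv")))
      }
      write.csv(cohort$phenotypes, cfg$paths$phenotypes, row.names = FALSE)
      write_partition(cohort$partition, cfg$paths$partition)
      spec_plain <- Filter(Negate(is.null), unclass(spec))
      jsonlite::write_json(
        lapply(spec_plain, function(v) if (is.numeric(v)) unname(v) else v),
        file.path(cfg$paths$output_dir, "cohort_spec.json"),
        auto_unbox = TRUE, digits = NA)
      cohort
    },
    curves = {
      inp <- read_cohort_inputs(cfg)
      dir <- file.path(cfg$paths$output_dir, "curves")
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (id in names(inp$cms)) {
        write_b0_curve(b0_curve(inp$cms[[id]]),
                       file.path(dir, paste0(id, ".csv")))
      }
      dir
    },
    features = {
      inp <- read_cohort_inputs(cfg)
      feats <- cohort_features(inp$cms)
      write.csv(feats, file.path(cfg$paths$output_dir, "features.csv"),
                row.names = FALSE)
      feats
    },
    null = {
      inp <- read_cohort_inputs(cfg)
      feats <- cohort_features(inp$cms)
      rows <- list(); prow <- list()
      for (i in seq_along(inp$cms)) {
        id <- names(inp$cms)[i]
        ens <- null_features(inp$cms[[i]], n_perm = cfg$analysis$n_perm_null,
                             seed = derive_seed(cfg$analysis$seed, i))
        obs <- feats[feats$subject_id == id, ]
        rows[[i]] <- cbind(subject_id = id,
                           perm = seq_len(ens$n_perm), ens$features)
        prow[[i]] <- data.frame(
          subject_id = id,
          p_auc = empirical_p(obs$auc, ens, "auc", "greater"),
          p_slope = empirical_p(obs$slope, ens, "slope", "less"),
          p_kurtosis = empirical_p(obs$kurtosis, ens, "kurtosis",
                                   "two.sided"))
      }
      nulls <- do.call(rbind, rows)
      ptab <- do.call(rbind, prow)
      # pooled p: fraction of all subject-by-permutation draws at least as
      # extreme as the matching subject's observed value
      obs_rep <- feats[match(nulls$subject_id, feats$subject_id), ]
      nperm_all <- nrow(nulls)
      k_ge <- (1 + sum(nulls$kurtosis >= obs_rep$kurtosis)) / (1 + nperm_all)
      k_le <- (1 + sum(nulls$kurtosis <= obs_rep$kurtosis)) / (1 + nperm_all)
      pooled <- data.frame(
        subject_id = "(pooled)",
        p_auc = (1 + sum(nulls$auc >= obs_rep$auc)) / (1 + nperm_all),
        p_slope = (1 + sum(nulls$slope <= obs_rep$slope)) / (1 + nperm_all),
        p_kurtosis = min(1, 2 * min(k_ge, k_le)))
      ptab <- rbind(ptab, pooled)
      write.csv(nulls, file.path(cfg$paths$output_dir, "null_features.csv"),
                row.names = FALSE)
      write.csv(ptab, file.path(cfg$paths$output_dir, "null_p.csv"),
                row.names = FALSE)
      ptab
    },
    infer = {
      inp <- read_cohort_inputs(cfg)
      feats <- read.csv(file.path(cfg$paths$output_dir, "features.csv"),
                        stringsAsFactors = FALSE)
      fit <- fit_group_model(feats, inp$phen, case = cfg$analysis$case)
      write.csv(fit$coefficients,
                file.path(cfg$paths$output_dir, "model.csv"),
                row.names = FALSE)
      fit
    },
    scan = {
      inp <- read_cohort_inputs(cfg)
      sc <- subnetwork_scan(inp$cms, inp$partition, inp$phen,
                            case = cfg$analysis$case)
      sc <- fwe_correct(sc, n_perm = cfg$analysis$n_perm_fwe,
                        seed = cfg$analysis$seed,
                        alpha_cell = cfg$analysis$alpha_cell)
      write.csv(sc$cells[setdiff(names(sc$cells), "nodes")],
                file.path(cfg$paths$output_dir, "scan.csv"),
                row.names = FALSE)
      sc
    },
    edges = {
      inp <- read_cohort_inputs(cfg)
      ep <- edge_proportion_test(inp$cms, inp$phen$group,
                                 eps = cfg$analysis$eps_list,
                                 case = cfg$analysis$case,
                                 alpha = cfg$analysis$alpha_edge)
      write.csv(ep, file.path(cfg$paths$output_dir, "edges.csv"),
                row.names = FALSE)
      ep
    },
    concord = {
      tabs <- cfg$paths$feature_tables
      if (is.null(tabs) || length(tabs) < 2) {
        stop("concord stage needs at least two feature_tables paths")
      }
      tables <- lapply(tabs, read.csv, stringsAsFactors = FALSE)
      kcc <- pairwise_kcc(tables)
      write.csv(kcc, file.path(cfg$paths$output_dir, "kcc.csv"),
                row.names = FALSE)
      kcc
    })
  update_manifest(cfg, stage, ok = TRUE)
  invisible(res)
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config = default_run_config()) {
  stages <- c("simulate", "curves", "features", "null", "infer", "scan",
              "edges")
  out <- list()
  for (st in stages) {
    res <- tryCatch(run_stage(st, config), error = function(e) e)
    if (inherits(res, "error")) {
      update_manifest(config, st, ok = FALSE,
                      message = conditionMessage(res))
      stop("pipeline stage '", st, "' failed: ", conditionMessage(res))
    }
    out[[st]] <- res
  }
  invisible(out)
}

update_manifest <- function(cfg, stage, ok, message = NULL) {
  path <- file.path(cfg$paths$output_dir, "manifest.json")
  manifest <- if (file.exists(path)) jsonlite::read_json(path) else
    list(package = "betticonn",
         version = as.character(utils::packageVersion("betticonn")),
         seed = cfg$analysis$seed,
         config = cfg, stages = list())
  manifest$stages[[stage]] <- list(
    ok = ok, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    message = message)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
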