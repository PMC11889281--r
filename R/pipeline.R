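#' Run the analysis pipeline
#'
#' Orchestrates the stages `simulate -> validate -> grm -> fit -> cv ->
#' pca -> describe` from a single configuration (an R list or a YAML
#' file path), writing every artifact as CSV plus a JSON manifest
#' recording inputs, outputs and the seed. Identical configuration and
#' seed give bit-identical numeric outputs. Configuration keys:
#'
#' * `out_dir` (required), `seed` (default 1), `stages` (default all),
#' * `sim`: arguments for [sim_config()] (when simulating),
#' * `dosage`, `pedigree`, `phenotypes`: input CSV paths (when not
#'   simulating),
#' * `ploidy` (default 4), `filter`: `max_missing` / `min_maf`,
#' * `model`: `traits` (default all), `fixed` (default "year"),
#' * `cv`: `schemes` (default `"total"`), `n_repeats`.
#'
#' Input paths are checked before any stage runs; a stage failure halts
#' the pipeline with a located error.
#'
#' @param config List or path to a YAML file.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop2("config$out_dir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  all_stages <- c("simulate", "validate", "grm", "fit", "cv", "pca",
                  "describe")
  stages <- if (is.null(config$stages)) all_stages else
    match.arg(config$stages, all_stages, several.ok = TRUE)
  ploidy_ <- if (is.null(config$ploidy)) 4L else as.integer(config$ploidy)

  # pre-flight: every file a selected stage needs must exist up front
  if (!"simulate" %in% stages) {
    need <- c(dosage = config$dosage, pedigree = config$pedigree)
    if (any(c("fit", "cv", "describe") %in% stages))
      need <- c(need, phenotypes = config$phenotypes)
    missing_keys <- names(need)[vapply(need, is.null, TRUE)]
    if (is.null(config$dosage) || is.null(config$pedigree) ||
        (any(c("fit", "cv", "describe") %in% stages) &&
         is.null(config$phenotypes)))
      stop2("pre-flight: input path(s) missing from config for the ",
            "selected stages")
    absent <- unlist(need)[!file.exists(unlist(need))]
    if (length(absent))
      stop2("pre-flight: input file(s) not found: ",
            paste(absent, collapse = ", "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, stages = stages, inputs = list(),
                   outputs = character(0),
                   package_version = as.character(utils::packageVersion("tetraGS")))
  emit <- function(name) manifest$outputs <<- c(manifest$outputs,
                                                file.path(config$out_dir, name))
  pth <- function(name) file.path(config$out_dir, name)

  if ("simulate" %in% stages) {
    sc <- do.call(sim_config, c(config$sim, list(seed = seed)))
    pop <- simulate_population(sc)
    dos <- pop$dosages; ped <- pop$pedigree; rec <- pop$records
    write_dosage(dos, pth("dosages.csv")); emit("dosages.csv")
    write_pedigree(ped, pth("pedigree.csv")); emit("pedigree.csv")
    write_phenotypes(rec, pth("phenotypes.csv")); emit("phenotypes.csv")
    utils::write.csv(pop$true_values, pth("true_values.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("true_values.csv")
  } else {
    dos <- read_dosage(config$dosage, ploidy = ploidy_)
    ped <- read_pedigree(config$pedigree)
    rec <- if (!is.null(config$phenotypes))
      read_phenotypes(config$phenotypes, ped) else NULL
    manifest$inputs <- list(dosage = config$dosage,
                            pedigree = config$pedigree,
                            phenotypes = config$phenotypes)
  }

  if ("validate" %in% stages) {
    fl <- filter_markers(dos,
                         max_missing = config$filter$max_missing %||% 0.2,
                         min_maf = config$filter$min_maf %||% 0.01)
    dos <- impute_missing(fl$matrix)
    utils::write.csv(fl$report, pth("marker_filter_report.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("marker_filter_report.csv")
  } else if (anyNA(dos)) dos <- impute_missing(dos)

  grm <- NULL
  if (any(c("grm", "fit", "cv") %in% stages)) {
    grm <- build_grm(dos)
    if ("grm" %in% stages) {
      write_grm(grm, pth("grm.csv")); emit("grm.csv")
    }
  }

  traits <- config$model$traits %||% unique(rec$trait)
  fixed <- config$model$fixed %||% "year"
  fits <- list()
  if (any(c("fit", "cv") %in% stages)) {
    if (is.null(rec)) stop2("fit/cv stages need phenotype records")
    for (tr in traits) {
      spec <- model_spec(tr, fixed = fixed)
      fit <- fit_gblup(rec, spec, grm, ped)
      fits[[tr]] <- fit
      if ("fit" %in% stages) {
        gt <- data.frame(id = names(fit$gebv), gebv = unname(fit$gebv),
                         pev = unname(fit$pev),
                         accuracy = unname(fit$accuracy),
                         n_records = unname(fit$n_records[names(fit$gebv)]))
        utils::write.csv(gt, pth(paste0("gebv_", tr, ".csv")),
                         row.names = FALSE, quote = FALSE)
        emit(paste0("gebv_", tr, ".csv"))
        vcdf <- data.frame(trait = tr, sigma_a2 = fit$vc$sigma_a2,
                           sigma_e2 = fit$vc$sigma_e2,
                           h2 = fit$heritability,
                           loglik = fit$vc$loglik,
                           boundary = fit$vc$boundary)
        utils::write.csv(vcdf, pth(paste0("vc_", tr, ".csv")),
                         row.names = FALSE, quote = FALSE)
        emit(paste0("vc_", tr, ".csv"))
        utils::write.csv(fit$wald, pth(paste0("wald_", tr, ".csv")),
                         row.names = FALSE, quote = FALSE)
        emit(paste0("wald_", tr, ".csv"))
      }
    }
  }

  if ("cv" %in% stages) {
    schemes <- config$cv$schemes %||% "total"
    nrep <- config$cv$n_repeats %||% 200L
    for (tr in traits) {
      spec <- model_spec(tr, fixed = fixed)
      rows <- list()
      for (sch in schemes) {
        res <- subpopulation_cv(rec, spec, grm, ped, scheme = sch,
                                n_repeats = nrep,
                                seed = derive_seed(seed, paste0("cv:", tr)))
        rows[[sch]] <- if (sch == "AAxAA*")
          data.frame(trait = tr, scheme = sch, group = "mean",
                     n = res$n_per_draw, r = res$mean_r, p_value = NA_real_)
        else {
          groups <- c(list(overall = res$overall), res$by_cross_type)
          do.call(rbind, lapply(names(groups), function(g)
            data.frame(trait = tr, scheme = sch, group = g,
                       n = groups[[g]]$n, r = groups[[g]]$r,
                       p_value = groups[[g]]$p_value)))
        }
        if (sch == "total") {
          utils::write.csv(res$folds, pth(paste0("cv_folds_", tr, ".csv")),
                           row.names = FALSE, quote = FALSE)
          emit(paste0("cv_folds_", tr, ".csv"))
        }
      }
      cvtab <- do.call(rbind, rows); rownames(cvtab) <- NULL
      utils::write.csv(cvtab, pth(paste0("cv_summary_", tr, ".csv")),
                       row.names = FALSE, quote = FALSE)
      emit(paste0("cv_summary_", tr, ".csv"))
    }
  }

  if ("pca" %in% stages) {
    pc <- pca_dosage(dos, n_components = min(10L, nrow(dos) - 1L))
    sc <- data.frame(id = rownames(pc$scores), pc$scores)
    utils::write.csv(sc, pth("pca_scores.csv"), row.names = FALSE,
                     quote = FALSE)
    emit("pca_scores.csv")
    utils::write.csv(data.frame(component = seq_along(pc$percent_var),
                                percent_var = pc$percent_var),
                     pth("pca_variance.csv"), row.names = FALSE, quote = FALSE)
    emit("pca_variance.csv")
  }

  if ("describe" %in% stages) {
    if (is.null(rec)) stop2("describe stage needs phenotype records")
    utils::write.csv(describe_traits(rec, ped), pth("trait_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("trait_summary.csv")
  }

  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
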