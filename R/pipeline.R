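# end-to-end pipeline ----------------------------------------------------------

#' Read and validate a run configuration
#'
#' A run configuration is a YAML file (or equivalent list) with exactly one
#' of a `simulation` block (parameters for [sim_config()]) or an `input`
#' block (`vcf`, `phenotypes`, `sample_map`, optional `families` paths),
#' plus optional blocks `filters` (`maf`, `min_depth`, `max_depth`,
#' `call_rate`), `grm` (`method`, `ploidy`), `model` (`traits`, `mode`,
#' `vc`: `"reml"` or a variance-component file path, `reml`: `tol`,
#' `max_iter`), `validation` (`strategy`: `"family_cv"`, `"forward"` or
#' `"none"`, `min_family_size`, `cutoff_year`), and top-level `seed` and
#' `output_dir`.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return The validated configuration list, classed `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s",
                                            config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    abort("config must contain exactly one of `simulation` or `input`.")
  }
  if (has_input) {
    for (f in c("vcf", "phenotypes", "sample_map")) {
      p <- config$input[[f]]
      if (is.null(p)) abort(sprintf("input block is missing `%s`.", f))
      if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
    }
  }
  config$seed <- config$seed %||% 1L
  config$filters <- modifyList(
    list(maf = 0.05, min_depth = 10, max_depth = 200, call_rate = 0.7),
    config$filters %||% list()
  )
  config$grm <- modifyList(list(method = "betabinomial", ploidy = 6),
                           config$grm %||% list())
  config$model <- modifyList(
    list(mode = "single", vc = "reml",
         reml = list(tol = 1e-6, max_iter = 100)),
    config$model %||% list()
  )
  config$validation <- modifyList(
    list(strategy = "none", min_family_size = 10, cutoff_year = NULL),
    config$validation %||% list()
  )
  structure(config, class = c("run_config", "list"))
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- cbind(setNames(data.frame(rownames(x)), rownames_as),
               as.data.frame(x))
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write / read variance components as structured text
#'
#' @param vc A [variance_components()] object.
#' @param path File path (YAML).
#' @return `path` (write) or the `variance_components` object (read).
#' @export
write_variance_components <- function(vc, path) {
  stopifnot(inherits(vc, "variance_components"))
  yaml::write_yaml(list(
    traits = vc$traits,
    V_M = apply(vc$V_M, 1, as.list, simplify = FALSE),
    V_C = apply(vc$V_C, 1, as.list, simplify = FALSE),
    V_E = apply(vc$V_E, 1, as.list, simplify = FALSE)
  ), path)
  invisible(path)
}

#' @rdname write_variance_components
#' @export
read_variance_components <- function(path) {
  x <- yaml::read_yaml(path)
  as_m <- function(l) {
    m <- do.call(rbind, lapply(l, function(r) unlist(r, use.names = FALSE)))
    matrix(as.numeric(m), nrow = length(l))
  }
  variance_components(as_m(x$V_M), as_m(x$V_C), as_m(x$V_E),
                      traits = x$traits)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)), parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (simulate to files, or ingest the
#' configured VCF/phenotype/sample-map files), continuous-genotype
#' construction with repeated-sample merging, marker filtering and
#' imputation, relationship-matrix construction, variance-component
#' estimation (EM-REML or a component file), GBLUP, genetic-parameter
#' derivation, and (optionally) validation. Every stage writes its
#' artifact under `output_dir` and the run closes with a YAML manifest
#' recording seed, thresholds, marker attrition, the mean diagonal of G,
#' and all artifact paths. Reruns with the same configuration reproduce
#' all stochastic stages bit-identically through the recorded seed.
#'
#' @param config A [read_run_config()] result, a config list, or a YAML
#'   path.
#' @param output_dir Overrides the configured output directory.
#' @param until Last stage to execute: one of `"simulate"`,
#'   `"genotypes"`, `"grm"`, `"vc"`, `"gblup"`, `"params"`, `"all"`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL, until = "all") {
  config <- read_run_config(config)
  stages <- c("simulate", "genotypes", "grm", "vc", "gblup", "params", "all")
  until <- match.arg(until, stages)
  rank <- match(until, stages)
  out <- output_dir %||% config$output_dir %||% "gbsblup_run"
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = as.character(packageVersion("gbsblup")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    filters = config$filters,
    grm = config$grm,
    model = config$model[c("mode", "vc")],
    artifacts = list()
  )
  art <- function(name, path) manifest$artifacts[[name]] <<- path

  # -- acquire data
  families <- NULL
  if (!is.null(config$simulation)) {
    run_stage("simulate", {
      sim_args <- config$simulation
      sim_args$seed <- sim_args$seed %||% config$seed
      for (nm in c("V_M", "V_C", "V_E")) {
        if (!is.null(sim_args[[nm]])) {
          sim_args[[nm]] <- as.matrix(do.call(rbind, lapply(
            sim_args[[nm]], function(r) as.numeric(unlist(r)))))
        }
      }
      scfg <- do.call(sim_config, sim_args)
      sim <- simulate_dataset(scfg, dir = file.path(out, "sim"))
      families <- sim$genos$families
      config$input <- sim$paths
      art("vcf", sim$paths$vcf)
      art("phenotypes", sim$paths$phenotypes)
      art("sample_map", sim$paths$sample_map)
      write_tsv(families, file.path(out, "families.tsv"))
      art("families", file.path(out, "families.tsv"))
      manifest$simulation <- list(
        n_mothers = scfg$n_mothers, n_markers = scfg$n_markers,
        n_families = scfg$n_families, traits = scfg$trait_names
      )
    })
  } else if (!is.null(config$input$families)) {
    families <- tibble::as_tibble(
      read.table(config$input$families, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE))
  }
  if (rank < match("genotypes", stages)) {
    return(finish_manifest(manifest, out))
  }

  # -- genotypes
  cg <- run_stage("genotypes", {
    rd <- read_vcf_depths(config$input$vcf)
    smap <- read.table(config$input$sample_map, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    cg <- continuous_genotypes(rd) |>
      merge_repeated_samples(smap) |>
      filter_markers(maf_min = config$filters$maf,
                     depth_min = config$filters$min_depth,
                     depth_max = config$filters$max_depth,
                     call_rate_min = config$filters$call_rate) |>
      impute_missing()
    write_tsv(round(cg$f, 6), file.path(out, "genotypes.tsv"),
              rownames_as = "individual")
    write_tsv(cg$filter_log, file.path(out, "filter_log.tsv"))
    art("genotypes", file.path(out, "genotypes.tsv"))
    art("filter_log", file.path(out, "filter_log.tsv"))
    manifest$marker_attrition <- setNames(as.list(cg$filter_log$markers),
                                           cg$filter_log$step)
    cg
  })
  if (rank < match("grm", stages)) return(finish_manifest(manifest, out))

  # -- relationship matrix
  g <- run_stage("grm", {
    g <- genomic_relationship(cg, method = config$grm$method,
                              ploidy = config$grm$ploidy)
    write_tsv(round(g$G, 8), file.path(out, "grm.tsv"),
              rownames_as = "individual")
    art("grm", file.path(out, "grm.tsv"))
    if (!is.null(g$tau)) {
      write_tsv(g$tau, file.path(out, "tau.tsv"))
      art("tau", file.path(out, "tau.tsv"))
    }
    manifest$grm_summary <- as.list(grm_summary(g))
    g
  })
  if (rank < match("vc", stages)) return(finish_manifest(manifest, out))

  # -- phenotypes and variance components
  phen <- run_stage("vc", {
    read.table(config$input$phenotypes, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  })
  traits <- config$model$traits %||%
    setdiff(names(phen), c("record_id", "mother_id", "progeny_id", "trial",
                           "year", "location"))
  data <- trait_data(phen, traits)
  vc <- run_stage("vc", {
    if (identical(config$model$vc, "reml")) {
      rf <- em_reml(data, g, traits = traits,
                    tol = config$model$reml$tol,
                    max_iter = config$model$reml$max_iter)
      manifest$reml <- list(n_iter = rf$n_iter, converged = rf$converged,
                             loglik = rf$loglik)
      rf$vc
    } else {
      read_variance_components(config$model$vc)
    }
  })
  write_variance_components(vc, file.path(out, "variance_components.yml"))
  art("variance_components", file.path(out, "variance_components.yml"))
  if (rank < match("gblup", stages)) return(finish_manifest(manifest, out))

  # -- GBLUP
  fit <- run_stage("gblup", {
    fit <- solve_gblup(data, g, vc, traits = traits,
                       mode = config$model$mode)
    write_tsv(fit$gebv, file.path(out, "gebv.tsv"))
    art("gebv", file.path(out, "gebv.tsv"))
    fit
  })
  if (rank < match("params", stages)) return(finish_manifest(manifest, out))

  # -- genetic parameters
  run_stage("params", {
    gp <- genetic_params(vc, grm_summary(g)$mean_diag)
    write_tsv(gp$params, file.path(out, "genetic_params.tsv"))
    write_tsv(round(param_table(gp), 2), file.path(out, "param_table.tsv"),
              rownames_as = "trait")
    art("genetic_params", file.path(out, "genetic_params.tsv"))
    art("param_table", file.path(out, "param_table.tsv"))
  })

  # -- validation
  if (!identical(config$validation$strategy, "none") && rank >= 7) {
    run_stage("validate", {
      splits <- switch(
        config$validation$strategy,
        family_cv = {
          if (is.null(families)) {
            abort("family cross-validation needs a families table.")
          }
          family_cv_splits(data, families,
                           config$validation$min_family_size)
        },
        forward = list(forward_split(data, config$validation$cutoff_year)),
        abort(sprintf("unknown validation strategy '%s'",
                      config$validation$strategy))
      )
      rep <- run_validation(data, g, vc, splits, traits = traits,
                            mode = config$model$mode)
      write_tsv(rep, file.path(out, "validation.tsv"))
      art("validation", file.path(out, "validation.tsv"))
      manifest$validation <- list(
        strategy = config$validation$strategy,
        n_splits = length(splits),
        mean_predictive_ability = mean(rep$predictive_ability, na.rm = TRUE)
      )
    })
  }
  finish_manifest(manifest, out)
}

finish_manifest <- function(manifest, out) {
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  yaml::write_yaml(manifest, file.path(out, "manifest.yml"))
  invisible(manifest)
}
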