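#' Run the full analysis pipeline from a config
#'
#' Wires the package's stages into the standard workflow
#' `simulate -> divstats -> dist -> ibd -> ranges -> dresd`, executing the
#' requested stages in dependency order, writing every artifact under a
#' run directory, and recording a manifest (package version, config,
#' per-stage seeds, md5 of every output). Re-running the same config
#' reproduces identical artifacts: one global `seed` expands into
#' per-stage seeds through a fixed counter scheme, so each stage is also
#' individually reproducible.
#'
#' Config is a YAML file or an equivalent nested list. Top-level keys:
#' `seed`, `out_dir`, `stages`, `inputs`, and one optional block per
#' stage (`simulate`, `divstats`, `dist`, `ibd`, `ranges`, `dresd`);
#' unknown keys are rejected. Without a `simulate` stage, `inputs` must
#' name a `genotypes` file (+ `genotypes_dialect`), a `coords` CSV and —
#' for `ranges` — a `membership` CSV.
#'
#' @param config path to a YAML file, or a named list.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("seed", "out_dir", "stages", "inputs",
             "simulate", "divstats", "dist", "ibd", "ranges", "dresd")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  seed <- as.integer(cfg$seed %||% 1)
  out_dir <- cfg$out_dir %||% "spatgen_run"
  stage_order <- c("simulate", "divstats", "dist", "ibd", "ranges", "dresd")
  stages <- unlist(cfg$stages %||% stage_order)
  bad <- setdiff(stages, stage_order)
  if (length(bad) > 0) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  stages <- intersect(stage_order, stages)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  state <- list()
  artifacts <- character()
  stage_seeds <- setNames(vapply(seq_along(stage_order), function(k) {
    derive_seed(seed, k)
  }, 0L), stage_order)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  save_csv <- function(df, file) {
    path <- file.path(out_dir, file)
    readr::write_csv(as_tibble(df), path, progress = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sim_args <- cfg$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% stage_seeds[["simulate"]]
      sim <- simulate_dataset(do.call(synth_config, sim_args))
      state$genotypes <<- sim$genotypes
      state$geo <<- sim$geo
      state$membership <<- sim$membership
      write_genotypes(sim$genotypes,
                      file.path(out_dir, "genotypes.csv"), "csv_wide")
      artifacts <<- c(artifacts, file.path(out_dir, "genotypes.csv"))
      save_csv(sim$geo, "coords.csv")
      save_csv(sim$membership, "membership.csv")
      jsonlite::write_json(
        list(group = as.list(sim$truth$group)),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE)
      artifacts <<- c(artifacts, file.path(out_dir, "truth.json"))
    })
  } else {
    inp <- cfg$inputs %||% list()
    if (!is.null(inp$genotypes)) {
      if (!file.exists(inp$genotypes)) {
        abort(paste0("stage 'inputs' failed: genotype file not found: ",
                     inp$genotypes))
      }
      state$genotypes <- read_genotypes(inp$genotypes,
                                        inp$genotypes_dialect %||% "csv_wide")
    }
    if (!is.null(inp$coords)) {
      if (!file.exists(inp$coords)) {
        abort(paste0("stage 'inputs' failed: coordinates file not found: ",
                     inp$coords))
      }
      state$geo <- read_coords(inp$coords)
    }
    if (!is.null(inp$membership)) {
      if (!file.exists(inp$membership)) {
        abort(paste0("stage 'inputs' failed: membership file not found: ",
                     inp$membership))
      }
      state$membership <- read_membership(inp$membership, "csv")
    }
  }

  if ("divstats" %in% stages) {
    run_stage("divstats", function() {
      if (is.null(state$genotypes)) abort("no genotypes available")
      a <- cfg$divstats %||% list()
      ds <- diversity_summary(state$genotypes,
                              raref_n = a$raref_n,
                              fis_mode = a$fis_mode %||% "wc",
                              n_boot = a$n_boot %||% 1000,
                              seed = stage_seeds[["divstats"]])
      state$diversity <<- ds
      save_csv(tidy(ds), "diversity_per_locus.csv")
      save_csv(glance(ds), "diversity_summary.csv")
    })
  }

  if ("dist" %in% stages) {
    run_stage("dist", function() {
      if (is.null(state$genotypes)) abort("no genotypes available")
      a <- cfg$dist %||% list()
      metric <- a$metric %||% "dlr"
      state$dgen <<- switch(metric,
        dlr = {
          groups <- if (identical(a$groups_from, "qmatrix")) {
            if (is.null(state$membership)) abort("no membership matrix for qmatrix groups")
            state$membership
          } else NULL
          dlr_distances(state$genotypes, groups = groups,
                        loo = a$loo %||% TRUE)
        },
        dps = dps_distances(state$genotypes),
        abort(paste0("unknown dist metric: ", metric))
      )
      if (is.null(state$geo)) abort("no coordinates available")
      state$dgeo <<- geographic_distances(state$geo)
      m <- as.data.frame(unclass(state$dgen))
      save_csv(cbind(sample_id = rownames(state$dgen), m), "dist_gen.csv")
    })
  }

  if ("ibd" %in% stages) {
    run_stage("ibd", function() {
      if (is.null(state$dgen) || is.null(state$dgeo)) abort("run the dist stage first")
      a <- cfg$ibd %||% list()
      pairs <- build_pairs(state$geo, state$dgen)
      model <- fit_ibd(pairs, model = a$model %||% "asymptotic_exp")
      mt <- mantel_test(state$dgeo, state$dgen,
                        n_perm = a$n_perm %||% 999,
                        seed = stage_seeds[["ibd"]])
      model <- set_mantel(model, mt)
      state$ibd <<- model
      state$pairs <<- build_pairs(state$geo, state$dgen, ibd_model = model)
      save_csv(glance(model), "ibd_model.csv")
      save_csv(tidy(model), "ibd_parameters.csv")
    })
  }

  if ("ranges" %in% stages) {
    run_stage("ranges", function() {
      if (is.null(state$membership)) abort("no membership matrix available")
      a <- cfg$ranges %||% list()
      grid <- grid_from_samples(state$geo, spacing = a$spacing %||% 5)
      rc <- classify_ranges(state$membership, state$geo, grid = grid,
                            n_boot = a$n_boot %||% 1000,
                            alpha = a$alpha %||% 0.05,
                            resample = a$resample %||% "permute",
                            seed = stage_seeds[["ranges"]])
      state$ranges <<- rc
      write_grid_field(
        rc$field %>% select("x", "y", "group", "value", "lower", "upper", "class"),
        file.path(out_dir, "ranges_grid.csv"), "csv")
      artifacts <<- c(artifacts, file.path(out_dir, "ranges_grid.csv"))
      jsonlite::write_json(rc$report, file.path(out_dir, "ranges_report.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts <<- c(artifacts, file.path(out_dir, "ranges_report.json"))
    })
  }

  if ("dresd" %in% stages) {
    run_stage("dresd", function() {
      if (is.null(state$pairs)) abort("run the ibd stage first")
      a <- cfg$dresd %||% list()
      grid <- grid_from_samples(state$geo, spacing = a$spacing %||% 5)
      classes <- a$classes %||% list(c(20, 80), c(80, 140), c(140, 250))
      classes <- lapply(classes, as.numeric)
      dr <- dresd_analysis(state$pairs, grid, classes = classes,
                           n_iter = a$n_iter %||% 1000,
                           alpha = a$alpha %||% 0.05,
                           seed = stage_seeds[["dresd"]])
      state$dresd <<- dr
      if (nrow(dr$field) > 0) {
        write_grid_field(dr$field %>%
                           select("x", "y", "class_id", "value", "p", "label"),
                         file.path(out_dir, "dresd_grid.csv"), "csv")
        artifacts <<- c(artifacts, file.path(out_dir, "dresd_grid.csv"))
      }
      save_csv(glance(dr), "dresd_classes.csv")
    })
  }

  manifest <- list(
    package = "spatgen",
    version = as.character(utils::packageVersion("spatgen")),
    seed = seed,
    stage_seeds = as.list(stage_seeds[stages]),
    stages = stages,
    config = cfg,
    artifacts = lapply(setNames(nm = artifacts), function(p) {
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(state, list(manifest = manifest)))
}
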