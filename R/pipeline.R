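# End-to-end orchestration: reproducible configuration, staged execution
# (simulate -> detect -> classify -> fit -> report), delimited-text
# artifacts with documented headers, fixtures, a run manifest, and a small
# command-line front end.

write_stage_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname run_pipeline
#' @param path file path of a stage artifact.
#' @export
read_stage_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Pipeline run configuration
#'
#' A flat, file-serializable list of everything a run needs. Replicate
#' counts default to full analysis scale (2000 Silverman
#' bootstrap replicates, 1000 sensing-QDA replicates, 100 encounter samples,
#' 500 worm bootstraps); fixture-scale runs pass smaller counts.
#'
#' @param out_dir output directory for stage artifacts.
#' @param stages subset of c("simulate", "detect", "classify", "fit").
#' @param layout_kind,density_conditions,n_worms_per_condition,duration_s
#'   simulate-stage settings; one simulated plate per density condition.
#' @param fps frames per second.
#' @param seed master seed; stage seeds are derived by fixed splitting.
#' @param alpha_grid GMM regularization grid.
#' @param n_qda_replicates,n_encounter_sets,n_worm_sets replicate counts.
#' @param glm_spec covariate names for the fitted model.
#' @param lambda ridge penalty for the fit stage.
#' @param acclimation_density history-covariate initialization.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "detect", "classify", "fit"),
                       layout_kind = "isometric_grid",
                       density_conditions = c(0, 5, 10),
                       n_worms_per_condition = 1L,
                       duration_s = 1200, fps = 3, seed = 1L,
                       alpha_grid = 0.025, n_qda_replicates = 1000L,
                       n_encounter_sets = 100L, n_worm_sets = 500L,
                       glm_spec = c("rho_k", "tau_s"), lambda = 0.01,
                       acclimation_density = 10) {
  bad <- setdiff(stages, c("simulate", "detect", "classify", "fit"))
  if (length(bad)) stop_config("unknown stages: ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, stages = stages,
                 layout_kind = layout_kind,
                 density_conditions = density_conditions,
                 n_worms_per_condition = as.integer(n_worms_per_condition),
                 duration_s = duration_s, fps = fps, seed = as.integer(seed),
                 alpha_grid = alpha_grid,
                 n_qda_replicates = as.integer(n_qda_replicates),
                 n_encounter_sets = as.integer(n_encounter_sets),
                 n_worm_sets = as.integer(n_worm_sets),
                 glm_spec = glm_spec, lambda = lambda,
                 acclimation_density = acclimation_density),
            class = "run_config")
}

#' Write / read a run configuration as a flat key-value file
#'
#' Vector-valued fields are comma-joined; the round trip is exact.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(unclass(config)), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  kv <- strsplit(readLines(path), " = ", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x)
    if (length(x) > 1) strsplit(x[2], ",", fixed = TRUE)[[1]] else ""),
    vapply(kv, `[[`, "", 1))
  num <- c("density_conditions", "n_worms_per_condition", "duration_s",
           "fps", "seed", "alpha_grid", "n_qda_replicates",
           "n_encounter_sets", "n_worm_sets", "lambda",
           "acclimation_density")
  for (k in intersect(num, names(vals))) vals[[k]] <- as.numeric(vals[[k]])
  do.call(run_config, vals)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  content <- config
  content$out_dir <- NULL   # hash the scientific content, not the location
  write_config(content, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the foraging-analysis pipeline
#'
#' Executes the enabled stages in order. `simulate` writes trajectory,
#' arena, and ground-truth tables (one simulated plate per density
#' condition, worm ids globally unique); `detect` writes the encounter
#' table; `classify` writes the classification table (posteriors plus the
#' three-way search/sample/exploit probabilities); `fit` writes the
#' coefficient table with ensemble means, sds, CIs, and p-values. A manifest
#' (config hash, per-stage row counts, seeds, timings) is written and
#' returned; identical configurations yield identical manifests hashes and
#' byte-identical tables.
#'
#' @param config a `run_config`.
#' @return invisible manifest data.frame (also written to
#'   `manifest.tsv` in `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, rows, seed, secs) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, rows = rows, seed = seed,
      wall_clock_s = round(secs, 3))
  }
  artifact <- function(name) file.path(config$out_dir, name)
  need <- function(name, producer) {
    if (!file.exists(artifact(name)))
      stop("missing upstream artifact '", name, "'; run the '", producer,
           "' stage first", call. = FALSE)
    read_stage_table(artifact(name))
  }

  if ("simulate" %in% config$stages) {
    t0 <- proc.time()[3]
    params <- behavior_params(fps = config$fps,
                              acclimation_density =
                                config$acclimation_density)
    trajs <- list(); truths <- list(); arenas <- list()
    wid0 <- 0L
    for (ci in seq_along(config$density_conditions)) {
      dens <- config$density_conditions[ci]
      arena <- generate_world(config$layout_kind, dens,
                              seed = derive_seed(config$seed, ci))
      sim <- simulate_worms(arena, params, config$duration_s,
                            config$n_worms_per_condition,
                            seed = derive_seed(config$seed, 100L + ci))
      sim$trajectory$worm_id <- sim$trajectory$worm_id + wid0
      sim$truth$worm_id <- sim$truth$worm_id + wid0
      at <- arena$patches
      at$condition <- ci
      at$arena_radius <- arena$arena_radius
      trajs[[ci]] <- cbind(sim$trajectory, condition = ci)
      truths[[ci]] <- sim$truth
      arenas[[ci]] <- at
      wid0 <- wid0 + config$n_worms_per_condition
    }
    write_stage_table(do.call(rbind, trajs), artifact("trajectory.tsv"))
    write_stage_table(do.call(rbind, arenas), artifact("arena.tsv"))
    write_stage_table(do.call(rbind, truths), artifact("ground_truth.tsv"))
    note("simulate", sum(vapply(trajs, nrow, 1L)), config$seed,
         proc.time()[3] - t0)
  }

  if ("detect" %in% config$stages) {
    t0 <- proc.time()[3]
    traj <- need("trajectory.tsv", "simulate")
    at <- need("arena.tsv", "simulate")
    enc <- do.call(rbind, lapply(split(seq_len(nrow(at)), at$condition),
      function(ri) {
        a <- structure(list(arena_radius = at$arena_radius[ri[1]],
                            patches = at[ri, c("patch_id", "x", "y",
                                               "radius", "density")],
                            layout_kind = "custom", grid_spacing = NA),
                       class = "arena_spec")
        tr <- traj[traj$condition == at$condition[ri[1]], ]
        detect_encounters(tr, a, detection_thresholds(), config$fps)
      }))
    rownames(enc) <- NULL
    write_stage_table(enc, artifact("encounters.tsv"))
    note("detect", nrow(enc), config$seed, proc.time()[3] - t0)
  }

  if ("classify" %in% config$stages) {
    t0 <- proc.time()[3]
    enc <- need("encounters.tsv", "detect")
    cls <- classify_encounters(enc, alpha_grid = config$alpha_grid,
                               n_replicates = config$n_qda_replicates,
                               seed = derive_seed(config$seed, 300L))
    write_stage_table(cls$encounters, artifact("classification.tsv"))
    note("classify", nrow(cls$encounters), config$seed,
         proc.time()[3] - t0)
  }

  if ("fit" %in% config$stages) {
    t0 <- proc.time()[3]
    cls <- need("classification.tsv", "classify")
    cls$q <- cls$p_exploit
    ds <- build_covariates(cls,
                           acclimation_density = config$acclimation_density)
    ens <- fit_ensemble(ds, config$glm_spec,
                        n_encounter_sets = config$n_encounter_sets,
                        n_worm_sets = config$n_worm_sets,
                        seed = derive_seed(config$seed, 400L),
                        lambda = config$lambda)
    ct <- coefficient_test(ens)
    ci <- ensemble_ci(ens)
    ct$ci_lower <- ci[, 1]; ct$ci_upper <- ci[, 2]
    write_stage_table(ct, artifact("coefficients.tsv"))
    write_stage_table(as.data.frame(ens$beta), artifact("ensemble.tsv"))
    note("fit", nrow(ct), config$seed, proc.time()[3] - t0)
  }

  man <- do.call(rbind, manifest)
  rownames(man) <- NULL
  man$config_hash <- config_hash(config)
  man$package_version <- as.character(utils::packageVersion("patchforage"))
  write_stage_table(man, artifact("manifest.tsv"))
  invisible(man)
}

#' Write a named, self-contained test fixture
#'
#' `"tiny-world"`: three simulated 20-minute plates (densities 0, 5, 10; one
#' worm each, 19-patch grid) with trajectory, arena, and ground-truth tables.
#' `"glm-bench"`: a 200-worm x 20-encounter covariate-level dataset with the
#' benchmark coefficients beta_true = (-2, 1, 0.5, -0.5, -0.5) and its
#' ground-truth answer file.
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisible character vector of written files.
#' @export
make_fixture <- function(name = c("tiny-world", "glm-bench"), seed = 7L,
                         dir = tempdir()) {
  name <- match.arg(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (name == "tiny-world") {
    cfg <- run_config(out_dir = dir, stages = "simulate", seed = seed)
    run_pipeline(cfg)
    files <- file.path(dir, c("trajectory.tsv", "arena.tsv",
                              "ground_truth.tsv"))
  } else {
    g <- generate_covariate_dataset(seed = seed)
    write_stage_table(as.data.frame(g$dataset),
                      file.path(dir, "glm_bench_dataset.tsv"))
    write_stage_table(data.frame(coef = c("intercept", "rho_k", "tau_s",
                                          "rho_h", "rho_e"),
                                 beta_true = attr(g$dataset, "beta_true")),
                      file.path(dir, "glm_bench_truth.tsv"))
    write_stage_table(g$truth, file.path(dir, "glm_bench_draws.tsv"))
    files <- file.path(dir, c("glm_bench_dataset.tsv",
                              "glm_bench_truth.tsv", "glm_bench_draws.tsv"))
  }
  invisible(files)
}

#' Command-line entry point
#'
#' Subcommands: `simulate | detect | classify | fit` (run those stages from
#' a config file), `run` (all stages), `fixture <name> <seed> <dir>`, and
#' `config <path>` (write a default config to edit). Invoked by the
#' `inst/cli/patchforage` script as
#' `Rscript -e 'patchforage::pipeline_cli()' <args>`.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return invisibly, the manifest or file list of the executed command.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: patchforage <run|simulate|detect|classify|fit>",
                 "--config <path> | fixture <name> <seed> <dir> |",
                 "config <path>")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  if (cmd == "fixture") {
    if (length(args) < 4L) stop(usage, call. = FALSE)
    return(invisible(make_fixture(args[2], as.integer(args[3]), args[4])))
  }
  if (cmd == "config") {
    if (length(args) < 2L) stop(usage, call. = FALSE)
    return(invisible(write_config(run_config(out_dir = "pipeline_out"),
                                  args[2])))
  }
  ci <- which(args == "--config")
  if (!length(ci) || ci + 1L > length(args)) stop(usage, call. = FALSE)
  config <- read_config(args[ci + 1L])
  if (cmd != "run") {
    if (!cmd %in% c("simulate", "detect", "classify", "fit"))
      stop(usage, call. = FALSE)
    config$stages <- cmd
  }
  man <- run_pipeline(config)
  message("pipeline complete: ", nrow(man), " stage(s), outputs in ",
          config$out_dir)
  invisible(man)
}
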