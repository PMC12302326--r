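# End-to-end orchestration: generate (or load) inputs, dock, analyse
# trajectories, evaluate variants, and write a report bundle.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    # stage toggles
    run_dock = TRUE, run_trajectory = TRUE, run_variants = TRUE,
    run_stability = TRUE, run_conservation = TRUE,
    # synthetic inputs
    n_frames = 200L, n_replicas = 3L,
    pocket = "channel",
    # trajectory analytics
    contact_cutoff = 2.5, hotspot_threshold = 50, exclude_resnos = 267L,
    hbond_dist = 3.5, hbond_angle = 150, salt_dist = 4.0, q_ion = 0.25,
    energy_cutoff = 10, min_state_frames = 5L,
    aromatic_resno = 134L, donor_resno = 330L,
    # docking
    dock_units = 2L, dock_samples = 200L, dock_keep = 10L,
    dock_dihedral_samples = 2L, dock_jitter = 15, dock_rmsd = 2.0,
    dock_seed_radius = 8, dock_clash = 2.0, dock_cutoff = 10,
    # variants
    variant_folds = c(F134W = 2.8, D304M = 3.0, `F134W/D304M` = 5.3),
    parent_activity = 77, screen_noise_cv = 0.03, screen_replicates = 3L,
    epistasis_singles = c("F134W", "D304M"),
    epistasis_combo = "F134W/D304M", k_sigma = 2,
    # stability
    tm_parent = 85.7, tm_variant = 89.9, melt_noise = 0.01,
    # conservation
    msa_length = 320L, msa_seqs = 60L,
    conserved_positions = setdiff(300:308, 304:305),
    variable_positions = c(304L, 305L),
    cons_window = 9L, ic_high = 3.0, ic_low = 1.0
  )
}

#' Build and validate a pipeline run configuration
#'
#' A single flat configuration drives [run_pipeline()]: stage toggles, every
#' tunable with its module default, and the master seed. Unknown keys are
#' rejected.
#'
#' @param ... Named overrides of the defaults, or a single unnamed list /
#'   YAML file path carrying them.
#' @return Named list of class `pa_run_config`.
#' @export
pipeline_config <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots))) {
    x <- dots[[1]]
    if (is.character(x) && length(x) == 1) x <- yaml::read_yaml(x)
    dots <- x
  }
  cfg <- .pipeline_defaults()
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (k in names(dots)) {
    v <- dots[[k]]
    if (k %in% c("variant_folds")) v <- unlist(v)
    cfg[[k]] <- v
  }
  if (!is.numeric(cfg$seed)) stop("seed must be numeric")
  structure(cfg, class = c("pa_run_config", "list"))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

.write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline on the packaged synthetic bundle
#'
#' Executes, under a single seed: input generation, incremental docking of a
#' short polyamide oligomer into the toy pocket, trajectory analytics
#' (contacts, hotspots, hydrogen bonds, salt bridges, conditional energies,
#' side-chain states), variant evaluation (specific activities,
#' fold-changes, epistasis), thermal-stability extraction, and conservation
#' analysis. Artifacts (TSV/JSON plus a markdown summary) are written to
#' `out_dir`, each run stamped with the configuration hash and seed. A stage
#' failure retains the artifacts already written and raises an error naming
#' the stage.
#'
#' @param config A [pipeline_config()] (or arguments accepted by it).
#' @param out_dir Output directory, created if missing.
#' @return List of class `pa_pipeline_result` with per-stage results,
#'   artifact paths, and timings (seconds).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("padock_run_")) {
  if (!inherits(config, "pa_run_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  stamp <- list(config_hash = cfg_hash, seed = config$seed)
  paths <- character(0)
  timings <- numeric(0)
  res <- list()

  run_stage <- function(name, enabled, fun) {
    if (!enabled) {
      message("stage ", name, ": skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    message("stage ", name, ": running")
    out <- tryCatch(fun(), error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res[[name]] <<- out
    out
  }

  .write_json(c(stamp, unclass(config)), file.path(out_dir, "run_config.json"))
  paths <- c(paths, file.path(out_dir, "run_config.json"))

  inputs <- run_stage("generate", TRUE, function() {
    cx <- make_toy_complex(config$pocket, seed = config$seed)
    truth <- planted_truth(donor_resno = config$donor_resno,
                           aromatic_resno = config$aromatic_resno)
    trajs <- make_trajectory(truth, n_frames = config$n_frames,
                             n_replicas = config$n_replicas,
                             seed = config$seed)
    plate <- make_screen_plate(config$variant_folds,
                               parent_activity = config$parent_activity,
                               noise_cv = config$screen_noise_cv,
                               n_replicates = config$screen_replicates,
                               seed = config$seed + 1L)
    melts <- list(
      parent = make_melt_curve(config$tm_parent, noise = config$melt_noise,
                               seed = config$seed + 2L),
      variant = make_melt_curve(config$tm_variant, noise = config$melt_noise,
                                seed = config$seed + 3L))
    msa <- make_msa(make_msa_profile(config$msa_length,
                                     config$conserved_positions,
                                     config$variable_positions,
                                     seed = config$seed + 4L),
                    n_seqs = config$msa_seqs, seed = config$seed + 5L)
    list(complex = cx, truth = truth, trajectories = trajs, plate = plate,
         melts = melts, msa = msa)
  })

  run_stage("dock", isTRUE(config$run_dock), function() {
    cfgd <- dock_config(cutoff = config$dock_cutoff,
                        clash_threshold = config$dock_clash,
                        seed_radius = config$dock_seed_radius,
                        n_samples = config$dock_samples,
                        keep_k = config$dock_keep,
                        rmsd_cutoff = config$dock_rmsd,
                        n_dihedral_samples = config$dock_dihedral_samples,
                        jitter = config$dock_jitter)
    base_spec <- oligomer_spec(config$dock_units, "Ace", "COO-", 1)
    runs <- lapply(enumerate_orientations(base_spec), function(sp) {
      dock_oligomer(inputs$complex$structure, sp, inputs$complex$table,
                    cfgd, seed = config$seed)
    })
    report <- purrr::map_dfr(runs, function(r) {
      tibble::tibble(label = r$label, orientation = r$orientation,
                     binding_energy_estimate = r$binding_energy_estimate,
                     best_score = r$best_score,
                     n_clusters = nrow(r$clusters),
                     top_population = r$clusters$population[1])
    })
    p1 <- .write_tsv(report, file.path(out_dir, "docking_summary.tsv"))
    p2 <- .write_json(c(stamp, list(
      runs = lapply(runs, function(r) list(
        label = r$label, orientation = r$orientation,
        binding_energy_estimate = r$binding_energy_estimate,
        best_score = r$best_score,
        clusters = as.data.frame(r$clusters)))
    )), file.path(out_dir, "docking.json"))
    paths <<- c(paths, p1, p2)
    list(runs = runs, report = report)
  })

  run_stage("trajectory", isTRUE(config$run_trajectory), function() {
    trajs <- inputs$trajectories
    profs <- lapply(trajs, contact_frequencies, cutoff = config$contact_cutoff)
    agg <- aggregate_contacts(profs)
    hot <- select_hotspots(profs, threshold = config$hotspot_threshold,
                           exclude = config$exclude_resnos)
    hb <- lapply(trajs, detect_interactions, donor_group = "donor",
                 acceptor_group = "acceptor", kind = "hbond",
                 dist_cutoff = config$hbond_dist,
                 angle_cutoff = config$hbond_angle)
    sb <- lapply(trajs, detect_interactions, donor_group = "donor",
                 acceptor_group = "acceptor", kind = "salt_bridge",
                 dist_cutoff = config$salt_dist, q_ion = config$q_ion)
    hb_occ <- aggregate_replicas(vapply(hb, occupancy, 0))
    sb_occ <- aggregate_replicas(vapply(sb, occupancy, 0))
    ce <- purrr::map2(trajs, hb, function(tr, series) {
      conditional_energy(interaction_energy_series(tr,
                                                   cutoff = config$energy_cutoff),
                         series, min_frames = config$min_state_frames)
    })
    de <- aggregate_replicas(vapply(ce, function(z) z$delta_e, 0))
    states <- lapply(trajs, classify_sidechain, resno = config$aromatic_resno,
                     origin_group = "axis_origin", mouth_group = "axis_mouth")
    frac1 <- aggregate_replicas(vapply(states, function(s)
      attr(s, "fractions")[["conformation_1"]], 0))
    p1 <- .write_tsv(agg, file.path(out_dir, "contacts.tsv"))
    p2 <- .write_tsv(hot, file.path(out_dir, "hotspots.tsv"))
    p3 <- .write_json(c(stamp, list(
      hbond_occupancy_pct = as.list(hb_occ),
      salt_bridge_occupancy_pct = as.list(sb_occ),
      delta_e_kj_mol = as.list(de),
      conformation_1_fraction = as.list(frac1)
    )), file.path(out_dir, "interactions.json"))
    paths <<- c(paths, p1, p2, p3)
    list(contacts = agg, hotspots = hot, hbond = hb_occ, salt = sb_occ,
         delta_e = de, conformation_1 = frac1)
  })

  run_stage("variants", isTRUE(config$run_variants), function() {
    plate <- inputs$plate
    vnames <- setdiff(unique(plate$variant), "blank")
    acts <- purrr::map_dfr(vnames, function(v) {
      a <- specific_activity(plate[plate$variant == v, ])
      tibble::tibble(variant = v, activity = a$mean, sem = a$sem, n = a$n)
    })
    parent <- acts[acts$variant == "parent", ]
    folds <- purrr::map_dfr(setdiff(vnames, "parent"), function(v) {
      a <- acts[acts$variant == v, ]
      fc <- fold_change(list(mean = a$activity, sem = a$sem),
                        list(mean = parent$activity, sem = parent$sem))
      tibble::tibble(variant = v, fold = fc$fold, sem = fc$sem,
                     fold_rounded = fc$fold_rounded)
    })
    singles <- folds[match(config$epistasis_singles, folds$variant), ]
    combo <- folds[folds$variant == config$epistasis_combo, ]
    ep <- classify_epistasis(singles, combo, k_sigma = config$k_sigma)
    p1 <- .write_tsv(dplyr::left_join(acts, folds, by = "variant"),
                     file.path(out_dir, "variants.tsv"))
    p2 <- .write_json(c(stamp, list(
      expected_fold = ep$expected, sigma_expected = ep$sigma_expected,
      combo_fold = ep$combo, class = ep$class
    )), file.path(out_dir, "epistasis.json"))
    paths <<- c(paths, p1, p2)
    list(activities = acts, folds = folds, epistasis = ep)
  })

  run_stage("stability", isTRUE(config$run_stability), function() {
    fits <- lapply(inputs$melts, extract_tm)
    delta <- fits$variant$tm - fits$parent$tm
    p <- .write_json(c(stamp, list(
      tm_parent_c = fits$parent$tm, tm_variant_c = fits$variant$tm,
      delta_tm_c = delta
    )), file.path(out_dir, "stability.json"))
    paths <<- c(paths, p)
    list(fits = fits, delta_tm = delta)
  })

  run_stage("conservation", isTRUE(config$run_conservation), function() {
    prof <- column_profile(inputs$msa)
    isl <- variable_in_conserved(prof, window = config$cons_window,
                                 ic_high = config$ic_high,
                                 ic_low = config$ic_low)
    p1 <- .write_tsv(prof, file.path(out_dir, "conservation.tsv"))
    p2 <- .write_tsv(isl, file.path(out_dir, "conserved_islands.tsv"))
    paths <<- c(paths, p1, p2)
    list(profile = prof, islands = isl)
  })

  summary_lines <- c(
    "# Pipeline run summary", "",
    paste0("- config hash: ", cfg_hash),
    paste0("- seed: ", config$seed),
    if (!is.null(res$dock)) paste0(
      "- docking best score: ",
      signif(min(res$dock$report$best_score), 6), " kJ/mol"),
    if (!is.null(res$trajectory)) c(
      paste0("- hotspots: ",
             paste(res$trajectory$hotspots$resno, collapse = ", ")),
      paste0("- H-bond occupancy: ", round(res$trajectory$hbond$mean, 1),
             " +/- ", round(res$trajectory$hbond$sem, 1), " %"),
      paste0("- conditional dE: ", round(res$trajectory$delta_e$mean, 1),
             " +/- ", round(res$trajectory$delta_e$sem, 1), " kJ/mol")),
    if (!is.null(res$variants)) paste0(
      "- epistasis: ", res$variants$epistasis$class, " (combo ",
      round(res$variants$epistasis$combo, 1), " vs expected ",
      round(res$variants$epistasis$expected, 1), ")"),
    if (!is.null(res$stability)) paste0(
      "- delta Tm: ", round(res$stability$delta_tm, 1), " C"),
    if (!is.null(res$conservation)) paste0(
      "- variable-in-conserved positions: ",
      paste(res$conservation$islands$position, collapse = ", ")),
    "", "## Stage timings (s)",
    paste0("- ", names(timings), ": ", round(unname(timings), 2))
  )
  writeLines(summary_lines, file.path(out_dir, "summary.md"))
  paths <- c(paths, file.path(out_dir, "summary.md"))

  structure(list(config = config, config_hash = cfg_hash, out_dir = out_dir,
                 stages = res, paths = paths, timings = timings),
            class = "pa_pipeline_result")
}

#' @export
print.pa_pipeline_result <- function(x, ...) {
  cat("<pa_pipeline_result> ", length(x$stages), " stages -> ", x$out_dir,
      "\n", sep = "")
  cat("  stages:", paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}

#' Command-line entry point
#'
#' Implements `padock run --config run.yml --out results/`. Installed as the
#' executable script `exec/padock` in the package tree; call it with
#' `Rscript $(Rscript -e 'cat(system.file("exec", "padock", package = "padock"))') ...`
#' or directly from R via this function.
#'
#' @param args Character vector of CLI arguments.
#' @return The [run_pipeline()] result, invisibly.
#' @export
padock_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: padock run [--config <run.yml>] [--out <dir>] [--seed <int>]"
  if (length(args) == 0 || args[1] != "run") stop(usage, call. = FALSE)
  args <- args[-1]
  get_opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 0) return(NULL)
    if (i == length(args)) stop("missing value for ", flag, call. = FALSE)
    args[i + 1]
  }
  cfg_path <- get_opt("--config")
  out <- get_opt("--out")
  seed <- get_opt("--seed")
  config <- if (is.null(cfg_path)) pipeline_config() else pipeline_config(cfg_path)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(out)) out <- "padock_results"
  invisible(run_pipeline(config, out))
}
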