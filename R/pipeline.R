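#' Default pipeline configuration
#'
#' @param seed Root seed recorded in all outputs.
#' @param out_dir Output directory (created if missing).
#' @param conditions Preset names analysed at both levels and ranked.
#' @param n_lineages Lineages per condition for the sub-organismal arm.
#' @param n_lines,generations,carry_n Competition design.
#' @param n_boot Bootstrap replicates for all estimators.
#' @param normalization `"ratio"` or `"difference"`.
#' @param measurement If `TRUE`, recorded frequencies pass through the ddPCR
#'   forward model before estimation.
#' @param n_rep_predict Replicates for the net-trajectory forecasts.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("mitolevel_run_"),
                       conditions = c("wt_control", "wt_restricted",
                                      "daf16_control", "daf16_restricted"),
                       n_lineages = 30, n_lines = 8, generations = 10,
                       carry_n = 500, n_boot = 1000,
                       normalization = "ratio", measurement = FALSE,
                       n_rep_predict = 20) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected (fail-fast); omitted keys take the
#' [run_config] defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(run_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Simulation, optional ddPCR measurement layer, estimation at both
#' selection levels, and the multilevel forecast with condition ranking.
#' All intermediate tables and a JSON summary (with config echo, root seed,
#' config hash and package version) are written to `config$out_dir`; the
#' run is fully reproducible from the config and root seed.
#'
#' @param config A [run_config] (or path to a YAML config).
#' @return Invisibly, a result bundle: per-condition `shift_fit`s,
#'   `org_fit`s, s_org estimates, predictions and the rank table.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  maybe_measure <- function(f, tag) {
    if (!config$measurement) return(f)
    measure_frequency(f, seed = child_seed(seed, tag))
  }
  bundle <- list(config = config)

  ## sub-organismal arm: isolated lineages per condition
  bundle$sublevel <- .stage("sublevel", {
    fits <- list()
    for (i in seq_along(config$conditions)) {
      cn <- config$conditions[i]
      tab <- simulate_lineages(config$n_lineages, condition_presets(cn),
                               seed = child_seed(seed, 100 + i))
      tab$parent_f <- maybe_measure(tab$parent_f, 500 + i)
      tab$adult_f <- maybe_measure(tab$adult_f, 600 + i)
      write_table(tab, file.path(config$out_dir, paste0("lineages_", cn, ".csv")))
      fits[[cn]] <- fit_shift_function(per_generation_shift(tab),
                                       n_boot = config$n_boot,
                                       seed = child_seed(seed, 200 + i))
    }
    fits
  })

  ## organismal arm: competed + non-competed lines per condition
  bundle$orglevel <- .stage("orglevel", {
    fits <- list()
    for (i in seq_along(config$conditions)) {
      cn <- config$conditions[i]
      pr <- condition_presets(cn)
      co <- simulate_competition(config$n_lines, config$generations,
                                 config$carry_n, preset = pr, competed = TRUE,
                                 seed = child_seed(seed, 300 + i))
      nc <- simulate_competition(config$n_lines, config$generations,
                                 config$carry_n, preset = pr, competed = FALSE,
                                 seed = child_seed(seed, 400 + i))
      co$pooled_f <- maybe_measure(co$pooled_f, 700 + i)
      nc$pooled_f <- maybe_measure(nc$pooled_f, 800 + i)
      write_table(co, file.path(config$out_dir, paste0("competition_", cn, ".csv")))
      write_table(nc, file.path(config$out_dir, paste0("noncompeted_", cn, ".csv")))
      traj <- normalize_to_noncompeted(co, nc, config$normalization)
      fits[[cn]] <- list(
        org_fit = fit_org_decline(traj, n_boot = config$n_boot,
                                  seed = child_seed(seed, 900 + i)),
        s_org = estimate_s_org(fraction_trajectory(co),
                               n_boot = config$n_boot,
                               seed = child_seed(seed, 1000 + i)))
    }
    fits
  })

  ## multilevel forecast and ranking
  bundle$multilevel <- .stage("multilevel", {
    preds <- lapply(seq_along(config$conditions), function(i)
      predict_trajectory(config$conditions[i], generations = config$generations,
                         n_rep = config$n_rep_predict,
                         seed = child_seed(seed, 1100 + i)))
    ranks <- rank_conditions(preds)
    write_table(ranks, file.path(config$out_dir, "condition_ranks.csv"))
    traj <- do.call(rbind, lapply(preds, function(p)
      cbind(condition = p$condition, p$trajectory)))
    write_table(traj, file.path(config$out_dir, "predicted_trajectories.csv"))
    list(predictions = preds, ranks = ranks)
  })

  ## summary with reproducibility metadata
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  summary <- list(
    metadata = list(
      seed = seed,
      config_hash = unname(tools::md5sum(cfg_path)),
      package_version = as.character(utils::packageVersion("mitolevel"))),
    shift_fits = lapply(bundle$sublevel, function(f)
      list(a_hat = f$a_hat, b_hat = f$b_hat, f_star = f$f_star)),
    org_fits = lapply(bundle$orglevel, function(f)
      list(slope = f$org_fit$slope_hat, s_org = f$s_org$s_org)),
    ranks = bundle$multilevel$ranks)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ml_log("pipeline complete: ", config$out_dir)
  invisible(bundle)
}
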