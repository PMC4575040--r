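# Configuration files, experiment presets and the command-line interface.

.config_keys <- c("width", "height", "lp_hp_ratio", "aggregation_mode",
                  "K_H", "K_L", "r_H", "r_L", "n_blue", "n_red", "init_pop",
                  "c", "c1", "fusion_threshold", "cc_fraction",
                  "decisions_per_year", "years", "seed", "n_reps")

#' Read a simulation configuration
#'
#' Reads a flat YAML document whose keys mirror the [sim_params()] fields
#' exactly. Omitted keys take the baseline defaults; unknown keys are
#' rejected by name. `lp_hp_ratio` may be written either as a string
#' `"3:1"` or as a two-element sequence.
#'
#' @param path Path to a YAML file (an empty file yields the full default
#'   parameter set).
#' @return A validated [sim_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("config must be a mapping of parameter keys")
  unknown <- setdiff(names(doc), .config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(doc$lp_hp_ratio) && is.character(doc$lp_hp_ratio))
    doc$lp_hp_ratio <- .parse_ratio(doc$lp_hp_ratio)
  do.call(sim_params, doc)
}

.parse_ratio <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  v <- suppressWarnings(as.numeric(parts))
  if (length(v) != 2L || anyNA(v))
    stop("lp_hp_ratio must look like \"LP:HP\", got \"", s, "\"")
  v
}

#' Write a simulation configuration
#'
#' Serialises a parameter set to YAML such that
#' `load_config(write_config(p, f))` reproduces `p` exactly.
#'
#' @param params A [sim_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  doc <- unclass(params)
  doc$lp_hp_ratio <- paste(doc$lp_hp_ratio, collapse = ":")
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

# --- experiment presets ----------------------------------------------------

# The five sensitivity analyses, each a named list of parameter overrides.
.experiment_presets <- function() {
  list(
    patch_ratio = list(
      `1:1` = list(lp_hp_ratio = c(1, 1)),
      `3:1` = list(lp_hp_ratio = c(3, 1)),
      `1:3` = list(lp_hp_ratio = c(1, 3))
    ),
    threshold = list(
      T4 = list(fusion_threshold = 4),
      T3 = list(fusion_threshold = 3),
      T2 = list(fusion_threshold = 2)
    ),
    aggregation = list(
      RANDOM = list(aggregation_mode = "RANDOM"),
      BLOCK9 = list(aggregation_mode = "BLOCK9"),
      BLOCK49 = list(aggregation_mode = "BLOCK49"),
      BLOCK81 = list(aggregation_mode = "BLOCK81")
    ),
    growth = list(
      baseline = list(r_H = 0.03, r_L = 0.01),
      slow = list(r_H = 0.01, r_L = 0.005)
    ),
    war_constant = list(
      `c0.001` = list(c = 0.001),
      `c0.1` = list(c = 0.1)
    )
  )
}

#' Run an experiment preset
#'
#' Runs one replicate ensemble per variant of a named sensitivity analysis:
#' `"patch_ratio"` (LP:HP 1:1, 3:1, 1:3), `"threshold"` (fusion threshold
#' 4, 3, 2), `"aggregation"` (random and block layouts), `"growth"`
#' (baseline vs slow growth) and `"war_constant"` (`c` 0.001 vs 0.1). All
#' other parameters stay at their baseline values.
#'
#' @param preset Preset name.
#' @param params Base parameter set the variants override.
#' @param n_reps Replicates per variant (default `params$n_reps`).
#' @param base_seed Base seed; variant `k` uses `base_seed + (k-1) * 1000`
#'   so replicate seeds never collide across variants.
#' @return A named list of `sim_ensemble` objects, one per variant.
#' @export
run_experiment <- function(preset = c("patch_ratio", "threshold",
                                      "aggregation", "growth",
                                      "war_constant"),
                           params = sim_params(), n_reps = params$n_reps,
                           base_seed = params$seed) {
  preset <- match.arg(preset)
  variants <- .experiment_presets()[[preset]]
  out <- vector("list", length(variants))
  names(out) <- names(variants)
  for (k in seq_along(variants)) {
    p <- params
    for (nm in names(variants[[k]])) p[[nm]] <- variants[[k]][[nm]]
    .validate_params(p)
    out[[k]] <- run_replicates(p, n_reps = n_reps,
                               base_seed = as.integer(base_seed) +
                                 (k - 1L) * 1000L)
  }
  out
}

# --- file outputs ----------------------------------------------------------

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write the output files of a single run
#'
#' Writes `census.csv` (one row per year), `events.csv`, `histogram.csv`
#' (year, bin, count; yearly MCG size-bin counts plus a final-state row at
#' the horizon year), `snapshot_final.csv` (occupied patches of the final
#' world) and `config_echo.yaml` into a directory.
#'
#' @param result A `sim_result` object.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_run_outputs <- function(result, dir) {
  stopifnot(inherits(result, "sim_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_csv(result$census, file.path(dir, "census.csv"))
  .write_csv(result$events, file.path(dir, "events.csv"))
  years <- result$params$years
  hist_long <- data.frame(
    year = rep(c(0:(years - 1), years), each = length(.size_bins$label)),
    bin = rep(.size_bins$label, years + 1L),
    count = c(t(result$histograms), .mcg_size_counts(result$world))
  )
  .write_csv(hist_long, file.path(dir, "histogram.csv"))
  .write_csv(as.data.frame(result$world),
             file.path(dir, "snapshot_final.csv"))
  write_config(result$params, file.path(dir, "config_echo.yaml"))
  invisible(dir)
}

#' Command-line entry point
#'
#' Implements the `grouplife` command; a thin wrapper script is installed
#' under `inst/cli/grouplife.R`. Subcommands:
#'
#' * `run [--config FILE] [--seed S] [--years Y] --out DIR` — one
#'   simulation; writes `census.csv`, `events.csv`, `histogram.csv`,
#'   `snapshot_final.csv`, `config_echo.yaml` and `manifest.json`.
#' * `experiment --preset NAME [--config FILE] [--reps N] [--seed S]
#'   --out DIR` — a sensitivity analysis (see [run_experiment()]); writes
#'   `ensemble.csv` (per-variant per-year means and SDs),
#'   `mcgs_formed.csv` (per-variant per-replicate fusion counts) and
#'   `manifest.json`.
#' * `snapshot [--config FILE] [--seed S] --out FILE` — the generated
#'   landscape as `row,col,productivity` CSV.
#'
#' @param argv Character vector of command-line arguments (default: those
#'   of the calling `Rscript`).
#' @return Integer exit status, invisibly (0 on success); configuration and
#'   I/O errors print a message and return 1.
#' @export
run_command <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    .dispatch_command(argv)
    0L
  }, error = function(e) {
    message("grouplife: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_usage <- paste(
  "usage: grouplife run [--config FILE] [--seed S] [--years Y] --out DIR",
  "       grouplife experiment --preset NAME [--config FILE] [--reps N]",
  "                            [--seed S] --out DIR",
  "       grouplife snapshot [--config FILE] [--seed S] --out FILE",
  sep = "\n")

.parse_flags <- function(args, allowed) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, "\n",
                                   .cli_usage)
    key <- substring(a, 3L)
    if (!key %in% allowed) stop("unknown flag --", key, "\n", .cli_usage)
    if (i == length(args)) stop("flag --", key, " needs a value")
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

.dispatch_command <- function(argv) {
  if (length(argv) == 0L) stop("no subcommand given\n", .cli_usage)
  sub <- argv[1]
  args <- argv[-1]
  params_from <- function(fl) {
    p <- if (!is.null(fl$config)) load_config(fl$config) else sim_params()
    if (!is.null(fl$seed)) p$seed <- as.integer(fl$seed)
    if (!is.null(fl$years)) p$years <- as.integer(fl$years)
    if (!is.null(fl$reps)) p$n_reps <- as.integer(fl$reps)
    .validate_params(p)
    p
  }
  if (sub == "run") {
    fl <- .parse_flags(args, c("config", "seed", "years", "out"))
    if (is.null(fl$out)) stop("run needs --out DIR")
    p <- params_from(fl)
    res <- run_simulation(p)
    write_run_outputs(res, fl$out)
    .write_manifest(fl$out, command = "run", params = p, seeds = p$seed,
                    files = c("census.csv", "events.csv", "histogram.csv",
                              "snapshot_final.csv", "config_echo.yaml"))
  } else if (sub == "experiment") {
    fl <- .parse_flags(args, c("preset", "config", "reps", "seed", "out"))
    if (is.null(fl$preset)) stop("experiment needs --preset NAME")
    if (is.null(fl$out)) stop("experiment needs --out DIR")
    p <- params_from(fl)
    ens <- run_experiment(fl$preset, params = p, n_reps = p$n_reps,
                          base_seed = p$seed)
    dir.create(fl$out, recursive = TRUE, showWarnings = FALSE)
    summ <- lapply(ens, ensemble_summary)
    ens_df <- do.call(rbind, lapply(names(summ), function(v)
      cbind(variant = v, summ[[v]]$census)))
    .write_csv(ens_df, file.path(fl$out, "ensemble.csv"))
    formed <- do.call(rbind, lapply(names(summ), function(v)
      data.frame(variant = v,
                 replicate = seq_along(summ[[v]]$mcgs_formed$values),
                 mcgs_formed = summ[[v]]$mcgs_formed$values)))
    .write_csv(formed, file.path(fl$out, "mcgs_formed.csv"))
    write_config(p, file.path(fl$out, "config_echo.yaml"))
    seeds <- lapply(seq_along(ens), function(k)
      p$seed + (k - 1L) * 1000L + seq_len(p$n_reps) - 1L)
    names(seeds) <- names(ens)
    .write_manifest(fl$out, command = "experiment", params = p,
                    seeds = seeds, preset = fl$preset,
                    files = c("ensemble.csv", "mcgs_formed.csv",
                              "config_echo.yaml"))
  } else if (sub == "snapshot") {
    fl <- .parse_flags(args, c("config", "seed", "out"))
    if (is.null(fl$out)) stop("snapshot needs --out FILE")
    p <- params_from(fl)
    land <- generate_landscape(p$width, p$height, p$lp_hp_ratio,
                               p$aggregation_mode, p$K_H, p$K_L, p$r_H,
                               p$r_L, seed = p$seed)
    .write_csv(as.data.frame(land), fl$out)
  } else {
    stop("unknown subcommand \"", sub, "\"\n", .cli_usage)
  }
  invisible(NULL)
}

.write_manifest <- function(dir, command, params, seeds, files,
                            preset = NULL) {
  manifest <- list(
    tool = "grouplife",
    version = as.character(utils::packageVersion("grouplife")),
    command = command,
    preset = preset,
    seeds = seeds,
    params = {
      p <- unclass(params)
      p$lp_hp_ratio <- paste(p$lp_hp_ratio, collapse = ":")
      p
    },
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
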