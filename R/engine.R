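# Yearly scheduler, full-run driver and replicate-ensemble runner.

#' Simulation parameter set
#'
#' Builds and validates the full parameter set of a run. The defaults are
#' the model's baseline condition: a 33 x 33 lattice with a random 1:1
#' LP:HP layout, carrying capacities 50/100 persons, growth rates 0.01/0.03
#' per year, 10 blue and 10 red founding SCGs of 30 persons, war constants
#' `c = 0.001` and `c1 = 1`, fusion threshold 4 at >90% of capacity, 20
#' cell decisions per year, 600 years, 15 replicates.
#'
#' @param width,height Lattice dimensions.
#' @param lp_hp_ratio Integer pair `c(LP, HP)`.
#' @param aggregation_mode `"RANDOM"`, `"BLOCK9"`, `"BLOCK49"` or
#'   `"BLOCK81"`.
#' @param K_H,K_L,r_H,r_L Patch carrying capacities and growth rates.
#' @param n_blue,n_red,init_pop Founding SCG counts and population.
#' @param c,c1 War-propensity and cost constants.
#' @param fusion_threshold Minimum number of blue SCGs that fuse.
#' @param cc_fraction Capacity fraction for fusion eligibility.
#' @param decisions_per_year Number of cells sampled for decisions yearly.
#' @param years Run length in years.
#' @param seed RNG seed of a single run / base seed of an ensemble.
#' @param n_reps Default replicate count for [run_replicates()].
#' @return A validated list of class `sim_params`.
#' @examples
#' sim_params(fusion_threshold = 3)
#' @export
sim_params <- function(width = 33, height = 33, lp_hp_ratio = c(1, 1),
                       aggregation_mode = "RANDOM",
                       K_H = 100, K_L = 50, r_H = 0.03, r_L = 0.01,
                       n_blue = 10, n_red = 10, init_pop = 30,
                       c = 0.001, c1 = 1,
                       fusion_threshold = 4, cc_fraction = 0.9,
                       decisions_per_year = 20, years = 600,
                       seed = 1, n_reps = 15) {
  p <- list(width = as.integer(width), height = as.integer(height),
            lp_hp_ratio = as.numeric(lp_hp_ratio),
            aggregation_mode = match.arg(aggregation_mode,
                                         .aggregation_modes),
            K_H = K_H, K_L = K_L, r_H = r_H, r_L = r_L,
            n_blue = as.integer(n_blue), n_red = as.integer(n_red),
            init_pop = init_pop, c = c, c1 = c1,
            fusion_threshold = as.integer(fusion_threshold),
            cc_fraction = cc_fraction,
            decisions_per_year = as.integer(decisions_per_year),
            years = as.integer(years), seed = as.integer(seed),
            n_reps = as.integer(n_reps))
  .validate_params(p)
  structure(p, class = "sim_params")
}

.validate_params <- function(p) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(p$width >= 1L && p$height >= 1L, "lattice dimensions must be >= 1")
  chk(length(p$lp_hp_ratio) == 2L && all(p$lp_hp_ratio >= 0) &&
        sum(p$lp_hp_ratio) > 0,
      "lp_hp_ratio must be two non-negative numbers, not both zero")
  chk(p$K_H > 0 && p$K_L > 0, "carrying capacities must be positive")
  chk(p$r_H >= 0 && p$r_L >= 0, "growth rates must be non-negative")
  chk(p$n_blue >= 0L && p$n_red >= 0L, "founding SCG counts must be >= 0")
  chk(p$init_pop > 0, "init_pop must be positive")
  chk(p$c >= 0 && p$c1 >= 0, "war constants must be non-negative")
  chk(p$fusion_threshold >= 2L, "fusion_threshold must be >= 2")
  chk(p$cc_fraction > 0 && p$cc_fraction < 1,
      "cc_fraction must lie strictly between 0 and 1")
  chk(p$decisions_per_year >= 0L, "decisions_per_year must be >= 0")
  chk(p$years >= 1L, "years must be >= 1")
  chk(p$n_reps >= 1L, "n_reps must be >= 1")
  invisible(TRUE)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat("  ", format(k, width = 18), paste(v, collapse = ":"), "\n", sep = "")
  }
  invisible(x)
}

#' Advance a world by one simulated year
#'
#' One year consists of: (1) a growth phase over every cell; (2) a decision
#' phase in which `decisions_per_year` cells are sampled uniformly without
#' replacement (all cells, in random order, if fewer exist) and each in turn
#' executes its decision — stay static, bud, or go to war — immediately
#' followed by one fusion attempt; (3) the year counter advances. Cells
#' created during the decision phase (buds, captured patches) are not
#' eligible for the remaining decision slots of that year, and a slot whose
#' sampled cell has been destroyed by an earlier war that year is skipped.
#'
#' @param world A `world` object (mutated in place).
#' @param params A [sim_params()] object.
#' @return The world, invisibly.
#' @export
step_year <- function(world, params) {
  stopifnot(inherits(world, "world"), inherits(params, "sim_params"))
  .grow_world(world)
  occ <- which(world$pop > 0)
  n_occ <- length(occ)
  if (n_occ > 0L && params$decisions_per_year > 0L) {
    take <- min(params$decisions_per_year, n_occ)
    chosen <- occ[sample.int(n_occ, take)]
    for (i in chosen) {
      if (world$grp[i] == 0L) next        # destroyed earlier this year
      act <- .choose_action_idx(world, i, params$c)
      if (act$variant == "BUD") {
        .bud_idx(world, i, act$target)
      } else if (act$variant == "WAR") {
        .resolve_war_idx(world, i, act$target, params$c1)
      }
      attempt_fusion(world, params$fusion_threshold, params$cc_fraction)
    }
  }
  world$year <- world$year + 1L
  invisible(world)
}

#' Run one simulation
#'
#' Seeds the RNG, generates the landscape, places the founding SCGs and
#' iterates [step_year()] for `params$years` years. A census row is recorded
#' at the start of each year (so row 1 is the founding state at year 0 and
#' the census has exactly `years` rows); the state after the final year is
#' kept as the result's `world`. A result is fully determined by
#' `(params, seed)`.
#'
#' @param params A [sim_params()] object.
#' @param seed Overrides `params$seed` when given.
#' @return An object of class `sim_result`: a list with `census` (data
#'   frame, one row per year), `histograms` (years x bins matrix of MCG
#'   size-bin counts, see [size_histogram()]), `events` (data frame),
#'   `world` (final state), `params` and `seed`.
#' @examples
#' res <- run_simulation(sim_params(years = 5, seed = 1))
#' res$census
#' @export
run_simulation <- function(params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) params$seed <- as.integer(seed)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(params$seed)
  land <- generate_landscape(params$width, params$height,
                             params$lp_hp_ratio, params$aggregation_mode,
                             params$K_H, params$K_L, params$r_H, params$r_L)
  world <- place_initial_groups(land, params$n_blue, params$n_red,
                                params$init_pop)
  cen <- vector("list", params$years)
  hist <- matrix(0L, nrow = params$years, ncol = length(.size_bins$label),
                 dimnames = list(NULL, .size_bins$label))
  for (t in seq_len(params$years)) {
    cen[[t]] <- census(world)
    hist[t, ] <- .mcg_size_counts(world)
    step_year(world, params)
  }
  structure(list(
    census = do.call(rbind, cen),
    histograms = hist,
    events = world_events(world),
    world = world,
    params = params,
    seed = params$seed
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", x$params$years, " years, seed ", x$seed, "; ",
      mcgs_formed(x), " MCGs formed, ",
      sum(x$events$type == "WAR"), " wars, ",
      sum(x$events$type == "BUD"), " buddings\n", sep = "")
  invisible(x)
}

#' Run a replicate ensemble
#'
#' Runs `n_reps` independent simulations whose seeds are derived
#' deterministically from `base_seed` (replicate `i` uses
#' `base_seed + i - 1`), so an ensemble is reproducible and its first
#' member equals `run_simulation(params, seed = base_seed)`.
#'
#' @param params A [sim_params()] object.
#' @param n_reps Number of replicates (default `params$n_reps`).
#' @param base_seed Seed of the first replicate (default `params$seed`).
#' @return A list of `sim_result` objects of class `sim_ensemble`, ordered
#'   by replicate index.
#' @export
run_replicates <- function(params = sim_params(), n_reps = params$n_reps,
                           base_seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  out <- lapply(seq_len(n_reps) - 1L, function(k)
    run_simulation(params, seed = as.integer(base_seed) + k))
  structure(out, class = "sim_ensemble")
}

#' @export
print.sim_ensemble <- function(x, ...) {
  formed <- vapply(x, mcgs_formed, numeric(1))
  cat("<sim_ensemble> ", length(x), " replicates of ",
      x[[1]]$params$years, " years; MCGs formed: mean ",
      round(mean(formed), 2), " (sd ",
      round(stats::sd(formed), 2), ")\n", sep = "")
  invisible(x)
}
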