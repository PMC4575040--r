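# Census, size-distribution, emergence-time and dominance statistics.

# MCG size bins: decades up to 100 cells, centuries up to 500, then open.
# Bin labels follow the convention "10" = 2-10 cells, "20" = 11-20, ...,
# "200" = 101-200, ..., ">500" = more than 500.
.size_bins <- list(
  lo = c(2, 11, 21, 31, 41, 51, 61, 71, 81, 91, 101, 201, 301, 401, 501),
  hi = c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 200, 300, 400, 500, Inf),
  label = c("10", "20", "30", "40", "50", "60", "70", "80", "90", "100",
            "200", "300", "400", "500", ">500")
)

#' Yearly census of a world
#'
#' Counts groups by kind and colour: red SCGs (on low-productivity patches),
#' blue SCGs (on high-productivity patches), MCGs, the number of cells
#' belonging to MCGs, total occupied patches, and the size and landscape
#' share of the largest MCG.
#'
#' @param world A `world` object.
#' @return A one-row data frame with columns `year`, `n_red_scg`,
#'   `n_blue_scg`, `n_mcg`, `n_mcg_cells`, `n_cells_total`,
#'   `largest_mcg_cells`, `largest_mcg_occupancy_fraction`.
#' @export
census <- function(world) {
  stopifnot(inherits(world, "world"))
  occ <- which(world$grp != 0L)
  keys <- world$grp[occ]
  kind <- world$g_kind[keys]
  scg <- kind == .SCG
  high <- world$landscape$high[occ]
  sizes <- tabulate(keys[kind == .MCG], nbins = length(world$g_kind))
  mcg_keys <- which(world$g_kind == .MCG)
  largest <- if (length(mcg_keys)) max(sizes[mcg_keys]) else 0L
  data.frame(
    year = world$year,
    n_red_scg = sum(scg & !high),
    n_blue_scg = sum(scg & high),
    n_mcg = length(mcg_keys),
    n_mcg_cells = sum(kind == .MCG),
    n_cells_total = length(occ),
    largest_mcg_cells = largest,
    largest_mcg_occupancy_fraction = largest / world$landscape$n
  )
}

# Bin counts of living MCG sizes (integer vector over .size_bins). An MCG
# whittled down to a single cell by war keeps its identity; such sizes < 2
# are counted in the smallest bin so the histogram always sums to n_mcg.
.mcg_size_counts <- function(world) {
  mcg_keys <- which(world$g_kind == .MCG)
  counts <- integer(length(.size_bins$label))
  if (length(mcg_keys)) {
    sizes <- tabulate(world$grp[world$grp != 0L],
                      nbins = length(world$g_kind))[mcg_keys]
    bin <- findInterval(pmax(sizes, 2), .size_bins$lo)
    counts <- tabulate(bin, nbins = length(.size_bins$label))
  }
  counts
}

#' MCG size histogram
#'
#' Bins the cell counts of living MCGs into the fixed edges 2-10, 11-20,
#' ..., 91-100, 101-200, ..., 401-500, >500 (bin labels name the upper
#' edge). MCGs reduced to a single cell by war are counted in the smallest
#' bin, so the counts always sum to the number of living MCGs.
#'
#' @param world A `world` object.
#' @return A data frame with columns `bin`, `lo`, `hi`, `count`.
#' @examples
#' w <- place_initial_groups(generate_landscape(seed = 1), seed = 1)
#' size_histogram(w)  # all zero: no MCGs yet
#' @export
size_histogram <- function(world) {
  stopifnot(inherits(world, "world"))
  data.frame(bin = .size_bins$label, lo = .size_bins$lo, hi = .size_bins$hi,
             count = .mcg_size_counts(world))
}

#' Year of the first MCG fusion
#'
#' @param result A `sim_result` object.
#' @return The year of the earliest FUSION event, or `NA_integer_` if no
#'   MCG ever formed.
#' @export
first_mcg_emergence_year <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  yrs <- result$events$year[result$events$type == "FUSION"]
  if (length(yrs) == 0L) NA_integer_ else min(yrs)
}

#' Cumulative number of MCGs formed during a run
#'
#' Counts fusion events — MCGs *formed*, as opposed to MCGs alive in a given
#' year (groups later driven extinct still count).
#'
#' @param result A `sim_result` object.
#' @return An integer count.
#' @export
mcgs_formed <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  sum(result$events$type == "FUSION")
}

#' Fraction of the landscape a group occupies
#'
#' @param world A `world` object.
#' @param group A group registry key.
#' @return Member-cell count divided by the number of lattice patches.
#' @export
occupancy_fraction <- function(world, group) {
  group_size(world, group) / world$landscape$n
}

#' Ensemble summary statistics
#'
#' Per-year sample means and standard deviations (n - 1 denominator) of
#' every census field across the replicates of an ensemble, the mean and SD
#' of the cumulative number of MCGs formed, and the mean and SD of the MCG
#' size histogram at the requested years.
#'
#' With a single replicate the SDs are reported as 0 and the result carries
#' `single_replicate = TRUE`.
#'
#' @param results A `sim_ensemble` (or plain list of `sim_result`s) with a
#'   common horizon.
#' @param hist_years Years at which to summarise the size histogram;
#'   defaults to every 100 years up to and including the horizon. Recorded
#'   histograms describe the state at the *start* of each year; the horizon
#'   row is computed from the final world state.
#' @return A list of class `ensemble_summary` with elements `census` (long
#'   data frame: `year`, `field`, `mean`, `sd`), `mcgs_formed` (list with
#'   `values`, `mean`, `sd`), `histogram` (data frame: `year`, `bin`,
#'   `mean`, `sd`), `n_reps` and `single_replicate`.
#' @export
ensemble_summary <- function(results, hist_years = NULL) {
  if (inherits(results, "sim_result")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "sim_result")))
  horizons <- vapply(results, function(r) r$params$years, integer(1))
  if (length(unique(horizons)) != 1L)
    stop("replicates have mismatched horizons: ",
         paste(unique(horizons), collapse = ", "))
  years <- horizons[1]
  n <- length(results)
  single <- n == 1L
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

  fields <- setdiff(names(results[[1]]$census), "year")
  cen <- do.call(rbind, lapply(fields, function(f) {
    m <- vapply(results, function(r) r$census[[f]], numeric(years))
    m <- matrix(m, nrow = years)
    data.frame(year = results[[1]]$census$year, field = f,
               mean = rowMeans(m), sd = apply(m, 1, sd0))
  }))

  formed <- vapply(results, mcgs_formed, numeric(1))

  if (is.null(hist_years))
    hist_years <- unique(c(if (years >= 100) seq(100, years, by = 100),
                           years))
  hist_years <- hist_years[hist_years >= 0 & hist_years <= years]
  hs <- do.call(rbind, lapply(hist_years, function(y) {
    m <- vapply(results, function(r) {
      if (y == years) .mcg_size_counts(r$world)
      else r$histograms[y + 1L, ]
    }, numeric(length(.size_bins$label)))
    m <- matrix(m, nrow = length(.size_bins$label))
    data.frame(year = y, bin = .size_bins$label,
               mean = rowMeans(m), sd = apply(m, 1, sd0))
  }))

  structure(list(census = cen,
                 mcgs_formed = list(values = formed, mean = mean(formed),
                                    sd = sd0(formed)),
                 histogram = hs,
                 n_reps = n, single_replicate = single),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary> ", x$n_reps, " replicates; MCGs formed ",
      round(x$mcgs_formed$mean, 2), " (sd ", round(x$mcgs_formed$sd, 2),
      ")\n", sep = "")
  if (x$single_replicate)
    cat("  note: single replicate, SDs reported as 0\n")
  invisible(x)
}
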