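# The world is an environment so that the yearly scheduler can mutate state
# in place; copying 600 years x 20 decisions of lattice vectors would
# dominate runtime under R's copy-on-modify semantics.
#
# Fields:
#   landscape   the immutable patch lattice
#   pop         numeric[n]  persons per patch, 0 = empty
#   grp         integer[n]  registry key of the owning group, 0 = empty
#   g_kind      integer[]   per registry key: 1 SCG, 2 MCG, 0 extinct
#   g_marker    integer[]   per registry key: heritable lineage marker
#   next_marker next unused marker value (monotone counter)
#   year        completed simulation years
#   ev          event log (see events.R)

.SCG <- 1L
.MCG <- 2L

.new_world <- function(landscape) {
  w <- new.env(parent = emptyenv())
  w$landscape <- landscape
  w$pop <- numeric(landscape$n)
  w$grp <- integer(landscape$n)
  w$g_kind <- integer(0)
  w$g_marker <- integer(0)
  w$next_marker <- 0L
  w$year <- 0L
  w$ev <- .new_event_log()
  class(w) <- "world"
  w
}

.new_group <- function(world, kind, marker = NULL) {
  key <- length(world$g_kind) + 1L
  if (is.null(marker)) {
    marker <- world$next_marker
    world$next_marker <- world$next_marker + 1L
  }
  world$g_kind[key] <- kind
  world$g_marker[key] <- as.integer(marker)
  key
}

#' Seed a world with its founding single-celled groups
#'
#' Places `n_blue` SCGs on distinct high-productivity patches and `n_red`
#' SCGs on distinct low-productivity patches, chosen uniformly at random,
#' each with an initial population of `init_pop` persons. Groups receive
#' heritable lineage markers `0 .. n_blue + n_red - 1` (blue groups first).
#'
#' @param landscape A [generate_landscape()] object.
#' @param n_blue,n_red Numbers of founding SCGs on HP and LP patches
#'   (defaults 10 and 10).
#' @param init_pop Founding population per group in persons (default 30).
#' @param seed Optional integer seed for a private RNG state; `NULL` uses
#'   the current stream.
#' @return A mutable object of class `world` at year 0.
#' @examples
#' w <- place_initial_groups(generate_landscape(seed = 1), seed = 1)
#' census(w)
#' @export
place_initial_groups <- function(landscape, n_blue = 10, n_red = 10,
                                 init_pop = 30, seed = NULL) {
  stopifnot(inherits(landscape, "landscape"))
  n_blue <- as.integer(n_blue); n_red <- as.integer(n_red)
  hp <- which(landscape$high); lp <- which(!landscape$high)
  if (n_blue > length(hp))
    stop("cannot place ", n_blue, " blue SCGs on ", length(hp), " HP patches")
  if (n_red > length(lp))
    stop("cannot place ", n_red, " red SCGs on ", length(lp), " LP patches")
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  w <- .new_world(landscape)
  sites <- c(if (n_blue > 0L) hp[sample.int(length(hp), n_blue)],
             if (n_red > 0L) lp[sample.int(length(lp), n_red)])
  for (i in sites) {
    key <- .new_group(w, .SCG)
    w$grp[i] <- key
    w$pop[i] <- init_pop
  }
  w
}

#' Yearly growth of one cell
#'
#' A cell grows by a fraction `growth_rate` per year unless its population
#' already exceeds the patch carrying capacity: growth applies whenever
#' `population <= carrying_capacity`, so a cell may overshoot its capacity
#' by a single multiplicative step and then freezes until war or budding
#' reduces it. That one-step overshoot is what arms the expansion decision
#' (bud/war) in the scheduler. Populations are real-valued.
#'
#' @param population Current population (persons); vectorised.
#' @param carrying_capacity Patch carrying capacity `K`.
#' @param growth_rate Yearly per-capita growth rate `r`.
#' @return The population after one year of growth.
#' @examples
#' grow_cell(30, 100, 0.03)   # 30.9
#' grow_cell(100, 100, 0.03)  # 103: at capacity still grows, overshooting
#' grow_cell(103, 100, 0.03)  # 103: above capacity, frozen
#' @export
grow_cell <- function(population, carrying_capacity, growth_rate) {
  ifelse(population <= carrying_capacity,
         population * (1 + growth_rate), population)
}

# In-place growth phase over every occupied patch.
.grow_world <- function(world) {
  i <- which(world$pop > 0 & world$pop <= world$landscape$K)
  world$pop[i] <- world$pop[i] * (1 + world$landscape$r[i])
  invisible(world)
}

#' Cell redness from patch productivity
#'
#' A cell's aggression level ("redness") is set by the productivity of the
#' patch it sits on: 1 on a low-productivity patch (warrior cells, resource
#' shortage drives conflict), 0 on a high-productivity patch (peaceful
#' cells).
#'
#' @param landscape A `landscape` object.
#' @param coord Integer pair `c(row, col)`, 0-based.
#' @return 0 or 1.
#' @export
cell_redness <- function(landscape, coord) {
  stopifnot(inherits(landscape, "landscape"))
  landscape$red[.idx(landscape, coord[1], coord[2])]
}

# --- group accessors (registry keys) ---------------------------------------

.group_cells <- function(world, key) which(world$grp == key)

.check_group <- function(world, key) {
  if (key < 1L || key > length(world$g_kind) || world$g_kind[key] == 0L)
    stop("group ", key, " is not registered in this world")
}

#' Group-level aggregates
#'
#' `group_population()` sums member-cell populations; `group_size()` counts
#' member cells; `group_redness()` is the unweighted arithmetic mean of the
#' member cells' rednesses (an MCG spanning both patch classes has an
#' intermediate aggression level); `group_kind()` returns `"SCG"` or
#' `"MCG"`; `group_marker()` the heritable lineage marker.
#'
#' @param world A `world` object.
#' @param group A group registry key as found in `world$grp` or
#'   [living_groups()].
#' @return A scalar.
#' @export
group_population <- function(world, group) {
  .check_group(world, group)
  sum(world$pop[.group_cells(world, group)])
}

#' @rdname group_population
#' @export
group_size <- function(world, group) {
  .check_group(world, group)
  length(.group_cells(world, group))
}

#' @rdname group_population
#' @export
group_redness <- function(world, group) {
  .check_group(world, group)
  cells <- .group_cells(world, group)
  if (length(cells) == 0L) stop("group ", group, " has no member cells")
  mean(world$landscape$red[cells])
}

#' @rdname group_population
#' @export
group_kind <- function(world, group) {
  .check_group(world, group)
  c("SCG", "MCG")[world$g_kind[group]]
}

#' @rdname group_population
#' @export
group_marker <- function(world, group) {
  .check_group(world, group)
  world$g_marker[group]
}

#' Registry keys of all living groups
#'
#' @param world A `world` object.
#' @return Integer vector of registry keys with at least one member cell.
#' @export
living_groups <- function(world) {
  which(world$g_kind != 0L)
}

#' Audit world-state consistency
#'
#' Verifies the structural invariants the simulation maintains: occupied
#' patches and group membership form a bijection (every occupied patch
#' belongs to a living group, every living group has at least one cell,
#' extinct registry entries own no cells), populations are positive on
#' occupied patches and zero elsewhere, no cell exceeds its patch's
#' single-step overshoot bound `K * (1 + r)` (or half the lattice-wide
#' maximum, for cells founded by a 50/50 split onto a poorer patch), and
#' SCGs have exactly one cell.
#'
#' @param world A `world` object.
#' @return `TRUE` invisibly; stops with a message on the first violated
#'   invariant.
#' @export
audit_world <- function(world) {
  stopifnot(inherits(world, "world"))
  land <- world$landscape
  occ <- which(world$grp != 0L)
  if (any(world$pop[occ] <= 0))
    stop("audit: occupied patch with non-positive population")
  emp <- which(world$grp == 0L)
  if (any(world$pop[emp] != 0))
    stop("audit: empty patch with non-zero population")
  # A cell that grew on its own patch is bounded by K*(1+r); a cell founded
  # by a 50/50 split (bud or war capture) may instead carry up to half the
  # lattice-wide maximum onto a poorer patch.
  bound <- pmax(land$K[occ] * (1 + land$r[occ]),
                max(land$K * (1 + land$r)) / 2)
  if (any(world$pop[occ] > bound + 1e-9))
    stop("audit: cell population above single-step overshoot bound")
  keys <- world$grp[occ]
  if (any(world$g_kind[keys] == 0L))
    stop("audit: cell owned by an extinct group")
  alive <- living_groups(world)
  sizes <- tabulate(keys, nbins = length(world$g_kind))
  if (any(sizes[alive] == 0L))
    stop("audit: registered group with zero cells")
  if (any(world$g_kind[alive] == .SCG & sizes[alive] != 1L))
    stop("audit: SCG with more than one cell")
  invisible(TRUE)
}

#' Snapshot a world as a data frame
#'
#' @param x A `world` object.
#' @param row.names,optional Ignored (standard generic arguments).
#' @param ... Ignored.
#' @return One row per occupied patch: `row`, `col` (0-based),
#'   `productivity` (`"H"`/`"L"`), `group_id` (registry key), `group_kind`
#'   (`"SCG"`/`"MCG"`) and `population`.
#' @export
as.data.frame.world <- function(x, row.names = NULL, optional = FALSE, ...) {
  occ <- which(x$grp != 0L)
  land <- x$landscape
  data.frame(
    row = .row(land, occ), col = .col(land, occ),
    productivity = ifelse(land$high[occ], "H", "L"),
    group_id = x$grp[occ],
    group_kind = c("SCG", "MCG")[x$g_kind[x$grp[occ]]],
    population = x$pop[occ]
  )
}

#' @export
print.world <- function(x, ...) {
  cen <- census(x)
  cat("<world> year ", x$year, ": ", cen$n_blue_scg, " blue SCGs, ",
      cen$n_red_scg, " red SCGs, ", cen$n_mcg, " MCGs (",
      cen$n_mcg_cells, " cells); ", cen$n_cells_total,
      " occupied patches\n", sep = "")
  invisible(x)
}

# Remove a cell from the lattice; deletes its group from the registry when
# it was the last cell (extinction logged by the caller via .kill_if_empty).
.remove_cell <- function(world, i) {
  world$pop[i] <- 0
  world$grp[i] <- 0L
}

.kill_if_empty <- function(world, key) {
  if (world$g_kind[key] != 0L && length(.group_cells(world, key)) == 0L) {
    world$g_kind[key] <- 0L
    .log_event(world$ev, world$year, "EXTINCTION", actor = key)
  }
  invisible(NULL)
}
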