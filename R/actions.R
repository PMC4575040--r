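# Per-cell decision logic and warfare resolution.
#
# The war-propensity, victory and attrition kernels are the minimal forms
# consistent with the model's behavioural statements (linear size dependence
# of victory; the constant c scaling the population term of aggression;
# redness driving aggression; c1 scaling war costs). They are kept behind
# this module's interface so alternative kernels can be swapped in.

#' Probability that a group initiates a war
#'
#' Aggression rises with the group's redness (the mean redness of its member
#' cells) and with its total population, the latter weighted by the war
#' constant `c`:
#' `p_war = min(1, redness + c * population)`.
#' At the default `c = 0.001` population size matters little — a peaceful
#' group of 100 attacks an occupied neighbour with probability 0.1 — while a
#' fully red group always fights.
#'
#' @param world A `world` object.
#' @param group Registry key of the acting group.
#' @param c War constant (default 0.001).
#' @return A probability in \[0, 1\], non-decreasing in redness and
#'   population.
#' @export
war_probability <- function(world, group, c = 0.001) {
  min(1, group_redness(world, group) + c * group_population(world, group))
}

#' Victory probability under the linear (Lanchester) law
#'
#' The attacker's chance of winning is its share of the total engaged
#' population, `N_A / (N_A + N_B)`, computed on whole-group populations:
#' an outnumbering group wins proportionally more often, and
#' `victory_probability(a, b) + victory_probability(b, a) == 1`.
#'
#' @param attacker_pop,defender_pop Total populations of the two groups.
#' @return The attacker's victory probability.
#' @examples
#' victory_probability(200, 100)  # 2/3
#' @export
victory_probability <- function(attacker_pop, defender_pop) {
  if (attacker_pop < 0 || defender_pop < 0)
    stop("populations must be non-negative")
  tot <- attacker_pop + defender_pop
  if (tot == 0) stop("victory between two empty groups is undefined")
  attacker_pop / tot
}

#' Decide what a sampled cell does this year
#'
#' A cell whose population does not exceed its patch carrying capacity stays
#' static. An over-capacity cell picks one von Neumann neighbour patch
#' uniformly at random: if the patch is empty it buds there; if it is held by
#' a foreign group it attacks with probability [war_probability()] of its own
#' group (else stays static); if it is held by its own group it stays static.
#'
#' @param world A `world` object.
#' @param coord Patch coordinate `c(row, col)` (0-based) of the acting cell.
#' @param c War constant passed to [war_probability()].
#' @return A list with `variant` (`"STATIC"`, `"BUD"` or `"WAR"`) and, for
#'   the latter two, `target`, the chosen neighbour coordinate.
#' @export
choose_action <- function(world, coord, c = 0.001) {
  stopifnot(inherits(world, "world"))
  i <- .idx(world$landscape, coord[1], coord[2])
  if (world$grp[i] == 0L) stop("no cell at (", coord[1], ",", coord[2], ")")
  a <- .choose_action_idx(world, i, c)
  if (a$variant == "STATIC") return(list(variant = "STATIC"))
  list(variant = a$variant,
       target = c(.row(world$landscape, a$target),
                  .col(world$landscape, a$target)))
}

.choose_action_idx <- function(world, i, c) {
  if (world$pop[i] <= world$landscape$K[i]) return(list(variant = "STATIC"))
  nb <- world$landscape$nbr[[i]]
  j <- nb[sample.int(length(nb), 1L)]
  gj <- world$grp[j]
  if (gj == 0L) return(list(variant = "BUD", target = j))
  if (gj != world$grp[i]) {
    p <- war_probability(world, world$grp[i], c)
    if (stats::runif(1) < p) return(list(variant = "WAR", target = j))
  }
  list(variant = "STATIC")
}

#' Bud into an empty neighbouring patch
#'
#' The parent cell's population is split in half; the other half founds a
#' new cell on the empty target patch. A daughter of an SCG becomes a new,
#' independent SCG that inherits the parent's heritable lineage marker and
#' takes its colour from its own patch (a blue SCG budding onto a
#' low-productivity patch founds a red SCG). A daughter of an MCG joins the
#' parent's MCG.
#'
#' @param world A `world` object (mutated in place).
#' @param coord Coordinate of the parent cell.
#' @param target Coordinate of the empty, adjacent target patch.
#' @return The world, invisibly.
#' @export
bud <- function(world, coord, target) {
  stopifnot(inherits(world, "world"))
  land <- world$landscape
  i <- .idx(land, coord[1], coord[2])
  j <- .idx(land, target[1], target[2])
  .bud_idx(world, i, j)
  invisible(world)
}

.bud_idx <- function(world, i, j) {
  if (world$grp[i] == 0L) stop("no cell on the budding patch")
  if (world$grp[j] != 0L) stop("bud target is occupied")
  if (!(j %in% world$landscape$nbr[[i]])) stop("bud target is not adjacent")
  before <- world$pop[i]
  half <- before / 2
  key <- world$grp[i]
  world$pop[i] <- half
  world$pop[j] <- half
  if (world$g_kind[key] == .SCG) {
    world$grp[j] <- .new_group(world, .SCG, marker = world$g_marker[key])
  } else {
    world$grp[j] <- key
  }
  .log_event(world$ev, world$year, "BUD", actor = key,
             target = world$grp[j], row = .row(world$landscape, j),
             col = .col(world$landscape, j), pop_before = before,
             pop_after = half)
  invisible(NULL)
}

#' Resolve a war between two adjacent cells
#'
#' The engaged cells' whole groups fight; the winner is drawn by the linear
#' Lanchester law on total group populations ([victory_probability()]).
#'
#' If the attacker's group wins, the defender's engaged cell is annihilated
#' and the attacker colonises the captured patch with half of its engaged
#' cell's population (the engaged cell keeps the other half) — an MCG
#' annexes the patch as a new member cell, while an SCG proliferates: the
#' captured patch founds a new independent SCG of the attacker's lineage,
#' exactly as in budding. The losing
#' group additionally suffers attrition `c1 * p_winner * N_winner`, where
#' `N_winner` is the winning group's total population at engagement —
#' casualties scale with the size of the force inflicting them — removed
#' proportionally across its remaining cells. If the defender's group wins,
#' the attacking cell is annihilated (its patch becomes empty — defenders
#' gain no territory) and the attacker's group suffers the symmetric
#' attrition. Any cell whose population falls below 1 person is removed; a
#' group losing its last cell goes extinct. A war between two large groups
#' can therefore strip the loser of hundreds of cells at once, which is
#' what eventually drives the landscape towards single-group dominance.
#'
#' @param world A `world` object (mutated in place).
#' @param coord Coordinate of the attacking cell.
#' @param target Coordinate of the defending cell (adjacent, foreign).
#' @param c1 Cost constant scaling war attrition (default 1).
#' @param winner Optional `"attacker"` or `"defender"` to force the outcome
#'   (for deterministic analysis); default `NULL` draws it.
#' @return The world, invisibly.
#' @export
resolve_war <- function(world, coord, target, c1 = 1, winner = NULL) {
  stopifnot(inherits(world, "world"))
  land <- world$landscape
  .resolve_war_idx(world, .idx(land, coord[1], coord[2]),
                   .idx(land, target[1], target[2]), c1, winner)
  invisible(world)
}

.resolve_war_idx <- function(world, i, j, c1, winner = NULL) {
  ga <- world$grp[i]; gd <- world$grp[j]
  if (ga == 0L || gd == 0L) stop("war requires two occupied patches")
  if (ga == gd) stop("a group cannot war with itself")
  if (!(j %in% world$landscape$nbr[[i]])) stop("combatants are not adjacent")
  Na <- group_population(world, ga)
  Nd <- group_population(world, gd)
  p_att <- victory_probability(Na, Nd)
  att_wins <- if (is.null(winner)) stats::runif(1) < p_att
              else match.arg(winner, c("attacker", "defender")) == "attacker"
  if (att_wins) {
    engaged <- world$pop[i]          # winner's engaged cell, at engagement
    .remove_cell(world, j)           # defender's cell annihilated
    half <- engaged / 2
    world$pop[i] <- half
    world$pop[j] <- half             # captured patch colonised
    # an MCG annexes the patch; an SCG proliferates, founding a new
    # independent SCG of its lineage (as in budding)
    world$grp[j] <- if (world$g_kind[ga] == .MCG) ga
                    else .new_group(world, .SCG, marker = world$g_marker[ga])
    gj <- world$grp[j]
    .apply_attrition(world, gd, c1 * p_att * Na)
    .cull_small_cells(world, c(i, j))
    .kill_if_empty(world, gj)
    win_key <- ga
  } else {
    .remove_cell(world, i)           # attacker's cell annihilated, no gain
    .apply_attrition(world, ga, c1 * (1 - p_att) * Nd)
    win_key <- gd
  }
  .log_event(world$ev, world$year, "WAR", actor = ga, target = gd,
             row = .row(world$landscape, j), col = .col(world$landscape, j),
             pop_before = Na, pop_after = .group_population_safe(world, ga),
             winner = win_key)
  .kill_if_empty(world, ga)
  .kill_if_empty(world, gd)
  invisible(NULL)
}

# Total population of a possibly-extinct group (0 if gone); internal helper
# for logging after a war may have emptied a side.
.group_population_safe <- function(world, key) {
  sum(world$pop[.group_cells(world, key)])
}

# Remove dN persons from a group, spread proportionally over its cells;
# cells driven below 1 person are culled.
.apply_attrition <- function(world, key, dN) {
  if (dN <= 0) return(invisible(NULL))
  cells <- .group_cells(world, key)
  if (length(cells) == 0L) return(invisible(NULL))
  tot <- sum(world$pop[cells])
  fac <- max(0, 1 - dN / tot)
  world$pop[cells] <- world$pop[cells] * fac
  .cull_small_cells(world, cells)
  invisible(NULL)
}

.cull_small_cells <- function(world, cells) {
  for (i in cells) {
    if (world$grp[i] != 0L && world$pop[i] < 1) .remove_cell(world, i)
  }
  invisible(NULL)
}
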