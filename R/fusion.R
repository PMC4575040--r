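# Birth of multicellular groups by fusion of adjacent near-capacity blue
# SCGs. Checked once after every cell decision in the yearly scheduler.

#' Blue SCGs eligible for fusion
#'
#' An SCG is eligible when it sits on a high-productivity patch (a blue SCG)
#' and its population strictly exceeds `cc_fraction` of the patch carrying
#' capacity: a blue SCG at exactly 90% of capacity is not yet eligible.
#' Red SCGs never fuse, whatever their population.
#'
#' @param world A `world` object.
#' @param cc_fraction Eligibility fraction of carrying capacity
#'   (default 0.9, strict inequality).
#' @return Integer vector of eligible group registry keys.
#' @export
eligible_blue_scgs <- function(world, cc_fraction = 0.9) {
  stopifnot(inherits(world, "world"))
  world$grp[.eligible_blue_idx(world, cc_fraction)]
}

# Patch indices of eligible blue SCGs (an SCG has exactly one cell, so the
# patch identifies the group).
.eligible_blue_idx <- function(world, cc_fraction) {
  land <- world$landscape
  cand <- which(land$high & world$pop > cc_fraction * land$K &
                  world$grp != 0L)
  cand[world$g_kind[world$grp[cand]] == .SCG]
}

#' Attempt one SCG-to-MCG fusion
#'
#' If at least `threshold` blue SCGs above the capacity fraction exist on
#' the landscape, one of them is chosen uniformly at random as the
#' reference. If at least `threshold - 1` of the reference's von Neumann
#' neighbour patches hold eligible blue SCGs, the reference and *all* its
#' adjacent eligible SCGs fuse into a single new MCG carrying a fresh,
#' never-used lineage marker; member cells keep their patches and
#' populations, so fusion conserves total population and occupancy exactly.
#' Otherwise nothing changes — one attempt, one candidate reference.
#'
#' @param world A `world` object (mutated in place).
#' @param threshold Minimum number of blue SCGs that fuse (default 4).
#' @param cc_fraction Capacity fraction for eligibility (default 0.9).
#' @return `TRUE` if an MCG was born, `FALSE` otherwise (invisibly).
#' @export
attempt_fusion <- function(world, threshold = 4, cc_fraction = 0.9) {
  stopifnot(inherits(world, "world"))
  elig <- .eligible_blue_idx(world, cc_fraction)
  if (length(elig) < threshold) return(invisible(FALSE))
  ref <- elig[sample.int(length(elig), 1L)]
  adj <- intersect(world$landscape$nbr[[ref]], elig)
  if (length(adj) < threshold - 1L) return(invisible(FALSE))
  members <- c(ref, adj)
  old_keys <- world$grp[members]
  key <- .new_group(world, .MCG)         # fresh marker from the counter
  world$grp[members] <- key
  world$g_kind[old_keys] <- 0L
  .log_event(world$ev, world$year, "FUSION", actor = key,
             target = length(members),
             row = .row(world$landscape, ref),
             col = .col(world$landscape, ref),
             pop_before = sum(world$pop[members]),
             pop_after = sum(world$pop[members]))
  invisible(TRUE)
}
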