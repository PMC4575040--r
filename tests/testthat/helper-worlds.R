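# Builders for bespoke test worlds. The world is a documented environment
# (pop/grp vectors plus a group registry), so fixtures are assembled
# directly in code.

# Landscape from a logical matrix (TRUE = high productivity), row-major.
land_from_matrix <- function(high, K_H = 100, K_L = 50,
                             r_H = 0.03, r_L = 0.01) {
  land <- generate_landscape(ncol(high), nrow(high), c(1, 1), "RANDOM",
                             K_H, K_L, r_H, r_L, seed = 1)
  land$high <- as.vector(t(high))
  land$K <- ifelse(land$high, K_H, K_L)
  land$r <- ifelse(land$high, r_H, r_L)
  land$red <- as.numeric(!land$high)
  land
}

empty_world <- function(land) {
  place_initial_groups(land, n_blue = 0, n_red = 0, seed = 1)
}

# Add a group with cells at `coords` (matrix of 0-based row,col) holding
# populations `pops`; returns the registry key.
add_group <- function(world, kind, coords, pops) {
  coords <- matrix(coords, ncol = 2)
  key <- length(world$g_kind) + 1L
  world$g_kind[key] <- if (kind == "SCG") 1L else 2L
  world$g_marker[key] <- world$next_marker
  world$next_marker <- world$next_marker + 1L
  idx <- coords[, 1] * world$landscape$width + coords[, 2] + 1L
  stopifnot(all(world$grp[idx] == 0L))
  world$grp[idx] <- key
  world$pop[idx] <- pops
  key
}

# Uniform all-high or all-low helper grids.
uniform_land <- function(nrow, ncol, high = TRUE, ...) {
  land_from_matrix(matrix(high, nrow, ncol), ...)
}

total_population <- function(world) sum(world$pop)
occupied_patches <- function(world) sum(world$grp != 0L)
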