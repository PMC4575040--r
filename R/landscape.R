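# Patch index convention: patches are stored in row-major order, index
# i = row * width + col + 1 with 0-based (row, col). All hot-path code works
# on indices; user-facing functions accept/return 0-based (row, col) pairs.

.idx <- function(landscape, row, col) {
  as.integer(row) * landscape$width + as.integer(col) + 1L
}

.row <- function(landscape, idx) (idx - 1L) %/% landscape$width
.col <- function(landscape, idx) (idx - 1L) %% landscape$width

# Round-half-up (base round() rounds half to even, which would split a
# 33x33 lattice 544/545 the wrong way for a 1:1 ratio).
.round_half_up <- function(x) floor(x + 0.5)

.aggregation_modes <- c("RANDOM", "BLOCK9", "BLOCK49", "BLOCK81")

#' Generate a patch landscape
#'
#' Builds the square lattice of habitable patches on which the simulation
#' runs. Each patch has one of two productivity classes: high-productivity
#' (HP) patches support larger populations (carrying capacity `K_H`) growing
#' faster (`r_H`), low-productivity (LP) patches support fewer people
#' (`K_L`, `r_L`). The number of LP patches is
#' `round(width * height * LP / (LP + HP))` under the declared `lp_hp_ratio`
#' (half-up rounding; LP absorbs the remainder), and their placement is
#' controlled by `aggregation_mode`:
#'
#' * `"RANDOM"`: productivity assigned by uniform draw of patch identities
#'   without replacement.
#' * `"BLOCK9"`, `"BLOCK49"`, `"BLOCK81"`: HP patches are laid down as
#'   non-overlapping square blocks (3x3, 7x7, 9x9) at uniformly random
#'   positions until the HP quota is met; any residual HP patches are placed
#'   4-adjacent to an existing block, so every HP patch belongs to a
#'   4-connected HP cluster of at least 9, 49 or 81 patches.
#'
#' The lattice has natural absorbing edges: no wrap-around, border patches
#' simply have fewer neighbours.
#'
#' @param width,height Lattice dimensions in patches (default 33 x 33).
#' @param lp_hp_ratio Integer pair `c(LP, HP)` giving the ratio of
#'   low- to high-productivity patches (default `c(1, 1)`).
#' @param aggregation_mode One of `"RANDOM"`, `"BLOCK9"`, `"BLOCK49"`,
#'   `"BLOCK81"`.
#' @param K_H,K_L Carrying capacities (persons) of HP and LP patches.
#' @param r_H,r_L Yearly per-capita growth rates on HP and LP patches.
#' @param seed Optional integer; when supplied the landscape is generated
#'   from a private RNG state seeded with it (the caller's RNG stream is
#'   left untouched). When `NULL`, draws come from the current RNG stream.
#'
#' @return An object of class `landscape`: a list with `width`, `height`,
#'   `n`, logical vector `high` (row-major patch order), numeric vectors
#'   `K`, `r`, `red` (per-patch cell redness, 0 for HP, 1 for LP),
#'   neighbour index list `nbr`, and the generation settings.
#' @examples
#' land <- generate_landscape(seed = 1)
#' table(land$high)
#' @export
generate_landscape <- function(width = 33, height = 33,
                               lp_hp_ratio = c(1, 1),
                               aggregation_mode = "RANDOM",
                               K_H = 100, K_L = 50,
                               r_H = 0.03, r_L = 0.01,
                               seed = NULL) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (width < 1L || height < 1L)
    stop("landscape dimensions must be >= 1 (got ", width, " x ", height, ")")
  lp_hp_ratio <- as.numeric(lp_hp_ratio)
  if (length(lp_hp_ratio) != 2L || any(lp_hp_ratio < 0) ||
      sum(lp_hp_ratio) == 0)
    stop("lp_hp_ratio must be two non-negative numbers, not both zero")
  aggregation_mode <- match.arg(aggregation_mode, .aggregation_modes)

  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }

  n <- width * height
  n_low <- as.integer(.round_half_up(n * lp_hp_ratio[1] / sum(lp_hp_ratio)))
  n_high <- n - n_low

  high <- logical(n)
  if (aggregation_mode == "RANDOM") {
    if (n_high > 0L) high[sample.int(n, n_high)] <- TRUE
  } else {
    side <- c(BLOCK9 = 3L, BLOCK49 = 7L, BLOCK81 = 9L)[[aggregation_mode]]
    k <- side * side
    if (n_high < k)
      stop("aggregation_mode ", aggregation_mode, " needs an HP quota of at ",
           "least ", k, " patches, but lp_hp_ratio ",
           paste(lp_hp_ratio, collapse = ":"), " on a ", width, " x ", height,
           " lattice yields only ", n_high)
    if (width < side || height < side)
      stop("aggregation_mode ", aggregation_mode, " needs a lattice of at ",
           "least ", side, " x ", side)
    high <- .place_blocks(width, height, n_high, side)
  }

  structure(list(
    width = width, height = height, n = n,
    high = high,
    K = ifelse(high, K_H, K_L),
    r = ifelse(high, r_H, r_L),
    red = as.numeric(!high),
    nbr = .neighbor_index_list(width, height),
    aggregation_mode = aggregation_mode,
    lp_hp_ratio = lp_hp_ratio,
    K_H = K_H, K_L = K_L, r_H = r_H, r_L = r_L
  ), class = "landscape")
}

# Non-overlapping uniform block placement with rejection sampling, then
# residual HP patches appended 4-adjacent to existing HP.
.place_blocks <- function(width, height, n_high, side) {
  n <- width * height
  high <- logical(n)
  placed <- 0L
  k <- side * side
  top_rows <- 0:(height - side)
  top_cols <- 0:(width - side)
  block_of <- function(r0, c0) {
    rows <- rep(r0:(r0 + side - 1L), each = side)
    cols <- rep(c0:(c0 + side - 1L), times = side)
    rows * width + cols + 1L
  }
  tries <- 0L
  max_tries <- 10000L
  while (placed + k <= n_high) {
    r0 <- top_rows[sample.int(length(top_rows), 1L)]
    c0 <- top_cols[sample.int(length(top_cols), 1L)]
    b <- block_of(r0, c0)
    if (!any(high[b])) {
      high[b] <- TRUE
      placed <- placed + k
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries) {
        # enumerate remaining feasible positions; if none, remainder goes
        # on as residual adjacent growth
        feas <- NULL
        for (rr in top_rows) for (cc in top_cols) {
          if (!any(high[block_of(rr, cc)])) feas <- rbind(feas, c(rr, cc))
        }
        if (is.null(feas)) break
        pick <- feas[sample.int(nrow(feas), 1L), ]
        high[block_of(pick[1], pick[2])] <- TRUE
        placed <- placed + k
        tries <- 0L
      }
    }
  }
  nbr <- .neighbor_index_list(width, height)
  while (placed < n_high) {
    frontier <- which(!high & vapply(nbr, function(js) any(high[js]),
                                     logical(1)))
    if (length(frontier) == 0L) frontier <- which(!high)
    high[frontier[sample.int(length(frontier), 1L)]] <- TRUE
    placed <- placed + 1L
  }
  high
}

# Precompute von Neumann neighbours for every patch, row-major order
# (up, left, right, down), absorbing edges.
.neighbor_index_list <- function(width, height) {
  n <- width * height
  row <- (seq_len(n) - 1L) %/% width
  col <- (seq_len(n) - 1L) %% width
  lapply(seq_len(n), function(i) {
    out <- integer(0)
    if (row[i] > 0L)          out <- c(out, i - width)
    if (col[i] > 0L)          out <- c(out, i - 1L)
    if (col[i] < width - 1L)  out <- c(out, i + 1L)
    if (row[i] < height - 1L) out <- c(out, i + width)
    out
  })
}

#' Von Neumann neighbours of a patch
#'
#' Returns the coordinates of the 4-neighbourhood of a patch that exist on
#' the lattice (absorbing edges: corner patches have 2 neighbours, edge
#' patches 3, interior patches 4), in deterministic row-major order.
#'
#' @param landscape A [generate_landscape()] object.
#' @param coord Integer pair `c(row, col)`, 0-based.
#' @return An integer matrix with columns `row` and `col`, one neighbour per
#'   row.
#' @examples
#' land <- generate_landscape(seed = 1)
#' neighbors(land, c(0, 0))
#' @export
neighbors <- function(landscape, coord) {
  stopifnot(inherits(landscape, "landscape"))
  row <- as.integer(coord[1]); col <- as.integer(coord[2])
  if (row < 0L || row >= landscape$height || col < 0L ||
      col >= landscape$width)
    stop("coordinate (", row, ",", col, ") is outside the ",
         landscape$height, " x ", landscape$width, " lattice")
  js <- landscape$nbr[[.idx(landscape, row, col)]]
  cbind(row = .row(landscape, js), col = .col(landscape, js))
}

#' Tabulate a landscape as a data frame
#'
#' @param x A `landscape` object.
#' @param row.names,optional Ignored (standard generic arguments).
#' @param ... Ignored.
#' @return A data frame with columns `row`, `col` (0-based) and
#'   `productivity` (`"H"`/`"L"`), one patch per row in row-major order.
#' @export
as.data.frame.landscape <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  idx <- seq_len(x$n)
  data.frame(row = .row(x, idx), col = .col(x, idx),
             productivity = ifelse(x$high, "H", "L"))
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", x$height, " x ", x$width, " patches (",
      sum(x$high), " HP / ", sum(!x$high), " LP), mode ",
      x$aggregation_mode, ", LP:HP ",
      paste(x$lp_hp_ratio, collapse = ":"), "\n", sep = "")
  invisible(x)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
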