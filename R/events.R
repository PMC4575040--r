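# Append-only event log with capacity doubling (an R list of one-row data
# frames would be quadratic over a 600-year run).

.new_event_log <- function(capacity = 256L) {
  ev <- new.env(parent = emptyenv())
  ev$n <- 0L
  ev$year <- integer(capacity)
  ev$type <- character(capacity)
  ev$actor <- integer(capacity)
  ev$target <- integer(capacity)
  ev$row <- integer(capacity)
  ev$col <- integer(capacity)
  ev$pop_before <- numeric(capacity)
  ev$pop_after <- numeric(capacity)
  ev$winner <- integer(capacity)
  ev
}

.log_event <- function(ev, year, type, actor = NA_integer_,
                       target = NA_integer_, row = NA_integer_,
                       col = NA_integer_, pop_before = NA_real_,
                       pop_after = NA_real_, winner = NA_integer_) {
  i <- ev$n + 1L
  if (i > length(ev$year)) {
    grow <- function(x) c(x, x)
    for (f in c("year", "actor", "target", "row", "col", "winner"))
      assign(f, grow(get(f, envir = ev)), envir = ev)
    ev$type <- grow(ev$type)
    ev$pop_before <- grow(ev$pop_before)
    ev$pop_after <- grow(ev$pop_after)
  }
  ev$n <- i
  ev$year[i] <- year
  ev$type[i] <- type
  ev$actor[i] <- actor
  ev$target[i] <- target
  ev$row[i] <- row
  ev$col[i] <- col
  ev$pop_before[i] <- pop_before
  ev$pop_after[i] <- pop_after
  ev$winner[i] <- winner
  invisible(NULL)
}

.event_frame <- function(ev) {
  i <- seq_len(ev$n)
  data.frame(year = ev$year[i], type = ev$type[i], actor = ev$actor[i],
             target = ev$target[i], row = ev$row[i], col = ev$col[i],
             pop_before = ev$pop_before[i], pop_after = ev$pop_after[i],
             winner = ev$winner[i])
}

#' Event log of a world
#'
#' Every budding, war, fusion and extinction is recorded as it happens.
#'
#' @param world A `world` object.
#' @return A data frame with columns `year`, `type` (`"BUD"`, `"WAR"`,
#'   `"FUSION"`, `"EXTINCTION"`), `actor` and `target` group registry keys,
#'   the patch `row`/`col` acted on, `pop_before`/`pop_after` of the acting
#'   cell, and (for wars) the `winner` group key.
#' @export
world_events <- function(world) {
  stopifnot(inherits(world, "world"))
  .event_frame(world$ev)
}
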