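# Decisions, budding and warfare.

# A 1x5 strip with an MCG of two cells (97 + 103) next to a lone blue SCG
# of 50: the canonical 200-vs-50 matchup.
strip_matchup <- function() {
  land <- uniform_land(1, 5, high = TRUE)
  w <- empty_world(land)
  mcg <- add_group(w, "MCG", rbind(c(0, 0), c(0, 1)), c(97, 103))
  scg <- add_group(w, "SCG", rbind(c(0, 2)), 50)
  list(w = w, mcg = mcg, scg = scg)
}

test_that("war propensity adds redness and population terms, capped at 1", {
  land <- uniform_land(1, 2, high = TRUE)
  w <- empty_world(land)
  blue <- add_group(w, "SCG", rbind(c(0, 0)), 100)
  expect_equal(war_probability(w, blue, c = 0.001), 0.1)
  expect_equal(war_probability(w, blue, c = 0), 0)
  expect_equal(war_probability(w, blue, c = 1), 1)  # capped

  lowland <- uniform_land(1, 2, high = FALSE)
  w2 <- empty_world(lowland)
  red <- add_group(w2, "SCG", rbind(c(0, 0)), 5)
  expect_equal(war_probability(w2, red), 1)  # redness 1 alone saturates
})

test_that("victory probabilities follow the linear law and sum to one", {
  expect_equal(victory_probability(100, 100), 0.5)
  expect_equal(victory_probability(200, 100), 2 / 3)
  expect_equal(victory_probability(100, 0), 1)
  expect_error(victory_probability(0, 0), "undefined")
  set.seed(99)
  for (i in 1:50) {
    a <- runif(1, 0, 1000); b <- runif(1, 0, 1000)
    expect_equal(victory_probability(a, b) + victory_probability(b, a), 1)
  }
})

test_that("cells at or below capacity stay static; over-capacity cells act", {
  land <- uniform_land(1, 3, high = TRUE)
  w <- empty_world(land)
  add_group(w, "SCG", rbind(c(0, 1)), 90)
  set.seed(1)
  expect_equal(choose_action(w, c(0, 1))$variant, "STATIC")
  w$pop[2] <- 103
  set.seed(1)
  act <- choose_action(w, c(0, 1))
  expect_equal(act$variant, "BUD")  # both neighbours empty
  expect_true(act$target[2] %in% c(0, 2))
})

test_that("over-capacity red cells attack foreign neighbours", {
  land <- uniform_land(1, 2, high = FALSE)
  w <- empty_world(land)
  add_group(w, "SCG", rbind(c(0, 0)), 51)   # over K_L = 50, redness 1
  add_group(w, "SCG", rbind(c(0, 1)), 30)
  set.seed(2)
  for (i in 1:5) expect_equal(choose_action(w, c(0, 0))$variant, "WAR")
})

test_that("own-group neighbours never trigger war or budding", {
  land <- uniform_land(1, 2, high = TRUE)
  w <- empty_world(land)
  add_group(w, "MCG", rbind(c(0, 0), c(0, 1)), c(103, 103))
  set.seed(3)
  for (i in 1:5) expect_equal(choose_action(w, c(0, 0))$variant, "STATIC")
})

test_that("budding halves the parent and founds a lineage SCG or MCG cell", {
  land <- land_from_matrix(matrix(c(TRUE, TRUE, FALSE), 1, 3))
  w <- empty_world(land)
  parent <- add_group(w, "SCG", rbind(c(0, 1)), 103)
  before <- total_population(w)
  bud(w, c(0, 1), c(0, 0))  # onto the HP patch
  expect_equal(total_population(w), before)           # exact conservation
  expect_equal(occupied_patches(w), 2)
  daughter <- w$grp[1]
  expect_true(daughter != parent)
  expect_equal(group_kind(w, daughter), "SCG")
  expect_equal(group_marker(w, daughter), group_marker(w, parent))
  expect_equal(group_population(w, daughter), 51.5)
  expect_equal(group_population(w, parent), 51.5)
  # blue parent budding onto LP founds a red SCG
  w$pop[2] <- 103
  bud(w, c(0, 1), c(0, 2))
  expect_equal(group_redness(w, w$grp[3]), 1)
  expect_error(bud(w, c(0, 1), c(0, 0)), "occupied")

  # an MCG daughter joins the group
  land2 <- uniform_land(1, 3, high = TRUE)
  w2 <- empty_world(land2)
  m <- add_group(w2, "MCG", rbind(c(0, 0), c(0, 1)), c(103, 103))
  n_groups <- length(living_groups(w2))
  bud(w2, c(0, 1), c(0, 2))
  expect_equal(length(living_groups(w2)), n_groups)
  expect_equal(group_size(w2, m), 3)
})

test_that("a forced attacker win captures the patch and splits the cell", {
  m <- strip_matchup()
  w <- m$w
  resolve_war(w, c(0, 1), c(0, 2), winner = "attacker")
  expect_false(m$scg %in% living_groups(w))           # defender extinct
  ext <- world_events(w)
  expect_true(any(ext$type == "EXTINCTION" & ext$actor == m$scg))
  expect_equal(w$pop[2], 51.5)                        # engaged cell halved
  expect_equal(w$pop[3], 51.5)                        # captured patch
  expect_equal(group_size(w, m$mcg), 3)               # MCG annexes
  expect_equal(total_population(w), 97 + 103 + 0)     # loser removed
  audit_world(w)
})

test_that("a forced defender win removes the attacker cell and bleeds its group", {
  m <- strip_matchup()
  w <- m$w
  resolve_war(w, c(0, 1), c(0, 2), winner = "defender")
  expect_equal(w$grp[2], 0L)                     # attacker cell annihilated
  expect_equal(w$pop[3], 50)                     # defender untouched
  # attrition 1 * (50/250) * 50 = 10 persons off the remaining MCG cell
  expect_equal(group_population(w, m$mcg), 97 - 10)
  audit_world(w)
})

test_that("an SCG that wins a war proliferates as a new lineage SCG", {
  land <- uniform_land(1, 3, high = TRUE)
  w <- empty_world(land)
  a <- add_group(w, "SCG", rbind(c(0, 0)), 103)
  b <- add_group(w, "SCG", rbind(c(0, 1)), 40)
  resolve_war(w, c(0, 0), c(0, 1), winner = "attacker")
  new_key <- w$grp[2]
  expect_true(new_key != a && new_key != b)
  expect_equal(group_kind(w, new_key), "SCG")
  expect_equal(group_marker(w, new_key), group_marker(w, a))
  expect_equal(w$pop[1], 51.5)
  expect_equal(w$pop[2], 51.5)
  audit_world(w)
})

test_that("wars between the same group or non-adjacent cells are rejected", {
  land <- uniform_land(1, 4, high = TRUE)
  w <- empty_world(land)
  add_group(w, "MCG", rbind(c(0, 0), c(0, 1)), c(50, 50))
  add_group(w, "SCG", rbind(c(0, 3)), 50)
  expect_error(resolve_war(w, c(0, 0), c(0, 1)), "itself")
  expect_error(resolve_war(w, c(0, 1), c(0, 3)), "adjacent")
  expect_error(resolve_war(w, c(0, 1), c(0, 2)), "occupied")
})

test_that("war never creates population and moves at most one patch", {
  set.seed(17)
  for (i in 1:40) {
    m <- strip_matchup()
    before_pop <- total_population(m$w)
    before_occ <- occupied_patches(m$w)
    resolve_war(m$w, c(0, 1), c(0, 2))
    expect_lte(total_population(m$w), before_pop)
    expect_lte(abs(occupied_patches(m$w) - before_occ), 1)
    audit_world(m$w)
  }
})

test_that("empirical win rate of a 200-vs-100 matchup matches the linear law", {
  land <- uniform_land(1, 2, high = TRUE)
  set.seed(123)
  wins <- 0L
  n <- 10000L
  for (i in seq_len(n)) {
    w <- empty_world(land)
    a <- add_group(w, "SCG", rbind(c(0, 0)), 200)
    add_group(w, "SCG", rbind(c(0, 1)), 100)
    resolve_war(w, c(0, 0), c(0, 1))
    ev <- world_events(w)
    wins <- wins + as.integer(ev$winner[ev$type == "WAR"] == a)
  }
  expect_equal(wins / n, 2 / 3, tolerance = 0.015)
})

test_that("identical seeds resolve an even matchup identically", {
  run_once <- function(seed) {
    set.seed(seed)
    land <- uniform_land(1, 2, high = TRUE)
    w <- empty_world(land)
    add_group(w, "SCG", rbind(c(0, 0)), 80)
    add_group(w, "SCG", rbind(c(0, 1)), 80)
    resolve_war(w, c(0, 0), c(0, 1))
    list(events = world_events(w), pop = w$pop, grp = w$grp)
  }
  expect_identical(run_once(5), run_once(5))
  one <- run_once(5)
  expect_equal(sum(one$grp != 0), if (one$events$winner[1] == 1) 2 else 1)
})
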