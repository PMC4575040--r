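# Census, histograms, emergence and ensemble statistics.

test_that("the census counts groups by kind and colour", {
  land <- generate_landscape(seed = 51)
  w <- place_initial_groups(land, seed = 51)
  expect_equal(unlist(census(w)[c("n_red_scg", "n_blue_scg", "n_mcg",
                                  "n_mcg_cells")], use.names = FALSE),
               c(10, 10, 0, 0))

  w0 <- place_initial_groups(land, 0, 0)
  expect_true(all(census(w0)[-1] == 0))

  high <- matrix(FALSE, 3, 3); high[1, ] <- TRUE
  land2 <- land_from_matrix(high)
  w2 <- empty_world(land2)
  add_group(w2, "MCG", rbind(c(0, 0), c(0, 1), c(0, 2), c(1, 0)),
            rep(40, 4))
  add_group(w2, "SCG", rbind(c(2, 0)), 30)
  add_group(w2, "SCG", rbind(c(2, 1)), 30)
  cen <- census(w2)
  expect_equal(cen$n_red_scg, 2)
  expect_equal(cen$n_blue_scg, 0)
  expect_equal(cen$n_mcg, 1)
  expect_equal(cen$n_mcg_cells, 4)
  expect_equal(cen$largest_mcg_cells, 4)
  expect_equal(cen$largest_mcg_occupancy_fraction, 4 / 9)
})

test_that("MCG sizes fall into the published bin edges", {
  land <- uniform_land(20, 20, high = TRUE)
  w <- empty_world(land)
  sizes <- c(4, 7, 150)
  r0 <- 0
  for (s in sizes) {
    rows <- (r0 + seq_len(s)) - 1
    add_group(w, "MCG", cbind(rows %/% 20, rows %% 20), rep(10, s))
    r0 <- r0 + s
  }
  h <- size_histogram(w)
  expect_equal(h$count[h$bin == "10"], 2)
  expect_equal(h$count[h$bin == "200"], 1)
  expect_equal(sum(h$count), 3)

  w501 <- empty_world(uniform_land(23, 23, high = TRUE))
  add_group(w501, "MCG", cbind((seq_len(501) - 1) %/% 23,
                               (seq_len(501) - 1) %% 23), rep(10, 501))
  h2 <- size_histogram(w501)
  expect_equal(h2$count[h2$bin == ">500"], 1)

  expect_true(all(size_histogram(empty_world(land))$count == 0))
})

test_that("an MCG whittled to one cell stays in the smallest bin", {
  land <- uniform_land(1, 3, high = TRUE)
  w <- empty_world(land)
  add_group(w, "MCG", rbind(c(0, 0)), 40)  # war-reduced remnant
  h <- size_histogram(w)
  expect_equal(sum(h$count), census(w)$n_mcg)
  expect_equal(h$count[h$bin == "10"], 1)
})

test_that("emergence year is the earliest fusion event", {
  quiet <- run_simulation(sim_params(decisions_per_year = 0, years = 30,
                                     seed = 52))
  expect_true(is.na(first_mcg_emergence_year(quiet)))

  res <- run_simulation(sim_params(years = 200, seed = 52))
  fy <- res$events$year[res$events$type == "FUSION"]
  expect_gt(length(fy), 0)
  expect_equal(first_mcg_emergence_year(res), min(fy))
  expect_equal(mcgs_formed(res), length(fy))
})

test_that("occupancy fractions scale cell counts by the lattice size", {
  land <- generate_landscape(seed = 53)  # 33x33
  w <- empty_world(land)
  scg <- add_group(w, "SCG", rbind(c(0, 0)), 30)
  expect_equal(occupancy_fraction(w, scg), 1 / 1089)
  idx <- 2:757  # 756 patches, skipping the SCG's patch
  coords <- cbind((idx - 1) %/% 33, (idx - 1) %% 33)
  # 756 of 1089 patches is the canonical 69% dominance snapshot
  big <- add_group(w, "MCG", coords, 10)
  expect_equal(round(occupancy_fraction(w, big), 2), 0.69)
  expect_equal(occupancy_fraction(w, big), 756 / 1089)
})

test_that("ensemble summaries average census fields and fusion counts", {
  p <- sim_params(years = 50, n_reps = 2, seed = 61)
  ens <- run_replicates(p)
  s <- ensemble_summary(ens)
  expect_equal(s$n_reps, 2)
  expect_false(s$single_replicate)
  # spot-check one field against direct computation
  f <- "n_blue_scg"
  v1 <- ens[[1]]$census[[f]]; v2 <- ens[[2]]$census[[f]]
  got <- s$census[s$census$field == f, ]
  expect_equal(got$mean, (v1 + v2) / 2)
  expect_equal(got$sd, apply(cbind(v1, v2), 1, sd))
  expect_equal(s$mcgs_formed$values,
               vapply(ens, mcgs_formed, numeric(1)))

  twin <- ensemble_summary(list(ens[[1]], ens[[1]]))
  expect_true(all(twin$census$sd == 0))

  solo <- ensemble_summary(ens[[1]])
  expect_true(solo$single_replicate)
  expect_true(all(solo$census$sd == 0))

  short <- run_simulation(sim_params(years = 10, seed = 1))
  expect_error(ensemble_summary(list(ens[[1]], short)), "horizons")
})

test_that("per-year histograms always sum to the living MCG count", {
  res <- run_simulation(sim_params(years = 250, seed = 62))
  expect_equal(unname(rowSums(res$histograms)), res$census$n_mcg)
})
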