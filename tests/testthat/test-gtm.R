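test_that("initiation rate is stepwise linear in the free ribosome pool", {
  p <- gtm_params(R_star = 50, alpha_scale = 1)
  expect_equal(initiation_rate(0.2, 0, p), 0)
  expect_equal(initiation_rate(0.2, 25, p), 0.1)
  expect_equal(initiation_rate(0.2, 50, p), 0.2)
  expect_equal(initiation_rate(0.2, 500, p), 0.2)   # plateau
  # growth-coupled feedback rescales the plateau to d * alpha0
  pf <- gtm_params(R_star = 50, d = 0.5, feedback = TRUE)
  expect_equal(initiation_rate(0.2, 100, pf), 0.1)
  # steric blocking: any ribosome within the first W sites closes the entry
  expect_equal(initiation_rate(0.2, 100, p, occupied = c(9, 40)), 0)
  expect_equal(initiation_rate(0.2, 100, p, occupied = c(10, 40)), 0.2)
})

test_that("KMC current matches exact master-equation enumeration", {
  cases <- list(
    list(L = 8L, W = 2L, alpha = 0.6, beta = 0.8, k = 1.5),
    list(L = 6L, W = 2L, alpha = 1.2, beta = 0.4, k = 2.0)
  )
  for (cs in cases) {
    exact <- tasep_exact_current(cs$L, cs$W, cs$alpha, cs$beta, cs$k)
    fix <- make_uniform_lattice_fixture(cs$L, cs$W, cs$alpha, cs$beta, cs$k)
    sim <- run_uniform_lattice(fix, t_end = 4000, burn_in = 400, seed = 21)
    expect_true(exact$n_states > 10)
    expect_lt(abs(sim$J - exact$current), 3 * sim$J_se)
  }
})

test_that("a jammed lattice packs ribosomes at exactly the footprint spacing", {
  n_sense <- 89L  # 90 lattice sites including the stop codon
  fix <- make_uniform_lattice_fixture(n_sense + 1L, W = 9L, alpha = 10,
                                      beta = 0, k = 5)
  sim <- run_uniform_lattice(fix, t_end = 400, burn_in = 40, seed = 3)
  pos <- sort(as.integer(sim$final_state$positions[[1]]))
  expect_equal(diff(pos), rep(9L, length(pos) - 1L))
  expect_equal(max(pos), 90L)   # front ribosome parked on the stop codon
  expect_equal(length(pos), 10L)
})

test_that("ribosome and tRNA conservation hold after a long event stream", {
  fix <- calibrated_fixture()
  sim <- simulate_cell(fix, t_end = 300, burn_in = 30, seed = 17,
                       record_density = FALSE)
  expect_gt(sim$counts$events, 2e5)
  fs <- sim$final_state
  expect_identical(fs$R_free + fs$n_bound, fix$params$R_total)
  expect_equal(fs$n_bound, sum(lengths(fs$positions)))
  expect_true(all(fs$Tc >= 0 & fs$Tc <= fix$trna$total))
  # exclusion: tracked positions on every lattice at least W apart
  spacings <- unlist(lapply(fs$positions, function(p) diff(sort(p))))
  if (length(spacings) > 0) expect_true(all(spacings >= fix$params$W))
})

test_that("initiation and exit fluxes balance at steady state", {
  fix <- calibrated_fixture()
  sim <- simulate_cell(fix, t_end = 260, burn_in = 60, seed = 23,
                       record_density = FALSE)
  in_rate <- sim$counts$inits / sim$t_record
  out_rate <- (sim$counts$terms + sim$counts$drops) / sim$t_record
  # the imbalance is bounded by the net change in bound ribosomes
  slack <- fix$params$R_total / sim$t_record + 3 * sim$J_se
  expect_lt(abs(in_rate - out_rate), slack)
})

test_that("an empty transcriptome produces no protein", {
  fix <- make_test_fixture()
  tx0 <- fix$transcriptome[0, ]
  attr(tx0, "codon_map") <- fix$codon_map
  sim <- simulate_gtm(tx0, fix$trna, fix$synthetases, fix$params,
                      fix$codon_map, t_end = 5, burn_in = 1, seed = 1)
  expect_equal(sim$J, 0)
  expect_equal(sim$counts$terms, 0)
})

test_that("fixed seeds reproduce trajectories exactly", {
  fix <- make_test_fixture()
  a <- simulate_cell(fix, t_end = 30, burn_in = 5, seed = 8)
  b <- simulate_cell(fix, t_end = 30, burn_in = 5, seed = 8)
  expect_identical(glance(a), glance(b))
  expect_identical(a$density, b$density)
  c <- simulate_cell(fix, t_end = 30, burn_in = 5, seed = 9)
  expect_false(identical(glance(a)$events, glance(c)$events))
})

test_that("downscaling divides counts exactly and preserves intensives", {
  fix <- calibrated_fixture()
  expect_identical(downscale(fix, 1), fix)
  half <- downscale(fix, 2)
  expect_equal(half$trna$total, pmax(floor(fix$trna$total / 2 + 0.5), 1))
  expect_equal(half$params$R_total, floor(fix$params$R_total / 2 + 0.5))
  expect_equal(half$synthetases$Km, fix$synthetases$Km / 2)
  expect_equal(half$params$lambda_scale, 2 * fix$params$lambda_scale)
  expect_equal(half$transcriptome$copy_number,
               pmax(floor(fix$transcriptome$copy_number / 2 + 0.5), 1))

  # intensive observables agree across scales within seed-to-seed error;
  # use copy numbers that divide exactly so rounding does not change the
  # mRNA concentration
  big <- synthetic_fixture(n_categories = 4, seed = 31,
                           copy_numbers = c(8, 6, 4, 2), mean_lengths = 150)
  small <- downscale(big, 2)
  qs <- function(f) vapply(1:3, function(s) {
    simulate_cell(f, t_end = 150, burn_in = 50, seed = s,
                  record_density = FALSE)$Q_mean
  }, numeric(1))
  q_full <- qs(big)
  q_half <- qs(small)
  se <- sqrt(stats::var(q_full) / 3 + stats::var(q_half) / 3)
  expect_lt(abs(mean(q_full) - mean(q_half)), max(3 * se, 0.02))
})

test_that("density profiles are proper occupancies and expose queues", {
  fix <- calibrated_fixture()
  sim <- simulate_cell(fix, t_end = 80, burn_in = 20, seed = 2)
  prof <- density_profile(sim, fix$transcriptome$category_id[1])
  expect_true(all(prof$rho >= 0 & prof$rho <= 1))
  expect_equal(nrow(prof), fix$transcriptome$length[1] + 1L)
  expect_error(density_profile(sim, "nope"), "unknown category")
  nodens <- simulate_cell(fix, t_end = 20, burn_in = 5, seed = 2,
                          record_density = FALSE)
  expect_error(density_profile(nodens), "record_density")
  expect_s3_class(autoplot(sim), "ggplot")
})
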