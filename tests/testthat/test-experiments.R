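test_that("dox mapping hits the measured anchors and refuses extrapolation", {
  expect_equal(as.numeric(dox_to_d(0)), 1)
  expect_equal(as.numeric(dox_to_d(0.5)), 0.035)
  mid <- dox_to_d(0.25)
  expect_equal(as.numeric(mid), sqrt(0.035), tolerance = 1e-12)
  expect_true(attr(mid, "interpolated"))
  expect_false(any(attr(dox_to_d(c(0, 0.5)), "interpolated")))
  expect_error(dox_to_d(-1), "negative")
  expect_error(dox_to_d(0.6), "extrapolate")
})

test_that("queue statistic is a ratio of upstream to downstream density", {
  expect_equal(queue_statistic(rep(0.3, 100), positions = 50), 1)
  rho <- c(rep(0.8, 50), rep(0.1, 50))
  expect_equal(queue_statistic(rho, positions = 50, window = 10), 8)
  prof <- tibble::tibble(site = 1:100, rho = rho)
  expect_equal(queue_statistic(prof, positions = 50, window = 10), 8)
  expect_error(queue_statistic(rho, integer(0)), "no slow-codon")
  expect_error(queue_statistic(rho, 500), "within the profile")
})

test_that("ranking concordance is a Spearman correlation over categories", {
  expect_equal(category_ranking_concordance(c(3, 2, 1), c(300, 20, 1)), 1)
  expect_equal(category_ranking_concordance(c(3, 2, 1), c(1, 2, 3)), -1)
  expect_error(category_ranking_concordance(1:3, 1:4), "same categories")
})

test_that("dose sweeps require calibration and are seed-deterministic", {
  fix_raw <- make_test_fixture()
  expect_error(run_dose_sweep(fix_raw), "not calibrated")

  fix <- calibrated_fixture()
  sw1 <- run_dose_sweep(fix, d_grid = c(1, 0.1), seeds = 1:2,
                        t_end = 40, burn_in = 10)
  sw2 <- run_dose_sweep(fix, d_grid = c(1, 0.1), seeds = 1:2,
                        t_end = 40, burn_in = 10)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  expect_equal(nrow(sw1), 4)
  expect_true(all(diff(sw1$d) >= 0))
  smry <- summarize_sweep(sw1)
  expect_true(all(c("mean", "se", "n") %in% names(smry)))
  expect_s3_class(autoplot(sw1), "ggplot")
})

test_that("global current falls monotonically with synthetase depletion", {
  fix <- calibrated_fixture()
  for (fb in c(FALSE, TRUE)) {
    sw <- run_dose_sweep(fix, d_grid = c(1, 0.2, 0.02), feedback = fb,
                         seeds = 1:2, t_end = 250, burn_in = 120)
    m <- summarize_sweep(sw) |> dplyr::filter(metric == "J")
    m <- m[order(m$d), ]
    # J non-increasing as d decreases, allowing seed noise
    expect_true(all(diff(m$mean) > -3 * sqrt(sum(m$se^2))))
    expect_gt(m$mean[nrow(m)], 2 * m$mean[1])
  }
})

test_that("feedback suppresses queues and preserves the category ranking", {
  fix <- calibrated_fixture()
  tx <- fix$transcriptome
  ngln <- vapply(tx$category_id, function(cc) length(gln_positions(tx, cc)),
                 integer(1))
  rich <- tx$category_id[which.max(ngln)]
  gpos <- gln_positions(tx, rich)
  expect_gt(length(gpos), 2)

  ref <- simulate_cell(fix, t_end = 300, burn_in = 60, seed = 301,
                       record_density = FALSE)
  J_ref <- tidy(ref)$J_a

  res <- tidyr::expand_grid(fb = c(FALSE, TRUE), seed = 1:3)
  res$queue <- NA_real_
  res$conc <- NA_real_
  for (i in seq_len(nrow(res))) {
    p <- fix$params
    p$d <- 0.05
    p$feedback <- res$fb[i]
    sim <- simulate_gtm(fix$transcriptome, fix$trna, fix$synthetases, p,
                        fix$codon_map, t_end = 700, burn_in = 250,
                        seed = res$seed[i])
    res$queue[i] <- queue_statistic(density_profile(sim, rich), gpos)
    res$conc[i] <- category_ranking_concordance(J_ref, tidy(sim)$J_a)
  }
  on <- res[res$fb, ]
  off <- res[!res$fb, ]
  # seed-matched orderings, 3-seed majority
  expect_gte(sum(on$queue < off$queue), 2)
  expect_gte(sum(on$conc > off$conc), 2)
  # with feedback the density is homogeneous around the Gln codons
  expect_true(all(on$queue > 0.7 & on$queue < 1.4))
  expect_true(all(off$queue > 2))
})
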