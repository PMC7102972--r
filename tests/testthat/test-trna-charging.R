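simple_pool <- function() {
  tibble::tibble(
    species = c("Gln-UUG", "Gln-CUG", "Lys-UUU"),
    anticodon = c("UUG", "CUG", "UUU"),
    amino_acid = c("Gln", "Gln", "Lys"),
    total = c(100L, 200L, 300L),
    charged = c(50L, 150L, 250L)
  )
}

simple_aars <- function() {
  tibble::tibble(amino_acid = c("Gln", "Lys"), E0 = c(1, 2),
                 kcat = c(1, 3), Km = c(50, 80), d = 1)
}

test_that("recharging follows Michaelis-Menten with isoacceptor competition", {
  # single isoacceptor at half saturation
  trna <- tibble::tibble(species = "Lys-UUU", anticodon = "UUU",
                         amino_acid = "Lys", total = 100L, charged = 50L)
  aars <- tibble::tibble(amino_acid = "Lys", E0 = 1, kcat = 1, Km = 50, d = 1)
  expect_equal(recharging_rate(trna, aars)$rate, 0.5)

  # empty uncharged pool gives exactly zero
  trna$charged <- 100L
  expect_equal(recharging_rate(trna, aars)$rate, 0)

  # two isoacceptors share the denominator: Vmax1 * 50 / (50 + 100)
  pool <- simple_pool()
  pool$charged <- c(50L, 150L, 250L)  # Tu = 50, 50, 50
  aars <- simple_aars()
  r <- recharging_rate(pool, aars, species = "Gln-UUG")
  expect_equal(r$rate, 1 * 50 / (50 + 100))
})

test_that("recharging rate is monotone in own and competitor pools", {
  set.seed(42)
  for (rep in 1:20) {
    tot <- sample(100:2000, 2)
    tu1 <- sample(seq_len(tot[1] - 1), 2)
    tu2 <- sample(seq_len(tot[2]), 1)
    km <- stats::runif(1, 10, 300)
    pool <- tibble::tibble(
      species = c("A-1", "A-2"), anticodon = c("1", "2"),
      amino_acid = "aaX", total = as.integer(tot),
      charged = as.integer(tot - c(max(tu1), tu2))
    )
    aars <- tibble::tibble(amino_acid = "aaX", E0 = 1,
                           kcat = stats::runif(1, 0.5, 5), Km = km, d = 1)
    hi <- recharging_rate(pool, aars, "A-1")$rate
    pool$charged[1] <- as.integer(tot[1] - min(tu1))  # fewer uncharged
    lo <- recharging_rate(pool, aars, "A-1")$rate
    expect_gt(hi, lo)
    # a larger competitor pool depresses the rate
    pool$charged[1] <- as.integer(tot[1] - max(tu1))
    pool$charged[2] <- 0L  # competitor fully uncharged
    comp <- recharging_rate(pool, aars, "A-1")$rate
    expect_lt(comp, hi + 1e-12)
  }
})

test_that("recharging rate saturates at V_max for large own pools", {
  pool <- tibble::tibble(species = "A-1", anticodon = "1", amino_acid = "aaX",
                         total = 10000000L, charged = 0L)
  aars <- tibble::tibble(amino_acid = "aaX", E0 = 2, kcat = 3, Km = 120, d = 1)
  r <- recharging_rate(pool, aars)$rate
  expect_equal(r, 6, tolerance = 0.01)
})

test_that("synthetase depletion rescales only the targeted enzyme", {
  aars <- simple_aars()
  dep <- apply_dox_ratio(aars, "Gln", 0.035)
  expect_equal(dep$d, c(0.035, 1))
  pool <- simple_pool()
  r_wt <- recharging_rate(pool, aars)
  r_dep <- recharging_rate(pool, dep)
  expect_equal(r_dep$rate[r_dep$amino_acid == "Gln"],
               0.035 * r_wt$rate[r_wt$amino_acid == "Gln"])
  expect_equal(r_dep$rate[r_dep$amino_acid == "Lys"],
               r_wt$rate[r_wt$amino_acid == "Lys"])
  # overexpression doubles V_max; d outside (0, 2] is rejected
  dbl <- apply_dox_ratio(aars, "Gln", 2)
  expect_equal(recharging_rate(pool, dbl)$vmax[1], 2 * r_wt$vmax[1])
  expect_error(apply_dox_ratio(aars, "Gln", 0), "positive")
  expect_error(apply_dox_ratio(aars, "Gln", 2.5), "must be in")
})

test_that("hopping rate is proportional to the cognate charged pool", {
  map <- default_codon_map()
  pool <- tibble::tibble(
    species = "Lys-UUU", anticodon = "UUU", amino_acid = "Lys",
    total = 400L, charged = 100L
  )
  k1 <- hopping_rate("AAA", pool, map, lambda_scale = 0.02)
  expect_equal(k1, 0.02 * 1 * 100)
  pool$charged <- 200L
  expect_equal(hopping_rate("AAA", pool, map, 0.02), 2 * k1)
  pool$charged <- 0L
  expect_equal(hopping_rate("AAA", pool, map, 0.02), 0)
  expect_error(hopping_rate(stop_codon(), pool, map), "stop")
})

test_that("wobble-decoded codons hop slower than Watson-Crick codons", {
  map <- default_codon_map()
  pool <- tibble::tibble(
    species = "Ala-AGC", anticodon = "AGC", amino_acid = "Ala",
    total = 500L, charged = 400L
  )
  expect_equal(hopping_rate("GCC", pool, map, 1) / hopping_rate("GCU", pool, map, 1),
               0.64)
})

test_that("charge/consume cycle conserves totals and closes exactly", {
  pool <- simple_pool()
  after <- recharge_trna(consume_charged(pool, "Gln-UUG"), "Gln-UUG")
  expect_identical(after, pool)
  expect_identical(consume_charged(pool, "Gln-UUG")$total, pool$total)

  # random event sequences never break per-species conservation
  set.seed(99)
  cur <- pool
  for (i in 1:500) {
    sp <- sample(cur$species, 1)
    j <- match(sp, cur$species)
    if (stats::runif(1) < 0.5 && cur$charged[j] > 0) {
      cur <- consume_charged(cur, sp)
    } else if (cur$charged[j] < cur$total[j]) {
      cur <- recharge_trna(cur, sp)
    }
    expect_identical(cur$total, pool$total)
    expect_true(all(cur$charged >= 0 & cur$charged <= cur$total))
  }

  empty <- pool
  empty$charged[1] <- 0L
  expect_error(consume_charged(empty, "Gln-UUG"), "empty charged pool")
})
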