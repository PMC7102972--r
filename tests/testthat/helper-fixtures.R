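# Shared fixtures for the test suite, all generated in code.

# Small, fast whole-cell fixture for unit tests.
make_test_fixture <- function(seed = 101, n_categories = 3) {
  synthetic_fixture(
    n_categories = n_categories, seed = seed,
    mean_lengths = 60, total_trna = 6000, R_total = 80,
    copy_numbers = c(4, 2, 1)[seq_len(n_categories)]
  )
}

# The standard desk-scale fixture used for calibrated runs; cached so the
# (cheap but not free) calibration happens once per test session.
calibrated_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fix <- synthetic_fixture(seed = 7)
      cache <<- calibrate_cell(
        fix, seed = 11,
        tol = c(elongation = 0.03, charging = 0.03, initiation = 0.02),
        t_end = 80, burn_in = 30
      )
    }
    cache
  }
})

# Minimal single-mRNA configuration with effectively constant hopping and
# initiation rates, used to compare the KMC against exact enumeration.
make_uniform_lattice_fixture <- function(L_sites, W, alpha, beta, k) {
  n_sense <- L_sites - 1L
  codon_map <- tibble::tibble(
    codon = "AAA", amino_acid = "Lys", species = "Lys-UUU",
    anticodon = "UUU", wobble = 1
  )
  tx <- tibble::tibble(
    category_id = "C01", copy_number = 1L, alpha0 = alpha,
    length = n_sense, codons = list(c(rep("AAA", n_sense), stop_codon()))
  )
  attr(tx, "codon_map") <- codon_map
  big <- 1e6L
  # fully charged pool + near-instant recharging: the charged count stays
  # pinned at `big`, so the hopping rate is the constant k = lambda * big
  trna <- tibble::tibble(species = "Lys-UUU", anticodon = "UUU",
                         amino_acid = "Lys", total = big, charged = big)
  # near-instant recharging keeps the charged pool (hence k) constant
  syn <- tibble::tibble(amino_acid = "Lys", E0 = 1, kcat = 5e5, Km = 1, d = 1)
  params <- gtm_params(W = W, beta = beta, gamma = 0, R_total = 1000,
                       R_star = 1, lambda_scale = k / big,
                       alpha_scale = 1)
  list(transcriptome = tx, trna = trna, synthetases = syn,
       codon_map = codon_map, params = params)
}

run_uniform_lattice <- function(fix, t_end, burn_in, seed) {
  simulate_gtm(fix$transcriptome, fix$trna, fix$synthetases, fix$params,
               fix$codon_map, t_end = t_end, burn_in = burn_in, seed = seed,
               record_density = FALSE)
}

# A two-gene table in the TSV gene-table layout.
make_test_genes <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    abundance = c(2, 1, 4),
    categories = c("translation:1", "translation:0.5;transport:0.5",
                   "transport:1"),
    AAA = c(1, 0, 2), CAA = c(0, 3, 0), GCU = c(5, 1, 1)
  )
}
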