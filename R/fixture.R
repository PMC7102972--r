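#' Build a complete synthetic desk-scale cell fixture
#'
#' Bundles a synthetic virtual transcriptome, matched tRNA pools, a
#' synthetase table and initial model parameters into one object ready for
#' [simulate_gtm()] / [calibrate_gtm()]. The defaults define the desk-scale
#' study conditions: 8 mRNA categories of 200 codons spanning near-Gln-free
#' to Gln-rich compositions, 36 mRNA copies, 200 ribosomes and ~24,000 tRNAs
#' over 16 species. Initial `lambda_scale`, synthetase capacities and the
#' initiation breakpoint are set from back-of-envelope steady-state
#' estimates so that calibration starts close to its fixed point.
#'
#' @param n_categories number of mRNA categories.
#' @param seed integer seed; the fixture is deterministic given the seed.
#' @param total_trna total tRNA count.
#' @param R_total total ribosome count.
#' @param mean_lengths,copy_numbers,gln_codon_fraction_range passed to
#'   [generate_synthetic_transcriptome()].
#' @param alpha_target initiation-rate calibration target used for sizing.
#' @param elongation_target elongation-rate calibration target (codons/s).
#' @param charged_fraction physiological charging level used for sizing.
#' @param params optional [gtm_params()] overriding the derived defaults.
#' @return A list of class `cell_fixture` with elements `transcriptome`,
#'   `trna`, `synthetases`, `codon_map`, `params`.
#' @export
#' @examples
#' fix <- synthetic_fixture(n_categories = 3, seed = 42)
#' names(fix)
synthetic_fixture <- function(n_categories = 8, seed = NULL,
                              total_trna = 24000, R_total = 200,
                              mean_lengths = 200, copy_numbers = NULL,
                              gln_codon_fraction_range = c(0.002, 0.03),
                              alpha_target = 0.15, elongation_target = 10,
                              charged_fraction = 0.8, params = NULL) {
  codon_map <- default_codon_map()
  tx <- generate_synthetic_transcriptome(
    n_categories, codon_map, gln_codon_fraction_range,
    mean_lengths, copy_numbers, seed = seed
  )
  trna <- synthetic_trna_table(tx, codon_map, total_trna = total_trna,
                               charged_fraction = charged_fraction)
  syn <- synthetic_synthetase_table(tx, trna, codon_map,
                                    alpha_target = alpha_target,
                                    charged_fraction = charged_fraction)
  if (is.null(params)) {
    # lambda guess: demand-weighted mean of wobble * charged count should map
    # to the target elongation rate
    dem <- codon_demand(tx) |>
      dplyr::left_join(codon_map, by = "codon") |>
      dplyr::left_join(trna[, c("species", "total")], by = "species") |>
      dplyr::mutate(kw = .data$wobble * charged_fraction * .data$total)
    mean_kw <- sum(dem$demand * dem$kw) / sum(dem$demand)
    lambda0 <- elongation_target / mean_kw
    # expected bound ribosomes: flux per copy x transit time
    bound <- alpha_target * sum(tx$copy_number * tx$length) / elongation_target
    r_star <- max(R_total - bound, 10)
    params <- gtm_params(R_total = R_total, R_star = r_star,
                         lambda_scale = lambda0)
  }
  structure(
    list(transcriptome = tx, trna = trna, synthetases = syn,
         codon_map = codon_map, params = params),
    class = "cell_fixture"
  )
}

#' @export
print.cell_fixture <- function(x, ...) {
  cat("<cell_fixture>\n")
  cat(sprintf("  %d mRNA categories, %d copies, %d sense codons total\n",
              nrow(x$transcriptome), sum(x$transcriptome$copy_number),
              sum(x$transcriptome$copy_number * x$transcriptome$length)))
  cat(sprintf("  %d tRNA species (%s molecules), %d synthetases, %d ribosomes\n",
              nrow(x$trna), format(sum(x$trna$total), big.mark = ","),
              nrow(x$synthetases), x$params$R_total))
  invisible(x)
}

#' Downscale a cell fixture by a volume factor
#'
#' Divides every extensive count — ribosomes, tRNA totals and charged counts,
#' synthetase abundances, Michaelis constants, mRNA copy numbers and the
#' initiation breakpoint — by `omega` (rounding half-up, minimum 1 for
#' molecule counts), leaving unary rate constants untouched. `lambda_scale`
#' is multiplied by `omega` so the physical hopping rate per ribosome (which
#' pairs a ribosome with a *count* of charged tRNAs) stays intensive;
#' likewise dividing `K_m` with the counts keeps enzyme saturation intensive.
#' Intensive observables (per-copy current, charging levels, densities) are
#' then approximately invariant.
#'
#' @param fixture a `cell_fixture`.
#' @param omega volume scale factor, >= 1.
#' @return The downscaled fixture; warns when a nonzero pool rounds to the
#'   minimum of 1.
#' @export
downscale <- function(fixture, omega) {
  assert_scalar_number(omega, "omega", lower = 1)
  if (omega == 1) return(fixture)
  f <- fixture
  scale_count <- function(x) pmax(round_half_up(x / omega), 1L)
  old_tot <- f$trna$total
  f$trna$total <- as.integer(scale_count(f$trna$total))
  f$trna$charged <- as.integer(pmin(round_half_up(f$trna$charged / omega),
                                    f$trna$total))
  if (any(old_tot > 0 & f$trna$total == 1L)) {
    warn("some tRNA pools downscaled to the minimum count of 1")
  }
  f$transcriptome$copy_number <- as.integer(scale_count(f$transcriptome$copy_number))
  f$synthetases$E0 <- scale_count(f$synthetases$E0)
  f$synthetases$Km <- f$synthetases$Km / omega
  p <- f$params
  f$params <- gtm_params(
    W = p$W, beta = p$beta, gamma = p$gamma,
    R_total = scale_count(p$R_total), R_star = p$R_star / omega,
    lambda_scale = p$lambda_scale * omega, vmax_scale = p$vmax_scale,
    alpha_scale = p$alpha_scale, d = p$d, feedback = p$feedback,
    dox_target = p$dox_target
  )
  f
}

# Convenience wrappers running the model components on a fixture -------------

#' @rdname simulate_gtm
#' @param fixture a `cell_fixture` bundling all tables and parameters.
#' @param ... passed on to [simulate_gtm()].
#' @export
simulate_cell <- function(fixture, ...) {
  simulate_gtm(fixture$transcriptome, fixture$trna, fixture$synthetases,
               fixture$params, fixture$codon_map, ...)
}

#' @rdname calibrate_gtm
#' @param fixture a `cell_fixture`.
#' @param ... passed on to [calibrate_gtm()].
#' @export
calibrate_cell <- function(fixture, ...) {
  cal <- calibrate_gtm(fixture$transcriptome, fixture$trna,
                       fixture$synthetases, fixture$params,
                       fixture$codon_map, ...)
  fixture$params <- cal$params
  # carry the equilibrated charged-pool state so downstream wild-type runs
  # start at (not merely relax towards) the calibrated steady state
  fixture$trna$charged <- as.integer(cal$charged_state)
  fixture$calibration <- cal
  fixture
}
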