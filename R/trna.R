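#' Synthetic tRNA pool table matched to a transcriptome
#'
#' Allocates a total cellular tRNA budget across species proportionally to
#' codon demand (copy-number-weighted codon counts of the transcriptome,
#' stop excluded), with a floor per species, emulating the abundance-demand
#' correlation of real tRNA pools. Initial charged counts are set to the
#' physiological charging level.
#'
#' @param transcriptome a virtual transcriptome tibble.
#' @param codon_map codon-to-tRNA assignment, see [default_codon_map()].
#' @param total_trna total tRNA molecules in the (downscaled) cell.
#' @param charged_fraction initial charged fraction per species.
#' @param min_total abundance floor per species.
#' @return A tibble with columns `species`, `anticodon`, `amino_acid`,
#'   `total`, `charged`.
#' @export
synthetic_trna_table <- function(transcriptome,
                                 codon_map = attr(transcriptome, "codon_map") %||%
                                   default_codon_map(),
                                 total_trna = 24000,
                                 charged_fraction = 0.8,
                                 min_total = 350) {
  validate_codon_map(codon_map)
  dem <- codon_demand(transcriptome)
  dem <- dplyr::left_join(dem, codon_map, by = "codon")
  sp_dem <- dem |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(demand = sum(.data$demand), .groups = "drop")
  sp <- codon_map |>
    dplyr::distinct(.data$species, .data$anticodon, .data$amino_acid) |>
    dplyr::left_join(sp_dem, by = "species") |>
    dplyr::mutate(demand = dplyr::coalesce(.data$demand, 0))
  tot <- pmax(apportion_counts(sp$demand + 1e-9, total_trna), min_total)
  sp |>
    dplyr::mutate(
      total = as.integer(tot),
      charged = as.integer(round_half_up(charged_fraction * tot))
    ) |>
    dplyr::select("species", "anticodon", "amino_acid", "total", "charged")
}

#' Synthetic aminoacyl-tRNA synthetase table
#'
#' One synthetase per amino acid. Catalytic rates are chosen so that at the
#' physiological charging level the Michaelis-Menten recharging rate of each
#' amino acid matches its expected translational demand at the target
#' initiation rate; the global calibration then only needs a small common
#' scale factor. The depletion ratio `d` starts at 1 (wild type) for every
#' enzyme.
#'
#' @param transcriptome a virtual transcriptome tibble.
#' @param trna a tRNA table, see [synthetic_trna_table()].
#' @param codon_map codon-to-tRNA assignment.
#' @param alpha_target expected realized initiation rate per mRNA copy (1/s),
#'   used to size the expected charged-tRNA demand.
#' @param E0 wild-type enzyme abundance per amino acid (count units).
#' @param Km Michaelis constant (count units at simulation scale).
#' @param charged_fraction charging level at which demand and supply balance.
#' @return A tibble with columns `amino_acid`, `E0`, `kcat`, `Km`, `d`.
#' @export
synthetic_synthetase_table <- function(transcriptome, trna,
                                       codon_map = attr(transcriptome, "codon_map") %||%
                                         default_codon_map(),
                                       alpha_target = 0.15,
                                       E0 = 100, Km = 100,
                                       charged_fraction = 0.8) {
  dem <- codon_demand(transcriptome) |>
    dplyr::left_join(codon_map, by = "codon") |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::summarise(demand = sum(.data$demand), .groups = "drop")
  tu <- trna |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::summarise(Tu = sum(.data$total) * (1 - charged_fraction),
                     .groups = "drop")
  out <- trna |>
    dplyr::distinct(.data$amino_acid) |>
    dplyr::left_join(dem, by = "amino_acid") |>
    dplyr::left_join(tu, by = "amino_acid") |>
    dplyr::mutate(
      demand = dplyr::coalesce(.data$demand, 0),
      usage = alpha_target * .data$demand,
      vmax0 = .data$usage * (Km + .data$Tu) / pmax(.data$Tu, 1),
      E0 = E0,
      kcat = .data$vmax0 / E0,
      Km = Km,
      d = 1
    )
  out |> dplyr::select("amino_acid", "E0", "kcat", "Km", "d")
}

validate_trna <- function(trna) {
  req <- c("species", "amino_acid", "total", "charged")
  missing <- setdiff(req, names(trna))
  if (length(missing) > 0) {
    abort(paste0("tRNA table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(trna$total < 0) || any(trna$charged < 0)) {
    abort("tRNA counts must be nonnegative")
  }
  if (any(trna$charged > trna$total)) {
    abort("charged tRNA count exceeds the fixed species total")
  }
  if (anyDuplicated(trna$species)) abort("duplicate tRNA species")
  invisible(trna)
}

validate_synthetases <- function(synthetases) {
  req <- c("amino_acid", "E0", "kcat", "Km", "d")
  missing <- setdiff(req, names(synthetases))
  if (length(missing) > 0) {
    abort(paste0("synthetase table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(synthetases$amino_acid)) {
    abort("exactly one synthetase per amino acid is required")
  }
  if (any(synthetases$d <= 0)) abort("synthetase ratio d must be positive")
  if (any(synthetases$E0 < 0) || any(synthetases$kcat < 0) ||
      any(synthetases$Km < 0)) {
    abort("synthetase parameters must be nonnegative")
  }
  invisible(synthetases)
}

#' Michaelis-Menten recharging rate with isoacceptor competition
#'
#' The recharging (aminoacylation) rate of tRNA species *i* is
#' \deqn{\chi_i = V_{max,i} T_i^u / (K_{m,i} + \sum_j T_j^u)}
#' where the sum runs over all isoacceptors *j* sharing species *i*'s amino
#' acid: isoacceptor tRNAs compete for the same synthetase, giving competitive
#' inhibition. \eqn{V_{max,i} = d \cdot E_0 \cdot k_{cat}} of the cognate
#' synthetase, so depleting an enzyme (small `d`) rescales its maximum
#' charging rate.
#'
#' @param trna a tRNA table with current `charged` counts.
#' @param synthetases a synthetase table (see
#'   [synthetic_synthetase_table()]); its `d` column carries any depletion.
#' @param species optional species name(s); default all.
#' @param vmax_scale global calibration factor applied to every `V_max`.
#' @return A tibble with columns `species`, `amino_acid`, `uncharged`,
#'   `vmax`, `rate` (1/s); `rate` is 0 exactly when the species has no
#'   uncharged molecules.
#' @export
#' @examples
#' trna <- tibble::tibble(species = "Gln-UUG", amino_acid = "Gln",
#'                        total = 100L, charged = 50L)
#' aars <- tibble::tibble(amino_acid = "Gln", E0 = 1, kcat = 1, Km = 50, d = 1)
#' recharging_rate(trna, aars)$rate # half saturation: vmax/2
recharging_rate <- function(trna, synthetases, species = NULL,
                            vmax_scale = 1) {
  validate_trna(trna)
  validate_synthetases(synthetases)
  tab <- trna |>
    dplyr::mutate(uncharged = .data$total - .data$charged) |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::mutate(sum_u = sum(.data$uncharged)) |>
    dplyr::ungroup() |>
    dplyr::left_join(synthetases, by = "amino_acid")
  if (any(is.na(tab$E0))) {
    abort(sprintf("no synthetase for amino acid '%s'",
                  tab$amino_acid[is.na(tab$E0)][1]))
  }
  tab <- tab |>
    dplyr::mutate(
      vmax = vmax_scale * .data$d * .data$E0 * .data$kcat,
      rate = ifelse(.data$uncharged > 0,
                    .data$vmax * .data$uncharged / (.data$Km + .data$sum_u),
                    0)
    ) |>
    dplyr::select("species", "amino_acid", "uncharged", "vmax", "rate")
  if (!is.null(species)) {
    miss <- setdiff(species, tab$species)
    if (length(miss) > 0) abort(sprintf("unknown tRNA species '%s'", miss[1]))
    tab <- tab[match(species, tab$species), ]
  }
  tab
}

#' Deplete (or overexpress) one synthetase by a protein ratio d
#'
#' Rescales the named amino acid's enzyme abundance by `d`, the ratio of the
#' perturbed to the wild-type synthetase concentration; all other synthetases
#' are untouched. `d = 1` is no perturbation, `d < 1` depletion (the
#' doxycycline shut-off regime), `d > 1` overexpression (up to 2x wild type).
#'
#' @param synthetases a synthetase table.
#' @param amino_acid which enzyme to rescale, default the glutaminyl enzyme.
#' @param d protein ratio in (0, 2].
#' @return The synthetase table with the `d` column updated for the target
#'   amino acid.
#' @export
apply_dox_ratio <- function(synthetases, amino_acid = "Gln", d) {
  validate_synthetases(synthetases)
  assert_scalar_number(d, "d", upper = 2)
  if (d <= 0) abort("`d` must be positive")
  if (!amino_acid %in% synthetases$amino_acid) {
    abort(sprintf("no synthetase for amino acid '%s'", amino_acid))
  }
  synthetases$d[synthetases$amino_acid == amino_acid] <- d
  synthetases
}

#' Codon-specific hopping rate
#'
#' The TASEP hopping (translocation) rate at a codon is proportional to the
#' number of cognate charged tRNAs currently available, times the codon's
#' wobble-pairing efficiency:
#' \eqn{k(c) = \lambda \cdot w(c) \cdot T^c_{cognate(c)}}.
#'
#' @param codon sense codon symbol(s).
#' @param trna a tRNA table with current `charged` counts.
#' @param codon_map codon-to-tRNA assignment with `wobble` factors.
#' @param lambda_scale proportionality constant fixed by calibration.
#' @return Numeric vector of rates (1/s); zero when the cognate charged pool
#'   is empty. Stop codons are rejected: termination is factor-mediated.
#' @export
hopping_rate <- function(codon, trna, codon_map = default_codon_map(),
                         lambda_scale = 1) {
  validate_trna(trna)
  if (any(codon == stop_codon())) {
    abort("stop codons are terminated, not translocated; no hopping rate")
  }
  idx <- match(codon, codon_map$codon)
  if (anyNA(idx)) {
    abort(sprintf("codon '%s' is not a sense codon of the map",
                  codon[is.na(idx)][1]))
  }
  sp <- codon_map$species[idx]
  tc <- trna$charged[match(sp, trna$species)]
  if (anyNA(tc)) {
    abort(sprintf("no tRNA pool for species '%s'", sp[is.na(tc)][1]))
  }
  lambda_scale * codon_map$wobble[idx] * tc
}

#' Consume a charged tRNA / recharge an uncharged tRNA
#'
#' `consume_charged()` is the tRNA side of one elongation event: one charged
#' molecule of the species becomes uncharged (the ribosome releases it after
#' peptidyl transfer). `recharge_trna()` is the reverse aminoacylation event.
#' Species totals are invariant under both.
#'
#' @param trna a tRNA table.
#' @param species the tRNA species affected.
#' @return The updated tRNA table.
#' @export
consume_charged <- function(trna, species) {
  validate_trna(trna)
  i <- match(species, trna$species)
  if (is.na(i)) abort(sprintf("unknown tRNA species '%s'", species))
  if (trna$charged[i] < 1) {
    abort(sprintf(
      "cannot consume from empty charged pool of '%s' (event rate is 0 there)",
      species))
  }
  trna$charged[i] <- trna$charged[i] - 1L
  trna
}

#' @rdname consume_charged
#' @export
recharge_trna <- function(trna, species) {
  validate_trna(trna)
  i <- match(species, trna$species)
  if (is.na(i)) abort(sprintf("unknown tRNA species '%s'", species))
  if (trna$charged[i] >= trna$total[i]) {
    abort(sprintf("no uncharged '%s' molecules left to recharge", species))
  }
  trna$charged[i] <- trna$charged[i] + 1L
  trna
}
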