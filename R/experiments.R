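#' Map a doxycycline concentration to a synthetase protein ratio
#'
#' The tet-off depletion system anchors the mapping at two measured points:
#' no doxycycline leaves the synthetase at 100% of wild type (`d = 1`), and
#' 0.5 ug/ml reduces it to 3.5% (`d = 0.035`). Intermediate concentrations
#' are interpolated log-linearly in `d` and flagged; beyond the measured
#' range there is no anchor and the mapping refuses to extrapolate.
#'
#' @param dox_ugml doxycycline concentration(s) in ug/ml, in `[0, 0.5]`.
#' @return Numeric vector of protein ratios `d`, with attribute
#'   `interpolated` marking values strictly between the anchors.
#' @export
#' @examples
#' dox_to_d(0)    # 1
#' dox_to_d(0.5)  # 0.035
dox_to_d <- function(dox_ugml) {
  if (!is.numeric(dox_ugml) || any(!is.finite(dox_ugml))) {
    abort("`dox_ugml` must be numeric and finite")
  }
  if (any(dox_ugml < 0)) abort("doxycycline concentration cannot be negative")
  if (any(dox_ugml > 0.5)) {
    abort("no anchor beyond 0.5 ug/ml; refusing to extrapolate")
  }
  d <- exp(log(1) + (dox_ugml / 0.5) * (log(0.035) - log(1)))
  structure(d, interpolated = dox_ugml > 0 & dox_ugml < 0.5)
}

#' Synthetase-depletion dose-response sweep of the translation model
#'
#' Runs one whole-cell simulation per (protein ratio, seed) pair on a
#' calibrated fixture, with or without the growth-coupled initiation
#' feedback, and collects the global current, elongation rate, realized
#' initiation rate, and charging levels (overall, per depletion-target
#' isoacceptor, and averaged over the non-target species).
#'
#' @param fixture a calibrated `cell_fixture` (see [calibrate_cell()]).
#' @param d_grid protein ratios to sweep; default spans wild type down to
#'   the strongest measured depletion, 0.035.
#' @param feedback logical: growth-coupled initiation feedback on or off.
#' @param seeds integer seeds; one run per (d, seed).
#' @param t_end,burn_in per-run simulation window (seconds).
#' @param record_density record density profiles (needed for queue
#'   statistics; off by default for speed).
#' @return A tibble of class `gtm_sweep`, one row per run, sorted by `d`.
#'   Columns include `J`, `elongation_rate`, `Q_mean`, `alpha_mean`,
#'   `Q_target_<species>` per target isoacceptor and `Q_other`. When
#'   `record_density` is TRUE the per-run `gtm_sim` objects are attached as
#'   attribute `sims`.
#' @export
run_dose_sweep <- function(fixture, d_grid = c(1, 0.5, 0.2, 0.1, 0.05, 0.035),
                           feedback = FALSE, seeds = 1:3,
                           t_end = 150, burn_in = 0.2 * t_end,
                           record_density = FALSE) {
  if (is.null(fixture$calibration)) {
    abort("fixture is not calibrated; run calibrate_cell() first")
  }
  if (any(d_grid <= 0)) abort("`d_grid` must be positive")
  d_grid <- sort(d_grid)
  target_aa <- fixture$params$dox_target
  target_sp <- fixture$trna$species[fixture$trna$amino_acid == target_aa]
  grid <- tidyr::expand_grid(d = d_grid, seed = as.integer(seeds))
  sims <- vector("list", nrow(grid))
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    p <- fixture$params
    p$d <- grid$d[i]
    p$feedback <- isTRUE(feedback)
    sim <- simulate_gtm(fixture$transcriptome, fixture$trna,
                        fixture$synthetases, p, fixture$codon_map,
                        t_end = t_end, burn_in = burn_in,
                        seed = grid$seed[i], record_density = record_density)
    if (record_density) sims[[i]] <<- sim
    qs <- setNames(sim$per_species$Q, sim$per_species$species)
    other <- sim$per_species$amino_acid != target_aa
    dplyr::bind_cols(
      tibble(d = grid$d[i], seed = grid$seed[i], feedback = isTRUE(feedback),
             J = sim$J, J_se = sim$J_se,
             elongation_rate = sim$elongation_rate,
             Q_mean = sim$Q_mean, alpha_mean = sim$alpha_mean,
             Q_other = mean(sim$per_species$Q[other])),
      as_tibble(as.list(setNames(qs[target_sp],
                                 paste0("Q_target_", target_sp))))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- structure(out, class = c("gtm_sweep", class(out)),
                   target_species = target_sp, target_aa = target_aa)
  if (record_density) attr(out, "sims") <- sims
  out
}

#' Summarise a dose sweep across seeds
#'
#' @param sweep a `gtm_sweep` tibble.
#' @return A tibble with mean and standard error of each metric per `d`.
#' @export
summarize_sweep <- function(sweep) {
  num <- setdiff(names(sweep)[vapply(sweep, is.numeric, TRUE)], c("d", "seed"))
  sweep |>
    tidyr::pivot_longer(dplyr::all_of(num), names_to = "metric") |>
    dplyr::group_by(.data$d, .data$feedback, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    )
}

#' @export
autoplot.gtm_sweep <- function(object, ...) {
  target <- attr(object, "target_species")
  keep <- c("J", "Q_other", paste0("Q_target_", target))
  df <- summarize_sweep(object) |>
    dplyr::filter(.data$metric %in% keep)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$mean,
                                   colour = .data$feedback,
                                   group = .data$feedback)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "synthetase protein ratio d", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dose-response sweep of the sequestration model
#'
#' @param params an [ssm_params()] object.
#' @param d_grid protein ratios to sweep.
#' @param seeds integer seeds; one SSA run per (d, seed).
#' @param t_end,burn_in per-run window (seconds).
#' @return A tibble of class `ssm_sweep`: per-species occupancy fractions
#'   for every run.
#' @export
run_ssm_sweep <- function(params, d_grid = c(1, 0.5, 0.2, 0.1, 0.05, 0.035),
                          seeds = 1:3, t_end = 60, burn_in = 0.2 * t_end) {
  if (any(d_grid <= 0)) abort("`d_grid` must be positive")
  grid <- tidyr::expand_grid(d = sort(d_grid), seed = as.integer(seeds))
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sim <- simulate_ssm(params, d = grid$d[i], t_end = t_end,
                        burn_in = burn_in, seed = grid$seed[i])
    dplyr::mutate(as_tibble(sim), seed = grid$seed[i])
  })
  structure(out, class = c("ssm_sweep", class(out)),
            dox_target = params$dox_target)
}

#' @export
autoplot.ssm_sweep <- function(object, ...) {
  tgt <- attr(object, "dox_target")
  df <- as_tibble(object) |>
    dplyr::mutate(group = ifelse(.data$species == tgt, tgt, "other")) |>
    tidyr::pivot_longer(dplyr::all_of(c("mean_e", "mean_b", "mean_c", "mean_u")),
                        names_to = "state", values_to = "fraction",
                        names_prefix = "mean_") |>
    dplyr::group_by(.data$d, .data$group, .data$state) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$fraction,
                                   colour = .data$state)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "synthetase protein ratio d", y = "occupancy fraction") +
    ggplot2::theme_minimal()
}

#' Ribosome queueing statistic around slow codons
#'
#' Ratio of the mean ribosome density over the `window` sites immediately
#' upstream of the given codon positions to the mean density over the
#' `window` sites immediately downstream. A ratio near 1 means no queue; a
#' large ratio means ribosomes pile up behind the positions (the signature
#' of depleted cognate charged tRNA).
#'
#' @param profile a density profile: tibble with columns `site` and `rho`
#'   (see [density_profile()]) or a plain numeric density vector.
#' @param positions 1-based codon positions of the slow (e.g. glutamine)
#'   codons on the same mRNA.
#' @param window number of sites on each side.
#' @return A single ratio (upstream mean / downstream mean).
#' @export
#' @examples
#' rho <- c(rep(0.8, 50), rep(0.1, 50))
#' queue_statistic(rho, positions = 50, window = 10) # 8
queue_statistic <- function(profile, positions, window = 10) {
  if (is.data.frame(profile)) {
    rho <- profile$rho[order(profile$site)]
  } else {
    rho <- as.numeric(profile)
  }
  if (length(positions) == 0 || any(is.na(positions))) {
    abort("no slow-codon positions supplied")
  }
  n <- length(rho)
  if (any(positions < 1 | positions > n)) {
    abort("positions must lie within the profile")
  }
  up <- unlist(purrr::map(positions, function(p) seq(max(1, p - window), p - 1)))
  down <- unlist(purrr::map(positions, function(p) {
    if (p >= n) integer(0) else seq(p + 1, min(n, p + window))
  }))
  up <- up[up >= 1]
  if (length(up) == 0 || length(down) == 0) {
    abort("window produces no upstream or downstream sites")
  }
  mean(rho[up]) / mean(rho[down])
}

#' Positions of the glutamine codons on a representative mRNA
#'
#' @param transcriptome a virtual transcriptome tibble.
#' @param category category id.
#' @param codon_map codon map used to identify glutamine codons.
#' @return Integer vector of 1-based codon positions.
#' @export
gln_positions <- function(transcriptome, category,
                          codon_map = attr(transcriptome, "codon_map") %||%
                            default_codon_map()) {
  i <- match(category, transcriptome$category_id)
  if (is.na(i)) abort(sprintf("unknown category '%s'", category))
  which(head(transcriptome$codons[[i]], -1) %in% gln_codons(codon_map))
}

#' Rank concordance of per-category protein production
#'
#' Spearman rank correlation between a reference per-category current vector
#' (typically the unperturbed cell) and a test condition's. A concordance
#' near 1 means the proportion of the different protein types in the cell is
#' maintained under the perturbation.
#'
#' @param J_a_reference,J_a_test numeric per-category currents, same length
#'   and category order.
#' @return Spearman's rank correlation in `[-1, 1]`.
#' @export
#' @examples
#' category_ranking_concordance(c(3, 2, 1), c(30, 20, 10)) # 1
category_ranking_concordance <- function(J_a_reference, J_a_test) {
  if (length(J_a_reference) != length(J_a_test)) {
    abort("reference and test vectors must cover the same categories")
  }
  if (length(J_a_reference) < 2) abort("need at least two categories")
  cor(J_a_reference, J_a_test, method = "spearman")
}
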