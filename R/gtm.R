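#' Parameters of the global translation model
#'
#' Bundles the physical constants of the whole-cell TASEP simulation.
#'
#' @param W ribosome footprint in codons; exclusion keeps tracked positions
#'   (the codon being translated) at least `W` apart, and initiation requires
#'   sites `1..W` free.
#' @param beta termination rate (1/s) at the stop codon, identical for all
#'   mRNAs and chosen non-limiting.
#' @param gamma premature drop-off rate (1/s) per mid-lattice ribosome;
#'   drop-off returns the ribosome to the free pool without producing protein.
#' @param R_total total ribosome count of the (downscaled) cell.
#' @param R_star breakpoint of the stepwise-linear initiation function: the
#'   initiation rate of mRNA m is `alpha0_m * min(R_free / R_star, 1)`. Set
#'   self-consistently to the wild-type steady-state free-pool size during
#'   calibration.
#' @param lambda_scale proportionality constant between the cognate charged
#'   tRNA count and the hopping rate; fixed by calibration to a mean
#'   elongation rate of 10 codons/s.
#' @param vmax_scale global scale on all synthetase `V_max`; fixed by
#'   calibration to a mean charging level of 80%.
#' @param alpha_scale global scale on all initiation rate constants; fixed by
#'   calibration to a realized mean initiation rate of 0.15/s.
#' @param d protein ratio of the depletion-target synthetase (perturbed /
#'   wild type); applied to `dox_target` at run time. `d = 1` is wild type.
#' @param feedback logical; when TRUE the growth-coupled negative feedback
#'   rescales every initiation rate constant to `d * alpha0` (slower growth
#'   means fewer ribosomes and initiation factors, hence slower initiation).
#' @param dox_target amino acid whose synthetase `d` rescales.
#' @return A list of class `gtm_params`.
#' @export
gtm_params <- function(W = 9, beta = 10, gamma = 5e-4,
                       R_total = 200, R_star = 90,
                       lambda_scale = 0.01, vmax_scale = 1, alpha_scale = 1,
                       d = 1, feedback = FALSE, dox_target = "Gln") {
  assert_scalar_number(W, "W", lower = 1)
  assert_scalar_number(beta, "beta", lower = 0)
  assert_scalar_number(gamma, "gamma", lower = 0)
  assert_scalar_number(R_total, "R_total", lower = 1)
  assert_scalar_number(R_star, "R_star", lower = 0)
  assert_scalar_number(lambda_scale, "lambda_scale", lower = 0)
  assert_scalar_number(vmax_scale, "vmax_scale", lower = 0)
  assert_scalar_number(alpha_scale, "alpha_scale", lower = 0)
  assert_scalar_number(d, "d", lower = 1e-12, upper = 2)
  structure(
    list(W = as.integer(W), beta = beta, gamma = gamma,
         R_total = as.integer(R_total), R_star = R_star,
         lambda_scale = lambda_scale, vmax_scale = vmax_scale,
         alpha_scale = alpha_scale, d = d, feedback = isTRUE(feedback),
         dox_target = dox_target),
    class = "gtm_params"
  )
}

#' Stepwise-linear initiation rate
#'
#' The initiation rate of an mRNA rises linearly with the free ribosome pool
#' up to a breakpoint `R_star`, where it plateaus at the mRNA's initiation
#' rate constant (times `d` when the growth-coupled feedback is on). The rate
#' is zero when no ribosome is free, or when any of the first `W` lattice
#' sites is covered by a ribosome.
#'
#' @param alpha0 initiation rate constant(s) of the mRNA(s) (1/s).
#' @param R_free current free ribosome count.
#' @param params a [gtm_params()] object (uses `R_star`, `alpha_scale`, `d`,
#'   `feedback`, `W`).
#' @param occupied optional integer vector of tracked ribosome positions on
#'   the lattice; if any is `<= W`, entry is sterically blocked and the rate
#'   is 0.
#' @return Numeric rate(s), 1/s.
#' @export
#' @examples
#' p <- gtm_params(R_star = 50)
#' initiation_rate(0.2, 100, p) # plateau: 0.2
#' initiation_rate(0.2, 25, p)  # linear regime: 0.1
initiation_rate <- function(alpha0, R_free, params = gtm_params(),
                            occupied = integer(0)) {
  assert_scalar_number(R_free, "R_free", lower = 0)
  if (length(occupied) > 0 && min(occupied) <= params$W) {
    return(rep(0, length(alpha0)))
  }
  fac <- if (R_free <= 0) 0 else if (params$R_star > 0) {
    min(R_free / params$R_star, 1)
  } else 1
  base <- alpha0 * params$alpha_scale * (if (params$feedback) params$d else 1)
  base * fac
}

# Assemble the integer-coded structures the C++ engine needs.
gtm_engine_inputs <- function(transcriptome, trna, synthetases, params,
                              codon_map, init_charged = NULL) {
  if (!is.null(init_charged)) {
    if (length(init_charged) != nrow(trna)) {
      abort("`init_charged` must have one count per tRNA species")
    }
    trna$charged <- as.integer(init_charged)
  }
  validate_transcriptome(transcriptome, codon_map)
  validate_trna(trna)
  validate_synthetases(synthetases)
  if (params$dox_target %in% synthetases$amino_acid) {
    syn <- apply_dox_ratio(synthetases, params$dox_target, params$d)
  } else if (params$d != 1) {
    abort(sprintf("depletion target '%s' has no synthetase in this system",
                  params$dox_target))
  } else {
    syn <- synthetases
  }
  aa_levels <- syn$amino_acid
  sp_aa <- match(trna$amino_acid, aa_levels)
  if (anyNA(sp_aa)) {
    abort(sprintf("no synthetase for amino acid '%s'",
                  trna$amino_acid[is.na(sp_aa)][1]))
  }
  sp_index <- setNames(seq_len(nrow(trna)), trna$species)
  map_sp <- sp_index[codon_map$species]
  if (anyNA(map_sp)) {
    abort(sprintf("codon map references unknown tRNA species '%s'",
                  codon_map$species[is.na(map_sp)][1]))
  }
  codon_sp <- setNames(as.integer(map_sp) - 1L, codon_map$codon)
  codon_w <- setNames(codon_map$wobble, codon_map$codon)
  lattice_species <- purrr::map(transcriptome$codons, function(cod) {
    unname(codon_sp[head(cod, -1)])
  })
  lattice_wobble <- purrr::map(transcriptome$codons, function(cod) {
    unname(codon_w[head(cod, -1)])
  })
  vmax <- params$vmax_scale * syn$d[sp_aa] * syn$E0[sp_aa] * syn$kcat[sp_aa]
  alpha_eff <- transcriptome$alpha0 * params$alpha_scale *
    (if (params$feedback) params$d else 1)
  list(
    lattice_species = lattice_species, lattice_wobble = lattice_wobble,
    copies = as.integer(transcriptome$copy_number), alpha_eff = alpha_eff,
    Tt = as.integer(trna$total), Tc0 = as.integer(trna$charged),
    vmax = vmax, Km = syn$Km[sp_aa], aa = as.integer(sp_aa) - 1L
  )
}

#' Simulate the global translation model
#'
#' Runs the exact continuous-time stochastic simulation (kinetic Monte Carlo
#' over initiation, elongation, termination, drop-off and recharging events)
#' of all mRNA copies competing for a finite ribosome pool and for charged
#' tRNAs. Observables are time-averaged over the post-burn-in window.
#'
#' @param transcriptome virtual transcriptome tibble (see
#'   [generate_synthetic_transcriptome()]).
#' @param trna tRNA pool table (see [synthetic_trna_table()]).
#' @param synthetases synthetase table (see [synthetic_synthetase_table()]).
#' @param params a [gtm_params()] object; `params$d` is applied to the
#'   depletion-target synthetase and, when `params$feedback` is TRUE, to the
#'   initiation rate constants.
#' @param codon_map codon-to-tRNA assignment.
#' @param t_end simulated seconds.
#' @param burn_in seconds discarded before time-averaging (default the first
#'   20% of `t_end`).
#' @param seed optional integer seed for exact reproducibility.
#' @param record_density record per-site time-averaged ribosome density
#'   profiles (tracked positions).
#' @param n_batch batches for Monte-Carlo standard errors (batch means).
#' @param max_events event-count guard; the run is truncated with a warning
#'   if exceeded.
#' @param init_charged optional integer vector of initial charged counts per
#'   tRNA species (in the order of `trna`), overriding `trna$charged`; used
#'   to warm-start runs from a previous steady state.
#' @return An object of class `gtm_sim`; see [glance.gtm_sim()],
#'   [tidy.gtm_sim()], [density_profile()] and [autoplot.gtm_sim()].
#' @export
simulate_gtm <- function(transcriptome, trna, synthetases,
                         params = gtm_params(),
                         codon_map = attr(transcriptome, "codon_map") %||%
                           default_codon_map(),
                         t_end = 150, burn_in = 0.2 * t_end, seed = NULL,
                         record_density = TRUE, n_batch = 10,
                         max_events = 5e7, init_charged = NULL) {
  if (t_end <= burn_in) abort("`t_end` must exceed `burn_in`")
  inp <- gtm_engine_inputs(transcriptome, trna, synthetases, params, codon_map,
                           init_charged)
  raw <- with_local_seed(seed, gtm_engine_cpp(
    inp$lattice_species, inp$lattice_wobble, inp$copies, inp$alpha_eff,
    params$R_total, params$R_star, params$W, params$beta, params$gamma,
    params$lambda_scale, inp$Tt, inp$Tc0, inp$vmax, inp$Km, inp$aa,
    t_end, burn_in, as.integer(n_batch), isTRUE(record_density), max_events
  ))
  if (isTRUE(raw$truncated)) {
    warn(sprintf("simulation truncated after %g events (max_events)",
                 raw$events))
  }
  t_rec <- raw$t_record
  n_cat <- nrow(transcriptome)
  total_copies <- sum(transcriptome$copy_number)
  sense_sites <- sum(transcriptome$copy_number * transcriptome$length)

  hops_b <- raw$hops_batch
  nb_b <- raw$nbound_batch
  term_b <- raw$term_batch
  bl <- raw$batch_len
  el_b <- ifelse(nb_b > 0, hops_b / nb_b, NA_real_)
  j_b <- term_b / bl
  se <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }

  per_category <- tibble(
    category_id = transcriptome$category_id,
    copy_number = transcriptome$copy_number,
    length = transcriptome$length,
    terminations = as.numeric(raw$term_cat),
    J_a = if (t_rec > 0) {
      raw$term_cat / (t_rec * transcriptome$copy_number)
    } else NA_real_
  )
  per_species <- tibble(
    species = trna$species, amino_acid = trna$amino_acid,
    total = trna$total, Q = as.numeric(raw$Qi),
    charged_final = as.integer(raw$Tc)
  )
  density <- NULL
  if (record_density && !is.null(raw$density)) {
    density <- purrr::map2_dfr(
      seq_len(n_cat), raw$density,
      function(i, rho) tibble(
        category_id = transcriptome$category_id[i],
        site = seq_along(rho), rho = as.numeric(rho)
      )
    )
  }

  out <- list(
    J = if (t_rec > 0) raw$terms / t_rec else NA_real_,
    J_se = se(j_b),
    site_flux = if (t_rec > 0 && sense_sites > 0) {
      raw$hops / (t_rec * sense_sites)
    } else NA_real_,
    elongation_rate = if (raw$int_nbound > 0) raw$hops / raw$int_nbound
                      else NA_real_,
    elongation_se = se(el_b),
    Q_mean = if (t_rec > 0) raw$int_Q / t_rec else NA_real_,
    alpha_mean = if (t_rec > 0) raw$int_alpha / t_rec else NA_real_,
    R_free_mean = if (t_rec > 0) raw$int_Rfree / t_rec else NA_real_,
    n_bound_mean = if (t_rec > 0) raw$int_nbound / t_rec else NA_real_,
    per_category = per_category, per_species = per_species, density = density,
    counts = tibble(inits = raw$inits, hops = raw$hops, terms = raw$terms,
                    drops = raw$drops, rechs = raw$rechs,
                    events = raw$events),
    final_state = list(R_free = raw$R_free, n_bound = raw$n_bound,
                       Tc = as.integer(raw$Tc),
                       positions = raw$final_positions,
                       category = as.integer(raw$final_category)),
    params = params, t_end = t_end, burn_in = burn_in, t_record = t_rec,
    seed = seed, total_copies = total_copies,
    truncated = isTRUE(raw$truncated)
  )
  class(out) <- "gtm_sim"
  out
}

#' @export
print.gtm_sim <- function(x, ...) {
  cat("<gtm_sim> whole-cell translation simulation\n")
  cat(sprintf("  t_end %.4g s (burn-in %.4g s), %s events, d = %.4g, feedback %s\n",
              x$t_end, x$burn_in, format(x$counts$events, big.mark = ","),
              x$params$d, if (x$params$feedback) "on" else "off"))
  cat(sprintf("  J = %.4g proteins/s   elongation = %.4g codons/s\n",
              x$J, x$elongation_rate))
  cat(sprintf("  <Q> = %.4g   <alpha> = %.4g /s   <R_free> = %.4g\n",
              x$Q_mean, x$alpha_mean, x$R_free_mean))
  invisible(x)
}

#' One-row summary of a translation simulation
#'
#' @param x a `gtm_sim` object.
#' @param ... unused.
#' @return A one-row tibble with the global current `J` (proteins/s) and its
#'   standard error, the site-averaged ribosomal flux per sense codon, the
#'   mean elongation rate (codons/s), the species-averaged charging level
#'   `Q_mean`, the realized mean initiation rate `alpha_mean` (1/s), mean
#'   free-ribosome and bound-ribosome counts, and run metadata.
#' @export
glance.gtm_sim <- function(x, ...) {
  tibble(
    J = x$J, J_se = x$J_se, site_flux = x$site_flux,
    elongation_rate = x$elongation_rate, elongation_se = x$elongation_se,
    Q_mean = x$Q_mean, alpha_mean = x$alpha_mean,
    R_free_mean = x$R_free_mean, n_bound_mean = x$n_bound_mean,
    d = x$params$d, feedback = x$params$feedback,
    t_end = x$t_end, burn_in = x$burn_in, events = x$counts$events
  )
}

#' Per-category observables of a translation simulation
#'
#' @param x a `gtm_sim` object.
#' @param ... unused.
#' @return A tibble with one row per mRNA category: copy number, length,
#'   termination events and the mean per-copy current `J_a` (proteins/s).
#' @export
tidy.gtm_sim <- function(x, ...) x$per_category

#' Ribosome density profile of one mRNA category
#'
#' Time-averaged occupancy of each lattice site by tracked ribosome positions,
#' averaged over the category's mRNA copies.
#'
#' @param sim a `gtm_sim` object run with `record_density = TRUE`.
#' @param category category id (default: first category).
#' @return A tibble with columns `category_id`, `site`, `rho` in `[0, 1]`.
#' @export
density_profile <- function(sim, category = NULL) {
  if (is.null(sim$density) || sim$t_record <= 0) {
    abort("no post-burn-in density samples: rerun with record_density = TRUE")
  }
  category <- category %||% sim$density$category_id[1]
  out <- dplyr::filter(sim$density, .data$category_id == category)
  if (nrow(out) == 0) abort(sprintf("unknown category '%s'", category))
  out
}

#' Density-profile plot of a simulation
#'
#' @param object a `gtm_sim` object.
#' @param categories optional subset of category ids.
#' @param ... unused.
#' @return A ggplot: per-site ribosome density along each mRNA.
#' @export
autoplot.gtm_sim <- function(object, categories = NULL, ...) {
  if (is.null(object$density)) abort("simulation was run without density recording")
  df <- object$density
  if (!is.null(categories)) {
    df <- dplyr::filter(df, .data$category_id %in% categories)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$rho)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~category_id, scales = "free_x") +
    ggplot2::labs(x = "codon position", y = "ribosome density ρ") +
    ggplot2::theme_minimal()
}

#' Calibrate the global translation model to physiological targets
#'
#' Iterative alternating (damped fixed-point) adjustment of three global
#' scale factors at wild type (`d = 1`): `lambda_scale` is tuned until the
#' mean elongation rate matches 10 codons/s, `vmax_scale` until the mean tRNA
#' charging level matches 80%, and `alpha_scale` until the realized mean
#' initiation rate matches 0.15/s. The initiation breakpoint `R_star` is
#' simultaneously relaxed towards the steady-state free-pool size, making the
#' stepwise-linear initiation function self-consistent.
#'
#' @inheritParams simulate_gtm
#' @param targets named numeric: `elongation` (codons/s), `charging`
#'   (fraction), `initiation` (1/s).
#' @param tol relative tolerance on each target; either one number for all
#'   three or a named vector per metric.
#' @param max_iter maximum fixed-point iterations.
#' @param t_end,burn_in length of each calibration run (seconds).
#' @param seed integer; iteration seeds are derived deterministically.
#' @param damping exponent in (0, 1] of the multiplicative updates.
#' @return An object of class `gtm_calibration` holding the calibrated
#'   `params`, the achieved values, and the iteration history; errors with
#'   diagnostics when not converged within `max_iter`.
#' @export
calibrate_gtm <- function(transcriptome, trna, synthetases,
                          params = gtm_params(),
                          codon_map = attr(transcriptome, "codon_map") %||%
                            default_codon_map(),
                          targets = c(elongation = 10, charging = 0.8,
                                      initiation = 0.15),
                          tol = 0.05, max_iter = 40,
                          t_end = 60, burn_in = 20,
                          seed = 1, damping = 0.8) {
  if (params$d != 1) abort("calibration must be run at wild type (d = 1)")
  tg <- as.list(targets)
  if (length(tol) == 1L) tol <- setNames(rep(tol, 3), names(targets))
  tol <- tol[names(targets)]
  if (anyNA(tol)) abort("`tol` must be one number or named per target metric")
  hist <- list()
  converged <- FALSE
  # typical per-amino-acid pool size and Michaelis constant, used to invert
  # the saturating recharging law when stepping vmax_scale
  t_aa <- mean(tapply(trna$total, trna$amino_acid, sum))
  km_bar <- mean(synthetases$Km)
  charged <- NULL  # warm-start each iteration from the previous pool state
  cur_t_end <- t_end
  for (it in seq_len(max_iter)) {
    sim <- simulate_gtm(transcriptome, trna, synthetases, params, codon_map,
                        t_end = cur_t_end, burn_in = burn_in,
                        seed = seed + it, record_density = FALSE,
                        init_charged = charged)
    charged <- sim$final_state$Tc
    meas <- c(elongation = sim$elongation_rate, charging = sim$Q_mean,
              initiation = sim$alpha_mean)
    rel <- abs(meas - unlist(tg)) / unlist(tg)
    verified <- FALSE
    if (all(is.finite(rel)) && all(rel <= tol)) {
      # guard against transient agreement: confirm on a longer window before
      # accepting, and if the long run disagrees, update from it instead
      vsim <- simulate_gtm(transcriptome, trna, synthetases, params,
                           codon_map, t_end = 3 * t_end, burn_in = burn_in,
                           seed = seed + 1000 + it, record_density = FALSE,
                           init_charged = charged)
      charged <- vsim$final_state$Tc
      meas <- c(elongation = vsim$elongation_rate, charging = vsim$Q_mean,
                initiation = vsim$alpha_mean)
      rel <- abs(meas - unlist(tg)) / unlist(tg)
      sim <- vsim
      verified <- TRUE
      # from here on measure on long windows only: the short-window bias
      # (pool still drifting) is what the verification just exposed
      cur_t_end <- max(cur_t_end, 3 * t_end)
    }
    hist[[it]] <- tibble(iter = it, metric = names(meas),
                         value = as.numeric(meas),
                         target = as.numeric(unlist(tg)),
                         rel_err = as.numeric(rel),
                         verified = verified,
                         lambda_scale = params$lambda_scale,
                         vmax_scale = params$vmax_scale,
                         alpha_scale = params$alpha_scale,
                         R_star = params$R_star)
    if (verified && all(is.finite(rel)) && all(rel <= tol)) {
      converged <- TRUE
      break
    }
    if (!all(is.finite(meas)) || any(meas <= 0)) {
      abort("calibration run produced degenerate observables; check the fixture")
    }
    # The elongation and charging controls are coupled: the vmax update moves
    # the charging level from q to its target, which rescales every charged
    # pool (hence every hopping rate) by target/q. Fold that anticipated
    # shift into the lambda update so the two do not fight each other.
    fac_el <- (tg$elongation / meas[["elongation"]]) *
      (meas[["charging"]] / tg$charging)
    params$lambda_scale <- params$lambda_scale * fac_el^damping
    # invert the Michaelis-Menten law: at steady state usage = vmax * s(Tu)
    # with s(Tu) = Tu/(Km + Tu); moving Tu from its measured to its target
    # value at constant usage requires vmax' = vmax * s(Tu)/s(Tu*). The
    # naive (1-Q) ratio ignores saturation and overshoots badly when Tu >> Km.
    s_of <- function(q) {
      tu <- (1 - q) * t_aa
      tu / (km_bar + tu)
    }
    fac_vm <- s_of(meas[["charging"]]) / s_of(tg$charging)
    params$vmax_scale <- params$vmax_scale * fac_vm^damping
    params$alpha_scale <- params$alpha_scale *
      (tg$initiation / meas[["initiation"]])^damping
    params$R_star <- 0.5 * params$R_star + 0.5 * sim$R_free_mean
    # near the fixed point, lengthen the measurement window to beat noise
    if (all(rel < 3 * tol)) cur_t_end <- min(2 * t_end, 4 * t_end)
  }
  history <- dplyr::bind_rows(hist)
  if (!converged) {
    last <- dplyr::filter(history, .data$iter == max(.data$iter))
    abort(paste0(
      "calibration did not converge in ", max_iter, " iterations; last: ",
      paste(sprintf("%s = %.4g (target %.4g)", last$metric, last$value,
                    last$target), collapse = ", ")
    ))
  }
  achieved <- dplyr::filter(history, .data$iter == max(.data$iter))
  structure(
    list(params = params, achieved = achieved, history = history,
         iterations = max(history$iter), converged = converged,
         targets = targets, tol = tol, charged_state = charged),
    class = "gtm_calibration"
  )
}

#' @export
print.gtm_calibration <- function(x, ...) {
  cat(sprintf("<gtm_calibration> converged in %d iteration(s)\n", x$iterations))
  for (i in seq_len(nrow(x$achieved))) {
    cat(sprintf("  %-11s %.4g (target %.4g, rel err %.2g%%)\n",
                x$achieved$metric[i], x$achieved$value[i],
                x$achieved$target[i], 100 * x$achieved$rel_err[i]))
  }
  cat(sprintf("  lambda_scale %.5g  vmax_scale %.5g  alpha_scale %.5g  R* %.4g\n",
              x$params$lambda_scale, x$params$vmax_scale,
              x$params$alpha_scale, x$params$R_star))
  invisible(x)
}

#' @export
glance.gtm_calibration <- function(x, ...) {
  tibble(
    converged = x$converged, iterations = x$iterations,
    lambda_scale = x$params$lambda_scale, vmax_scale = x$params$vmax_scale,
    alpha_scale = x$params$alpha_scale, R_star = x$params$R_star
  )
}

#' @export
tidy.gtm_calibration <- function(x, ...) x$achieved
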