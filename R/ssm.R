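#' Growth-coupled usage feedback factor
#'
#' The charged-tRNA usage rate of the sequestration model is scaled by a
#' coupling factor `f` reflecting the growth slow-down under synthetase
#' depletion: growth (and hence translation and tRNA usage) is unaffected
#' until the synthetase ratio `d` falls below 0.2, after which it decreases
#' proportionally. The stepwise-linear form is `f = 5 d` for `d < 0.2` and
#' `f = 1` otherwise (continuous at `d = 0.2`).
#'
#' @param d synthetase protein ratio(s) in (0, 2].
#' @return Numeric vector of coupling factors in (0, 1].
#' @export
#' @examples
#' feedback_factor(c(0.1, 0.2, 1)) # 0.5, 1, 1
feedback_factor <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d))) abort("`d` must be numeric")
  if (any(d <= 0)) abort("`d` must be positive")
  if (any(d > 2)) abort("`d` must be at most 2")
  ifelse(d < 0.2, 5 * d, 1)
}

#' Calibrated parameters of the synthetase sequestration model
#'
#' One three-state cycle (empty -> bound -> charged -> empty) per tRNA
#' species, by default one species per amino acid for all 20 amino acids.
#' Rate constants are calibrated in closed form so that at wild type
#' (`d = 1`) every species sits at the physiological configuration: a
#' `charged_fraction` of the pool charged, with a fraction `bound_share` of
#' the uncharged molecules sequestered on the synthetase. The default places
#' 80% of each pool in the charged state and 96% of the uncharged remainder
#' on the enzyme, so the unperturbed stochastic cell keeps comfortably more
#' than 95% of its uncharged tRNA sequestered (invisible to the starvation
#' kinase), with essentially none "empty".
#'
#' Given the usage rate constant `k3` and the dissociation/charging ratio
#' `k0_ratio`, the cycle flux at the target fixed point determines
#' `k2 = k3 c* / b*` and `k1 = (k0 + k2) b* / ((E0 - b*) e*)`, which
#' requires `E0 > b*`.
#'
#' @param species species names; default the 20 amino acids.
#' @param totals total tRNA count per species (recycled).
#' @param E0 wild-type synthetase count per species (recycled).
#' @param k3 usage rate constant (1/s per charged molecule).
#' @param k0_ratio dissociation rate constant as a fraction of `k2`.
#' @param charged_fraction wild-type charged fraction target.
#' @param bound_share wild-type bound share of the uncharged pool.
#' @param dox_target species whose synthetase the ratio `d` depletes.
#' @return An object of class `ssm_params`: a list with the per-species rate
#'   table (`species`, `total`, `E0`, `k1`, `k0`, `k2`), the shared `k3`,
#'   and the calibration targets.
#' @export
#' @examples
#' p <- ssm_params()
#' p$table[p$table$species == "Gln", ]
ssm_params <- function(species = amino_acids_20(), totals = 10000,
                       E0 = 10000, k3 = 0.1, k0_ratio = 0.1,
                       charged_fraction = 0.8, bound_share = 0.96,
                       dox_target = "Gln") {
  n <- length(species)
  if (anyDuplicated(species)) abort("species names must be unique")
  totals <- rep_len(totals, n)
  E0 <- rep_len(E0, n)
  assert_scalar_number(k3, "k3", lower = 0)
  assert_scalar_number(charged_fraction, "charged_fraction", lower = 0, upper = 1)
  assert_scalar_number(bound_share, "bound_share", lower = 0, upper = 1)
  if (!dox_target %in% species) {
    abort(sprintf("dox_target '%s' is not among the species", dox_target))
  }
  c1 <- charged_fraction * totals
  u1 <- totals - c1
  b1 <- bound_share * u1
  e1 <- u1 - b1
  if (any(E0 <= b1)) {
    abort("E0 must exceed the target bound count b* for the fixed point to exist")
  }
  k2 <- k3 * c1 / b1
  k0 <- k0_ratio * k2
  k1 <- (k0 + k2) * b1 / ((E0 - b1) * e1)
  structure(
    list(
      table = tibble(species = species, total = as.integer(round_half_up(totals)),
                     E0 = E0, k1 = k1, k0 = k0, k2 = k2),
      k3 = k3, dox_target = dox_target,
      charged_fraction = charged_fraction, bound_share = bound_share
    ),
    class = "ssm_params"
  )
}

#' The 20 proteinogenic amino acids
#' @return Character vector of three-letter codes.
#' @export
amino_acids_20 <- function() {
  c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
    "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
}

#' @export
print.ssm_params <- function(x, ...) {
  cat(sprintf("<ssm_params> %d species, k3 = %.4g, depletion target '%s'\n",
              nrow(x$table), x$k3, x$dox_target))
  cat(sprintf("  wild-type fixed point: %.0f%% charged, %.0f%% of uncharged bound\n",
              100 * x$charged_fraction, 100 * x$bound_share))
  invisible(x)
}

# effective synthetase count per species under depletion ratio d
ssm_etilde <- function(params, d) {
  et <- params$table$E0
  et[params$table$species == params$dox_target] <-
    et[params$table$species == params$dox_target] * d
  et
}

#' Reaction propensities of the sequestration model
#'
#' Mass-action rates of the four transitions of each species' cycle:
#' association `k1 (Etilde - b) e`, dissociation `k0 b`, aminoacyl transfer
#' `k2 b`, and usage `f k3 c` with the growth coupling factor
#' `f = feedback_factor(d)`. Depletion rescales the synthetase count of the
#' target species only (`Etilde = d E0`); `f` applies to the usage of every
#' species, since slowed growth slows all translation.
#'
#' @param state a tibble with columns `species`, `e`, `b`, `c`.
#' @param params an [ssm_params()] object.
#' @param d synthetase protein ratio.
#' @return A tibble with columns `species`, `assoc`, `dissoc`, `charge`,
#'   `usage` (1/s).
#' @export
ssm_propensities <- function(state, params, d = 1) {
  assert_scalar_number(d, "d", lower = 1e-12, upper = 2)
  idx <- match(params$table$species, state$species)
  if (anyNA(idx)) abort("state lacks some species of the parameter table")
  st <- state[idx, ]
  if (any(st$e < 0 | st$b < 0 | st$c < 0)) abort("state counts must be nonnegative")
  et <- ssm_etilde(params, d)
  if (any(st$b > et + 1e-9)) {
    abort("bound count exceeds synthetase abundance (b > Etilde)")
  }
  f <- feedback_factor(d)
  tibble(
    species = params$table$species,
    assoc = params$table$k1 * (et - st$b) * st$e,
    dissoc = params$table$k0 * st$b,
    charge = params$table$k2 * st$b,
    usage = f * params$k3 * st$c
  )
}

#' Deterministic fixed point of the sequestration model
#'
#' Solves the stationary mass-action rate equations of each species' cycle
#' under the conservation constraint `e + b + c = total`. Stationarity gives
#' `b = f k3 c / k2` (flux through the charging step equals usage) and
#' `e = (k0 + k2) b / (k1 (Etilde - b))` (association balances exit from the
#' bound state), leaving one monotone scalar equation for `c` with a unique
#' positive root, found by bisection.
#'
#' @param params an [ssm_params()] object.
#' @param d synthetase protein ratio.
#' @return A tibble with columns `species`, `e`, `b`, `c`, `total` and the
#'   corresponding fractions `frac_e`, `frac_b`, `frac_c`, `frac_u`.
#' @export
ssm_steady_state <- function(params, d = 1) {
  assert_scalar_number(d, "d", lower = 1e-12, upper = 2)
  f <- feedback_factor(d)
  et <- ssm_etilde(params, d)
  tab <- params$table
  out <- purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    T_i <- tab$total[i]
    k1 <- tab$k1[i]; k0 <- tab$k0[i]; k2 <- tab$k2[i]
    usage_coef <- f * params$k3
    if (usage_coef <= 0 || T_i == 0) {
      return(tibble(species = tab$species[i], e = 0, b = 0, c = as.numeric(T_i)))
    }
    if (k2 <= 0 || k1 <= 0) abort("k1 and k2 must be positive for a charging cycle")
    b_of <- function(c) usage_coef * c / k2
    e_of <- function(b) (k0 + k2) * b / (k1 * pmax(et[i] - b, .Machine$double.eps))
    c_sat <- k2 * et[i] / usage_coef
    upper <- min(T_i, c_sat * (1 - 1e-12))
    fn <- function(c) {
      b <- b_of(c)
      e_of(b) + b + c - T_i
    }
    if (fn(upper) < 0) {
      abort("no positive stationary point found (flux exceeds enzyme capacity)")
    }
    root <- uniroot(fn, lower = 0, upper = upper, tol = 1e-10)$root
    b <- b_of(root)
    tibble(species = tab$species[i], e = e_of(b), b = b, c = root)
  })
  out$total <- tab$total
  out |>
    dplyr::mutate(
      frac_e = .data$e / .data$total, frac_b = .data$b / .data$total,
      frac_c = .data$c / .data$total,
      frac_u = (.data$e + .data$b) / .data$total
    )
}

#' Simulate the sequestration model by exact SSA
#'
#' Gillespie (direct-method) simulation of every species' three-state cycle;
#' occupancies are time-averaged (propensity-weighted residence times, exact
#' for the SSA) over the post-burn-in window.
#'
#' @param params an [ssm_params()] object.
#' @param d synthetase protein ratio.
#' @param t_end simulated seconds.
#' @param burn_in seconds discarded (default the first 20% of `t_end`).
#' @param seed optional integer for reproducibility.
#' @param init optional initial state tibble (`species`, `e`, `b`, `c`);
#'   default the deterministic fixed point rounded to integers.
#' @param n_batch batches for standard errors.
#' @param max_events event guard.
#' @return An object of class `ssm_sim`: a tibble with per-species mean
#'   occupancy fractions `mean_e`, `mean_b`, `mean_c`, `mean_u` (uncharged,
#'   `= mean_e + mean_b`), standard errors `se_c`, `se_u`, and final counts.
#' @export
simulate_ssm <- function(params, d = 1, t_end = 60, burn_in = 0.2 * t_end,
                         seed = NULL, init = NULL, n_batch = 10,
                         max_events = 5e7) {
  assert_scalar_number(d, "d", lower = 1e-12, upper = 2)
  if (t_end <= burn_in) abort("`t_end` must exceed `burn_in`")
  tab <- params$table
  if (is.null(init)) {
    ss <- ssm_steady_state(params, d)
    init <- tibble(
      species = ss$species,
      e = round_half_up(ss$e), b = round_half_up(ss$b), c = round_half_up(ss$c)
    )
    # rounding must respect conservation exactly
    init$c <- tab$total - init$e - init$b
  }
  idx <- match(tab$species, init$species)
  if (anyNA(idx)) abort("init lacks some species of the parameter table")
  init <- init[idx, ]
  f <- feedback_factor(d)
  raw <- with_local_seed(seed, ssm_engine_cpp(
    as.integer(init$e), as.integer(init$b), as.integer(init$c),
    ssm_etilde(params, d), tab$k1, tab$k0, tab$k2, params$k3, f,
    t_end, burn_in, as.integer(n_batch), max_events
  ))
  if (isTRUE(raw$truncated)) {
    warn(sprintf("SSM simulation truncated after %g events", raw$events))
  }
  bl <- raw$batch_len
  se_row <- function(m, tot) {
    apply(m, 1, function(x) stats::sd(x / bl) / sqrt(length(x))) / tot
  }
  out <- tibble(
    species = tab$species, total = tab$total, d = d,
    mean_e = raw$mean_e / tab$total,
    mean_b = raw$mean_b / tab$total,
    mean_c = raw$mean_c / tab$total,
    mean_u = (raw$mean_e + raw$mean_b) / tab$total,
    se_c = se_row(raw$int_c_batch, tab$total),
    se_u = se_row(raw$int_u_batch, tab$total),
    final_e = as.integer(raw$final_e),
    final_b = as.integer(raw$final_b),
    final_c = as.integer(raw$final_c)
  )
  structure(out,
    class = c("ssm_sim", class(out)),
    events = raw$events, t_record = raw$t_record, seed = seed,
    dox_target = params$dox_target
  )
}

#' @export
glance.ssm_sim <- function(x, ...) {
  tgt <- attr(x, "dox_target")
  g <- x[x$species == tgt, ]
  tibble(
    d = g$d, target = tgt,
    target_charged = g$mean_c, target_uncharged = g$mean_u,
    target_bound = g$mean_b, target_empty = g$mean_e,
    bound_share_of_uncharged = g$mean_b / g$mean_u,
    other_charged = mean(x$mean_c[x$species != tgt]),
    events = attr(x, "events")
  )
}

#' @export
tidy.ssm_sim <- function(x, ...) {
  tidyr::pivot_longer(
    as_tibble(x)[, c("species", "d", "mean_e", "mean_b", "mean_c", "mean_u")],
    dplyr::all_of(c("mean_e", "mean_b", "mean_c", "mean_u")),
    names_to = "state", values_to = "fraction", names_prefix = "mean_"
  )
}
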