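#' Build the codon composition of a gene-ontology category
#'
#' Sums per-gene codon counts over all genes carrying the category, scaling
#' each gene's counts by its mRNA abundance and by its membership weight for
#' the category, so that genes assigned to more than one category contribute
#' proportionally to each.
#'
#' @param genes a gene table: a data frame with columns `gene_id`, `abundance`,
#'   `categories` (a string `"cat:weight;cat:weight"`, weights summing to 1)
#'   and one numeric column per codon holding that gene's codon counts.
#' @param category_id the category to compose.
#' @return A tibble with columns `codon` and `weight` (abundance- and
#'   membership-weighted summed codon counts), one row per codon with
#'   positive weight in the gene table.
#' @export
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = c("g1", "g2"), abundance = c(2, 1),
#'   categories = c("ribosome:1", "ribosome:1"),
#'   AAA = c(1, 0), CAA = c(0, 3)
#' )
#' build_category_composition(genes, "ribosome")
build_category_composition <- function(genes, category_id) {
  genes <- as_tibble(genes)
  req <- c("gene_id", "abundance", "categories")
  missing <- setdiff(req, names(genes))
  if (length(missing) > 0) {
    abort(paste0("gene table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  codon_cols <- setdiff(names(genes), req)
  if (length(codon_cols) == 0) abort("gene table has no codon-count columns")
  counts <- as.matrix(genes[, codon_cols, drop = FALSE])
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("codon counts must be finite and nonnegative")
  }
  w_cat <- purrr::map_dbl(genes$categories, function(s) {
    ws <- parse_category_weights(s)
    ws[[category_id]] %||% 0
  })
  if (all(w_cat == 0)) {
    abort(sprintf("unknown category '%s': no gene carries it", category_id))
  }
  scale <- w_cat * genes$abundance
  if (all(scale == 0)) {
    abort(sprintf("all genes in category '%s' have zero abundance", category_id))
  }
  weight <- as.numeric(crossprod(counts, scale))
  tibble(codon = codon_cols, weight = weight)
}

# "cat1:0.6;cat2:0.4" -> c(cat1 = 0.6, cat2 = 0.4); validates the weights
parse_category_weights <- function(s) {
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) abort("empty category assignment string")
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) abort(sprintf("malformed category token '%s'", parts[bad][1]))
  ws <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2)))
  nm <- vapply(kv, `[`, "", 1)
  if (any(is.na(ws)) || any(ws < 0) || any(ws > 1)) {
    abort("category weights must be numbers in [0, 1]")
  }
  if (abs(sum(ws) - 1) > 1e-9) {
    abort(sprintf("category weights must sum to 1 (got %.12g)", sum(ws)))
  }
  as.list(setNames(ws, nm))
}

#' Abundance-weighted mean initiation rate constant
#'
#' Each representative mRNA carries the mean of the initiation rate constants
#' of its member genes, weighted by their mRNA abundance.
#'
#' @param per_gene_alpha numeric vector of per-gene initiation rate constants
#'   (1/s).
#' @param abundances numeric vector of mRNA abundances, same length.
#' @return The abundance-weighted mean, a single number.
#' @export
#' @examples
#' weighted_alpha0(c(1, 3), c(3, 1)) # 1.5
weighted_alpha0 <- function(per_gene_alpha, abundances) {
  if (length(per_gene_alpha) != length(abundances)) {
    abort("`per_gene_alpha` and `abundances` must have the same length")
  }
  if (length(abundances) == 0 || all(abundances == 0)) {
    abort("`abundances` must contain at least one positive value")
  }
  if (any(abundances < 0)) abort("`abundances` must be nonnegative")
  sum(per_gene_alpha * abundances) / sum(abundances)
}

# Largest-remainder apportionment of `n` integer slots proportional to
# nonnegative `weights`; deterministic (ties broken by index order) and
# mass-preserving: the result always sums to exactly n.
apportion_counts <- function(weights, n) {
  if (any(weights < 0)) abort("composition weights must be nonnegative")
  total <- sum(weights)
  if (total <= 0) abort("composition has zero total mass")
  quota <- n * weights / total
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate a category-representative mRNA
#'
#' Draws a codon multiset of size `mean_length` from a category codon
#' composition by largest-remainder apportionment (deterministic and
#' mass-preserving), randomizes the codon order, and appends the stop codon.
#' The stop codon is factor-mediated at termination and is excluded from tRNA
#' demand.
#'
#' @param composition a named numeric vector of codon weights, or a tibble
#'   with columns `codon` and `weight` as returned by
#'   [build_category_composition()].
#' @param mean_length number of sense codons of the representative mRNA.
#' @param copy_number mRNA copies of this category in the simulation cell.
#' @param alpha0 initiation rate constant of the category (1/s).
#' @param seed optional integer; fixing it makes the codon order reproducible.
#' @param category_id identifier stored with the mRNA.
#' @param stop stop codon symbol appended at the 3' end.
#' @return A one-row tibble with columns `category_id`, `copy_number`,
#'   `alpha0`, `length` (sense codons) and `codons` (list column holding the
#'   codon sequence, stop included as last element).
#' @export
make_representative_mrna <- function(composition, mean_length, copy_number,
                                     alpha0, seed = NULL,
                                     category_id = "C01", stop = stop_codon()) {
  if (is.data.frame(composition)) {
    composition <- setNames(composition$weight, composition$codon)
  }
  if (length(composition) == 0) abort("`composition` is empty")
  assert_scalar_number(mean_length, "mean_length", lower = 1)
  assert_scalar_number(copy_number, "copy_number", lower = 1)
  assert_scalar_number(alpha0, "alpha0", lower = 0)
  counts <- apportion_counts(composition, as.integer(mean_length))
  multiset <- rep(names(composition), counts)
  codons <- with_local_seed(seed, sample(multiset, length(multiset)))
  tibble(
    category_id = category_id,
    copy_number = as.integer(round_half_up(copy_number)),
    alpha0 = alpha0,
    length = as.integer(mean_length),
    codons = list(c(codons, stop))
  )
}

#' Generate a synthetic virtual transcriptome
#'
#' Emulates the coarse-graining of a transcriptome into category-representative
#' mRNAs at desk scale: each category receives a distinct random codon
#' composition over the sense alphabet, with its glutamine-codon content set
#' on a grid spanning `gln_codon_fraction_range` (log-spaced when possible and
#' permuted across categories, so Gln content is not confounded with the
#' initiation-rate ranking). Categories differ in initiation rate constant and
#' copy number, giving a well-defined wild-type ranking of per-category
#' protein production.
#'
#' @param n_categories number of representative mRNAs.
#' @param codon_map codon alphabet and tRNA assignment, see
#'   [default_codon_map()].
#' @param gln_codon_fraction_range length-2 numeric: range of the total
#'   glutamine-codon (CAA+CAG) fraction across categories. The default spans
#'   Gln-poor to Gln-rich (about six Gln codons on a 200-codon mRNA). A
#'   category with a positive fraction always receives at least one Gln
#'   codon (glutamine occurs in essentially every real protein); request a
#'   fraction of exactly 0 for a Gln-free category.
#' @param mean_lengths sense-codon lengths per category (recycled).
#' @param copy_numbers mRNA copy numbers per category (recycled); default a
#'   descending ramp.
#' @param alpha0 initiation rate constants per category (recycled); default a
#'   descending four-fold geometric ramp around 0.2/s, rescaled during
#'   calibration.
#' @param seed integer seed; the build is fully deterministic for a fixed seed.
#' @return A tibble of representative mRNAs (class `virtual_transcriptome`)
#'   with one row per category and the columns of
#'   [make_representative_mrna()], plus attributes `codon_map` and
#'   `stop_codon`.
#' @export
#' @examples
#' tx <- generate_synthetic_transcriptome(3, seed = 1)
#' tx$category_id
generate_synthetic_transcriptome <- function(n_categories = 8,
                                             codon_map = default_codon_map(),
                                             gln_codon_fraction_range = c(0.002, 0.03),
                                             mean_lengths = 200,
                                             copy_numbers = NULL,
                                             alpha0 = NULL,
                                             seed = NULL) {
  assert_scalar_number(n_categories, "n_categories", lower = 1)
  n_categories <- as.integer(n_categories)
  validate_codon_map(codon_map)
  if (nrow(codon_map) == 0) abort("`codon_map` is empty")
  rng <- range(gln_codon_fraction_range)
  if (rng[1] < 0 || rng[2] >= 1) {
    abort("`gln_codon_fraction_range` must lie in [0, 1)")
  }
  mean_lengths <- rep_len(as.integer(mean_lengths), n_categories)
  if (is.null(copy_numbers)) {
    copy_numbers <- pmax(round_half_up(seq(8, 1, length.out = n_categories)), 1)
  }
  copy_numbers <- rep_len(as.integer(copy_numbers), n_categories)
  if (is.null(alpha0)) {
    # four-fold geometric span: initiation-rate constants of real transcript
    # classes differ several-fold, and the spread defines a wild-type
    # per-category current ranking that is resolvable above counting noise
    alpha0 <- 0.2 * exp(seq(log(1.8), log(0.45), length.out = n_categories))
  }
  alpha0 <- rep_len(alpha0, n_categories)

  gln <- gln_codons(codon_map)
  non_gln <- setdiff(codon_map$codon, gln)
  if (n_categories == 1) {
    fr <- mean(rng)
  } else if (rng[1] > 0) {
    fr <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_categories))
  } else {
    fr <- seq(rng[1], rng[2], length.out = n_categories)
  }

  with_local_seed(seed, {
    fr <- sample(fr, n_categories)
    rows <- purrr::map(seq_len(n_categories), function(i) {
      w <- stats::rgamma(length(non_gln), shape = 2, rate = 1)
      w <- (1 - fr[i]) * w / sum(w)
      comp <- setNames(w, non_gln)
      if (length(gln) > 0 && fr[i] > 0) {
        # CAA slightly favoured over CAG, as in biased yeast transcripts
        split <- rep_len(c(0.55, 0.45), length(gln))
        comp <- c(comp, setNames(fr[i] * split / sum(split), gln))
      }
      m <- make_representative_mrna(comp, mean_lengths[i], copy_numbers[i],
                                    alpha0[i],
                                    category_id = sprintf("C%02d", i))
      if (length(gln) > 0 && fr[i] > 0 &&
          !any(m$codons[[1]] %in% gln)) {
        # glutamine occurs in essentially every real protein: a category
        # with a positive requested Gln fraction must carry at least one
        # Gln codon even when apportionment rounds its quota to zero
        cod <- m$codons[[1]]
        sense <- head(cod, -1)
        swap <- which(sense == names(which.max(table(sense))))[1]
        cod[swap] <- gln[1]
        m$codons[[1]] <- cod
      }
      m
    })
    tx <- dplyr::bind_rows(rows)
    structure(tx,
      codon_map = codon_map, stop_codon = stop_codon(),
      class = c("virtual_transcriptome", class(tx))
    )
  })
}

#' Validate a virtual transcriptome against a codon map
#'
#' Checks category uniqueness, positive lengths and copy numbers, terminal
#' stop codons, and that every sense codon is decoded by some tRNA species.
#'
#' @param transcriptome a transcriptome tibble.
#' @param codon_map a codon map tibble.
#' @return The transcriptome, invisibly; errors describe the first violation.
#' @export
validate_transcriptome <- function(transcriptome,
                                   codon_map = attr(transcriptome, "codon_map") %||%
                                     default_codon_map()) {
  tx <- transcriptome
  req <- c("category_id", "copy_number", "alpha0", "length", "codons")
  missing <- setdiff(req, names(tx))
  if (length(missing) > 0) {
    abort(paste0("transcriptome lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tx$category_id)) abort("category_ids must be unique")
  if (any(tx$copy_number < 1)) abort("copy_number must be >= 1")
  if (any(tx$length < 1)) abort("mRNA length must be >= 1")
  stop_sym <- attr(tx, "stop_codon") %||% stop_codon()
  for (i in seq_len(nrow(tx))) {
    cod <- tx$codons[[i]]
    if (length(cod) != tx$length[i] + 1L) {
      abort(sprintf("category %s: codon vector length != length + stop",
                    tx$category_id[i]))
    }
    if (tail(cod, 1) != stop_sym) {
      abort(sprintf("category %s: last position must be the stop codon",
                    tx$category_id[i]))
    }
    orphan <- setdiff(head(cod, -1), codon_map$codon)
    if (length(orphan) > 0) {
      abort(sprintf("category %s: codon '%s' has no cognate tRNA species",
                    tx$category_id[i], orphan[1]))
    }
  }
  invisible(transcriptome)
}

# Codon demand per codon symbol, copy-number weighted, stop excluded.
codon_demand <- function(transcriptome) {
  counts <- purrr::map2(
    transcriptome$codons, transcriptome$copy_number,
    function(cod, cp) {
      tab <- table(head(cod, -1))
      setNames(as.numeric(tab) * cp, names(tab))
    }
  )
  all_codons <- sort(unique(unlist(purrr::map(counts, names))))
  out <- setNames(numeric(length(all_codons)), all_codons)
  for (ct in counts) out[names(ct)] <- out[names(ct)] + ct
  tibble(codon = names(out), demand = as.numeric(out))
}
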