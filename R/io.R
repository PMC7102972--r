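#' Read and write the model's tabular inputs
#'
#' Plain TSV schemas, one table per component:
#' * gene table: `gene_id`, `abundance`, `categories` (a
#'   `"cat:weight;cat:weight"` string), then one numeric column per codon;
#' * tRNA table: `species`, `anticodon`, `amino_acid`, `copies`;
#' * codon map: `codon`, `species`, `wobble_factor`;
#' * synthetase table: `amino_acid`, `E0`, `kcat`, `Km`.
#'
#' Readers validate the schema and value ranges and name the offending file
#' and column on failure.
#'
#' @param path file path.
#' @param charged_fraction initial charging level applied to tRNA copies.
#' @return A tibble in the package's internal column layout.
#' @name io_tables
NULL

read_tsv_checked <- function(path, required, file_label) {
  if (!file.exists(path)) abort(sprintf("%s: file '%s' not found", file_label, path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s '%s': missing column(s) %s", file_label, path,
                  paste(missing, collapse = ", ")))
  }
  df
}

#' @rdname io_tables
#' @export
read_gene_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "abundance", "categories"),
                         "gene table")
  codon_cols <- setdiff(names(df), c("gene_id", "abundance", "categories"))
  for (cc in codon_cols) {
    if (!is.numeric(df[[cc]]) || any(df[[cc]] < 0, na.rm = TRUE)) {
      abort(sprintf("gene table '%s': column '%s' must be nonnegative numeric",
                    path, cc))
    }
  }
  purrr::walk(df$categories, parse_category_weights)
  as_tibble(df)
}

#' @rdname io_tables
#' @export
read_trna_table <- function(path, charged_fraction = 0.8) {
  df <- read_tsv_checked(path, c("species", "anticodon", "amino_acid", "copies"),
                         "tRNA table")
  if (any(df$copies < 0)) {
    abort(sprintf("tRNA table '%s': column 'copies' must be nonnegative", path))
  }
  out <- tibble(
    species = df$species, anticodon = df$anticodon,
    amino_acid = df$amino_acid, total = as.integer(df$copies),
    charged = as.integer(round_half_up(charged_fraction * df$copies))
  )
  validate_trna(out)
  out
}

#' @rdname io_tables
#' @export
read_codon_map_table <- function(path) {
  df <- read_tsv_checked(path, c("codon", "species", "wobble_factor"),
                         "codon map")
  tibble(
    codon = df$codon, species = df$species,
    amino_acid = if ("amino_acid" %in% names(df)) df$amino_acid else NA_character_,
    anticodon = if ("anticodon" %in% names(df)) df$anticodon else NA_character_,
    wobble = df$wobble_factor
  )
}

#' @rdname io_tables
#' @export
read_synthetase_table <- function(path) {
  df <- read_tsv_checked(path, c("amino_acid", "E0", "kcat", "Km"),
                         "synthetase table")
  out <- tibble(amino_acid = df$amino_acid, E0 = df$E0, kcat = df$kcat,
                Km = df$Km, d = 1)
  validate_synthetases(out)
  out
}

#' Read and cross-validate the full input bundle
#'
#' Loads the transcriptome, tRNA, codon-map and synthetase tables and checks
#' their mutual consistency: every sense codon of the transcriptome must map
#' to a tRNA species present in the tRNA table, the codon map's amino-acid
#' assignment must be resolvable, and every amino acid must have exactly one
#' synthetase.
#'
#' @param transcriptome_path,trna_path,codon_map_path,synthetase_path TSV
#'   file paths.
#' @param charged_fraction initial charging level for the tRNA pools.
#' @return A list with `transcriptome`, `trna`, `codon_map`, `synthetases`.
#' @export
read_tables <- function(transcriptome_path, trna_path, codon_map_path,
                        synthetase_path, charged_fraction = 0.8) {
  trna <- read_trna_table(trna_path, charged_fraction)
  codon_map <- read_codon_map_table(codon_map_path)
  # resolve amino acids of the map from the tRNA table when absent
  idx <- match(codon_map$species, trna$species)
  if (anyNA(idx)) {
    abort(sprintf("codon map: species '%s' absent from tRNA table",
                  codon_map$species[is.na(idx)][1]))
  }
  codon_map$amino_acid <- trna$amino_acid[idx]
  codon_map$anticodon <- trna$anticodon[idx]
  validate_codon_map(codon_map)
  syn <- read_synthetase_table(synthetase_path)
  missing_aa <- setdiff(unique(trna$amino_acid), syn$amino_acid)
  if (length(missing_aa) > 0) {
    abort(sprintf("no synthetase for amino acid '%s'", missing_aa[1]))
  }
  tx <- read_transcriptome(transcriptome_path)
  attr(tx, "codon_map") <- codon_map
  validate_transcriptome(tx, codon_map)
  list(transcriptome = tx, trna = trna, codon_map = codon_map,
       synthetases = syn)
}

#' @rdname io_tables
#' @param trna,codon_map,synthetases,genes tibbles in the package's internal
#'   layout.
#' @export
write_trna_table <- function(trna, path) {
  df <- tibble(species = trna$species, anticodon = trna$anticodon,
               amino_acid = trna$amino_acid, copies = trna$total)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
write_codon_map_table <- function(codon_map, path) {
  df <- tibble(codon = codon_map$codon, species = codon_map$species,
               wobble_factor = codon_map$wobble)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
write_synthetase_table <- function(synthetases, path) {
  df <- tibble(amino_acid = synthetases$amino_acid,
               E0 = synthetases$E0,
               kcat = sprintf("%.9g", synthetases$kcat),
               Km = sprintf("%.9g", synthetases$Km))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path, progress = FALSE)
  invisible(path)
}

#' Write / read a virtual transcriptome dump
#'
#' TSV with columns `category_id`, `copy_number`, `alpha0` and `codons`
#' (space-separated codon string, stop included); round-trips exactly.
#'
#' @param transcriptome a transcriptome tibble.
#' @param path file path.
#' @export
write_transcriptome <- function(transcriptome, path) {
  df <- tibble(
    category_id = transcriptome$category_id,
    copy_number = transcriptome$copy_number,
    alpha0 = sprintf("%.9g", transcriptome$alpha0),
    codons = purrr::map_chr(transcriptome$codons, paste, collapse = " ")
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_transcriptome
#' @export
read_transcriptome <- function(path) {
  df <- read_tsv_checked(path, c("category_id", "copy_number", "alpha0",
                                 "codons"), "transcriptome dump")
  codons <- strsplit(df$codons, " ", fixed = TRUE)
  tx <- tibble(
    category_id = df$category_id,
    copy_number = as.integer(df$copy_number),
    alpha0 = as.numeric(df$alpha0),
    length = lengths(codons) - 1L,
    codons = codons
  )
  structure(tx, stop_codon = stop_codon(),
            class = c("virtual_transcriptome", class(tx)))
}

#' Write simulation observables to CSV
#'
#' Emits `#`-prefixed metadata lines (seed, package version, parameter hash)
#' followed by the global summary row and the per-category table in a fixed
#' column order, with rates printed to 9 significant digits, so output bytes
#' are deterministic for fixed inputs.
#'
#' @param sim a `gtm_sim` object.
#' @param path output file.
#' @export
write_observables <- function(sim, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# ribocharge %s", as.character(utils::packageVersion("ribocharge"))),
    sprintf("# seed: %s", sim$seed %||% "NA"),
    sprintf("# params_hash: %s", hash_object(sim$params)),
    sprintf("# t_end: %.9g burn_in: %.9g", sim$t_end, sim$burn_in)
  ), con)
  g <- glance(sim)
  fmt <- function(df) {
    df[] <- lapply(df, function(x) if (is.numeric(x)) sprintf("%.9g", x) else x)
    sub("\n$", "", readr::format_csv(df))
  }
  writeLines("# global", con)
  writeLines(fmt(g), con)
  writeLines("# per_category", con)
  writeLines(fmt(tidy(sim)), con)
  invisible(path)
}

#' Write run metadata sufficient to reproduce a run
#'
#' @param config a run configuration list (see [read_run_config()]), or any
#'   list of parameters.
#' @param seed the RNG seed of the run.
#' @param path output file.
#' @return The path, invisibly; the file holds `key: value` lines including
#'   a configuration hash.
#' @export
write_metadata <- function(config, seed, path) {
  lines <- c(
    sprintf("package: ribocharge %s",
            as.character(utils::packageVersion("ribocharge"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("config_hash: %s", hash_object(config)),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  setNames(lapply(kv, function(x) paste(x[-1], collapse = ": ")),
           vapply(kv, `[`, "", 1))
}

# Stable content hash of an R object (md5 of its serialized deparse).
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x, control = c("exact")), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a structured run configuration
#'
#' YAML with sections `tables` (paths to the four input TSVs), `params`
#' (fields of [gtm_params()] plus `t_end`, `burn_in`, `omega`), and optional
#' `seed` and `out_prefix`. Parameter ranges are validated before any
#' simulation; referenced files must exist.
#'
#' @param path YAML file path.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$tables)) {
    req <- c("transcriptome", "trna", "codon_map", "synthetases")
    missing <- setdiff(req, names(cfg$tables))
    if (length(missing) > 0) {
      abort(sprintf("config '%s': tables section lacks %s", path,
                    paste(missing, collapse = ", ")))
    }
    base <- dirname(path)
    cfg$tables <- lapply(cfg$tables, function(p) {
      if (!file.exists(p) && file.exists(file.path(base, p))) {
        p <- file.path(base, p)
      }
      if (!file.exists(p)) abort(sprintf("config '%s': file '%s' not found",
                                         path, p))
      p
    })
  }
  p <- cfg$params %||% list()
  known <- names(formals(gtm_params))
  extra <- c("t_end", "burn_in", "omega")
  unknown <- setdiff(names(p), c(known, extra))
  if (length(unknown) > 0) {
    abort(sprintf("config '%s': unknown parameter(s) %s", path,
                  paste(unknown, collapse = ", ")))
  }
  gp <- do.call(gtm_params, p[intersect(names(p), known)])
  cfg$gtm_params <- gp
  cfg$t_end <- p$t_end %||% 150
  cfg$burn_in <- p$burn_in %||% (0.2 * cfg$t_end)
  cfg$omega <- p$omega %||% 1
  structure(cfg, class = c("run_config", "list"))
}

#' Assemble a cell fixture from a run configuration
#'
#' @param config a `run_config` from [read_run_config()].
#' @return A `cell_fixture` ready for [simulate_cell()].
#' @export
fixture_from_config <- function(config) {
  if (is.null(config$tables)) abort("config has no tables section")
  tabs <- read_tables(config$tables$transcriptome, config$tables$trna,
                      config$tables$codon_map, config$tables$synthetases)
  fix <- structure(
    c(tabs, list(params = config$gtm_params)),
    class = "cell_fixture"
  )
  if ((config$omega %||% 1) > 1) fix <- downscale(fix, config$omega)
  fix
}
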