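test_that("category composition sums abundance- and weight-scaled counts", {
  genes <- make_test_genes()

  # identity: single gene, weight 1, abundance 1
  one <- tibble::tibble(gene_id = "g", abundance = 1,
                        categories = "cat:1", AAA = 2, CAA = 1)
  comp <- build_category_composition(one, "cat")
  expect_equal(setNames(comp$weight, comp$codon), c(AAA = 2, CAA = 1))

  # abundance scaling: g1 (abund 2, AAA:1) + g2 (abund 1, CAA:3, weight 0.5)
  comp <- build_category_composition(genes, "translation")
  w <- setNames(comp$weight, comp$codon)
  expect_equal(w[["AAA"]], 2 * 1)          # g1 only
  expect_equal(w[["CAA"]], 1 * 3 * 0.5)    # g2 at half weight
  expect_equal(w[["GCU"]], 2 * 5 + 1 * 1 * 0.5)
})

test_that("split category weights conserve total codon mass", {
  genes <- make_test_genes()
  a <- build_category_composition(genes, "translation")
  b <- build_category_composition(genes, "transport")
  total <- dplyr::bind_rows(a, b) |>
    dplyr::group_by(codon) |>
    dplyr::summarise(weight = sum(weight))
  # direct abundance-weighted sum over genes, ignoring categories
  counts <- as.matrix(genes[, c("AAA", "CAA", "GCU")])
  direct <- as.numeric(crossprod(counts, genes$abundance))
  expect_equal(setNames(total$weight, total$codon),
               setNames(direct, c("AAA", "CAA", "GCU")))
})

test_that("composition errors name the failure", {
  genes <- make_test_genes()
  expect_error(build_category_composition(genes, "nucleus"), "unknown category")
  zero <- dplyr::mutate(genes, abundance = 0)
  expect_error(build_category_composition(zero, "translation"),
               "zero abundance")
  bad <- dplyr::mutate(genes, categories = "translation:0.5;transport:0.4")
  expect_error(build_category_composition(bad, "translation"), "sum to 1")
})

test_that("weighted initiation-rate mean is the abundance-weighted mean", {
  expect_equal(weighted_alpha0(c(4, 4, 4), c(1, 7, 2)), 4)
  expect_equal(weighted_alpha0(c(1, 3), c(1, 1)), 2)
  expect_equal(weighted_alpha0(c(1, 3), c(3, 1)), 1.5)
  expect_error(weighted_alpha0(c(1, 2), c(1, 2, 3)), "same length")
  expect_error(weighted_alpha0(c(1, 2), c(0, 0)), "positive")
})

test_that("representative mRNA is a randomized multiset of the composition", {
  comp <- c(AAA = 3, CAA = 1, GCU = 2)
  m <- make_representative_mrna(comp, mean_length = 60, copy_number = 2,
                                alpha0 = 0.2, seed = 5)
  cods <- m$codons[[1]]
  expect_length(cods, 61)
  expect_identical(cods[61], stop_codon())
  # largest-remainder apportionment preserves proportions exactly here
  expect_equal(as.integer(table(cods[1:60])[c("AAA", "CAA", "GCU")]),
               c(30, 10, 20))

  # same seed reproduces; different seed permutes the same multiset
  m2 <- make_representative_mrna(comp, 60, 2, 0.2, seed = 5)
  expect_identical(m$codons[[1]], m2$codons[[1]])
  m3 <- make_representative_mrna(comp, 60, 2, 0.2, seed = 6)
  expect_false(identical(m$codons[[1]], m3$codons[[1]]))
  expect_equal(sort(m$codons[[1]]), sort(m3$codons[[1]]))

  # single codon type gives a homogeneous sequence
  mono <- make_representative_mrna(c(AAA = 7), 10, 1, 0.1, seed = 1)
  expect_identical(mono$codons[[1]], c(rep("AAA", 10), stop_codon()))

  expect_error(make_representative_mrna(c(AAA = 0), 10, 1, 0.1), "zero total mass")
})

test_that("synthetic transcriptome spans the requested Gln-codon range", {
  tx <- generate_synthetic_transcriptome(
    n_categories = 2, gln_codon_fraction_range = c(0, 0.1),
    mean_lengths = 100, seed = 3
  )
  counts <- sort(vapply(tx$category_id, function(cc) {
    length(gln_positions(tx, cc))
  }, integer(1)))
  expect_identical(counts[[1]], 0L)           # Gln-free end of the range
  expect_true(abs(counts[[2]] - 10L) <= 1L)   # ~10% Gln codons (apportioned)
  expect_equal(sum(vapply(tx$codons, length, integer(1))),
               2 * 101)  # sense codons + stop per category

  # fixed seed reproducibility
  tx2 <- generate_synthetic_transcriptome(
    n_categories = 2, gln_codon_fraction_range = c(0, 0.1),
    mean_lengths = 100, seed = 3
  )
  expect_identical(tx$codons, tx2$codons)
  expect_error(
    generate_synthetic_transcriptome(2, codon_map = default_codon_map()[0, ]),
    "empty"
  )
})

test_that("transcriptome validation catches structural defects", {
  tx <- generate_synthetic_transcriptome(2, seed = 1)
  expect_silent(validate_transcriptome(tx))
  bad <- tx
  bad$codons[[1]][5] <- "XXX"
  expect_error(validate_transcriptome(bad), "no cognate")
  bad2 <- tx
  bad2$category_id <- c("A", "A")
  expect_error(validate_transcriptome(bad2), "unique")
})
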