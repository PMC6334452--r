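# classification fixtures are built directly as allele records (window_seq +
# canonical edits), the same shape build_allele_table produces
toy_allele <- function(t, ops) {
  w <- quant_window(t)
  mut <- crispredit:::apply_ops(t$amplicon_seq, ops)
  wa <- window_allele(align_read(mut, t), t)
  list(window_seq = wa$window_seq, edits = crispredit:::ops_to_string(wa$edits))
}

test_that("targeted C->T edits create the expected stop codons", {
  t <- toy_target()
  ref_allele <- list(window_seq = substr(t$amplicon_seq, 3, 26), edits = "")
  tr0 <- splice_and_translate(ref_allele, t)
  expect_false(tr0$premature_stop)
  expect_identical(tr0$peptide, tr0$ref_peptide)
  # protospacer C8 edit = G->A at the TGG codon's second base -> TAG
  a_tag <- toy_allele(t, crispredit:::edit_op("sub", 23L, alt = "A"))
  tr1 <- splice_and_translate(a_tag, t)
  expect_true(tr1$premature_stop)
  expect_identical(tr1$stop_codon_coordinate, 22L)
  # both window Cs edited -> TAA
  a_taa <- toy_allele(t, rbind(crispredit:::edit_op("sub", 23L, alt = "A"),
                               crispredit:::edit_op("sub", 24L, alt = "A")))
  mut <- crispredit:::mutant_amplicon(a_taa$window_seq, t)
  expect_identical(substr(mut, 23, 25), "TAA")
  expect_true(splice_and_translate(a_taa, t)$premature_stop)
  # the truncated peptide introduces no novel residues
  expect_identical(count_stop <- classify_allele(a_tag, t)$novel_residue_count, 0L)
})

test_that("classification covers every category with the declared precedence", {
  t <- toy_target()
  cut <- cut_site(t)
  # 2-bp deletion: frameshift, null
  c_fs <- classify_allele(toy_allele(t, crispredit:::edit_op("del", cut, len = 2L)), t)
  expect_identical(c_fs$class, "frameshift")
  expect_true(c_fs$is_null)
  expect_false(c_fs$carries_targeted_stop)
  # 3-bp deletion that creates no stop: in-frame indel, not null
  c_if <- classify_allele(toy_allele(t, crispredit:::edit_op("del", 15L, len = 3L)), t)
  expect_identical(c_if$class, "in_frame_indel")
  expect_false(c_if$is_null)
  # single in-window C->T creating TAG: nonsense, null, targeted, 0 novel
  c_ns <- classify_allele(toy_allele(t, crispredit:::edit_op("sub", 23L, alt = "A")), t)
  expect_identical(c_ns$class, "nonsense")
  expect_true(c_ns$is_null)
  expect_true(c_ns$carries_targeted_stop)
  expect_identical(c_ns$novel_residue_count, 0L)
  # non-window missense and silent substitutions
  c_ms <- classify_allele(toy_allele(t, crispredit:::edit_op("sub", 16L, alt = "G")), t)
  expect_identical(c_ms$class, "missense")
  expect_false(c_ms$carries_targeted_stop)
  # CCA -> CCG is a synonymous proline codon: silent
  c_si <- classify_allele(toy_allele(t, crispredit:::edit_op("sub", 21L, alt = "G")), t)
  expect_identical(c_si$class, "silent")
  expect_false(c_si$is_null)
  # reference
  c_ref <- classify_allele(list(window_seq = substr(t$amplicon_seq, 3, 26),
                                edits = ""), t)
  expect_identical(c_ref$class, "reference")
})

test_that("frameshift precedence is stable under edit-list permutation", {
  t <- toy_target()
  ops <- rbind(crispredit:::edit_op("del", cut_site(t), len = 2L),
               crispredit:::edit_op("sub", 23L, alt = "A"))
  a <- toy_allele(t, ops)
  cls1 <- classify_allele(a, t)$class
  # permute the canonical edit string
  parts <- strsplit(a$edits, ";", fixed = TRUE)[[1]]
  a2 <- a
  a2$edits <- paste(rev(parts), collapse = ";")
  expect_identical(classify_allele(a2, t)$class, cls1)
  expect_identical(cls1, "frameshift")  # shifted stop is not "nonsense"
})

test_that("substitution-only classes are local to the edited codon", {
  # the same targeted edit classifies identically on the padded amplicon
  t1 <- toy_target()
  t2 <- padded_target()
  c1 <- classify_allele(toy_allele(t1, crispredit:::edit_op("sub", 23L, alt = "A")), t1)
  c2 <- classify_allele(toy_allele(t2, crispredit:::edit_op("sub", 28L, alt = "A")), t2)
  expect_identical(c1$class, c2$class)
  expect_identical(c1$carries_targeted_stop, c2$carries_targeted_stop)
})

test_that("frameshifts introduce novel residues, targeted stops do not", {
  t <- toy_target()
  sim <- simulate_reads(t, be3_profile(t, p_edit = 0.4, purity = 1,
                                       byproduct_weight = 0, indel_weight = 0),
                        error_model(0), n = 4000, seed = 21)
  tab <- build_allele_table(sim$reads, t, run_config(), "be3pure")
  calls <- classify_alleles(tab, t)
  edited <- calls[calls$class != "reference", ]
  expect_true(all(edited$class == "nonsense"))
  expect_true(all(edited$carries_targeted_stop))
  expect_true(all(edited$novel_residue_count == 0L))
  # Cas9-like: frameshift-dominated nulls carrying novel residues
  sim2 <- simulate_reads(t, cas9_profile(t, p_edit = 0.4), error_model(0),
                         n = 4000, seed = 22)
  tab2 <- build_allele_table(sim2$reads, t, run_config(), "cas9")
  calls2 <- classify_alleles(tab2, t)
  fs <- calls2[calls2$class == "frameshift", ]
  expect_gt(sum(fs$frequency), 0.5 * sum(calls2$frequency[calls2$is_null]))
  expect_true(all(fs$novel_residue_count > 0L))
})

test_that("mutation spectrum partitions edited mass and flags emptiness", {
  t <- toy_target()
  # indel-only simulation: single-base-change fraction is exactly 0
  sim <- simulate_reads(t, cas9_profile(t, p_edit = 0.3), error_model(0),
                        n = 3000, seed = 31)
  sp <- mutation_spectrum(build_allele_table(sim$reads, t, run_config(), "c"))
  expect_identical(sp$single_base_change, 0)
  expect_equal(sp$single_base_change + sp$multi_substitution + sp$insertion +
                 sp$deletion + sp$mixed, 1, tolerance = 1e-9)
  # one edited allele with one substitution: fraction 1
  edited <- crispredit:::apply_ops(t$amplicon_seq,
                                   crispredit:::edit_op("sub", 24L, alt = "A"))
  tab1 <- build_allele_table(make_reads(c(rep(t$amplicon_seq, 50), edited)),
                             t, run_config(), "one")
  expect_identical(mutation_spectrum(tab1)$single_base_change, 1)
  # unedited sample: all-zero fractions with the empty flag
  tab0 <- build_allele_table(make_reads(rep(t$amplicon_seq, 50)),
                             t, run_config(), "none")
  sp0 <- mutation_spectrum(tab0)
  expect_true(sp0$empty)
  expect_identical(sp0$single_base_change, 0)
})

test_that("null-allele statistics use the edited non-silent denominator", {
  # fabricated calls exercise the arithmetic exactly
  calls <- data.frame(
    window_seq = letters[1:4], count = c(800, 100, 60, 40),
    frequency = c(0.80, 0.054, 0.092, 0.054),
    edits = c("", "S1:A", "D1:2", "S2:A"),
    class = c("reference", "nonsense", "frameshift", "missense"),
    is_null = c(FALSE, TRUE, TRUE, FALSE),
    carries_targeted_stop = c(FALSE, TRUE, FALSE, FALSE),
    novel_residue_count = c(0L, 0L, 5L, 1L),
    stop_codon_coordinate = NA_integer_,
    stringsAsFactors = FALSE
  )
  st <- null_allele_stats(list(records = NULL), calls)
  expect_equal(st$absolute_null_frequency, 0.146)
  expect_equal(st$edited_nonsilent_mass, 0.20)
  expect_equal(st$relative_null_percentage, 73.0)
  # all edited alleles frameshift -> relative 100%
  calls2 <- calls[c(1, 3), ]
  expect_equal(null_allele_stats(list(), calls2)$relative_null_percentage, 100)
  # zero edited mass -> relative absent (NA), not 0
  calls3 <- calls[1, ]
  expect_true(is.na(null_allele_stats(list(), calls3)$relative_null_percentage))
})

test_that("ambiguous bases translate to X rather than being dropped", {
  t <- toy_target()
  a_n <- list(window_seq = sub("TGG", "TNG",
                               substr(t$amplicon_seq, 3, 26), fixed = TRUE),
              edits = "S24:N")
  tr <- splice_and_translate(a_n, t)
  expect_true(grepl("X", tr$peptide, fixed = TRUE))
})
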