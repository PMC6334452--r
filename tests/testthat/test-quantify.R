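test_that("QC keeps mean quality >= threshold, boundary inclusive", {
  seqs <- rep(substr(TOY_AMPLICON, 1, 10), 3)
  reads <- make_reads(seqs)
  reads$qual <- c(
    strrep(intToUtf8(33 + 33), 10),                          # all Q33: kept
    paste0(strrep(intToUtf8(33 + 33), 9), intToUtf8(23 + 33)),  # mean 32: out
    strrep(intToUtf8(40 + 33), 10)                           # Q40: kept
  )
  qc <- qc_filter(reads, 33)
  expect_identical(qc$n_kept, 2L)
  expect_identical(qc$n_discarded, 1L)
  expect_identical(qc$reads$read_id, reads$read_id[c(1, 3)])
  # empty input: empty output with zero counters
  qc0 <- qc_filter(reads[0, ], 33)
  expect_identical(qc0$n_kept, 0L)
  expect_identical(qc0$n_discarded, 0L)
})

test_that("alignment is exact for reference reads and flags junk", {
  t <- toy_target()
  a <- align_read(t$amplicon_seq, t)
  expect_identical(a$score, 2 * nchar(t$amplicon_seq))
  expect_false(grepl("-", a$pattern, fixed = TRUE))
  expect_false(a$unalignable)
  # one 2-bp deletion at the cut: exactly one deletion of length 2
  del_read <- crispredit:::apply_ops(t$amplicon_seq,
                                     crispredit:::edit_op("del", cut_site(t),
                                                          len = 2L))
  a2 <- align_read(del_read, t)
  expect_identical(nw_affine_score(del_read, t$amplicon_seq), a2$score)
  gaps <- gregexpr("-+", a2$pattern)[[1]]
  expect_identical(length(gaps), 1L)
  expect_identical(attr(gaps, "match.length"), 2L)
  # a random same-length string falls below the identity floor
  set.seed(99)
  junk <- paste(sample(c("A", "C", "G", "T"), nchar(t$amplicon_seq),
                       replace = TRUE), collapse = "")
  expect_true(align_read(junk, t)$unalignable)
})

test_that("window extraction is window-exclusive and maps edits correctly", {
  t <- toy_target()
  w <- quant_window(t)
  ref_win <- substr(t$amplicon_seq, w[1] + 1, w[2])
  # unedited read
  wa <- window_allele(align_read(t$amplicon_seq, t), t)
  expect_true(wa$spans)
  expect_identical(wa$window_seq, ref_win)
  expect_identical(nrow(wa$edits), 0L)
  # C->T at protospacer position 7 = G->A at plus-strand coordinate 24
  edited <- crispredit:::apply_ops(t$amplicon_seq,
                                   crispredit:::edit_op("sub", 24L, alt = "A"))
  wa2 <- window_allele(align_read(edited, t), t)
  expect_identical(wa2$edits$type, "sub")
  expect_identical(wa2$edits$pos, 24L)
  expect_identical(wa2$edits$alt, "A")
  # a substitution well downstream of the window leaves the allele reference
  far <- crispredit:::apply_ops(t$amplicon_seq,
                                crispredit:::edit_op("sub", 45L, alt = "C"))
  wa3 <- window_allele(align_read(far, t), t)
  expect_identical(wa3$window_seq, ref_win)
  expect_identical(nrow(wa3$edits), 0L)
})

test_that("frequency floor is strict less-than and excluded mass is reported", {
  t <- toy_target()
  edited <- crispredit:::apply_ops(t$amplicon_seq,
                                   crispredit:::edit_op("sub", 24L, alt = "A"))
  # exactly 0.01%: retained ("less than 0.01% were excluded" honored literally)
  reads <- make_reads(c(rep(t$amplicon_seq, 19998), rep(edited, 2)))
  tab <- build_allele_table(reads, t, run_config(), "boundary")
  expect_identical(nrow(tab$records), 2L)
  expect_identical(tab$excluded_lowfreq_alleles, 0L)
  # 0.005%: excluded, with its mass reported, frequencies not renormalized
  reads2 <- make_reads(c(rep(t$amplicon_seq, 19999), edited))
  tab2 <- build_allele_table(reads2, t, run_config(), "boundary2")
  expect_identical(nrow(tab2$records), 1L)
  expect_equal(tab2$excluded_lowfreq_mass, 1 / 20000)
  expect_false(tab2$freq_renormalized)
  expect_equal(sum(tab2$records$frequency) + tab2$excluded_lowfreq_mass, 1,
               tolerance = 1e-9)
})

test_that("allele table recovers a known spectrum at n = 50,000", {
  t <- toy_target()
  cut <- cut_site(t)
  prof <- editing_profile(0.2, list(
    list(ops = crispredit:::edit_op("del", cut, len = 2L), weight = 0.75),
    list(ops = crispredit:::edit_op("sub", 24L, alt = "A"), weight = 0.25)
  ))
  sim <- simulate_reads(t, prof, error_model(0), n = 50000, seed = 3)
  tab <- build_allele_table(sim$reads, t, run_config(), "spectrum")
  # expected read fractions: ref 0.8, del2 0.15, C->T 0.05
  expect_identical(nrow(tab$records), 3L)
  expect_equal(tab$records$frequency[1], 0.8, tolerance = 0.005 / 0.8)
  del_rec <- tab$records[tab$records$n_del == 1, ]
  sub_rec <- tab$records[tab$records$n_sub == 1, ]
  expect_equal(del_rec$frequency, 0.15, tolerance = 0.005 / 0.15)
  expect_equal(sub_rec$frequency, 0.05, tolerance = 0.005 / 0.05)
  # reference allele ranked first by construction
  expect_identical(tab$records$edits[1], "")
})

test_that("read-count conservation is exact across QC, alignment, spanning", {
  t <- toy_target()
  sim <- simulate_reads(t, cas9_profile(t, 0.3), error_model(0.002),
                        n = 2000, seed = 13)
  reads <- sim$reads
  # inject low-quality reads, junk reads, and a window-truncated read
  lowq <- make_reads(rep(t$amplicon_seq, 5), q = 20L,
                     ids = sprintf("lowq%d", 1:5))
  set.seed(1)
  junk <- make_reads(vapply(1:4, function(i) {
    paste(sample(c("A", "C", "G", "T"), nchar(t$amplicon_seq), replace = TRUE),
          collapse = "")
  }, character(1)), ids = sprintf("junk%d", 1:4))
  trunc <- make_reads(substr(t$amplicon_seq, 1, 20), ids = "trunc1")
  all_reads <- rbind(reads, lowq, junk, trunc)
  tab <- build_allele_table(all_reads, t, run_config(), "cons")
  expect_identical(
    tab$qc_discarded + tab$unalignable + tab$non_spanning + tab$usable_reads,
    tab$total_reads
  )
  expect_identical(tab$total_reads, nrow(all_reads))
  expect_identical(as.integer(sum(tab$records$count) +
                                round(tab$excluded_lowfreq_mass *
                                        tab$usable_reads)),
                   tab$usable_reads)
  expect_equal(sum(tab$records$frequency) + tab$excluded_lowfreq_mass, 1,
               tolerance = 1e-9)
})

test_that("top alleles honor the deterministic sort and tie-break", {
  t <- toy_target()
  a1 <- crispredit:::apply_ops(t$amplicon_seq,
                               crispredit:::edit_op("sub", 23L, alt = "A"))
  a2 <- crispredit:::apply_ops(t$amplicon_seq,
                               crispredit:::edit_op("sub", 24L, alt = "A"))
  reads <- make_reads(c(rep(t$amplicon_seq, 10), rep(a1, 4), rep(a2, 4)))
  tab <- build_allele_table(reads, t, run_config(), "ties")
  expect_identical(nrow(top_alleles(tab, 10)), 3L)  # fewer alleles than n
  tied <- tab$records[2:3, ]
  expect_identical(tied$count, c(4L, 4L))
  expect_true(tied$window_seq[1] < tied$window_seq[2])  # lexicographic
})

test_that("insertions belong to the window only via their left neighbor", {
  t <- toy_target()
  w <- quant_window(t)  # [2, 26)
  # left neighbor = last window base (25): included in the allele
  ins_right <- crispredit:::apply_ops(
    t$amplicon_seq, crispredit:::edit_op("ins", w[2] - 1L, alt = "GG"))
  wa_r <- window_allele(align_read(ins_right, t), t)
  # left neighbor just outside the window start: excluded ("TT" cannot be
  # gap-shifted into the window against the following G)
  ins_left <- crispredit:::apply_ops(
    t$amplicon_seq, crispredit:::edit_op("ins", w[1] - 1L, alt = "TT"))
  wa_l <- window_allele(align_read(ins_left, t), t)
  ref_win <- substr(t$amplicon_seq, w[1] + 1, w[2])
  expect_identical(wa_l$window_seq, ref_win)
  expect_identical(nrow(wa_l$edits), 0L)
  expect_identical(nchar(wa_r$window_seq), nchar(ref_win) + 2L)
  expect_identical(wa_r$edits$type, "ins")
})
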