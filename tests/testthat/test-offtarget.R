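# synthetic candidate sites derived from the gMH guide by planting a chosen
# number of mismatches, optionally scrubbing editing-window cytosines
make_candidate <- function(guide, n_mm, window_c = TRUE, mm_from = 12L) {
  s <- strsplit(guide, "", fixed = TRUE)[[1]]
  swap <- c(A = "G", C = "A", G = "T", T = "C")
  if (n_mm > 0) {
    at <- seq(mm_from, by = 2L, length.out = n_mm)
    s[at] <- swap[s[at]]
  }
  if (!window_c) {
    win <- 4:8
    s[win][s[win] == "C"] <- "A"
  }
  paste(s, collapse = "")
}

test_that("panel selection applies both clauses with inclusive boundaries", {
  guide <- GMH
  cands <- data.frame(
    site_id = c("on", "mm3_C", "mm4_C", "mm2_noC", "short"),
    sequence = c(guide,
                 make_candidate(guide, 3),
                 make_candidate(guide, 4),
                 make_candidate(guide, 0, window_c = FALSE),  # 2 mm, both Cs gone
                 substr(guide, 1, 18)),
    pam = "TGG", locus_label = "locus", source = "predicted",
    stringsAsFactors = FALSE
  )
  sel <- select_be_panel(cands, guide)
  expect_setequal(sel$panel$site_id, c("on", "mm3_C"))  # "up to 3" inclusive
  expect_identical(sel$log$reason[sel$log$site_id == "mm4_C"],
                   "4 mismatches > 3")
  expect_match(sel$log$reason[sel$log$site_id == "mm2_noC"], "cytosine")
  expect_match(sel$log$reason[sel$log$site_id == "short"], "length")
  # mismatch annotation: window-C scrub does not count for the on-target
  expect_identical(sel$panel$n_mismatches[sel$panel$site_id == "on"], 0L)
  expect_identical(sel$panel$mismatch_positions[sel$panel$site_id == "on"], "")
})

test_that("panel selection is idempotent and order-independent", {
  guide <- GMH
  cands <- data.frame(
    site_id = sprintf("s%d", 1:6),
    sequence = vapply(0:5, function(k) make_candidate(guide, k), character(1)),
    pam = "TGG", locus_label = "l", source = "circle_seq",
    stringsAsFactors = FALSE
  )
  sel1 <- select_be_panel(cands, guide)
  sel2 <- select_be_panel(cands[rev(seq_len(nrow(cands))), ], guide)
  expect_setequal(sel1$panel$site_id, sel2$panel$site_id)
  sel3 <- select_be_panel(sel1$panel[, names(cands)], guide)
  expect_setequal(sel3$panel$site_id, sel1$panel$site_id)
})

test_that("site mutation counts distinguish zero from absent", {
  st <- site_target("site1", GMH, "TGG", strrep("T", 20), strrep("A", 20))
  # error-free reference reads: observed zero
  f0 <- site_mutation_frequency(make_reads(rep(st$amplicon_seq, 200)), st)
  expect_identical(f0$edited, 0L)
  expect_identical(f0$total, 200L)
  expect_false(f0$absent)
  # 10% in-window C->T editing recovers within binomial bounds
  sim <- simulate_reads(st, be3_profile(st, p_edit = 0.1, purity = 1,
                                        byproduct_weight = 0, indel_weight = 0),
                        error_model(0), n = 5000, seed = 29)
  f1 <- site_mutation_frequency(sim$reads, st)
  # at error rate 0 the edited count recovers the simulator truth exactly
  expect_identical(f1$edited, sum(sim$truth$allele_id > 0L))
  expect_identical(f1$total, 5000L)
  # reads from an unrelated amplicon: absent entry, not zero
  other <- second_locus()
  f2 <- site_mutation_frequency(make_reads(rep(other$amplicon_seq, 50)), st)
  expect_true(f2$absent)
  expect_true(is.na(f2$edited))
})

test_that("group comparison matches a hypergeometric oracle and handles ties", {
  counts <- data.frame(
    site_id = "hot", group = c("treated", "control"),
    sample_id = c("t1", "c1"), edited = c(300L, 0L),
    total = c(10000L, 10000L), stringsAsFactors = FALSE
  )
  cmp <- compare_groups(counts)
  expect_lt(cmp$p_value, 1e-6)
  expect_true(cmp$significant)
  expect_equal(cmp$p_value, fisher_exact_oracle(300L, 9700L, 0L, 10000L),
               tolerance = 1e-8)
  # identical counts in both groups: p = 1, never significant
  same <- data.frame(site_id = "flat", group = c("treated", "control"),
                     sample_id = c("t1", "c1"), edited = c(12L, 12L),
                     total = c(4000L, 4000L), stringsAsFactors = FALSE)
  cmp2 <- compare_groups(same)
  expect_equal(cmp2$p_value, 1)
  expect_false(cmp2$significant)
})

test_that("treated identical to control yields no significant site", {
  set.seed(101)
  counts <- do.call(rbind, lapply(1:12, function(i) {
    e <- rpois(1, 5)
    data.frame(site_id = sprintf("s%02d", i), group = c("treated", "control"),
               sample_id = c("t1", "c1"), edited = c(e, e),
               total = c(3000L, 3000L), stringsAsFactors = FALSE)
  }))
  cmp <- compare_groups(counts)
  expect_false(any(cmp$significant))
  expect_equal(cmp$p_value, rep(1, nrow(cmp)), tolerance = 1e-8)
})

test_that("rank method runs on per-sample frequencies", {
  counts <- do.call(rbind, lapply(c("t1", "t2", "t3", "c1", "c2", "c3"),
    function(s) {
      treated <- startsWith(s, "t")
      data.frame(site_id = "s1", group = if (treated) "treated" else "control",
                 sample_id = s, edited = if (treated) 40L else 2L,
                 total = 1000L, stringsAsFactors = FALSE)
    }))
  cmp <- compare_groups(counts, method = "rank")
  expect_lt(cmp$p_value, 0.11)  # smallest attainable two-sided p at 3 vs 3
  expect_identical(cmp$method, "rank")
})

test_that("heat-map table carries masks, numbering, and NA for absent cells", {
  guide <- GMH
  cands <- data.frame(
    site_id = c("on", "mm1"),
    sequence = c(guide, make_candidate(guide, 1, mm_from = 11L)),
    pam = "TGG", locus_label = "l", source = "predicted",
    stringsAsFactors = FALSE
  )
  sel <- select_be_panel(cands, guide)
  per_sample <- data.frame(
    site_id = rep(c("on", "mm1"), each = 2),
    sample_id = rep(c("t1", "c1"), 2),
    group = rep(c("treated", "control"), 2),
    edited = c(50L, 1L, 0L, NA),
    total = c(1000L, 1000L, 1000L, NA),
    stringsAsFactors = FALSE
  )
  cmp <- compare_groups(per_sample)
  hm_d <- heatmap_table(sel$panel, cmp, per_sample, "pam_distal")
  hm_p <- heatmap_table(sel$panel, cmp, per_sample, "pam_proximal")
  expect_identical(hm_d$mismatch_positions[hm_d$site_id == "on"][1], "")
  # distal position 11 is proximal position 10 for L = 20 (and vice versa)
  expect_identical(hm_d$mismatch_positions[hm_d$site_id == "mm1"][1], "11")
  expect_identical(hm_p$mismatch_positions[hm_p$site_id == "mm1"][1], "10")
  expect_true(is.na(hm_d$frequency[4]))  # absent cell stays NA, not 0
})
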