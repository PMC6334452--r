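# Shared fixtures, built in code.
#
# The toy locus embeds the reverse complement of the gMH guide
# (CAGGTTCCATGGGATGCTCT) on the minus strand, with PAM TGG on the plus
# strand at [8,11) and the cut at plus-strand coordinate 14. Plus-strand
# bases 22..24 (0-based) form a TGG tryptophan codon in the anchored frame;
# the two editing-window cytosines of the protospacer (positions 7 and 8,
# PAM-distal) map onto its G bases, so pure C->T conversion creates
# TAG / TGA / TAA stops - a stand-in for the targeted W159 codon.

GMH <- "CAGGTTCCATGGGATGCTCT"
GM <- "GGCTGATGAGGCCGCACATG"
GH <- "GTCCCGCGGGCGCCCGTGCGC"  # 21 nt as printed

TOY_AMPLICON <- paste0("ACGTACGTCCA", "AGAGCATCCCATGGAACCTG",
                       "GATCTAGGCATCGGATTACA")

toy_target <- function(quant_halfwidth = 12L, edit_window = c(4L, 8L)) {
  guide_target(
    target_id = "A_toy", amplicon_seq = TOY_AMPLICON,
    protospacer = GMH, pam = "TGG", strand = "-", protospacer_start = 11L,
    frame_anchor = 1L, cds_bounds = c(1L, 49L),
    quant_halfwidth = quant_halfwidth, edit_window = edit_window
  )
}

# toy locus with a 5' pad so the cut sits >= 15 bp from both ends
padded_target <- function(quant_halfwidth = 12L) {
  guide_target(
    target_id = "A_pad", amplicon_seq = paste0("CTGAC", TOY_AMPLICON),
    protospacer = GMH, pam = "TGG", strand = "-", protospacer_start = 16L,
    frame_anchor = 6L, cds_bounds = c(6L, 54L),
    quant_halfwidth = quant_halfwidth
  )
}

# an unrelated plus-strand locus (gM guide), used as the fusion partner
second_locus <- function(quant_halfwidth = 12L) {
  guide_target(
    target_id = "B_locus",
    amplicon_seq = paste0("TTACGGATCGTTAGCCATGA", GM, "TGG",
                          "CCATTAGGACCGTTAACGGA"),
    protospacer = GM, pam = "TGG", strand = "+", protospacer_start = 20L,
    frame_anchor = 21L, cds_bounds = c(21L, 60L),
    quant_halfwidth = quant_halfwidth
  )
}

# embed a protospacer at a chosen plus-strand offset between filler flanks
embedded_target <- function(protospacer, offset, flank3 = 30L,
                            target_id = "embedded", strand = "+") {
  filler <- function(n) substr(strrep("ACTGTCAG", ceiling(n / 8)), 1, n)
  L <- nchar(protospacer)
  if (strand == "+") {
    amp <- paste0(filler(offset), protospacer, "TGG", filler(flank3))
  } else {
    amp <- paste0(filler(offset - 3L), "CCA",
                  crispredit:::revcomp(protospacer), filler(flank3))
  }
  guide_target(target_id, amp, protospacer, "TGG", strand,
               protospacer_start = offset)
}

# a random valid target whose protospacer/PAM are read off the amplicon;
# the footprint occupies 0-based [offset, offset + L) on the plus strand
random_target <- function(seed, strand = "+", amp_len = 120L, L = 20L) {
  set.seed(seed)
  amp <- sample(c("A", "C", "G", "T"), amp_len, replace = TRUE)
  offset <- sample(30:(amp_len - L - 33L), 1)
  footprint_idx <- offset + 1:L  # R 1-based indices of the footprint
  if (strand == "+") {
    amp[offset + L + 2:3] <- "G"  # plus-strand PAM xGG 3' of the footprint
    pam <- paste(amp[offset + L + 1:3], collapse = "")
    proto <- paste(amp[footprint_idx], collapse = "")
  } else {
    # plus-strand PAM footprint at [offset-3, offset) must be CCx
    amp[offset - 2L] <- "C"
    amp[offset - 1L] <- "C"
    pam <- crispredit:::revcomp(paste(amp[(offset - 2L):offset], collapse = ""))
    proto <- crispredit:::revcomp(paste(amp[footprint_idx], collapse = ""))
  }
  guide_target(paste0("rnd", seed), paste(amp, collapse = ""), proto, pam,
               strand, protospacer_start = offset)
}

# constant-quality reads data.frame
make_reads <- function(seqs, q = 37L, ids = NULL) {
  data.frame(
    read_id = ids %||% sprintf("r%04d", seq_along(seqs)),
    seq = seqs,
    qual = vapply(nchar(seqs), function(n) strrep(intToUtf8(q + 33L), n),
                  character(1)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# central 99% binomial interval for an observed count
binom99 <- function(n, p) {
  c(qbinom(0.005, n, p), qbinom(0.995, n, p))
}

expect_within_binom99 <- function(count, n, p) {
  iv <- binom99(n, p)
  expect_gte(count, iv[1])
  expect_lte(count, iv[2])
}
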