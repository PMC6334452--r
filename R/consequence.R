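# Translation of consolidated alleles in genomic context and classification
# into mutation categories: reference, silent, missense, in-frame indel,
# frameshift, nonsense. Null alleles are frameshifts and nonsense alleles.
# A "targeted stop" is a premature stop created solely by editing-window
# C-to-T conversion (G-to-A on the opposite strand), e.g. TGG -> TAG/TGA/TAA
# at a tryptophan codon.

CONSEQUENCE_CLASSES <- c("reference", "silent", "missense", "in_frame_indel",
                         "frameshift", "nonsense")

# rebuild the full mutant amplicon from a window sequence
mutant_amplicon <- function(window_seq, t) {
  w <- quant_window(t)
  amp <- t$amplicon_seq
  paste0(substr(amp, 1L, w[1]), gsub("-", "", window_seq, fixed = TRUE),
         substr(amp, w[2] + 1L, nchar(amp)))
}

translate_segment <- function(seq, from0, to0) {
  len <- ((to0 - from0) %/% 3L) * 3L
  if (len < 3L) return(list(peptide = "", stop_index = NA_integer_))
  pep <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, from0 + 1L, from0 + len)),
    if.fuzzy.codon = "X"
  ))
  stop_at <- regexpr("*", pep, fixed = TRUE)
  if (stop_at > 0) {
    list(peptide = substr(pep, 1L, stop_at - 1L), stop_index = as.integer(stop_at))
  } else {
    list(peptide = pep, stop_index = NA_integer_)
  }
}

#' Splice an allele into the amplicon and translate it
#'
#' Reconstructs the mutant amplicon by substituting the allele's window
#' sequence into the reference, then translates the coding interval in the
#' anchored frame through the first stop codon (or the segment end).
#' Ambiguous bases translate to X, never silently dropped. The reading-frame
#' anchor must lie outside the quantification window so the frame of the
#' spliced sequence is unambiguous.
#'
#' @param allele one `allele_table` record (or a list with `window_seq` and
#'   `edits`).
#' @param t a `guide_target` with frame_anchor and cds_bounds set.
#' @return list with `peptide` (mutant, through the first stop, stop
#'   excluded), `ref_peptide`, `premature_stop` (logical),
#'   `stop_codon_coordinate` (0-based coordinate of the stop's first base in
#'   the mutant amplicon, or NA), and `net_indel`.
#' @export
splice_and_translate <- function(allele, t) {
  if (is.na(t$frame_anchor) || any(is.na(t$cds_bounds))) {
    config_error(paste0("target '", t$target_id,
                        "' has no frame_anchor/cds_bounds"))
  }
  w <- quant_window(t)
  a <- t$frame_anchor
  if (a >= w[1] && a < w[2]) {
    config_error("frame_anchor lies inside the quantification window")
  }
  ops <- parse_ops(allele$edits)
  net <- sum(nchar(ops$alt[ops$type == "ins"])) - sum(ops$len[ops$type == "del"])
  mut <- mutant_amplicon(allele$window_seq, t)
  c1 <- t$cds_bounds[2]
  a_m <- if (a < w[1]) a else a + net
  c1_m <- if (c1 >= w[2]) c1 + net else c1
  mt <- translate_segment(mut, a_m, c1_m)
  rt <- translate_segment(t$amplicon_seq, a, c1)
  premature <- !is.na(mt$stop_index) &&
    (is.na(rt$stop_index) || mt$stop_index < rt$stop_index)
  list(
    peptide = mt$peptide,
    ref_peptide = rt$peptide,
    premature_stop = premature,
    stop_codon_coordinate = if (!is.na(mt$stop_index)) {
      a_m + 3L * (mt$stop_index - 1L)
    } else NA_integer_,
    net_indel = net
  )
}

# count mutant residues strictly before the first stop that differ from the
# reference peptide aligned from the frame anchor (position-wise)
count_novel_residues <- function(mut_pep, ref_pep) {
  if (!nchar(mut_pep)) return(0L)
  m <- strsplit(mut_pep, "", fixed = TRUE)[[1]]
  r <- strsplit(ref_pep, "", fixed = TRUE)[[1]]
  n <- length(m)
  r <- c(r, rep("", max(0L, n - length(r))))[seq_len(n)]
  sum(m != r)
}

#' Classify one allele into a mutation category
#'
#' Rules, applied in order so every allele receives exactly one class:
#' no edits -> reference; net indel length not a multiple of 3 -> frameshift;
#' premature stop in translation -> nonsense; non-zero in-frame net indel ->
#' in-frame indel; any changed residue -> missense; otherwise silent.
#' Frameshift takes precedence over nonsense so that a stop reached through
#' a shifted frame is reported as a frameshift consequence.
#'
#' @param allele one `allele_table` record.
#' @param t a `guide_target` with frame information.
#' @return a `consequence_call` list: class, is_null, premature stop
#'   coordinate, novel_residue_count, carries_targeted_stop.
#' @export
classify_allele <- function(allele, t) {
  ops <- parse_ops(allele$edits)
  if (!nrow(ops)) {
    return(structure(
      list(class = "reference", is_null = FALSE,
           stop_codon_coordinate = NA_integer_, novel_residue_count = 0L,
           carries_targeted_stop = FALSE),
      class = "consequence_call"
    ))
  }
  tr <- splice_and_translate(allele, t)
  cls <-
    if (tr$net_indel %% 3L != 0L) "frameshift"
    else if (tr$premature_stop) "nonsense"
    else if (tr$net_indel != 0L) "in_frame_indel"
    else if (tr$peptide != tr$ref_peptide ||
             nchar(tr$peptide) != nchar(tr$ref_peptide)) "missense"
    else "silent"
  novel <- count_novel_residues(tr$peptide, tr$ref_peptide)
  targeted <- cls == "nonsense" && all(ops$type == "sub") &&
    all(is_targeted_conversion(ops, t))
  structure(
    list(class = cls, is_null = cls %in% c("frameshift", "nonsense"),
         stop_codon_coordinate = if (tr$premature_stop || cls == "frameshift") {
           tr$stop_codon_coordinate
         } else NA_integer_,
         novel_residue_count = novel,
         carries_targeted_stop = targeted),
    class = "consequence_call"
  )
}

# TRUE per op when it is an editing-window C->T on the protospacer strand,
# expressed on the plus strand (C->T for a + protospacer, G->A for -)
is_targeted_conversion <- function(ops, t) {
  cpos <- edit_window_c_positions(t)
  coords <- if (length(cpos)) proto_to_amplicon(t, cpos) else integer(0)
  expected_alt <- if (t$strand == "+") "T" else "A"
  vapply(seq_len(nrow(ops)), function(i) {
    o <- ops[i, ]
    o$type == "sub" && o$pos %in% coords && o$alt == expected_alt
  }, logical(1))
}

#' Classify all alleles of a table
#'
#' @param table an `allele_table`.
#' @param t a `guide_target` with frame information.
#' @return data.frame with one row per retained allele: window_seq, count,
#'   frequency, edits, class, is_null, carries_targeted_stop,
#'   novel_residue_count, stop_codon_coordinate.
#' @export
classify_alleles <- function(table, t) {
  rec <- table$records
  calls <- lapply(seq_len(nrow(rec)), function(i) classify_allele(rec[i, ], t))
  data.frame(
    window_seq = rec$window_seq, count = rec$count,
    frequency = rec$frequency, edits = rec$edits,
    class = vapply(calls, `[[`, character(1), "class"),
    is_null = vapply(calls, `[[`, logical(1), "is_null"),
    carries_targeted_stop = vapply(calls, `[[`, logical(1),
                                   "carries_targeted_stop"),
    novel_residue_count = vapply(calls, `[[`, integer(1),
                                 "novel_residue_count"),
    stop_codon_coordinate = vapply(calls, `[[`, integer(1),
                                   "stop_codon_coordinate"),
    stringsAsFactors = FALSE
  )
}

#' Mutation-type spectrum among edited allele mass
#'
#' Partitions the edited (non-reference) read mass into disjoint categories:
#' single-base change (exactly one substitution, no indel), multi-substitution
#' (substitutions only), insertion only, deletion only, and mixed. Fractions
#' are relative to the edited mass and sum to 1.
#'
#' @param table an `allele_table`.
#' @return list with the five fractions, `edited_mass` (fraction of usable
#'   reads that are edited), and `empty` (TRUE when there is no edited mass).
#' @export
mutation_spectrum <- function(table) {
  rec <- table$records
  edited <- rec$edits != ""
  mass <- sum(rec$frequency[edited])
  if (mass <= 0) {
    return(list(single_base_change = 0, multi_substitution = 0,
                insertion = 0, deletion = 0, mixed = 0,
                edited_mass = 0, empty = TRUE))
  }
  cat_of <- function(r) {
    if (r$n_sub == 1L && r$n_ins == 0L && r$n_del == 0L) "single_base_change"
    else if (r$n_sub >= 2L && r$n_ins == 0L && r$n_del == 0L) "multi_substitution"
    else if (r$n_sub == 0L && r$n_ins >= 1L && r$n_del == 0L) "insertion"
    else if (r$n_sub == 0L && r$n_ins == 0L && r$n_del >= 1L) "deletion"
    else "mixed"
  }
  cats <- vapply(which(edited), function(i) cat_of(rec[i, ]), character(1))
  frac <- function(k) sum(rec$frequency[edited][cats == k]) / mass
  list(single_base_change = frac("single_base_change"),
       multi_substitution = frac("multi_substitution"),
       insertion = frac("insertion"), deletion = frac("deletion"),
       mixed = frac("mixed"), edited_mass = mass, empty = FALSE)
}

#' Null-allele statistics
#'
#' Absolute null frequency is the summed frequency of frameshift and
#' nonsense alleles over usable reads. The relative null percentage divides
#' that by the summed frequency of edited, non-silent alleles (silent
#' substitutions are excluded from the denominator) and is expressed in
#' percent. With zero edited mass the relative percentage is undefined and
#' reported as NA, not 0.
#'
#' @param table an `allele_table`.
#' @param calls output of [classify_alleles()] for the same table.
#' @return list with `absolute_null_frequency`, `relative_null_percentage`,
#'   `edited_nonsilent_mass`, `per_class` (summed frequency by class), and
#'   `denominator` (a description recorded into report output).
#' @export
null_allele_stats <- function(table, calls) {
  per_class <- vapply(CONSEQUENCE_CLASSES, function(k) {
    sum(calls$frequency[calls$class == k])
  }, numeric(1))
  absolute <- sum(calls$frequency[calls$is_null])
  edited <- sum(calls$frequency[!calls$class %in% c("reference", "silent")])
  list(
    absolute_null_frequency = absolute,
    relative_null_percentage = if (edited > 0) 100 * absolute / edited else NA_real_,
    edited_nonsilent_mass = edited,
    per_class = per_class,
    denominator = "edited non-silent allele mass (silent substitutions excluded)"
  )
}

#' Translate and report the most frequent alleles
#'
#' @param table an `allele_table`.
#' @param t a `guide_target` with frame information.
#' @param n number of alleles (default 10).
#' @return data.frame with window_seq, count, frequency, class, is_null,
#'   carries_targeted_stop, novel_residue_count, and the predicted peptide.
#' @export
translate_top_alleles <- function(table, t, n = 10L) {
  top <- top_alleles(table, n)
  if (!nrow(top)) return(data.frame())
  calls <- lapply(seq_len(nrow(top)), function(i) classify_allele(top[i, ], t))
  peps <- vapply(seq_len(nrow(top)), function(i) {
    tr <- splice_and_translate(top[i, ], t)
    if (tr$premature_stop) paste0(tr$peptide, "*") else tr$peptide
  }, character(1))
  data.frame(
    window_seq = top$window_seq, count = top$count,
    frequency = top$frequency,
    class = vapply(calls, `[[`, character(1), "class"),
    is_null = vapply(calls, `[[`, logical(1), "is_null"),
    carries_targeted_stop = vapply(calls, `[[`, logical(1),
                                   "carries_targeted_stop"),
    novel_residue_count = vapply(calls, `[[`, integer(1),
                                 "novel_residue_count"),
    peptide = peps, stringsAsFactors = FALSE
  )
}
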