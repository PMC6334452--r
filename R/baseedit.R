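# Per-position base-substitution profiling over the protospacer, reported on
# the protospacer strand, and summary statistics for base-editing outcomes:
# the targeted-transition fraction (editing-window C->T share of all
# substitution mass) and the indel rate of an allele table.

#' Per-position substitution matrix over the protospacer
#'
#' Counts base changes at each protospacer position (1..L) among QC-passing,
#' alignable reads. Positions spanned by a deletion in a read are excluded
#' from that position's denominator rather than counted as non-edits, so
#' indel-rich samples do not dilute substitution percentages. Entries are
#' strand-adjusted: a G-to-A change on the plus strand at a position whose
#' protospacer is on the minus strand is recorded as C-to-T.
#'
#' Two denominators are emitted: `frequency` (count over reads covering the
#' position) and `frequency_per_substitution` (count over all substitution
#' counts across the protospacer).
#'
#' @param reads data.frame with read_id, seq, qual.
#' @param t a `guide_target`.
#' @param cfg a [run_config()]; controls QC and the reported numbering.
#' @return a `substitution_matrix`: long data.frame (position, numbering,
#'   ref_base, alt_base, count, coverage, frequency,
#'   frequency_per_substitution) with positions of zero coverage absent, plus
#'   totals. Rows are one per (position, non-reference base).
#' @export
substitution_matrix <- function(reads, t, cfg = run_config()) {
  qc <- qc_filter(reads, cfg$min_mean_quality)
  if (!qc$n_kept) data_error("no QC-passing reads")
  L <- nchar(t$protospacer)
  coords <- proto_to_amplicon(t, seq_len(L))  # plus-strand coord per distal pos
  useqs <- unique(qc$reads$seq)
  a <- align_unique(useqs, t$amplicon_seq)
  ucount <- table(factor(qc$reads$seq, levels = useqs))

  # per unique alignment, the read base (or "-") aligned at each coord
  base_at <- matrix("-", nrow = length(useqs), ncol = L)
  keep <- a$identity >= MIN_ALIGN_IDENTITY
  for (i in which(keep)) {
    pat <- strsplit(a$pattern[i], "", fixed = TRUE)[[1]]
    sub <- strsplit(a$subject[i], "", fixed = TRUE)[[1]]
    ref_cols <- which(sub != "-")
    # ref_cols[k] is the alignment column of 0-based reference coord k-1
    base_at[i, ] <- pat[ref_cols[coords + 1L]]
  }
  w_reads <- as.integer(ucount)
  ref_plus <- strsplit(t$amplicon_seq, "", fixed = TRUE)[[1]][coords + 1L]
  flip <- t$strand == "-"
  rows <- list()
  total_sub <- 0L
  for (p in seq_len(L)) {
    col <- base_at[keep, p]
    wts <- w_reads[keep]
    covered <- col %in% BASES
    coverage <- sum(wts[covered])
    if (!coverage) next
    ref_b <- if (flip) comp_base(ref_plus[p]) else ref_plus[p]
    for (alt_plus in BASES) {
      if (alt_plus == ref_plus[p]) next
      cnt <- sum(wts[covered & col == alt_plus])
      alt_b <- if (flip) comp_base(alt_plus) else alt_plus
      total_sub <- total_sub + cnt
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, ref_base = ref_b, alt_base = alt_b,
        count = cnt, coverage = coverage, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) data_error("no protospacer position has coverage")
  df <- do.call(rbind, rows)
  df$frequency <- df$count / df$coverage
  df$frequency_per_substitution <- if (total_sub > 0) df$count / total_sub else NA_real_
  df$numbering <- cfg$position_numbering
  if (cfg$position_numbering == "pam_proximal") {
    df$position <- convert_position(df$position, "pam_distal", "pam_proximal", L)
  }
  df <- df[order(df$position, df$alt_base), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(
    list(matrix = df[, c("position", "numbering", "ref_base", "alt_base",
                         "count", "coverage", "frequency",
                         "frequency_per_substitution")],
         L = L, numbering = cfg$position_numbering,
         total_substitutions = total_sub, target_id = t$target_id),
    class = "substitution_matrix"
  )
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("substitution_matrix: target '", x$target_id, "', ", x$L,
      " positions (", x$numbering, "), ", x$total_substitutions,
      " substitution calls\n", sep = "")
  print(utils::head(x$matrix[x$matrix$count > 0, ], 10))
  invisible(x)
}

#' Targeted-transition fraction
#'
#' The share of all protospacer substitution mass that is editing-window
#' C-to-T on the protospacer strand - the signature of cytidine base
#' editing. Reported as NA when no substitutions were observed (0/0).
#'
#' @param m a `substitution_matrix`.
#' @param t the `guide_target` it was built from.
#' @return fraction in `[0, 1]`, or NA.
#' @export
targeted_transition_fraction <- function(m, t) {
  if (m$total_substitutions == 0L) return(NA_real_)
  df <- m$matrix
  pos_distal <- if (m$numbering == "pam_proximal") {
    convert_position(df$position, "pam_proximal", "pam_distal", m$L)
  } else df$position
  in_win <- pos_distal >= t$edit_window[1] & pos_distal <= t$edit_window[2]
  targeted <- sum(df$count[in_win & df$ref_base == "C" & df$alt_base == "T"])
  targeted / m$total_substitutions
}

#' Indel rate of an allele table
#'
#' Read-mass fraction of alleles containing at least one insertion or
#' deletion within the quantification window.
#'
#' @param table an `allele_table`.
#' @return list with `indel_rate` and `empty` (TRUE when there is no edited
#'   mass at all).
#' @export
indel_rate <- function(table) {
  rec <- table$records
  edited_mass <- sum(rec$frequency[rec$edits != ""])
  list(indel_rate = sum(rec$frequency[rec$n_ins + rec$n_del > 0]),
       empty = edited_mass <= 0)
}

#' Write a substitution matrix as long-format TSV
#'
#' @param m a `substitution_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_substitution_matrix <- function(m, path) {
  write_report_tsv(
    m$matrix, path,
    comments = c(
      paste0("target=", m$target_id, " numbering=", m$numbering),
      "frequency denominator: reads covering the position (per_read);",
      "frequency_per_substitution denominator: all substitution calls (per_substitution)"
    )
  )
}
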