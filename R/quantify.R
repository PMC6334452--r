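# Windowed allele quantification: read QC, global alignment to the
# reference amplicon, extraction of the read sequence within the
# quantification window (insertions included, deletions marked with '-'),
# and consolidation into an allele table with a strict frequency floor.

ALIGN_MATCH <- 2
ALIGN_MISMATCH <- -4
ALIGN_GAP_OPEN <- 10   # Biostrings convention: gap of length k costs open + k*ext
ALIGN_GAP_EXT <- 1
MIN_ALIGN_IDENTITY <- 0.6

align_sub_matrix <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(ALIGN_MISMATCH, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- ALIGN_MATCH
  m["N", "N"] <- ALIGN_MISMATCH  # N never counts as a match
  m
}

#' Quality-filter reads on mean Phred score
#'
#' Keeps reads whose arithmetic-mean Phred quality is greater than or equal
#' to the threshold (the boundary is inclusive: a read of uniform Q33 passes
#' a threshold of 33).
#'
#' @param reads data.frame with read_id, seq, qual (Phred+33).
#' @param min_mean_quality threshold (default 33).
#' @return list with `reads` (kept rows), `n_kept`, `n_discarded`.
#' @export
qc_filter <- function(reads, min_mean_quality = 33) {
  if (!nrow(reads)) {
    return(list(reads = reads, n_kept = 0L, n_discarded = 0L))
  }
  keep <- phred_mean(reads$qual) >= min_mean_quality
  list(reads = reads[keep, , drop = FALSE],
       n_kept = sum(keep), n_discarded = sum(!keep))
}

# one global alignment per unique sequence; returns a list parallel to
# unique(seqs) with gapped pattern/subject strings, score and identity.
#
# Same-length ACGT reads with at most 3 mismatches take a gapless fast
# path: converting a mismatch to a match gains 6 while any length-neutral
# gap arrangement costs at least 2 * (open + ext) = 22, so the gapless
# alignment is provably optimal there. Everything else goes through
# Biostrings::pairwiseAlignment.
align_unique <- function(useqs, ref) {
  n <- length(useqs)
  pattern <- character(n)
  subject <- character(n)
  score <- numeric(n)
  identity <- numeric(n)
  L <- nchar(ref)
  ref_int <- utf8ToInt(ref)
  fast <- logical(n)
  eligible <- which(nchar(useqs) == L & !grepl("N", useqs, fixed = TRUE))
  for (i in eligible) {
    k <- sum(utf8ToInt(useqs[i]) != ref_int)
    if (k <= 3L) {
      fast[i] <- TRUE
      pattern[i] <- useqs[i]
      subject[i] <- ref
      score[i] <- ALIGN_MATCH * (L - k) + ALIGN_MISMATCH * k
      identity[i] <- (L - k) / L
    }
  }
  slow <- which(!fast)
  if (length(slow)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(useqs[slow]), Biostrings::DNAString(ref),
      type = "global", substitutionMatrix = align_sub_matrix(),
      gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXT
    )
    pattern[slow] <- as.character(Biostrings::alignedPattern(aln))
    subject[slow] <- as.character(Biostrings::alignedSubject(aln))
    score[slow] <- Biostrings::score(aln)
    identity[slow] <- Biostrings::nmatch(aln) / L
  }
  list(pattern = pattern, subject = subject, score = score,
       identity = identity)
}

#' Align one read globally to the reference amplicon
#'
#' Needleman-Wunsch with affine gaps (match +2, mismatch -4, gap open -10,
#' gap extend -1 per base). Reads whose alignment identity over the amplicon
#' falls below 60% are flagged unalignable and excluded from allele tables.
#'
#' @param read a read sequence (character) or a one-row reads data.frame.
#' @param t a `guide_target`.
#' @return a `read_alignment`: gapped pattern/subject strings, score,
#'   identity, and `unalignable` flag.
#' @export
align_read <- function(read, t) {
  seq <- if (is.data.frame(read)) read$seq[1] else read
  a <- align_unique(seq, t$amplicon_seq)
  structure(
    list(pattern = a$pattern[1], subject = a$subject[1], score = a$score[1],
         identity = a$identity[1],
         unalignable = a$identity[1] < MIN_ALIGN_IDENTITY),
    class = "read_alignment"
  )
}

# Extract window sequence and canonical edits from one gapped alignment.
# Returns list(window_seq, ops, spans) or list(spans = FALSE) when the read
# does not cover the window. Deleted window columns are marked '-';
# insertions whose left reference neighbor is the last window base belong to
# the allele, insertions left of the window do not (half-open logic).
extract_window <- function(pat_chars, sub_chars, wstart, wend) {
  refpos <- cumsum(sub_chars != "-")  # 1-based ref coordinate of each ref column
  covered <- which(pat_chars != "-")
  if (!length(covered)) return(list(spans = FALSE))
  cov_cols <- range(covered)
  # reference coords covered by the read (coordinate of the nearest consumed
  # reference base at/before the column, 0-based)
  cov_start <- refpos[cov_cols[1]] - (sub_chars[cov_cols[1]] != "-")
  cov_end <- refpos[cov_cols[2]] - 1L
  if (cov_start > wstart || cov_end < wend - 1L) return(list(spans = FALSE))

  win_chars <- character(0)
  subs <- list(); dels <- list(); inss <- list()
  cur_del <- NULL; cur_ins <- NULL
  flush_del <- function() {
    if (!is.null(cur_del)) dels[[length(dels) + 1L]] <<- cur_del
    cur_del <<- NULL
  }
  flush_ins <- function() {
    if (!is.null(cur_ins)) inss[[length(inss) + 1L]] <<- cur_ins
    cur_ins <<- NULL
  }
  r <- 0L  # ref coords consumed so far; current column's ref coord when S != '-'
  for (k in seq_along(sub_chars)) {
    S <- sub_chars[k]; P <- pat_chars[k]
    if (S != "-") {
      coord <- r
      r <- r + 1L
      flush_ins()
      if (coord < wstart || coord >= wend) { flush_del(); next }
      if (P == "-") {
        win_chars <- c(win_chars, "-")
        if (is.null(cur_del)) cur_del <- list(pos = coord, len = 1L)
        else cur_del$len <- cur_del$len + 1L
      } else {
        flush_del()
        win_chars <- c(win_chars, P)
        if (P != S) subs[[length(subs) + 1L]] <- list(pos = coord, alt = P)
      }
    } else {
      # insertion column; left reference neighbor is r - 1
      lcoord <- r - 1L
      if (lcoord >= wstart && lcoord <= wend - 1L) {
        win_chars <- c(win_chars, P)
        if (is.null(cur_ins)) cur_ins <- list(pos = lcoord, seq = P)
        else cur_ins$seq <- paste0(cur_ins$seq, P)
      }
    }
  }
  flush_del(); flush_ins()
  ops <- ops_bind(
    if (length(subs)) do.call(rbind, lapply(subs, function(s)
      edit_op("sub", s$pos, alt = s$alt))),
    if (length(inss)) do.call(rbind, lapply(inss, function(s)
      edit_op("ins", s$pos, alt = s$seq))),
    if (length(dels)) do.call(rbind, lapply(dels, function(s)
      edit_op("del", s$pos, len = s$len)))
  )
  list(spans = TRUE, window_seq = paste(win_chars, collapse = ""), ops = ops)
}

#' Window sequence and canonical edits for one aligned read
#'
#' @param aln a `read_alignment` from [align_read()].
#' @param t a `guide_target`.
#' @return list with `window_seq` (deletions marked '-', insertions
#'   included), `edits` (edit-op data.frame, window-scoped), and `spans`
#'   (FALSE when the read does not cover the window; then no allele is
#'   extracted).
#' @export
window_allele <- function(aln, t) {
  w <- quant_window(t)
  res <- extract_window(strsplit(aln$pattern, "", fixed = TRUE)[[1]],
                        strsplit(aln$subject, "", fixed = TRUE)[[1]],
                        w[1], w[2])
  if (!res$spans) return(list(spans = FALSE))
  list(spans = TRUE, window_seq = res$window_seq,
       edits = res$ops %||% edit_op("sub", 0L)[0, ])
}

# canonical string form of window ops (1-based positions); "" for reference
parse_ops <- function(s) {
  if (is.na(s) || s == "") {
    return(data.frame(type = character(), pos = integer(), alt = character(),
                      len = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  do.call(rbind, lapply(parts, function(p) {
    type <- substr(p, 1, 1)
    body <- strsplit(substr(p, 2, nchar(p)), ":", fixed = TRUE)[[1]]
    pos <- as.integer(body[1]) - 1L
    switch(type,
      S = edit_op("sub", pos, alt = body[2]),
      I = edit_op("ins", pos, alt = body[2]),
      D = edit_op("del", pos, len = as.integer(body[2]))
    )
  }))
}

#' Build the consolidated allele table for one sample
#'
#' Reads are quality-filtered, aligned to the amplicon, and grouped by their
#' sequence within the quantification window. Frequencies are relative to
#' reads that pass QC, align, and span the window. Alleles with a frequency
#' strictly below `cfg$allele_freq_floor` are removed and their total mass
#' reported as `excluded_lowfreq_mass` (frequencies are deliberately not
#' renormalized after the exclusion; the excluded mass is reported instead).
#' Records are sorted by descending count, ties broken by lexicographic
#' window sequence.
#'
#' @param reads data.frame with read_id, seq, qual.
#' @param t a `guide_target`.
#' @param cfg a [run_config()].
#' @param sample_id label recorded in the table.
#' @return an `allele_table`: counters plus a `records` data.frame
#'   (window_seq, count, frequency, edits, n_sub, n_ins, n_del, net_indel).
#' @export
build_allele_table <- function(reads, t, cfg = run_config(),
                               sample_id = "sample") {
  total <- nrow(reads)
  qc <- qc_filter(reads, cfg$min_mean_quality)
  n_unalignable <- 0L
  n_nonspanning <- 0L
  keys <- character(0)
  if (qc$n_kept > 0L) {
    useqs <- unique(qc$reads$seq)
    a <- align_unique(useqs, t$amplicon_seq)
    w <- quant_window(t)
    per_unique <- lapply(seq_along(useqs), function(i) {
      if (a$identity[i] < MIN_ALIGN_IDENTITY) return(list(state = "unalignable"))
      res <- extract_window(strsplit(a$pattern[i], "", fixed = TRUE)[[1]],
                            strsplit(a$subject[i], "", fixed = TRUE)[[1]],
                            w[1], w[2])
      if (!res$spans) return(list(state = "nonspanning"))
      list(state = "ok", window_seq = res$window_seq,
           edits = ops_to_string(res$ops))
    })
    names(per_unique) <- useqs
    states <- vapply(per_unique, `[[`, character(1), "state")[qc$reads$seq]
    n_unalignable <- sum(states == "unalignable")
    n_nonspanning <- sum(states == "nonspanning")
    ok <- states == "ok"
    keys <- vapply(per_unique[qc$reads$seq[ok]], function(p)
      paste0(p$window_seq, "\t", p$edits), character(1))
  }
  n_usable <- length(keys)
  if (n_usable == 0L) {
    data_error(paste0("no usable reads for sample '", sample_id,
                      "' at target '", t$target_id, "'"))
  }
  # alleles are identified by window sequence alone; should distinct global
  # alignments ever yield the same window sequence with different edit
  # descriptions, the description of the most frequent variant is kept
  tab <- table(keys)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  sub_records <- data.frame(
    window_seq = vapply(parts, `[`, character(1), 1),
    count = as.integer(tab),
    edits = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                   character(1)),
    stringsAsFactors = FALSE
  )
  sub_records <- sub_records[order(-sub_records$count), , drop = FALSE]
  counts <- tapply(sub_records$count, sub_records$window_seq, sum)
  first_edit <- sub_records$edits[!duplicated(sub_records$window_seq)]
  names(first_edit) <- sub_records$window_seq[!duplicated(sub_records$window_seq)]
  records <- data.frame(
    window_seq = names(counts),
    count = as.integer(counts),
    edits = unname(first_edit[names(counts)]),
    stringsAsFactors = FALSE
  )
  records$frequency <- records$count / n_usable
  opsl <- lapply(records$edits, parse_ops)
  records$n_sub <- vapply(opsl, function(o) sum(o$type == "sub"), integer(1))
  records$n_ins <- vapply(opsl, function(o) sum(o$type == "ins"), integer(1))
  records$n_del <- vapply(opsl, function(o) sum(o$type == "del"), integer(1))
  records$net_indel <- vapply(opsl, function(o) {
    sum(nchar(o$alt[o$type == "ins"])) - sum(o$len[o$type == "del"])
  }, integer(1))

  low <- records$frequency < cfg$allele_freq_floor
  excluded_mass <- sum(records$frequency[low])
  excluded_n <- sum(low)
  records <- records[!low, , drop = FALSE]
  records <- records[order(-records$count, records$window_seq), , drop = FALSE]
  rownames(records) <- NULL
  records <- records[, c("window_seq", "count", "frequency", "edits",
                         "n_sub", "n_ins", "n_del", "net_indel")]
  structure(
    list(sample_id = sample_id, target_id = t$target_id,
         total_reads = total, qc_passing_reads = qc$n_kept,
         qc_discarded = qc$n_discarded, unalignable = n_unalignable,
         non_spanning = n_nonspanning, usable_reads = n_usable,
         excluded_lowfreq_mass = excluded_mass,
         excluded_lowfreq_alleles = excluded_n,
         freq_renormalized = FALSE,
         records = records),
    class = "allele_table"
  )
}

#' @export
print.allele_table <- function(x, ...) {
  cat("allele_table: sample '", x$sample_id, "', target '", x$target_id,
      "'\n  reads: ", x$total_reads, " total, ", x$qc_passing_reads,
      " QC-passing, ", x$usable_reads, " usable (",
      x$unalignable, " unalignable, ", x$non_spanning, " non-spanning)\n",
      "  alleles: ", nrow(x$records), " retained, ",
      x$excluded_lowfreq_alleles, " below floor (mass ",
      signif(x$excluded_lowfreq_mass, 3), ")\n", sep = "")
  print(utils::head(x$records, 5))
  invisible(x)
}

#' Top-n alleles of a table
#'
#' @param table an `allele_table`.
#' @param n number of records (default 10, the usual reporting depth).
#' @return the first `min(n, nrow)` records under the table's deterministic
#'   sort (descending count, lexicographic window-sequence tie-break).
#' @export
top_alleles <- function(table, n = 10L) {
  utils::head(table$records, n)
}

#' Write an allele table as TSV with a JSON-style run summary header
#'
#' @param table an `allele_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_table <- function(table, path) {
  counters <- table[setdiff(names(table), "records")]
  write_report_tsv(
    table$records, path,
    comments = c(
      paste0("sample=", table$sample_id, " target=", table$target_id),
      paste0("counters=", jsonlite::toJSON(counters, auto_unbox = TRUE)),
      "frequencies are not renormalized after the low-frequency exclusion"
    )
  )
}
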