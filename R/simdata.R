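# Read simulator with per-read ground truth. Emulates Cas9-like indel
# spectra centered at the cut site, BE3-like C-to-T conversion confined to
# the editing window (with rare non-C-to-T byproducts and rare indels),
# control libraries, and fusion-junction libraries between two loci.
#
# Reads are single-end, plus-strand, and cover the whole amplicon;
# sequencing error is substitution-only so that every read maps back to its
# source allele unambiguously at error rate 0.

# --- edit operations -------------------------------------------------------
# An edit op is a one-row data.frame: type ("sub","ins","del"), pos (0-based
# plus-strand amplicon coordinate; for "ins" the left reference neighbor),
# alt (sub: replacement base; ins: inserted sequence; del: ""), len
# (del: deleted length; otherwise 0).

edit_op <- function(type, pos, alt = "", len = 0L) {
  data.frame(type = type, pos = as.integer(pos), alt = alt,
             len = as.integer(len), stringsAsFactors = FALSE)
}

ops_bind <- function(...) do.call(rbind, list(...))

# canonical 1-based string form, ops sorted by position then type
ops_to_string <- function(ops) {
  if (is.null(ops) || !nrow(ops)) return("")
  ops <- ops[order(ops$pos, ops$type, ops$alt), , drop = FALSE]
  parts <- vapply(seq_len(nrow(ops)), function(i) {
    o <- ops[i, ]
    switch(o$type,
      sub = paste0("S", o$pos + 1L, ":", o$alt),
      ins = paste0("I", o$pos + 1L, ":", o$alt),
      del = paste0("D", o$pos + 1L, ":", o$len)
    )
  }, character(1))
  paste(parts, collapse = ";")
}

# overlap check: deletions occupy [pos, pos+len), subs [pos, pos+1),
# insertions sit at the boundary 3' of pos
ops_overlap <- function(ops) {
  if (nrow(ops) < 2L) return(FALSE)
  iv <- lapply(seq_len(nrow(ops)), function(i) {
    o <- ops[i, ]
    if (o$type == "del") c(o$pos, o$pos + o$len)
    else if (o$type == "sub") c(o$pos, o$pos + 1L)
    else c(o$pos + 0.5, o$pos + 0.5)  # ins: point at the boundary
  })
  for (i in seq_along(iv)) for (j in seq_along(iv)) {
    if (i >= j) next
    a <- iv[[i]]; b <- iv[[j]]
    if (identical(a, b)) return(TRUE)
    if (a[1] < b[2] && b[1] < a[2]) return(TRUE)
  }
  FALSE
}

# apply ops to a reference sequence (descending position so coordinates of
# untouched ops stay valid)
apply_ops <- function(ref, ops) {
  if (is.null(ops) || !nrow(ops)) return(ref)
  n <- nchar(ref)
  if (any(ops$pos < 0L) || any(ops$pos >= n) ||
      any(ops$type == "del" & ops$pos + ops$len > n)) {
    validation_error("edit operation outside the amplicon")
  }
  if (ops_overlap(ops)) {
    validation_error("overlapping edit operations in one allele")
  }
  ops <- ops[order(-ops$pos), , drop = FALSE]
  s <- ref
  for (i in seq_len(nrow(ops))) {
    o <- ops[i, ]
    if (o$type == "sub") {
      s <- paste0(substr(s, 1L, o$pos), o$alt, substr(s, o$pos + 2L, nchar(s)))
    } else if (o$type == "del") {
      s <- paste0(substr(s, 1L, o$pos), substr(s, o$pos + o$len + 1L, nchar(s)))
    } else {
      s <- paste0(substr(s, 1L, o$pos + 1L), o$alt, substr(s, o$pos + 2L, nchar(s)))
    }
  }
  s
}

# --- profiles --------------------------------------------------------------

#' Editing-outcome profile for the read simulator
#'
#' @param p_edit fraction of reads drawn from non-reference alleles.
#' @param alleles list of `list(ops = <edit-op data.frame>, weight = w)`;
#'   weights are relative among edited reads and must be positive.
#' @return an `editing_profile` object.
#' @export
editing_profile <- function(p_edit, alleles) {
  if (p_edit < 0 || p_edit > 1) config_error("p_edit must be in [0, 1]")
  if (!length(alleles) && p_edit > 0) config_error("p_edit > 0 but no alleles")
  w <- vapply(alleles, function(a) a$weight, numeric(1))
  if (any(w <= 0)) config_error("allele weights must be > 0")
  for (a in alleles) {
    if (ops_overlap(a$ops)) validation_error("overlapping ops in one allele")
  }
  structure(list(p_edit = p_edit, alleles = alleles), class = "editing_profile")
}

#' Sequencing error and quality model
#'
#' Substitution-only sequencing error at a uniform per-base rate, with
#' per-base Phred qualities drawn from a normal distribution and clipped to
#' `[2, 41]`.
#'
#' @param per_base_error substitution rate per base, at most 0.05.
#' @param quality_mean,quality_sd Phred quality distribution parameters.
#' @return an `error_model` object.
#' @export
error_model <- function(per_base_error = 0.001, quality_mean = 37,
                        quality_sd = 2) {
  if (per_base_error < 0 || per_base_error > 0.05) {
    config_error("per_base_error must be in [0, 0.05]")
  }
  structure(list(per_base_error = per_base_error, quality_mean = quality_mean,
                 quality_sd = quality_sd), class = "error_model")
}

#' BE3-like editing profile
#'
#' Enumerates all non-empty subsets of protospacer-strand cytosines inside
#' the editing window as pure C-to-T conversion alleles (reflected to the
#' plus strand as G-to-A when the protospacer is on the minus strand), plus
#' optional non-C-to-T byproduct alleles (C-to-G at each window cytosine)
#' and a 1-bp deletion at the cut site. The pure mass is split equally among
#' the subsets, the byproduct mass equally among the byproduct alleles.
#'
#' Defaults emulate the reported character of BE3 outcomes: about 90% of
#' edited reads carry pure single-base conversions, with small byproduct and
#' indel remainders.
#'
#' @param t a `guide_target` with at least one editing-window cytosine.
#' @param p_edit fraction of edited reads.
#' @param purity weight mass of pure C-to-T alleles (default 0.90).
#' @param byproduct_weight weight mass of non-C-to-T substitution byproducts
#'   (default 0.05).
#' @param indel_weight weight mass of the 1-bp deletion allele (default 0.05).
#' @return an `editing_profile`.
#' @export
be3_profile <- function(t, p_edit = 0.25, purity = 0.90,
                        byproduct_weight = 0.05, indel_weight = 0.05) {
  cpos <- edit_window_c_positions(t)
  if (!length(cpos)) {
    validation_error(paste0("target '", t$target_id,
                            "' has no editing-window cytosine"))
  }
  sub_op <- function(p, to_proto) {
    coord <- proto_to_amplicon(t, p)
    alt <- if (t$strand == "+") to_proto else comp_base(to_proto)
    edit_op("sub", coord, alt = alt)
  }
  # all non-empty subsets of window Cs, converted C->T
  subsets <- unlist(lapply(seq_along(cpos), function(k) {
    utils::combn(cpos, k, simplify = FALSE)
  }), recursive = FALSE)
  alleles <- lapply(subsets, function(ps) {
    list(ops = do.call(rbind, lapply(ps, sub_op, to_proto = "T")),
         weight = purity / length(subsets))
  })
  if (byproduct_weight > 0) {
    alleles <- c(alleles, lapply(cpos, function(p) {
      list(ops = sub_op(p, "G"), weight = byproduct_weight / length(cpos))
    }))
  }
  if (indel_weight > 0) {
    alleles <- c(alleles, list(list(ops = edit_op("del", cut_site(t), len = 1L),
                                    weight = indel_weight)))
  }
  editing_profile(p_edit, alleles)
}

#' Cas9-like NHEJ indel profile
#'
#' Small deletions centered on the cut site and a 1-bp insertion at the cut,
#' the canonical NHEJ repair spectrum. Default weights put about 70% of the
#' edited mass in frameshifting lengths, in line with the frameshift-dominated
#' null-allele shares reported for Cas9 amplicon outcomes.
#'
#' @param t a `guide_target`.
#' @param p_edit fraction of edited reads.
#' @param del_weights named numeric vector: deletion length -> weight.
#' @param ins1_weight weight of the 1-bp insertion ("A") at the cut.
#' @return an `editing_profile`.
#' @export
cas9_profile <- function(t, p_edit = 0.25,
                         del_weights = c(`1` = 0.25, `2` = 0.15, `3` = 0.15,
                                         `4` = 0.10, `6` = 0.10, `9` = 0.05),
                         ins1_weight = 0.20) {
  cut <- cut_site(t)
  alleles <- lapply(names(del_weights), function(k) {
    len <- as.integer(k)
    start <- cut - len %/% 2L
    list(ops = edit_op("del", start, len = len), weight = unname(del_weights[k]))
  })
  if (ins1_weight > 0) {
    alleles <- c(alleles, list(list(ops = edit_op("ins", cut - 1L, alt = "A"),
                                    weight = ins1_weight)))
  }
  editing_profile(p_edit, alleles)
}

# --- simulation ------------------------------------------------------------

BASES <- c("A", "C", "G", "T")

# substitution errors applied in-place; returns character vector of sequences
apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

sim_qualities <- function(lens, err) {
  vapply(lens, function(L) {
    phred_string(as.integer(round(stats::rnorm(L, err$quality_mean, err$quality_sd))))
  }, character(1))
}

#' Simulate amplicon reads with ground truth
#'
#' Each read is the reference amplicon with the edits of one spectrum allele
#' applied (or no edits, for reference reads), followed by substitution-only
#' sequencing errors and simulated Phred qualities. Deterministic for a
#' fixed seed; the caller's RNG stream is left untouched.
#'
#' @param t a `guide_target`.
#' @param prof an `editing_profile`.
#' @param err an `error_model`.
#' @param n number of reads (>= 1).
#' @param seed integer seed.
#' @param id_prefix prefix for read identifiers.
#' @return list with `reads` (data.frame: read_id, seq, qual) and `truth`
#'   (data.frame: read_id, allele_id with 0 = reference, ops, is_fusion).
#' @export
simulate_reads <- function(t, prof, err, n, seed, id_prefix = "read") {
  if (n < 1L) config_error("n must be >= 1")
  ref <- t$amplicon_seq
  allele_seqs <- c(ref, vapply(prof$alleles, function(a) apply_ops(ref, a$ops),
                               character(1)))
  allele_ops <- c("", vapply(prof$alleles, function(a) ops_to_string(a$ops),
                             character(1)))
  w <- vapply(prof$alleles, function(a) a$weight, numeric(1))
  with_local_seed(seed, {
    edited <- stats::runif(n) < prof$p_edit
    idx <- integer(n)  # 0 = reference
    if (any(edited)) {
      idx[edited] <- sample.int(length(w), sum(edited), replace = TRUE,
                                prob = w / sum(w))
    }
    seqs <- allele_seqs[idx + 1L]
    seqs <- apply_seq_errors(seqs, err$per_base_error)
    quals <- sim_qualities(nchar(seqs), err)
    ids <- sprintf("%s_%06d", id_prefix, seq_len(n))
    list(
      reads = data.frame(read_id = ids, seq = seqs, qual = quals,
                         stringsAsFactors = FALSE),
      truth = data.frame(read_id = ids, allele_id = idx,
                         ops = allele_ops[idx + 1L], is_fusion = FALSE,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a library containing fusion-junction reads
#'
#' Fusion reads are full copies of the balanced or acentric fusion template
#' between the two loci (built by [build_fusion_templates()]); non-fusion
#' reads are drawn evenly from the two reference amplicons. Both cut sites
#' must be at least 15 bp from their amplicon ends so every fusion read
#' spans the junction with adequate flanks.
#'
#' @param tA,tB `guide_target`s for the two loci.
#' @param geometry `"balanced"` or `"acentric"`.
#' @param p_fusion fraction of fusion reads.
#' @param n number of reads.
#' @param seed integer seed.
#' @param err an `error_model`.
#' @return list with `reads`, `truth` (with `source` in A/B/fusion), and the
#'   `template` used.
#' @export
simulate_fusion_library <- function(tA, tB, geometry = "balanced", p_fusion,
                                    n, seed, err = error_model(0)) {
  if (p_fusion < 0 || p_fusion > 1) config_error("p_fusion must be in [0, 1]")
  tmpl <- build_fusion_templates(tA, tB)[[geometry]]
  if (is.null(tmpl)) config_error("geometry must be 'balanced' or 'acentric'")
  if (tmpl$junction_offset < 15L ||
      nchar(tmpl$sequence) - tmpl$junction_offset < 15L) {
    validation_error("fusion template has < 15 bp flank on one side of the junction")
  }
  with_local_seed(seed, {
    is_fusion <- stats::runif(n) < p_fusion
    src <- ifelse(is_fusion, "fusion",
                  ifelse(stats::runif(n) < 0.5, "A", "B"))
    pool <- c(A = tA$amplicon_seq, B = tB$amplicon_seq, fusion = tmpl$sequence)
    seqs <- unname(pool[src])
    seqs <- apply_seq_errors(seqs, err$per_base_error)
    quals <- sim_qualities(nchar(seqs), err)
    ids <- sprintf("fus_%06d", seq_len(n))
    list(
      reads = data.frame(read_id = ids, seq = seqs, qual = quals,
                         stringsAsFactors = FALSE),
      truth = data.frame(read_id = ids, allele_id = ifelse(is_fusion, 1L, 0L),
                         ops = "", is_fusion = is_fusion, source = src,
                         stringsAsFactors = FALSE),
      template = tmpl
    )
  })
}

# --- FASTQ I/O -------------------------------------------------------------
# Strict 4-line Phred+33 records, matching what the simulator emits; the
# reader reports the offending line on malformed input.

#' Write reads as Phred+33 FASTQ
#'
#' @param reads data.frame with read_id, seq, qual.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  if (nrow(reads)) {
    lines[seq(1, length(lines), 4)] <- paste0("@", reads$read_id)
    lines[seq(2, length(lines), 4)] <- reads$seq
    lines[seq(3, length(lines), 4)] <- "+"
    lines[seq(4, length(lines), 4)] <- reads$qual
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read Phred+33 FASTQ
#'
#' @param path FASTQ file (4-line records).
#' @return data.frame with read_id, seq, qual; zero rows for an empty file.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) config_error(paste0("FASTQ not found: ", path))
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(read_id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    data_error(paste0("truncated FASTQ record at line ", length(lines) + 1L,
                      " in ", path))
  }
  hdr <- lines[seq(1, length(lines), 4)]
  seqs <- lines[seq(2, length(lines), 4)]
  plus <- lines[seq(3, length(lines), 4)]
  qual <- lines[seq(4, length(lines), 4)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    data_error(paste0("malformed FASTQ header at line ", (bad_hdr[1] - 1L) * 4L + 1L))
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    data_error(paste0("malformed FASTQ separator at line ", (bad_plus[1] - 1L) * 4L + 3L))
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len)) {
    data_error(paste0("sequence/quality length mismatch at line ",
                      (bad_len[1] - 1L) * 4L + 4L))
  }
  data.frame(read_id = sub("^@", "", hdr), seq = toupper(seqs), qual = qual,
             stringsAsFactors = FALSE)
}

#' Write a simulator truth table as TSV
#'
#' @param truth truth data.frame from [simulate_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
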