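# Fusion-junction analysis between two cut loci: template construction for
# balanced (co-directional tail join) and acentric (head-to-head join)
# inter-chromosomal translocations, exact-match in-silico PCR, and detection
# of junction-spanning reads.

#' Build balanced and acentric fusion templates between two cut loci
#'
#' Balanced: the plus-strand sequence of locus A 5' of its cut joined to the
#' plus-strand sequence of locus B 3' of its cut (co-directional).
#' Acentric: locus A 5' of its cut joined head-to-head to the reverse
#' complement of locus B 5' of its cut, which makes two locus-forward
#' primers convergent on the fused molecule - the geometry implied by an
#' acentric-assay primer pair of two forward primers. The head-to-head
#' arrangement is an assumption recorded in report headers.
#'
#' @param tA,tB `guide_target`s for the two loci.
#' @return list with `balanced` and `acentric` `fusion_template`s: sequence,
#'   junction_offset (0-based coordinate of the first base 3' of the
#'   junction), geometry, and provenance.
#' @export
build_fusion_templates <- function(tA, tB) {
  cutA <- cut_site(tA)
  cutB <- cut_site(tB)
  lenA <- nchar(tA$amplicon_seq)
  lenB <- nchar(tB$amplicon_seq)
  if (cutA <= 0L || cutA >= lenA || cutB <= 0L || cutB >= lenB) {
    validation_error("cut at a sequence boundary yields a degenerate template")
  }
  headA <- substr(tA$amplicon_seq, 1L, cutA)
  make <- function(geometry, right_seq) {
    structure(
      list(geometry = geometry,
           sequence = paste0(headA, right_seq),
           junction_offset = cutA,
           provenance = list(target_id_A = tA$target_id, cut_A = cutA,
                             target_id_B = tB$target_id, cut_B = cutB,
                             arrangement = if (geometry == "balanced") {
                               "A[0:cutA) + B[cutB:end), co-directional"
                             } else {
                               "A[0:cutA) + revcomp(B[0:cutB)), head-to-head (assumed)"
                             })),
      class = "fusion_template"
    )
  }
  list(
    balanced = make("balanced", substr(tB$amplicon_seq, cutB + 1L, lenB)),
    acentric = make("acentric", revcomp(substr(tB$amplicon_seq, 1L, cutB)))
  )
}

#' Exact-match in-silico PCR on a template
#'
#' The forward primer must match the template plus strand; the second primer
#' must bind the opposite strand downstream (its reverse complement occurs
#' on the plus strand 3' of the forward primer). `second_orientation`
#' records whether the supplied second-primer sequence is a reverse primer
#' of the template locus or a forward primer of its own locus that becomes
#' convergent after a head-to-head fusion; binding is tested identically.
#' Product length is the distance between the two primer 5' ends, inclusive.
#'
#' @param template a `fusion_template` or a plain sequence string.
#' @param fwd_primer,second_primer primer sequences, 5' to 3', >= 15 nt.
#' @param second_orientation `"reverse"` or `"forward"` (annotation only).
#' @param max_product longest reported product (default 2000).
#' @return list with `product_length` (NA when no product), `products`
#'   (all lengths when a primer binds more than once, with a warning), and
#'   the primer 5' offsets of the first product.
#' @export
in_silico_pcr <- function(template, fwd_primer, second_primer,
                          second_orientation = c("reverse", "forward"),
                          max_product = 2000L) {
  second_orientation <- match.arg(second_orientation)
  seq <- if (inherits(template, "fusion_template")) template$sequence else template
  if (nchar(fwd_primer) < 15L || nchar(second_primer) < 15L) {
    config_error("primers must be at least 15 nt")
  }
  find_all <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                  Biostrings::DNAString(seq))
    Biostrings::start(m) - 1L  # 0-based 5' offsets on the plus strand
  }
  fwd_hits <- find_all(toupper(fwd_primer))
  rc_hits <- find_all(revcomp(toupper(second_primer)))
  if (!length(fwd_hits) || !length(rc_hits)) {
    return(list(product_length = NA_integer_, products = integer(0),
                fwd_offset = NA_integer_, second_offset = NA_integer_))
  }
  prods <- list()
  for (f in fwd_hits) for (r in rc_hits) {
    second5 <- r + nchar(second_primer) - 1L  # 5' end of the second primer
    len <- second5 - f + 1L
    if (len >= nchar(fwd_primer) + nchar(second_primer) && len <= max_product) {
      prods[[length(prods) + 1L]] <- c(f, second5, len)
    }
  }
  if (!length(prods)) {
    return(list(product_length = NA_integer_, products = integer(0),
                fwd_offset = NA_integer_, second_offset = NA_integer_))
  }
  if (length(prods) > 1L) {
    warning("ambiguous amplification: a primer binds at multiple sites; ",
            "all products listed")
  }
  lens <- vapply(prods, `[`, numeric(1), 3)
  list(product_length = as.integer(lens[1]),
       products = as.integer(lens),
       fwd_offset = as.integer(prods[[1]][1]),
       second_offset = as.integer(prods[[1]][2]))
}

#' Detect junction-spanning reads
#'
#' A read counts as a junction read when it contains, as an exact substring,
#' the template sequence spanning the junction with `min_flank` bases on
#' each side. Exact matching keeps the assay presence/absence: at error rate
#' 0 no non-fusion read is ever counted.
#'
#' @param reads data.frame with read_id, seq.
#' @param template a `fusion_template`.
#' @param min_flank exact-match bases required on each side (default 15).
#' @return list with `count` and `read_ids`.
#' @export
detect_junction_reads <- function(reads, template, min_flank = 15L) {
  j <- template$junction_offset
  len <- nchar(template$sequence)
  if (j < min_flank || len - j < min_flank) {
    validation_error("template flanks shorter than min_flank")
  }
  kmer <- substr(template$sequence, j - min_flank + 1L, j + min_flank)
  hit <- grepl(kmer, reads$seq, fixed = TRUE)
  list(count = sum(hit), read_ids = reads$read_id[hit])
}

#' Per-sample translocation report
#'
#' @param samples named list; each element has `reads`, optionally
#'   `templates` (from [build_fusion_templates()]) and `expected_products`
#'   (named numeric, e.g. `c(balanced = 327, acentric = 492)`; the expected
#'   gel band sizes are configuration inputs, not derived quantities).
#' @param templates default templates used when a sample supplies none.
#' @param min_flank passed to [detect_junction_reads()].
#' @return data.frame per sample x geometry: junction read count, fraction,
#'   expected PCR product length, and a `band` flag (count > 0; NA for an
#'   empty sample).
#' @export
translocation_report <- function(samples, templates = NULL, min_flank = 15L) {
  rows <- list()
  for (nm in names(samples)) {
    s <- samples[[nm]]
    tpl <- s$templates %||% templates
    if (is.null(tpl)) config_error("no fusion templates supplied")
    for (geo in c("balanced", "acentric")) {
      n <- nrow(s$reads)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = nm, geometry = geo, junction_reads = NA_integer_,
          fraction = NA_real_,
          expected_product = unname(s$expected_products[geo]) %||% NA_real_,
          band = NA, stringsAsFactors = FALSE
        )
        next
      }
      det <- detect_junction_reads(s$reads, tpl[[geo]], min_flank)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = nm, geometry = geo, junction_reads = det$count,
        fraction = det$count / n,
        expected_product = unname(s$expected_products[geo]) %||% NA_real_,
        band = det$count > 0L, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "assumption") <-
    "acentric geometry: head-to-head join of the two upstream segments (assumed from primer orientations)"
  out
}
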