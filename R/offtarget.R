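# Off-target panel analysis for base editing: select candidate sites by the
# mismatch/window-cytosine rule, quantify per-site mutation frequencies with
# the windowed allele machinery, compare treated versus control groups with
# exact tests, and export a long heat-map table.

#' Read an off-target candidate panel from TSV
#'
#' Expected columns: site_id, sequence (protospacer-like, L nt), pam,
#' locus_label, source (e.g. circle_seq or predicted). Lines starting with
#' '#' are ignored.
#'
#' @param path TSV file.
#' @return data.frame of candidate sites.
#' @export
read_offtarget_panel <- function(path) {
  if (!file.exists(path)) config_error(paste0("panel TSV not found: ", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("site_id", "sequence", "pam", "locus_label", "source")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    config_error(paste0("panel TSV lacks columns: ",
                        paste(missing, collapse = ", ")))
  }
  df$sequence <- toupper(df$sequence)
  df$pam <- toupper(df$pam)
  df
}

# mismatch positions (PAM-distal numbering) between two equal-length sequences
mismatch_positions <- function(site, guide) {
  a <- strsplit(site, "", fixed = TRUE)[[1]]
  b <- strsplit(guide, "", fixed = TRUE)[[1]]
  which(a != b)
}

#' Select the base-editing off-target panel
#'
#' Keeps candidate sites with at most `max_mismatches` mismatches relative
#' to the on-target guide (boundary inclusive) AND at least one cytosine on
#' the protospacer strand inside the editing window. Candidates whose length
#' differs from the guide are rejected. A per-candidate selection log with
#' reasons is returned alongside the panel.
#'
#' @param candidates data.frame as from [read_offtarget_panel()].
#' @param guide on-target protospacer sequence.
#' @param max_mismatches mismatch ceiling (default 3).
#' @param edit_window inclusive PAM-distal position interval (default 4..8).
#' @return list with `panel` (selected rows plus mismatch annotation columns)
#'   and `log` (site_id, kept, reason).
#' @export
select_be_panel <- function(candidates, guide, max_mismatches = 3L,
                            edit_window = c(4L, 8L)) {
  L <- nchar(guide)
  keep <- logical(nrow(candidates))
  reason <- character(nrow(candidates))
  mm_str <- character(nrow(candidates))
  n_mm <- integer(nrow(candidates))
  has_c <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    s <- candidates$sequence[i]
    if (nchar(s) != L) {
      reason[i] <- paste0("length ", nchar(s), " != guide length ", L)
      next
    }
    mm <- mismatch_positions(s, guide)
    n_mm[i] <- length(mm)
    mm_str[i] <- paste(mm, collapse = ",")
    win <- substr(s, edit_window[1], edit_window[2])
    has_c[i] <- grepl("C", win, fixed = TRUE)
    if (length(mm) > max_mismatches) {
      reason[i] <- paste0(length(mm), " mismatches > ", max_mismatches)
    } else if (!has_c[i]) {
      reason[i] <- "no cytosine in the editing window"
    } else {
      keep[i] <- TRUE
      reason[i] <- "selected"
    }
  }
  panel <- candidates[keep, , drop = FALSE]
  panel$n_mismatches <- n_mm[keep]
  panel$mismatch_positions <- mm_str[keep]
  panel$has_window_C <- has_c[keep]
  rownames(panel) <- NULL
  list(panel = panel,
       log = data.frame(site_id = candidates$site_id, kept = keep,
                        reason = reason, stringsAsFactors = FALSE))
}

#' Build a guide target for one off-target site
#'
#' Embeds the site protospacer and PAM (plus strand) between flanking
#' sequences so the windowed quantification machinery can run on per-site
#' amplicons.
#'
#' @param site_id,site_seq,pam site identity and sequences.
#' @param flank5,flank3 flanking sequences (each at least
#'   `quant_halfwidth` long around the cut).
#' @param quant_halfwidth window half-width (default 15).
#' @param edit_window editing window (default 4..8).
#' @return a `guide_target`.
#' @export
site_target <- function(site_id, site_seq, pam, flank5, flank3,
                        quant_halfwidth = 15L, edit_window = c(4L, 8L)) {
  guide_target(
    target_id = site_id,
    amplicon_seq = paste0(flank5, site_seq, pam, flank3),
    protospacer = site_seq, pam = pam, strand = "+",
    protospacer_start = nchar(flank5),
    quant_halfwidth = quant_halfwidth, edit_window = edit_window
  )
}

#' Per-site mutation counts
#'
#' Runs windowed allele quantification on the site's amplicon and counts
#' edited reads: the read mass of non-reference alleles above the frequency
#' floor. Returns integer counts suitable for exact tests. When no usable
#' reads remain the entry is absent (NA counts), which is distinct from an
#' observed zero.
#'
#' @param reads data.frame with read_id, seq, qual.
#' @param site a `guide_target` for the site (see [site_target()]).
#' @param cfg a [run_config()].
#' @return list with `edited`, `total`, `absent`.
#' @export
site_mutation_frequency <- function(reads, site, cfg = run_config()) {
  tab <- tryCatch(build_allele_table(reads, site, cfg),
                  crispredit_data_error = function(e) NULL)
  if (is.null(tab)) return(list(edited = NA_integer_, total = NA_integer_,
                                absent = TRUE))
  edited <- sum(tab$records$count[tab$records$edits != ""])
  list(edited = as.integer(edited), total = tab$usable_reads, absent = FALSE)
}

#' Compare treated versus control editing per site
#'
#' Default method is a two-sided Fisher exact test on edited/total counts
#' pooled within each group per site, with Benjamini-Hochberg adjustment
#' across panel sites; a site is significant at q < 0.05. `method = "rank"`
#' instead applies a two-sided Wilcoxon rank-sum test to per-sample edited
#' fractions (useful when per-animal dispersion matters). Unadjusted
#' p-values are always emitted alongside q-values.
#'
#' @param counts data.frame with columns site_id, group ("treated" or
#'   "control"), sample_id, edited, total (NA rows are dropped as absent).
#' @param method `"fisher"` (pooled counts) or `"rank"` (per-sample).
#' @return data.frame per site: pooled counts and frequencies per group,
#'   p_value, q_value, significant, method. Sites with all-zero totals get
#'   NA p-values and are never significant.
#' @export
compare_groups <- function(counts, method = c("fisher", "rank")) {
  method <- match.arg(method)
  if (!all(counts$group %in% c("treated", "control"))) {
    config_error("group must be 'treated' or 'control'")
  }
  counts <- counts[!is.na(counts$edited) & !is.na(counts$total), , drop = FALSE]
  sites <- unique(counts$site_id)
  rows <- lapply(sites, function(sid) {
    d <- counts[counts$site_id == sid, , drop = FALSE]
    tr <- d[d$group == "treated", , drop = FALSE]
    ct <- d[d$group == "control", , drop = FALSE]
    te <- sum(tr$edited); tt <- sum(tr$total)
    ce <- sum(ct$edited); cto <- sum(ct$total)
    p <- NA_real_
    if (tt + cto > 0) {
      if (method == "fisher") {
        m <- matrix(c(te, tt - te, ce, cto - ce), nrow = 2)
        p <- stats::fisher.test(m)$p.value
      } else {
        fx <- tr$edited / tr$total
        fy <- ct$edited / ct$total
        p <- tryCatch(
          suppressWarnings(stats::wilcox.test(fx, fy)$p.value),
          error = function(e) NA_real_
        )
      }
    }
    data.frame(site_id = sid, treated_edited = te, treated_total = tt,
               control_edited = ce, control_total = cto,
               treated_freq = if (tt > 0) te / tt else NA_real_,
               control_freq = if (cto > 0) ce / cto else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < 0.05
  out$method <- method
  out
}

#' Long heat-map table for the off-target panel
#'
#' One row per (site, sample): edited fraction (NA when the site/sample
#' entry is absent), the mismatch mask relative to the on-target guide in
#' the requested numbering, and the site-level significance flag.
#'
#' @param panel selected panel from [select_be_panel()].
#' @param comparisons output of [compare_groups()].
#' @param per_sample data.frame with site_id, sample_id, group, edited,
#'   total (NA for absent entries).
#' @param numbering `"pam_distal"` or `"pam_proximal"`.
#' @param L protospacer length (default 20).
#' @return data.frame ready for heat-map plotting.
#' @export
heatmap_table <- function(panel, comparisons, per_sample,
                          numbering = "pam_distal", L = 20L) {
  mm_of <- function(sid) {
    s <- panel$mismatch_positions[panel$site_id == sid]
    if (!length(s) || s == "") return("")
    pos <- as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
    if (numbering == "pam_proximal") {
      pos <- convert_position(pos, "pam_distal", "pam_proximal", L)
    }
    paste(sort(pos), collapse = ",")
  }
  sig_of <- function(sid) {
    v <- comparisons$significant[comparisons$site_id == sid]
    if (length(v)) v[1] else NA
  }
  data.frame(
    site_id = per_sample$site_id,
    sample_id = per_sample$sample_id,
    group = per_sample$group,
    frequency = ifelse(is.na(per_sample$total) | per_sample$total == 0,
                       NA_real_, per_sample$edited / per_sample$total),
    mismatch_positions = vapply(per_sample$site_id, mm_of, character(1)),
    numbering = numbering,
    significant = vapply(per_sample$site_id, sig_of, logical(1)),
    stringsAsFactors = FALSE
  )
}
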