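# Target geometry: protospacer/PAM placement on a reference amplicon,
# the predicted cleavage site, the quantification window used for allele
# consolidation, and the base-editing window.

#' Construct and validate a guide target
#'
#' A `guide_target` ties a guide RNA protospacer to a reference amplicon:
#' where the protospacer sits (strand-aware), where the NGG PAM is, where
#' SpCas9 is predicted to cut (blunt cut 3 bp 5' of the PAM, i.e. between
#' protospacer positions 17 and 18 in PAM-distal numbering), the window
#' around the cut used to consolidate alleles, and the reading-frame anchor
#' used to translate alleles.
#'
#' Coordinates are 0-based half-open in amplicon (plus-strand) space.
#' Protospacer positions are 1..L; PAM-distal numbering puts position 1 at
#' the protospacer 5' end, PAM-proximal numbering puts position 1 next to
#' the PAM (`p' = L + 1 - p`).
#'
#' @param target_id label for the target.
#' @param amplicon_seq reference amplicon, uppercase ACGTN.
#' @param protospacer 20- or 21-nt protospacer sequence (protospacer strand).
#' @param pam 3-nt PAM (protospacer strand), must match NGG.
#' @param strand `"+"` or `"-"`: strand of the protospacer relative to the
#'   amplicon. The protospacer footprint on the plus strand is
#'   `[protospacer_start, protospacer_start + L)` on either strand.
#' @param protospacer_start 0-based plus-strand offset of the protospacer
#'   footprint.
#' @param frame_anchor 0-based amplicon coordinate of the first base of an
#'   in-frame codon, or `NA` when translation is not needed.
#' @param cds_bounds length-2 integer vector, 0-based half-open interval of
#'   translatable sequence; `NA` when translation is not needed.
#' @param quant_halfwidth bases on each side of the cut coordinate in the
#'   quantification window (default 15, a 30-bp window).
#' @param edit_window inclusive protospacer-position interval (PAM-distal
#'   numbering) where the base editor deaminates; default `c(4, 8)`.
#' @return an object of class `guide_target`.
#' @export
guide_target <- function(target_id, amplicon_seq, protospacer, pam, strand,
                         protospacer_start, frame_anchor = NA_integer_,
                         cds_bounds = c(NA_integer_, NA_integer_),
                         quant_halfwidth = 15L, edit_window = c(4L, 8L)) {
  t <- structure(
    list(
      target_id = as.character(target_id),
      amplicon_seq = toupper(amplicon_seq),
      protospacer = toupper(protospacer),
      pam = toupper(pam),
      strand = strand,
      protospacer_start = as.integer(protospacer_start),
      frame_anchor = as.integer(frame_anchor),
      cds_bounds = as.integer(cds_bounds),
      quant_halfwidth = as.integer(quant_halfwidth),
      edit_window = as.integer(edit_window)
    ),
    class = "guide_target"
  )
  problems <- validate_guide_target(t)
  if (length(problems)) {
    validation_error(paste0(
      "invalid target '", target_id, "':\n  - ",
      paste(problems, collapse = "\n  - ")
    ))
  }
  t
}

# returns a character vector of violations (empty when valid)
validate_guide_target <- function(t) {
  p <- character()
  L <- nchar(t$protospacer)
  amp_len <- nchar(t$amplicon_seq)
  if (!is_dna(t$amplicon_seq)) p <- c(p, "amplicon_seq is not uppercase ACGTN")
  if (!is_dna(t$protospacer) || !(L %in% c(20L, 21L))) {
    p <- c(p, "protospacer must be a 20- or 21-nt ACGTN string")
  }
  if (!t$strand %in% c("+", "-")) p <- c(p, "strand must be '+' or '-'")
  if (!grepl("^[ACGTN]GG$", t$pam)) {
    p <- c(p, paste0("PAM '", t$pam, "' does not match NGG"))
  }
  if (length(p)) return(p)  # geometry checks below need sane fields

  s <- t$protospacer_start
  if (s < 0 || s + L > amp_len) {
    return(c(p, "protospacer footprint outside amplicon"))
  }
  footprint <- substr(t$amplicon_seq, s + 1L, s + L)
  observed <- if (t$strand == "+") footprint else revcomp(footprint)
  if (observed != t$protospacer) {
    p <- c(p, paste0("protospacer does not match amplicon at offset ", s,
                     " (", t$strand, " strand): found ", observed))
  }
  # PAM immediately 3' of the protospacer on the protospacer strand
  pam_iv <- if (t$strand == "+") c(s + L, s + L + 3L) else c(s - 3L, s)
  if (pam_iv[1] < 0 || pam_iv[2] > amp_len) {
    p <- c(p, "PAM outside amplicon")
  } else {
    pam_fp <- substr(t$amplicon_seq, pam_iv[1] + 1L, pam_iv[2])
    pam_obs <- if (t$strand == "+") pam_fp else revcomp(pam_fp)
    if (pam_obs != t$pam) {
      p <- c(p, paste0("PAM does not match amplicon: found ", pam_obs))
    }
  }
  if (!length(p)) {
    qw <- c(cut_site(t) - t$quant_halfwidth, cut_site(t) + t$quant_halfwidth)
    if (qw[1] < 0 || qw[2] > amp_len) {
      p <- c(p, paste0("quantification window [", qw[1], ",", qw[2],
                       ") outside amplicon of length ", amp_len))
    }
  }
  if (!is.na(t$frame_anchor)) {
    if (any(is.na(t$cds_bounds))) {
      p <- c(p, "frame_anchor set but cds_bounds missing")
    } else if ((t$frame_anchor - t$cds_bounds[1]) %% 3L != 0L) {
      p <- c(p, "frame_anchor is not in frame with cds_bounds start")
    } else if (t$cds_bounds[1] < 0 || t$cds_bounds[2] > amp_len ||
               t$frame_anchor < t$cds_bounds[1] ||
               t$frame_anchor >= t$cds_bounds[2]) {
      p <- c(p, "frame_anchor/cds_bounds outside amplicon")
    }
  }
  if (t$quant_halfwidth < 1L) p <- c(p, "quant_halfwidth must be >= 1")
  if (length(t$edit_window) != 2L || t$edit_window[1] > t$edit_window[2] ||
      t$edit_window[1] < 1L || t$edit_window[2] > L) {
    p <- c(p, "edit_window must be an interval within protospacer positions 1..L")
  }
  p
}

#' @export
print.guide_target <- function(x, ...) {
  cat("guide_target '", x$target_id, "': ", nchar(x$amplicon_seq),
      " bp amplicon, protospacer ", x$protospacer, " (", x$strand,
      " strand at ", x$protospacer_start, "), PAM ", x$pam,
      ", cut at ", cut_site(x), "\n", sep = "")
  invisible(x)
}

#' Predicted cleavage coordinate
#'
#' Blunt SpCas9 cut 3 bp 5' of the PAM, i.e. between protospacer positions
#' 17 and 18 in PAM-distal numbering (positions L-3 and L-2 for a 21-mer).
#' Returns the 0-based plus-strand coordinate of the base immediately 3' of
#' the cut.
#'
#' @param t a `guide_target`.
#' @return integer amplicon coordinate.
#' @export
cut_site <- function(t) {
  L <- nchar(t$protospacer)
  if (t$strand == "+") t$protospacer_start + L - 3L else t$protospacer_start + 3L
}

#' Quantification window around the cut site
#'
#' The half-open plus-strand interval `[cut - h, cut + h)` used to
#' consolidate alleles (`h = quant_halfwidth`, 30 bp total at the default).
#'
#' @param t a `guide_target`.
#' @return integer vector `c(start, end)`, 0-based half-open.
#' @export
quant_window <- function(t) {
  cut <- cut_site(t)
  w <- c(cut - t$quant_halfwidth, cut + t$quant_halfwidth)
  if (w[1] < 0 || w[2] > nchar(t$amplicon_seq)) {
    validation_error(paste0("quantification window [", w[1], ",", w[2],
                            ") outside amplicon for target '", t$target_id, "'"))
  }
  w
}

#' Convert protospacer position between numbering conventions
#'
#' PAM-distal numbering counts 1 at the protospacer 5' end; PAM-proximal
#' counts 1 at the PAM-adjacent base. The conversion is `p' = L + 1 - p`
#' when the conventions differ and the identity otherwise, so it is an
#' involution.
#'
#' @param p protospacer position(s), 1-based.
#' @param from,to `"pam_distal"` or `"pam_proximal"`.
#' @param L protospacer length (20 or 21).
#' @return converted position(s).
#' @export
convert_position <- function(p, from, to, L) {
  conv <- c("pam_distal", "pam_proximal")
  if (!(from %in% conv) || !(to %in% conv)) {
    config_error("numbering must be 'pam_distal' or 'pam_proximal'")
  }
  if (any(p < 1L | p > L)) {
    validation_error(paste0("protospacer position out of range 1..", L))
  }
  if (from == to) p else L + 1L - p
}

#' Map a protospacer position to a plus-strand amplicon coordinate
#'
#' @param t a `guide_target`.
#' @param p protospacer position(s), PAM-distal numbering.
#' @return 0-based plus-strand coordinate(s).
#' @export
proto_to_amplicon <- function(t, p) {
  L <- nchar(t$protospacer)
  if (any(p < 1L | p > L)) {
    validation_error(paste0("protospacer position out of range 1..", L))
  }
  if (t$strand == "+") t$protospacer_start + p - 1L else t$protospacer_start + L - p
}

# protospacer-strand base at PAM-distal position p (vectorized)
proto_base <- function(t, p) {
  coord <- proto_to_amplicon(t, p)
  b <- substring(t$amplicon_seq, coord + 1L, coord + 1L)
  if (t$strand == "+") b else comp_base(b)
}

# PAM-distal protospacer positions carrying a protospacer-strand C inside
# the editing window
edit_window_c_positions <- function(t) {
  pos <- seq.int(t$edit_window[1], t$edit_window[2])
  pos[proto_base(t, pos) == "C"]
}

#' Default run configuration
#'
#' @param min_mean_quality minimum arithmetic-mean Phred score for a read to
#'   pass QC (inclusive; default 33).
#' @param allele_freq_floor alleles with frequency strictly below this
#'   fraction are excluded from the table (default 1e-4, i.e. 0.01%).
#' @param top_n_alleles how many top alleles to translate/report (default 10).
#' @param position_numbering `"pam_distal"` or `"pam_proximal"` for report
#'   output.
#' @param rng_seed integer seed recorded into run manifests.
#' @return a `run_config` list.
#' @export
run_config <- function(min_mean_quality = 33, allele_freq_floor = 1e-4,
                       top_n_alleles = 10L, position_numbering = "pam_distal",
                       rng_seed = NA_integer_) {
  if (allele_freq_floor < 0 || allele_freq_floor >= 1) {
    config_error("allele_freq_floor must be in [0, 1)")
  }
  if (top_n_alleles < 1L) config_error("top_n_alleles must be >= 1")
  if (!position_numbering %in% c("pam_distal", "pam_proximal")) {
    config_error("position_numbering must be 'pam_distal' or 'pam_proximal'")
  }
  structure(
    list(min_mean_quality = min_mean_quality,
         allele_freq_floor = allele_freq_floor,
         top_n_alleles = as.integer(top_n_alleles),
         position_numbering = position_numbering,
         rng_seed = as.integer(rng_seed)),
    class = "run_config"
  )
}

#' Load guide targets from a FASTA file and a configuration file
#'
#' The configuration (YAML or JSON) holds a `targets:` list; each entry
#' names a FASTA record in `amplicon` and supplies protospacer geometry.
#' All validation failures across all targets are aggregated into a single
#' error message.
#'
#' @param fasta_path FASTA file of reference amplicons.
#' @param config_path YAML/JSON file with a `targets:` list.
#' @return list of `guide_target` objects, named by `target_id`.
#' @export
load_targets <- function(fasta_path, config_path) {
  if (!file.exists(fasta_path)) config_error(paste0("FASTA not found: ", fasta_path))
  if (!file.exists(config_path)) config_error(paste0("config not found: ", config_path))
  amps <- Biostrings::readDNAStringSet(fasta_path)
  cfg <- read_config_file(config_path)
  if (is.null(cfg$targets) || !length(cfg$targets)) {
    config_error("config has no 'targets' entry")
  }
  errs <- character()
  out <- list()
  for (tc in cfg$targets) {
    id <- tc$target_id
    if (is.null(id)) { errs <- c(errs, "a target entry lacks target_id"); next }
    if (is.null(tc$amplicon) || !tc$amplicon %in% names(amps)) {
      errs <- c(errs, paste0("target '", id, "': FASTA record '",
                             tc$amplicon, "' not found"))
      next
    }
    t <- tryCatch(
      guide_target(
        target_id = id,
        amplicon_seq = as.character(amps[[tc$amplicon]]),
        protospacer = tc$protospacer,
        pam = tc$pam,
        strand = tc$strand,
        protospacer_start = tc$protospacer_start,
        frame_anchor = tc$frame_anchor %||% NA_integer_,
        cds_bounds = unlist(tc$cds_bounds %||% c(NA_integer_, NA_integer_)),
        quant_halfwidth = tc$quant_halfwidth %||% 15L,
        edit_window = unlist(tc$edit_window %||% c(4L, 8L))
      ),
      error = function(e) {
        errs <<- c(errs, conditionMessage(e))
        NULL
      }
    )
    if (!is.null(t)) out[[id]] <- t
  }
  if (length(errs)) {
    validation_error(paste0("target validation failed:\n",
                            paste(errs, collapse = "\n")))
  }
  out
}

read_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
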