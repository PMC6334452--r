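# Pipeline orchestration: a single configuration drives simulation (or FASTQ
# input), windowed quantification, consequence classification, substitution
# profiling, and the optional off-target and translocation stages, then
# writes per-stage TSVs and a run manifest with checksums. The R functions
# are the interface; each stage is also callable on its own.

#' Run the full editing-outcome pipeline
#'
#' Stages run in order: simulate (or load FASTQ) -> quantify -> consequence
#' -> baseedit -> offtarget (optional) -> transloc (optional) -> report.
#' The first stage error aborts the run, tagged with sample and target
#' identifiers. Reruns with the same configuration and seed produce
#' byte-identical outputs.
#'
#' The configuration is a nested list (or a YAML/JSON file path) with:
#' \describe{
#'   \item{seed}{integer; per-sample seeds are derived as seed + sample index.}
#'   \item{run}{optional [run_config()] fields.}
#'   \item{targets}{list of target definitions: either inline `amplicon_seq`
#'     or `fasta` + `amplicon` record name, plus protospacer geometry.}
#'   \item{samples}{list of `list(sample_id, target, source)`; source is
#'     `list(type = "fastq", path = ...)` or `list(type = "simulate",
#'     profile = "be3"|"cas9"|"control", n, p_edit, ...)`.}
#'   \item{stages}{`consequence` and `baseedit` flags (default TRUE);
#'     optional `offtarget` and `transloc` blocks.}
#' }
#'
#' @param config nested list or path to a YAML/JSON configuration file.
#' @param out_dir output directory for TSVs and the manifest; `NULL` keeps
#'   results in memory only.
#' @return a `pipeline_result`: per-sample allele tables, consequence calls,
#'   spectra, null statistics, substitution matrices, optional off-target
#'   and translocation tables, the report, and the run manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config_file(config)
  cfg <- do.call(run_config, config$run %||% list())
  seed <- config$seed %||% 1L
  if (is.null(config$targets) || !length(config$targets)) {
    config_error("config names no targets")
  }
  if (is.null(config$samples) || !length(config$samples)) {
    config_error("config names no samples")
  }
  stages <- config$stages %||% list()
  do_consequence <- stages$consequence %||% TRUE
  do_baseedit <- stages$baseedit %||% TRUE

  targets <- build_config_targets(config$targets)

  # fail fast on configuration errors before any compute
  for (s in config$samples) {
    if (is.null(s$sample_id) || is.null(s$target)) {
      config_error("each sample needs sample_id and target")
    }
    t <- targets[[s$target]]
    if (is.null(t)) {
      config_error(paste0("sample '", s$sample_id, "': unknown target '",
                          s$target, "'"))
    }
    if (isTRUE(do_consequence) && is.na(t$frame_anchor)) {
      config_error(paste0("sample '", s$sample_id, "': consequence stage ",
                          "enabled but target '", t$target_id,
                          "' has no frame_anchor"))
    }
  }

  files <- character(0)
  emit <- function(writer, ..., name) {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    path <- file.path(out_dir, name)
    writer(..., path)
    files <<- c(files, path)
  }

  results <- list()
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    t <- targets[[s$target]]
    sample_seed <- (seed + i) %% .Machine$integer.max
    res <- tryCatch(
      run_sample(s, t, cfg, sample_seed, do_consequence, do_baseedit),
      error = function(e) {
        stop(paste0("stage failure in sample '", s$sample_id, "' (target '",
                    t$target_id, "'): ", conditionMessage(e)), call. = FALSE)
      }
    )
    results[[s$sample_id]] <- res
    emit(function(x, p) write_allele_table(x, p), res$allele_table,
         name = paste0(s$sample_id, ".alleles.tsv"))
    if (!is.null(res$calls)) {
      emit(function(x, p) write_report_tsv(x, p,
             comments = paste0("sample=", s$sample_id)), res$calls,
           name = paste0(s$sample_id, ".consequence.tsv"))
    }
    if (!is.null(res$sub_matrix)) {
      emit(function(x, p) write_substitution_matrix(x, p), res$sub_matrix,
           name = paste0(s$sample_id, ".substitutions.tsv"))
    }
  }

  offtarget <- NULL
  if (!is.null(stages$offtarget)) {
    offtarget <- run_offtarget_stage(stages$offtarget, cfg, seed)
    emit(function(x, p) write_report_tsv(x, p,
           comments = "off-target heat-map table"), offtarget$heatmap,
         name = "offtarget.heatmap.tsv")
    emit(function(x, p) write_report_tsv(x, p,
           comments = "off-target group comparison"), offtarget$comparison,
         name = "offtarget.comparison.tsv")
  }

  transloc <- NULL
  if (!is.null(stages$transloc)) {
    transloc <- run_transloc_stage(stages$transloc, targets, seed)
    emit(function(x, p) write_report_tsv(x, p,
           comments = c("translocation junction report",
                        attr(x, "assumption"))), transloc$report,
         name = "translocation.tsv")
  }

  rep <- pipeline_report(results, offtarget, transloc)
  emit(function(x, p) write_report_tsv(x, p,
         comments = "per-sample outcome summary"), rep$sample_summary,
       name = "report.summary.tsv")

  manifest <- list(
    tool = "crispredit",
    version = as.character(utils::packageVersion("crispredit")),
    seed = seed,
    config = config,
    stage_counts = lapply(results, function(r) {
      tb <- r$allele_table
      list(total = tb$total_reads, qc_passing = tb$qc_passing_reads,
           unalignable = tb$unalignable, non_spanning = tb$non_spanning,
           usable = tb$usable_reads, alleles = nrow(tb$records))
    }),
    outputs = if (length(files)) {
      data.frame(path = basename(files),
                 md5 = unname(tools::md5sum(files)),
                 stringsAsFactors = FALSE)
    } else NULL
  )
  if (!is.null(out_dir)) {
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  structure(
    list(samples = results, offtarget = offtarget, transloc = transloc,
         report = rep, manifest = manifest),
    class = "pipeline_result"
  )
}

build_config_targets <- function(target_cfgs) {
  targets <- list()
  for (tc in target_cfgs) {
    amp <- tc$amplicon_seq
    if (is.null(amp)) {
      if (is.null(tc$fasta) || is.null(tc$amplicon)) {
        config_error(paste0("target '", tc$target_id,
                            "': needs amplicon_seq or fasta + amplicon"))
      }
      recs <- Biostrings::readDNAStringSet(tc$fasta)
      if (!tc$amplicon %in% names(recs)) {
        config_error(paste0("target '", tc$target_id, "': FASTA record '",
                            tc$amplicon, "' not found"))
      }
      amp <- as.character(recs[[tc$amplicon]])
    }
    targets[[tc$target_id]] <- guide_target(
      target_id = tc$target_id, amplicon_seq = amp,
      protospacer = tc$protospacer, pam = tc$pam, strand = tc$strand,
      protospacer_start = tc$protospacer_start,
      frame_anchor = tc$frame_anchor %||% NA_integer_,
      cds_bounds = unlist(tc$cds_bounds %||% c(NA_integer_, NA_integer_)),
      quant_halfwidth = tc$quant_halfwidth %||% 15L,
      edit_window = unlist(tc$edit_window %||% c(4L, 8L))
    )
  }
  targets
}

sample_profile <- function(src, t) {
  switch(src$profile %||% "control",
    be3 = be3_profile(t, p_edit = src$p_edit %||% 0.25,
                      purity = src$purity %||% 0.90,
                      byproduct_weight = src$byproduct_weight %||% 0.05,
                      indel_weight = src$indel_weight %||% 0.05),
    cas9 = cas9_profile(t, p_edit = src$p_edit %||% 0.25),
    control = editing_profile(0, list()),
    config_error(paste0("unknown profile '", src$profile, "'"))
  )
}

run_sample <- function(s, t, cfg, seed, do_consequence, do_baseedit) {
  src <- s$source %||% list(type = "simulate", profile = "control", n = 1000L)
  if ((src$type %||% "simulate") == "fastq") {
    reads <- read_fastq(src$path)
    truth <- NULL
  } else {
    err <- error_model(per_base_error = src$per_base_error %||% 0.001)
    sim <- simulate_reads(t, sample_profile(src, t), err,
                          n = src$n %||% 10000L, seed = seed,
                          id_prefix = s$sample_id)
    reads <- sim$reads
    truth <- sim$truth
  }
  tab <- build_allele_table(reads, t, cfg, sample_id = s$sample_id)
  calls <- NULL; nulls <- NULL
  if (isTRUE(do_consequence)) {
    calls <- classify_alleles(tab, t)
    nulls <- null_allele_stats(tab, calls)
  }
  subm <- if (isTRUE(do_baseedit)) substitution_matrix(reads, t, cfg) else NULL
  list(sample_id = s$sample_id, target_id = t$target_id,
       allele_table = tab, calls = calls,
       spectrum = mutation_spectrum(tab), null_stats = nulls,
       sub_matrix = subm,
       targeted_transition = if (!is.null(subm)) {
         targeted_transition_fraction(subm, t)
       } else NULL,
       indel = indel_rate(tab),
       top_proteins = if (isTRUE(do_consequence)) {
         translate_top_alleles(tab, t, cfg$top_n_alleles)
       } else NULL,
       truth = truth)
}

# off-target stage: select the panel by the mismatch/window-C rule, then
# quantify simulated per-site libraries for each group (p_edit defaults to 0,
# the null expectation for a clean base editor off target)
run_offtarget_stage <- function(oc, cfg, seed) {
  if (is.null(oc$panel) || is.null(oc$guide)) {
    config_error("offtarget stage needs 'panel' (TSV path) and 'guide'")
  }
  candidates <- if (is.character(oc$panel)) {
    read_offtarget_panel(oc$panel)
  } else oc$panel
  sel <- select_be_panel(candidates, oc$guide,
                         max_mismatches = oc$max_mismatches %||% 3L,
                         edit_window = unlist(oc$edit_window %||% c(4L, 8L)))
  flank5 <- oc$flank5 %||% strrep("T", 20)
  flank3 <- oc$flank3 %||% strrep("A", 20)
  n_per_site <- oc$n_per_site %||% 2000L
  err <- error_model(per_base_error = oc$per_base_error %||% 0.001)
  groups <- oc$groups %||% list(treated = c("t1", "t2"), control = c("c1", "c2"))
  per_sample <- list()
  k <- 0L
  for (i in seq_len(nrow(sel$panel))) {
    site <- sel$panel[i, ]
    st <- site_target(site$site_id, site$sequence, site$pam, flank5, flank3,
                      quant_halfwidth = oc$quant_halfwidth %||% 15L)
    p_edit <- (oc$p_edit_per_site %||% list())[[site$site_id]] %||% 0
    for (g in names(groups)) for (sid in groups[[g]]) {
      k <- k + 1L
      p <- if (g == "treated") p_edit else 0
      prof <- if (p > 0) be3_profile(st, p_edit = p) else editing_profile(0, list())
      sim <- simulate_reads(st, prof, err, n_per_site,
                            seed = (seed + 1000L + k) %% .Machine$integer.max)
      f <- site_mutation_frequency(sim$reads, st, cfg)
      per_sample[[k]] <- data.frame(
        site_id = site$site_id, sample_id = sid, group = g,
        edited = f$edited, total = f$total, stringsAsFactors = FALSE
      )
    }
  }
  per_sample <- do.call(rbind, per_sample)
  comparison <- compare_groups(per_sample, method = oc$method %||% "fisher")
  heat <- heatmap_table(sel$panel, comparison, per_sample,
                        numbering = cfg$position_numbering,
                        L = nchar(oc$guide))
  list(selection = sel, per_sample = per_sample, comparison = comparison,
       heatmap = heat)
}

run_transloc_stage <- function(tc, targets, seed) {
  tA <- targets[[tc$target_a %||% ""]]
  tB <- targets[[tc$target_b %||% ""]]
  if (is.null(tA) || is.null(tB)) {
    config_error("transloc stage needs known target_a and target_b")
  }
  templates <- build_fusion_templates(tA, tB)
  expected <- unlist(tc$expected_products %||% c(balanced = NA_real_,
                                                 acentric = NA_real_))
  samples <- list()
  for (i in seq_along(tc$samples %||% list())) {
    sc <- tc$samples[[i]]
    sim <- simulate_fusion_library(
      tA, tB, geometry = sc$geometry %||% "balanced",
      p_fusion = sc$p_fusion %||% 0, n = sc$n %||% 2000L,
      seed = (seed + 2000L + i) %% .Machine$integer.max,
      err = error_model(per_base_error = sc$per_base_error %||% 0)
    )
    samples[[sc$sample_id]] <- list(reads = sim$reads, truth = sim$truth,
                                    expected_products = expected)
  }
  rep <- translocation_report(samples, templates = templates,
                              min_flank = tc$min_flank %||% 15L)
  list(templates = templates, samples = samples, report = rep)
}

#' Summarize pipeline outputs
#'
#' Builds the per-sample outcome summary: edited mass, mutation-type
#' spectrum, absolute and relative null-allele frequencies, targeted
#' transition fraction and indel rate, plus the optional off-target and
#' translocation tables when those stages ran.
#'
#' @param results named per-sample result list from [run_pipeline()].
#' @param offtarget,transloc optional stage outputs.
#' @return list with `sample_summary` (data.frame), `top_proteins` (named
#'   list of data.frames), and `stages_run`.
#' @export
pipeline_report <- function(results, offtarget = NULL, transloc = NULL) {
  rows <- lapply(results, function(r) {
    sp <- r$spectrum
    data.frame(
      sample_id = r$sample_id, target_id = r$target_id,
      usable_reads = r$allele_table$usable_reads,
      n_alleles = nrow(r$allele_table$records),
      edited_mass = sp$edited_mass,
      single_base_change = sp$single_base_change,
      insertion = sp$insertion, deletion = sp$deletion,
      multi_substitution = sp$multi_substitution, mixed = sp$mixed,
      absolute_null = r$null_stats$absolute_null_frequency %||% NA_real_,
      relative_null_pct = r$null_stats$relative_null_percentage %||% NA_real_,
      targeted_transition = r$targeted_transition %||% NA_real_,
      indel_rate = r$indel$indel_rate,
      stringsAsFactors = FALSE
    )
  })
  list(
    sample_summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    top_proteins = lapply(results, `[[`, "top_proteins"),
    stages_run = c(quantify = TRUE,
                   consequence = !is.null(results[[1]]$calls),
                   baseedit = !is.null(results[[1]]$sub_matrix),
                   offtarget = !is.null(offtarget),
                   transloc = !is.null(transloc))
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$samples), "sample(s); stages run:",
      paste(names(which(x$report$stages_run)), collapse = ", "), "\n")
  print(x$report$sample_summary)
  invisible(x)
}
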