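# Internal helpers shared across modules. All coordinates are 0-based
# half-open internally; report output is 1-based inclusive.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

is_dna <- function(x) {
  length(x) == 1L && is.character(x) && grepl("^[ACGTN]+$", x)
}

# condition constructors: configuration errors (bad inputs/config) vs
# validation/data errors (inputs read fine but violate a contract)
config_error <- function(msg) {
  stop(structure(
    class = c("crispredit_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(msg) {
  stop(structure(
    class = c("crispredit_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

data_error <- function(msg) {
  stop(structure(
    class = c("crispredit_data_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# run code under a local, seeded RNG without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# mean Phred score of a Phred+33 quality string
phred_mean <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1), USE.NAMES = FALSE)
}

phred_string <- function(q_int) {
  intToUtf8(pmin(pmax(q_int, 2L), 41L) + 33L)
}

#' Write a TSV table with '#' comment header lines
#'
#' All tabular outputs carry an explicit coordinate-convention token so that
#' downstream consumers never have to guess 0- vs 1-based numbering.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param comments character vector of header comment lines (without '#').
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in c(comments, "coords=1-based-inclusive")) {
    writeLines(paste0("# ", cm), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
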