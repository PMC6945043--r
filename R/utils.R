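# Internal helpers shared across modules.

#' @importFrom methods is
#' @importFrom stats ppois pchisq rpois runif rbinom rmultinom setNames
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_ALPHABET_STRICT <- c("A", "C", "G", "T", "N")
PROTEIN_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

abort <- function(..., class = "gatafam_error") {
  stop(errorCondition(paste0(...), class = c(class, "gatafam_error")))
}

assert_that <- function(cond, ..., class = "gatafam_error") {
  if (!isTRUE(cond)) abort(..., class = class)
  invisible(TRUE)
}

#' Set or query the package log level
#'
#' Pipeline stages report record counts at level `"info"`; per-record
#' decisions (pseudogene reasons, truncated promoters, unresolved splice
#' gaps) are reported at `"debug"`.
#'
#' @param level One of `"quiet"`, `"info"`, `"debug"`. Missing returns the
#'   current level.
#' @return The active log level, invisibly when setting.
#' @export
gf_log_level <- function(level) {
  if (missing(level)) {
    return(getOption("gatafam.log_level", "quiet"))
  }
  level <- match.arg(level, c("quiet", "info", "debug"))
  options(gatafam.log_level = level)
  invisible(level)
}

log_info <- function(...) {
  if (gf_log_level() %in% c("info", "debug")) message("[gatafam] ", ...)
  invisible(NULL)
}

log_debug <- function(...) {
  if (gf_log_level() == "debug") message("[gatafam:debug] ", ...)
  invisible(NULL)
}

# Reverse complement of a plain character DNA string (IUPAC-aware).
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# IUPAC code -> base set, uppercase.
iupac_sets <- function() {
  lapply(Biostrings::IUPAC_CODE_MAP, function(s) strsplit(s, "")[[1]])
}

# Integer RNG substream: derive a distinct, reproducible seed from a master
# seed and a stream index, staying within 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 2654435761 + stream * 97911) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
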