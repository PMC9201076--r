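#' @importFrom stats predict rbinom rnorm runif setNames
#' @importFrom utils head read.csv write.csv
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## note-type whitelists used when abstracting each stage kind
CLINICAL_NOTE_TYPES <- c("operative", "history_physical", "discharge_transfer", "progress")
PATHOLOGICAL_NOTE_TYPES <- c("pathology", "history_physical", "progress")
NOTE_TYPES <- c("operative", "history_physical", "discharge_transfer",
                "progress", "pathology", "radiology", "other")

AXES <- c("T", "N", "M")
## legal mention-level numeral ranges per axis
AXIS_RANGE <- list(T = 0:4, N = 0:3, M = 0:1)

STAGE_KINDS <- c("clinical", "pathological")
TASKS <- c("cT", "cN", "cM", "pT", "pN")
TASK_KIND <- c(cT = "clinical", cN = "clinical", cM = "clinical",
               pT = "pathological", pN = "pathological")
TASK_AXIS <- c(cT = "T", cN = "N", cM = "M", pT = "T", pN = "N")
## dichotomized category domains for each patient-level binary task
TASK_LEVELS <- list(cT = c("T1-2", "T3-4"), cN = c("N0", "N1"),
                    cM = c("M0", "M1"), pT = c("T2", "T3-4"),
                    pN = c("N0", "N1"))

tnm_verbose <- function() isTRUE(getOption("tnmstager.verbose", FALSE))

tnm_log <- function(..., force = FALSE) {
  if (force || tnm_verbose()) message("[tnmstager] ", ...)
}

#' Write a file atomically
#'
#' Writes via a temporary file in the destination directory followed by a
#' rename, so readers never observe a half-written artifact.
#'
#' @param path destination path.
#' @param writer function of one argument (a path) that writes the content.
#' @return `path`, invisibly.
#' @keywords internal
write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".tnm_tmp_", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) { # nocov start
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  } # nocov end
  invisible(path)
}

## escape a literal string for use inside a perl regex
regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

## 0-based half-open character span helpers built on gregexpr output
match_spans <- function(m) {
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L, end = as.integer(m) - 1L + len)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
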