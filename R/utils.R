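#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate filter select group_by summarise ungroup arrange
#'   left_join inner_join bind_rows across all_of n distinct rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rgamma rpois rnbinom runif setNames
#' @importFrom utils packageVersion head
NULL

# 32-bit FNV-1a over raw bytes; returned as 8 hex digits. Used only for
# deterministic content-derived identifiers, not for security.
fnv1a <- function(bytes) {
  h <- 0x811c9dc5
  prime <- 0x01000193
  for (b in as.integer(bytes)) {
    # xor on the low 16 bits only (b < 256); h itself can exceed integer range
    lo16 <- h %% 65536
    h <- (h - lo16) + bitwXor(as.integer(lo16), b)
    # 32-bit modular multiply, split to stay within exact double arithmetic
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * prime) + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

hash_string <- function(x) {
  vapply(x, function(s) fnv1a(utf8ToInt(s)), character(1), USE.NAMES = FALSE)
}

hash_file <- function(path) {
  fnv1a(as.integer(readBin(path, "raw", n = file.size(path))))
}

stop_scfa <- function(..., class = "scfapath_error") {
  stop(errorCondition(sprintf(...), class = c(class, "error")))
}

warn_scfa <- function(...) {
  warning(warningCondition(sprintf(...), class = c("scfapath_warning", "warning")))
}

# split/join helpers for set-valued TSV columns
join_set <- function(x) vapply(x, function(v) paste(v, collapse = ","), character(1))
split_set <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, ",", fixed = TRUE)[[1]]
  })
}
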