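# Internal helpers shared across modules.
#
# All identifier comparisons in the package use byte (C-locale) order so that
# canonical pair orientation, edge-id assignment and every exported artifact
# are independent of the session locale.

# Rank strings in byte order; ties impossible within the sorted unique set.
str_byte_rank <- function(x, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(x), method = "radix")
  match(x, universe)
}

sort_byte <- function(x) {
  if (is.null(x)) return(character(0))
  sort(x, method = "radix")
}

# Orient unordered pairs so that gene_a precedes gene_b in byte order.
# Returns a two-column character data.frame; self-pairs are NOT removed here.
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  u <- sort(unique(c(a, b)), method = "radix")
  ia <- match(a, u)
  ib <- match(b, u)
  swap <- ia > ib
  ga <- ifelse(swap, b, a)
  gb <- ifelse(swap, a, b)
  data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
}

# Separator for pair keys: \r cannot occur in a parsed identifier because
# fields are split on tabs and trimmed of surrounding whitespace.
pair_key <- function(ga, gb) paste(ga, gb, sep = "\r")

set_key <- function(x) paste(x, collapse = "\r")

# Sorted-vector set helpers (integer or character, both pre-sorted).
intersect_sorted <- function(x, y) x[x %in% y]

is_subset <- function(x, y) all(x %in% y)

trim_ws <- function(x) sub("^[ \t]+", "", sub("[ \t]+$", "", x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("pathbic_input_error", "error")))
}

stop_integrity <- function(...) {
  stop(errorCondition(paste0(...), class = c("pathbic_integrity_error", "error")))
}

pathbic_log <- function(level, msg, threshold = getOption("pathbic.log_level", "info")) {
  lv <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (lv[[level]] >= lv[[threshold]]) message(sprintf("[%s] %s", level, msg))
  invisible(NULL)
}
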