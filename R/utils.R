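# Internal helpers shared across modules.

ao_stop <- function(..., class = "aotk_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

ao_warn <- function(..., class = "aotk_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  (is.numeric(x)) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}

#' Test whether a string is an absolute IRI
#'
#' An IRI is considered absolute when it carries a scheme
#' (`scheme ":" ...` with a letter-initial scheme), e.g. `http://...`,
#' `urn:uuid:...`.
#'
#' @param x character vector to test.
#' @return logical vector.
#' @export
is_absolute_iri <- function(x) {
  is.character(x) & !is.na(x) & grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x)
}

# ISO-8601 parse check (UTC timestamps are the package convention).
is_iso8601 <- function(x) {
  if (!is_string(x)) return(FALSE)
  pat <- "^\\d{4}-\\d{2}-\\d{2}([T ]\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?(Z|[+-]\\d{2}:?\\d{2})?)?$"
  grepl(pat, x)
}

# Current time as an ISO-8601 UTC string.
ao_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_ao_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

# Escape a string for use inside N-Triples / Turtle double-quoted literals.
nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

nt_unescape <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    s <- x[[k]]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    buf <- character(0)
    i <- 1L
    n <- length(chars)
    while (i <= n) {
      ch <- chars[[i]]
      if (ch == "\\" && i < n) {
        nxt <- chars[[i + 1L]]
        rep <- switch(nxt,
          "n" = "\n", "r" = "\r", "t" = "\t",
          "\\" = "\\", "\"" = "\"", "'" = "'",
          "u" = NA_character_, "U" = NA_character_,
          NULL
        )
        if (!is.null(rep) && !is.na(rep)) {
          buf <- c(buf, rep); i <- i + 2L; next
        }
        if (!is.null(rep) && is.na(rep)) { # \uXXXX or \UXXXXXXXX
          width <- if (nxt == "u") 4L else 8L
          hex <- paste0(chars[(i + 2L):(i + 1L + width)], collapse = "")
          buf <- c(buf, intToUtf8(strtoi(hex, 16L)))
          i <- i + 2L + width
          next
        }
      }
      buf <- c(buf, ch)
      i <- i + 1L
    }
    out[[k]] <- paste0(buf, collapse = "")
  }
  out
}
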