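# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a validation error
#'
#' All user-input validation failures raised by this package carry the
#' condition class `geovar_error`, so callers (and the command-line
#' wrapper) can distinguish bad input (exit 1) from usage mistakes
#' (exit 2) and genuine bugs.
#'
#' @param ... message parts, pasted together.
#' @param class additional condition class(es), prepended.
#' @noRd
gv_stop <- function(..., class = character()) {
  stop(structure(
    class = c(class, "geovar_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

gv_usage_stop <- function(...) {
  stop(structure(
    class = c("geovar_usage_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

#' Derive a deterministic stage seed from a root seed
#'
#' One root seed drives a whole simulated dataset; each stage (site
#' placement, colonization order, sequence evolution, permutations)
#' re-seeds from a value mixed with the stage name, so stages are
#' individually reproducible. Kept below 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed integer root seed.
#' @param stage character stage tag.
#' @return integer seed in \[0, 2^31 - 20).
#' @noRd
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h * 7919) %% 2147483629)
}

# all permutations of 1:n as an n! x n matrix, lexicographic order
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# format a numeric so that read-back reproduces the double exactly,
# preferring the short decimal form when it already round-trips
format_exact <- function(x, digits = NA) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    if (!is.na(digits)) {
      s <- formatC(v, digits = digits, format = "g")
      return(trimws(s))
    }
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}
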