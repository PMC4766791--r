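#' Largest-remainder apportionment
#'
#' Distribute `n` integer units across categories in proportion to `shares`.
#' Each category first receives the floor of its exact (real-valued) quota
#' `n * shares / sum(shares)`; the remaining units go to the categories with
#' the largest fractional remainders.  The result never deviates from the
#' exact quota by 1 or more in any category.
#'
#' @param shares named non-negative numeric vector of weights (need not sum
#'   to one).
#' @param n total number of units to distribute (non-negative integer).
#' @return named integer vector summing to `n`, same names as `shares`.
#' @examples
#' largest_remainder(c(A = .5, B = .3, C = .2), 7)  # 4, 2, 1
#' @export
largest_remainder <- function(shares, n) {
  stopifnot(is.numeric(shares), length(shares) >= 1L, all(shares >= 0),
            sum(shares) > 0, length(n) == 1L, n >= 0, n == round(n))
  if (is.null(names(shares))) names(shares) <- as.character(seq_along(shares))
  quota <- n * shares / sum(shares)
  base <- floor(quota)
  left <- as.integer(round(n - sum(base)))
  out <- base
  if (left > 0L) {
    # ties on the fractional remainder broken by name so allocation is
    # deterministic regardless of input order
    rem <- quota - base
    idx <- order(-rem, names(shares))[seq_len(left)]
    out[idx] <- out[idx] + 1L
  }
  storage.mode(out) <- "integer"
  out
}

# stop() with a condition class so callers can distinguish error families
hv_stop <- function(msg, class) {
  stop(structure(class = c(class, "hierVA_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

hv_warn <- function(msg, class) {
  warning(structure(class = c(class, "hierVA_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# path to a bundled config file
#' Path to a bundled hierVA configuration file
#'
#' @param ... file path components under the package's `extdata` directory;
#'   with no arguments, lists the available files.
#' @return a file path, or a character vector of available files.
#' @export
hierva_example <- function(...) {
  if (...length() == 0L) {
    return(list.files(system.file("extdata", package = "hierVA"),
                      recursive = TRUE))
  }
  path <- system.file("extdata", ..., package = "hierVA")
  if (identical(path, "")) {
    hv_stop(sprintf("no bundled file '%s'", file.path(...)), "hierVA_io_error")
  }
  path
}
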