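#' @keywords internal
"_PACKAGE"

#' Derive a stream of child seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed through
#' this function: each (seed, n) pair deterministically yields `n` child
#' seeds, and the first `k` children are unchanged when `n` grows. This is
#' what lets a simulation add samples without perturbing earlier ones.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
seed_stream <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate code under a given seed, restoring the caller's RNG state
#'
#' Used throughout the package so that functions never disturb the user's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  force(code)
}

#' Read a tab-separated table
#'
#' TSV dialect used throughout: tab-separated, UTF-8, '#' comment lines
#' ignored, no quoting.
#'
#' @param path file path.
#' @return data.frame with columns as character/numeric, names untouched.
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Write a tab-separated table
#'
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

stop_schema <- function(...) stop("schema error: ", ..., call. = FALSE)
stop_parse <- function(...) stop("parse error: ", ..., call. = FALSE)
stop_integrity <- function(...) stop("integrity error: ", ..., call. = FALSE)
stop_config <- function(...) stop("config error: ", ..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
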