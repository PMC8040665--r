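#' Derive a reproducible sub-seed from a master seed and a label path
#'
#' Stage-level randomness is isolated by hashing the stage label into the
#' master seed, so adding or reordering downstream stages never perturbs the
#' random stream of an earlier stage.
#'
#' @param seed master integer seed
#' @param ... character labels identifying the consumer (e.g. stage name)
#' @return an integer seed in [1, 2^31 - 2]
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 104729
  for (ch in utf8ToInt(paste(c(...), collapse = "/"))) {
    h <- (h * 131 + ch) %% 2147483563
  }
  as.integer((abs(seed) %% 2147483563 + h) %% 2147483562 + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix for configuration errors
config_error <- function(...) stop("configuration error: ", ..., call. = FALSE)

# Write a data.frame as TSV with the conventions used throughout the
# pipeline: header row, no quoting beyond what is necessary, empty string
# for missing values.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", na.strings = "", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8", ...)
}
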