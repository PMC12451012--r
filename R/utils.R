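# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Natural ordering of chromosome names: numeric bodies (chr1 < chr2 < chr10,
# with or without the "chr" prefix) first, anything else after, alphabetically.
#' @keywords internal
#' @noRd
chromosome_order <- function(chroms) {
  u <- unique(as.character(chroms))
  body <- sub("^chr", "", u, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(body))
  recognized <- !is.na(num)
  c(u[recognized][order(num[recognized], u[recognized])],
    sort(u[!recognized]))
}

#' @keywords internal
#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# non-standard-evaluation columns used in ggplot calls
if (getRversion() >= "2.15.1") {
  utils::globalVariables(c("gini", "neg_log10_p"))
}
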