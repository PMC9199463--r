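#' @import methods
#' @importFrom stats loess predict pnorm rnbinom rlnorm rgamma runif var sd
#' @importFrom utils write.table read.delim combn packageVersion
NULL

# Evaluate expr under a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a reproducible per-label seed from a master seed
#'
#' Adds a stable (platform-independent) hash of a character label to a master
#' seed, modulo `.Machine$integer.max`, so that each tissue or stage gets its
#' own reproducible random stream.
#'
#' @param seed Master integer seed.
#' @param label Character scalar.
#' @return An integer seed.
#' @export
#' @examples
#' deriveSeed(42L, "lung")
deriveSeed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  codes <- utf8ToInt(label)
  h <- 0
  for (i in seq_along(codes)) h <- (h * 31 + codes[i]) %% 1000003
  as.integer((as.numeric(seed) + h) %% (.Machine$integer.max - 1L))
}

# signif() that leaves NA/Inf alone and keeps integers exact
signif6 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) signif(x, 6) else x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map mouse gene symbols to human ortholog symbols
#'
#' Symbol-level ortholog mapping by case convention: mouse symbols
#' (capitalized, e.g. `"Higd1b"`) become the upper-case human symbol
#' (`"HIGD1B"`). This covers the one-to-one symbol-identical orthologs used
#' when porting mouse-derived marker lists to human datasets; genuine
#' one-to-many homology is out of scope.
#'
#' @param genes Character vector of mouse gene symbols.
#' @return Character vector of human symbols.
#' @export
#' @examples
#' mouseToHumanSymbols(c("Higd1b", "Notch3"))
mouseToHumanSymbols <- function(genes) {
  stopifnot(is.character(genes))
  toupper(genes)
}
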