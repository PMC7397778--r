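#' @useDynLib Ki67Adapt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package funnel through this so that nothing leaks global random state.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
deriveSeed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 16807
  as.integer(s %% 2147483629) + 1L
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Nucleus class labels
#'
#' The three nucleus categories used throughout the package, in fixed
#' channel order: immunopositive tumor (IPT, DAB-brown Ki-67-positive),
#' immunonegative tumor (INT, hematoxylin-blue), and nontumor (NT).
#' @return Character vector of the three labels.
#' @export
nucleusClasses <- function() c("IPT", "INT", "NT")

checkLabels <- function(labels) {
  if (length(labels) && !all(labels %in% nucleusClasses()))
    stop("labels must be in {IPT, INT, NT}")
  invisible(TRUE)
}

# Empty annotation/detection tables with the canonical columns.
emptyAnnotations <- function() {
  data.frame(row = integer(0), col = integer(0), label = character(0),
             stringsAsFactors = FALSE)
}

emptyDetections <- function() {
  data.frame(row = integer(0), col = integer(0), label = character(0),
             score = numeric(0), stringsAsFactors = FALSE)
}
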