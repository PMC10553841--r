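#' @useDynLib riboTE, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median model.matrix oneway.test pnorm rgamma rpois
#'   runif rbinom rlnorm rnorm setNames wilcox.test lm coef quantile var
#' @importFrom utils read.delim write.table head
NULL

# geometric mean of a strictly positive vector
geomean <- function(x) exp(mean(log(x)))

# reverse complement for plain character DNA (used where a DNAString would
# be overkill; Biostrings does the heavy lifting on real sequence sets)
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Seed the session RNG with a fully specified generator
#'
#' All simulators call this so that a given seed reproduces outputs
#' byte-identically regardless of the calling session's RNG settings.
#'
#' @param seed integer seed.
#' @keywords internal
set_sim_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  invisible(seed)
}

msg <- function(...) message("[riboTE] ", sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a
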