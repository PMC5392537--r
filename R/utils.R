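# small shared helpers (internal)

#' Clamp values to the unit interval
#'
#' Beta values are methylation fractions and must lie in \[0, 1\]; several
#' operations (additive batch offsets, Gaussian noise, mean-shift
#' normalization, conversion correction) can push values outside and are
#' clamped back.
#'
#' @param x numeric vector.
#' @return `x` with values below 0 set to 0 and above 1 set to 1.
#' @keywords internal
clamp01 <- function(x) pmin(1, pmax(0, x))

# moment-based sample skewness g1 = m3 / m2^(3/2); 0 for symmetric errors
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

mae <- function(truth, pred) mean(abs(truth - pred))

# reverse complement on plain character vectors (delegates to Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Names of the CpG (beta value) columns of a beta matrix
#'
#' @param x a beta matrix `data.frame` (columns `sample_id`, `age`, ...,
#'   then `cg*` columns).
#' @return character vector of CpG column names.
#' @export
beta_cols <- function(x) grep("^cg", names(x), value = TRUE)

# run code with a private RNG stream so callers' RNG state is untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
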