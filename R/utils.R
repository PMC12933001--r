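# Internal helpers shared across modules.

#' @importFrom stats approx coef cor cor.test cov glm lm median pnorm
#'   prcomp predict prop.test qnorm qt quantile quasibinomial rlnorm rnorm
#'   runif sd setNames spline
#' @importFrom utils head read.csv read.table tail write.csv write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib ecglvh, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Canonical sex encoding
#'
#' Maps common encodings of sex to the package's numeric convention
#' (female = 0, male = 1).
#'
#' @param sex character ("male"/"female", "M"/"F"), logical, factor or
#'   numeric (0/1) vector.
#' @return integer vector with female = 0, male = 1.
#' @export
as_sex <- function(sex) {
  if (is.factor(sex)) sex <- as.character(sex)
  if (is.character(sex)) {
    s <- tolower(trimws(sex))
    out <- ifelse(s %in% c("male", "m", "1"), 1L,
      ifelse(s %in% c("female", "f", "0"), NA_integer_, NA_integer_))
    out[s %in% c("female", "f", "0")] <- 0L
    if (anyNA(out) && !anyNA(sex)) {
      stop_invalid("unrecognised sex value(s): %s",
        paste(unique(sex[is.na(out)]), collapse = ", "))
    }
    return(out)
  }
  if (is.logical(sex)) return(as.integer(sex))
  if (is.numeric(sex)) {
    if (any(!sex %in% c(0, 1) & !is.na(sex))) {
      stop_invalid("numeric sex must be 0 (female) or 1 (male)")
    }
    return(as.integer(sex))
  }
  stop_invalid("cannot interpret sex of class %s", class(sex)[1])
}

# Deterministic per-unit sub-seed derivation; keeps values < 2^31 - 1 so
# they remain representable as R integers.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Sample third standardised moment (skewness).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean(((x - m) / s)^3)
}

canonical_leads <- function() c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
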