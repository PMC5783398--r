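# internal helpers

assert_tokens <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad) > 0) {
    stop(
      "unknown ", what, " token(s): ", paste(bad, collapse = ", "),
      "; allowed tokens are: ", paste(allowed, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(x)
}

assert_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(df)
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used when reproducing printed percentage
#' tables; `base::round()` rounds half to even, which changes e.g. 0.5 -> 0.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(92.5, 5.5))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# canonical "origin -> destination" link keys
link_key <- function(origin, destination) {
  paste(origin, destination, sep = " -> ")
}

# survival function of the Kolmogorov distribution, Q(t) = P(K > t)
kolmogorov_pvalue <- function(t) {
  if (!is.finite(t) || t <= 0) {
    return(1)
  }
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}
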