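#' Probability-domain mean Phred score of a quality vector
#'
#' Per-base Phred scores are converted to error probabilities, averaged, and
#' converted back: \code{-10 * log10(mean(10^(-q/10)))}. This is the read
#' quality convention used by long-read quality filters: a read's chance of
#' error is governed by its mean error probability, not the arithmetic mean
#' of its Phred values (which is always an overestimate of quality, by
#' convexity of \code{10^(-q/10)}).
#'
#' @param quals Integer (or numeric) vector of per-base Phred scores.
#' @return The mean Phred score as a double.
#' @examples
#' mean_phred(rep(20, 100))   # 20
#' mean_phred(c(10, 30))      # ~12.97: the Q10 base dominates
#' @export
mean_phred <- function(quals) {
  if (length(quals) == 0L) stop("mean_phred: empty quality vector")
  -10 * log10(mean(10^(-as.numeric(quals) / 10)))
}

#' Convert between Phred scores, base-call accuracy and error probability
#'
#' `accuracy_from_phred()` returns percent accuracy `100 * (1 - 10^(-q/10))`;
#' Q10 is 90% accuracy, Q30 is 99.9%. `phred_from_error()` is the inverse map
#' from an error probability.
#'
#' @param q Phred score(s), >= 0.
#' @param p Error probability(ies) in (0, 1].
#' @return Percent accuracy, or a Phred score.
#' @examples
#' accuracy_from_phred(10)         # 90
#' phred_from_error(0.001)         # 30
#' @export
accuracy_from_phred <- function(q) {
  if (any(q < 0)) stop("accuracy_from_phred: q must be >= 0")
  100 * (1 - 10^(-q / 10))
}

#' @rdname accuracy_from_phred
#' @export
phred_from_error <- function(p) {
  if (any(p <= 0 | p > 1)) stop("phred_from_error: p must be in (0, 1]")
  -10 * log10(p)
}

#' Phred score equivalent to a clustering radius
#'
#' The integer Phred score at which the expected per-base error rate equals a
#' clustering radius: \code{round(-10 * log10(radius))}. At a 2% radius (98%
#' identity OTUs) this is Q17 — below it, per-base error alone pushes reads
#' outside their own cluster and inflates OTU counts; above it, error-driven
#' inflation collapses.
#'
#' @param radius Divergence fraction in (0, 1), e.g. 0.02 for 98% OTUs.
#' @return Integer Phred score.
#' @examples
#' phred_for_radius(0.02)  # 17
#' @export
phred_for_radius <- function(radius) {
  if (any(radius <= 0 | radius >= 1)) {
    stop("phred_for_radius: radius must be in (0, 1)")
  }
  as.integer(round(-10 * log10(radius)))
}
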