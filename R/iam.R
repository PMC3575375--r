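#' Allele frequency spectra (infinite-alleles data)
#'
#' Under the infinite-alleles model the data reduce to the multiset of
#' allele counts `n_1, ..., n_d` — the frequency spectrum, the
#' sufficient statistic of the model. `frequency_spectrum()` builds one
#' from a vector of positive allele counts (stored sorted in decreasing
#' order; alleles carry no labels); `spectrum_of()` collapses an
#' infinite-sites [incidence_matrix] to its spectrum by forgetting the
#' sites.
#'
#' @param counts Vector of positive integer allele counts.
#' @param m An [incidence_matrix].
#' @return An integer vector of class `freq_spectrum`, sorted
#'   decreasing.
#' @examples
#' spectrum_of(read_incidence_matrix(
#'   system.file("extdata", "foursite.tsv", package = "coalexact")))
#' @export
frequency_spectrum <- function(counts) {
  if (!length(counts) || any(is.na(counts)) || any(counts < 1) ||
      any(counts != as.integer(counts))) {
    abort_domain("allele counts must be positive integers")
  }
  structure(sort(as.integer(counts), decreasing = TRUE),
            class = "freq_spectrum")
}

#' @rdname frequency_spectrum
#' @export
spectrum_of <- function(m) {
  stopifnot(inherits(m, "incidence_matrix"))
  frequency_spectrum(haplotype_freq(m))
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat(sprintf("Allele frequency spectrum (n = %d): %s\n", sum(x),
              paste(unclass(x), collapse = ", ")))
  invisible(x)
}

#' Ewens sampling formula
#'
#' Exact probability of an allele frequency spectrum under the
#' infinite-alleles model at population mutation rate `theta`. With
#' `a_j` the number of alleles seen exactly `j` times in a sample of
#' size `n`,
#'
#' \deqn{P = \frac{n!}{\theta(\theta+1)\cdots(\theta+n-1)}
#'   \prod_j \frac{(\theta/j)^{a_j}}{a_j!}}
#'
#' This is the closed-form analogue of the infinite-sites recursion:
#' for a sample of two identical alleles it reduces to `1/(1+theta)`,
#' matching [exact_probability()] on the zero-mutation gene tree.
#'
#' @param s A [frequency_spectrum] or a bare vector of positive allele
#'   counts.
#' @param theta Positive population mutation rate.
#' @return A probability in `(0, 1]`.
#' @examples
#' esf_probability(c(1, 1), theta = 1)  # theta/(1+theta) = 0.5
#' @export
esf_probability <- function(s, theta) {
  if (!inherits(s, "freq_spectrum")) s <- frequency_spectrum(s)
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta <= 0) {
    abort_domain("theta must be a single positive number")
  }
  n <- sum(s)
  a <- tabulate(unclass(s), nbins = n)
  j <- which(a > 0)
  logp <- lfactorial(n) - sum(log(theta + 0:(n - 1))) +
    sum(a[j] * (log(theta) - log(j)) - lfactorial(a[j]))
  exp(logp)
}
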