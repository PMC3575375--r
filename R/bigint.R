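# Arbitrary-precision non-negative integers for genealogy counts, which
# grow combinatorially. The dynamic program needs only addition, so the
# representation is a little-endian vector of base-1e9 limbs stored as
# doubles.

BIG_BASE <- 1e9

big_new <- function(x = 0) {
  stopifnot(x >= 0, x == round(x), x < 2^53)
  limbs <- numeric()
  repeat {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- x %/% BIG_BASE
    if (x == 0) break
  }
  structure(limbs, class = "coalexact_bigint")
}

big_add <- function(a, b) {
  la <- unclass(a); lb <- unclass(b)
  k <- max(length(la), length(lb))
  la <- c(la, numeric(k - length(la)))
  lb <- c(lb, numeric(k - length(lb)))
  out <- numeric(k)
  carry <- 0
  for (i in seq_len(k)) {
    s <- la[i] + lb[i] + carry
    out[i] <- s %% BIG_BASE
    carry <- s %/% BIG_BASE
  }
  if (carry > 0) out <- c(out, carry)
  structure(out, class = "coalexact_bigint")
}

#' @export
as.character.coalexact_bigint <- function(x, ...) {
  limbs <- rev(unclass(x))
  parts <- c(format(limbs[1], scientific = FALSE),
             sprintf("%09.0f", limbs[-1]))
  paste(parts, collapse = "")
}

#' @export
as.numeric.coalexact_bigint <- function(x, ...) {
  sum(unclass(x) * BIG_BASE^(seq_along(unclass(x)) - 1))
}

#' @export
format.coalexact_bigint <- function(x, ...) as.character(x)

#' @export
print.coalexact_bigint <- function(x, ...) {
  cat(as.character(x), "\n")
  invisible(x)
}

#' @export
`==.coalexact_bigint` <- function(e1, e2) {
  if (!inherits(e1, "coalexact_bigint")) e1 <- big_new(e1)
  if (!inherits(e2, "coalexact_bigint")) e2 <- big_new(e2)
  as.character(e1) == as.character(e2)
}
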