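# Minimal exact rational arithmetic on reduced num/den pairs stored as
# doubles. Doubles represent integers exactly up to 2^53; every operation
# reduces by gcd and aborts cleanly if a numerator or denominator would
# leave that range. Sufficient for the desk-scale configurations the
# exact probability mode targets.

RAT_MAX <- 2^53

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

rat <- function(num, den = 1) {
  if (den == 0) abort_domain("rational with zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- gcd2(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  if (abs(num) > RAT_MAX || den > RAT_MAX) {
    abort_domain("exact-rational arithmetic overflow (value too large for exact mode)")
  }
  c(num = num, den = den)
}

rat_add <- function(a, b) rat(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
rat_mul <- function(a, b) rat(a[1] * b[1], a[2] * b[2])
rat_div <- function(a, b) rat(a[1] * b[2], a[2] * b[1])
rat_num <- function(a) unname(a[1] / a[2])
rat_format <- function(a) {
  a <- unname(a)
  if (a[2] == 1) format(a[1]) else paste0(format(a[1]), "/", format(a[2]))
}

# Convert a double to an exact rational via continued fractions; aborts if
# no fraction with a modest denominator reproduces the double to 1e-12
# relative accuracy (the exact mode requires a rational theta).
as_rational <- function(x, max_den = 1e9) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort_domain("theta must be a single finite number")
  }
  if (x == round(x)) return(rat(round(x)))
  a <- x
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  for (i in 1:64) {
    ai <- floor(a)
    p2 <- ai * p1 + p0; q2 <- ai * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) <= 1e-12 * abs(x)) return(rat(p1, q1))
    frac <- a - ai
    if (frac < 1e-15) break
    a <- 1 / frac
  }
  if (abs(p1 / q1 - x) <= 1e-12 * abs(x)) return(rat(p1, q1))
  abort_domain("theta is not representable as a rational for exact mode")
}
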