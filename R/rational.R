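#' Exact rational numbers
#'
#' A minimal reduced-fraction scalar type used wherever the null-model moments
#' must be exact: the enumeration oracle, the exact moment paths, and the
#' conservation identities. Numerator and denominator are stored as doubles
#' holding exact integers; every operation reduces by the gcd and errors if a
#' magnitude approaches 2^53, so results are exact or the computation aborts.
#'
#' @param num integer-valued numerator.
#' @param den integer-valued denominator (nonzero).
#' @return An object of class `rat`.
#' @examples
#' rat(2, 6) + rat(1, 3)   # 2/3
#' as.numeric(rat(1, 3))
#' @export
rat <- function(num, den = 1) {
  if (length(num) != 1L || length(den) != 1L) stop("rat() is scalar")
  if (den == 0) stop("zero denominator")
  if (num != round(num) || den != round(den)) stop("rat() needs integer parts")
  .rat_check(num); .rat_check(den)
  g <- .gcd(abs(num), abs(den))
  if (g > 1) { num <- num / g; den <- den / g }
  if (den < 0) { num <- -num; den <- -den }
  structure(list(num = num, den = den), class = "rat")
}

.RAT_MAX <- 2^52

.rat_check <- function(x) {
  if (abs(x) > .RAT_MAX)
    stop("exact rational arithmetic overflow (magnitude > 2^52)")
  invisible(x)
}

.gcd <- function(a, b) {
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  if (a == 0) 1 else a
}

.as_rat <- function(x) {
  if (inherits(x, "rat")) return(x)
  if (is.numeric(x) && length(x) == 1L && x == round(x)) return(rat(x))
  stop("cannot coerce to rat: ", deparse(x))
}

#' @export
Ops.rat <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(rat(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rat")
  }
  a <- .as_rat(e1); b <- .as_rat(e2)
  # cross-reduce before multiplying so intermediates stay representable
  add <- function(a, b, sign) {
    g <- .gcd(a$den, b$den)
    rat(a$num * (b$den / g) + sign * b$num * (a$den / g),
        a$den * (b$den / g))
  }
  mul <- function(a, b) {
    g1 <- .gcd(abs(a$num), b$den)
    g2 <- .gcd(abs(b$num), a$den)
    rat((a$num / g1) * (b$num / g2), (a$den / g2) * (b$den / g1))
  }
  switch(.Generic,
    "+" = add(a, b, 1),
    "-" = add(a, b, -1),
    "*" = mul(a, b),
    "/" = {
      if (b$num == 0) stop("division by zero rational")
      mul(a, rat(b$den * sign(b$num), abs(b$num)))
    },
    "==" = a$num == b$num && a$den == b$den,
    "!=" = !(a$num == b$num && a$den == b$den),
    "<"  = a$num * b$den <  b$num * a$den,
    "<=" = a$num * b$den <= b$num * a$den,
    ">"  = a$num * b$den >  b$num * a$den,
    ">=" = a$num * b$den >= b$num * a$den,
    stop(.Generic, " not defined for rat")
  )
}

#' @export
as.double.rat <- function(x, ...) x$num / x$den

# explicit numeric coercion used internally (as.numeric's internal dispatch
# is unreliable for list-backed classes)
rat_num <- function(x) x$num / x$den

#' @export
format.rat <- function(x, ...) {
  if (x$den == 1) sprintf("%g", x$num) else sprintf("%g/%g", x$num, x$den)
}

#' @export
print.rat <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Exact falling-power ratio a^(r)/b^(r) as a rational
#'
#' @param a,b integer bases; `r` nonnegative integer exponent.
#' @return `rat` value of \eqn{a^{\underline r} / b^{\underline r}}.
#' @keywords internal
.rat_falling_ratio <- function(a, b, r) {
  out <- rat(1)
  if (r == 0) return(out)
  ks <- 0:(r - 1)
  if (any(a - ks <= 0)) return(rat(0))  # numerator crosses zero: exact 0
  for (k in ks) {
    if (b - k <= 0) stop("falling-power ratio denominator crosses zero")
    out <- out * rat(a - k, b - k)
  }
  out
}
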