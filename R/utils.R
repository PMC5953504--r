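## Internal helpers shared across modules.

# 1 cm^2 = 1e14 nm^2
CM2_PER_NM2 <- 1e-14
NM2_PER_CM2 <- 1e14

#' Convert a diffusion coefficient between cm^2/s and nm^2/s
#'
#' The instrument frame works in nm; diffusion coefficients are reported in
#' the field's customary cm^2/s. The conversion is exact (1 cm^2 = 1e14 nm^2).
#'
#' @param D numeric diffusion coefficient(s).
#' @param from,to either `"cm2"` or `"nm2"`.
#' @return numeric vector in the target unit.
#' @export
convertD <- function(D, from = c("cm2", "nm2"), to = c("nm2", "cm2")) {
  from <- match.arg(from); to <- match.arg(to)
  if (from == to) return(D)
  if (from == "cm2") D * NM2_PER_CM2 else D * CM2_PER_NM2
}

## Raised-cosine radial profile used for both pits (negative) and swellings
## (positive): amp * cos^2(pi r / (2 a)) inside r < a, 0 outside.
raisedCosine <- function(r, a, amp) {
  z <- numeric(length(r))
  inside <- r < a
  z[inside] <- amp * cos(pi * r[inside] / (2 * a))^2
  z
}

## Bilinear interpolation of matrix `m` (rows = y index, cols = x index) at
## fractional (row, col) positions; positions outside the grid return NA.
bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(row))
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  out[ok] <- m[cbind(r0, c0)]         * (1 - fr) * (1 - fc) +
             m[cbind(r0 + 1, c0)]     * fr       * (1 - fc) +
             m[cbind(r0, c0 + 1)]     * (1 - fr) * fc +
             m[cbind(r0 + 1, c0 + 1)] * fr       * fc
  out
}

## Height quantization used by the generator and the TIFF writer: fixed
## 0.01 nm step with -100 nm offset (16-bit range), emulating the
## instrument's z-DAC. Far below the noise floor; makes write->read exact.
HEIGHT_STEP_NM <- 0.01
HEIGHT_OFFSET_NM <- -100
HEIGHT_MAXCODE <- 65535L

quantizeHeights <- function(z) {
  k <- round((z - HEIGHT_OFFSET_NM) / HEIGHT_STEP_NM)
  k <- pmax(0, pmin(HEIGHT_MAXCODE, k))
  k * HEIGHT_STEP_NM + HEIGHT_OFFSET_NM
}

## Moving average with a centered window that shrinks at the edges.
movingAverage <- function(x, half = 1L) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

## Central-difference slope with one-sided differences at the edges.
centralSlope <- function(x) {
  n <- length(x)
  if (n == 1L) return(0)
  s <- numeric(n)
  s[1] <- x[2] - x[1]
  s[n] <- x[n] - x[n - 1]
  if (n > 2L) s[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  s
}

## Gamma draw truncated to [0, upper] by inverse-CDF (deterministic given RNG).
rgammaTrunc <- function(n, shape, scale, upper) {
  pu <- stats::pgamma(upper, shape, scale = scale)
  u <- stats::runif(n, 0, pu)
  stats::qgamma(u, shape, scale = scale)
}

## Normal draw truncated to [lo, hi] by inverse-CDF.
rnormTrunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## Odd-size disc brush closest (from below) to a requested diameter in px.
discBrush <- function(diameter) {
  sz <- max(3L, as.integer(diameter) - (as.integer(diameter) + 1L) %% 2L)
  EBImage::makeBrush(sz, shape = "disc")
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
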