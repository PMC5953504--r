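#' Sample a 2-D Brownian trajectory with optional drift and confinement
#'
#' Per-step displacements are isotropic Gaussian with per-axis variance
#' 2*D*dt (total 4*D*dt), plus a constant drift vector per frame. With a
#' finite `confinementRadius` the walk is reflected radially into a disc
#' about the origin, emulating the corralled wander of membrane pits within
#' the cortical mesh; the free walk (default) is the model under which the
#' MSD slope equals 4D.
#'
#' @param D diffusion coefficient in cm^2/s.
#' @param drift nm/frame drift vector c(x, y).
#' @param nFrames number of positions to return (>= 1).
#' @param dt frame interval in seconds.
#' @param seed optional integer; when given, the RNG is seeded locally.
#' @param confinementRadius confinement disc radius in nm (Inf = free).
#' @return numeric nFrames x 2 matrix of positions in nm, first row (0, 0).
#' @examples
#' p <- sampleTrajectory(7.3e-9, c(0, 0), 10, 10, seed = 1)
#' @export
sampleTrajectory <- function(D, drift = c(0, 0), nFrames, dt,
                             seed = NULL, confinementRadius = Inf) {
  if (D < 0) stop("invalid parameter: D must be >= 0", call. = FALSE)
  if (dt <= 0) stop("invalid parameter: dt must be > 0", call. = FALSE)
  if (nFrames < 1) stop("invalid parameter: nFrames must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nFrames)
  sigma <- sqrt(2 * convertD(D, "cm2", "nm2") * dt)
  steps <- matrix(stats::rnorm(2 * (n - 1), 0, sigma), ncol = 2)
  steps[, 1] <- steps[, 1] + drift[1]
  steps[, 2] <- steps[, 2] + drift[2]
  pos <- matrix(0, n, 2)
  if (n > 1) {
    if (is.finite(confinementRadius)) {
      L <- confinementRadius
      for (i in 2:n) {
        p <- pos[i - 1, ] + steps[i - 1, ]
        r <- sqrt(sum(p^2))
        if (r > L && r > 0) {
          # closed-form triangular fold of the radius into [0, L]
          rr <- r %% (2 * L)
          if (rr > L) rr <- 2 * L - rr
          p <- p * (rr / r)
        }
        pos[i, ] <- p
      }
    } else {
      pos[2:n, 1] <- cumsum(steps[, 1])
      pos[2:n, 2] <- cumsum(steps[, 2])
    }
  }
  colnames(pos) <- c("x", "y")
  pos
}
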