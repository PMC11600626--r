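# Log2-space normal mixtures for intron-size simulation.
#
# Intron sizes within a genome are close to log-normally spread around two
# modes: a narrow peak of near-minimal introns and a broad peak of long
# introns.  The simulator realises sizes as 2^x for x drawn from a
# two-(or more-)component normal mixture in log2 space, so the position of
# the antimode (the local density minimum between the modes) can be
# controlled directly.

#' Mixture specification for synthetic intron sizes
#'
#' Describes a normal mixture in log2(bp) space.  When `antimode` is given
#' for a two-component mixture with `weights = NULL`, the free weight of the
#' first component is solved with [solve_mixture_weight()] so that the
#' mixture density has its interior local minimum exactly at `antimode`.
#'
#' @param means numeric vector of component means, log2 bp.
#' @param sds numeric vector of component standard deviations, log2 bp.
#' @param weights component weights summing to 1, or `NULL` to solve the
#'   first weight from `antimode` (two components only).
#' @param floor minimum intron size in bp; smaller draws are rejected and
#'   redrawn.  Default 60 bp, a typical vertebrate minimal intron size.
#' @param antimode target antimode position in log2 bp, or `NULL`.
#' @return an object of class `mixture_spec`.
#' @examples
#' spec <- mixture_spec(c(6.5, 10), c(0.35, 1.2), antimode = 8)
#' round(spec$weights, 3)
#' @seealso [td_mixture()], [vertebrate_mixture()], [sample_intron_sizes()]
#' @export
mixture_spec <- function(means, sds, weights = NULL, floor = 60,
                         antimode = NULL) {
  # sd = 0 is allowed as a degenerate point component (testing aid)
  stopifnot(length(means) == length(sds), length(means) >= 1L,
            all(sds >= 0), floor >= 1)
  if (is.null(weights)) {
    if (is.null(antimode))
      stop("either weights or antimode must be given")
    if (length(means) != 2L)
      stop("antimode-solved weights require exactly two components")
    w1 <- solve_mixture_weight(means[1], sds[1], means[2], sds[2], antimode)
    weights <- c(w1, 1 - w1)
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(weights < 0)) stop("weights must be non-negative")
  structure(list(means = as.numeric(means), sds = as.numeric(sds),
                 weights = as.numeric(weights), floor = floor,
                 antimode = antimode),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("log2-normal mixture:", length(x$means), "components\n")
  for (i in seq_along(x$means))
    cat(sprintf("  w=%.4f mean=%.3f sd=%.3f (log2 bp)\n",
                x$weights[i], x$means[i], x$sds[i]))
  cat(sprintf("  floor=%d bp", as.integer(x$floor)))
  if (!is.null(x$antimode)) cat(sprintf("  solved antimode=%.3f log2 bp", x$antimode))
  cat("\n")
  invisible(x)
}

#' Mixture density in log2 space
#'
#' @param x positions in log2 bp.
#' @param spec a [mixture_spec()] (weights must be resolved).
#' @return density values (not truncated by the size floor).
#' @export
mixture_density <- function(x, spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  d <- 0
  for (i in seq_along(spec$means))
    d <- d + spec$weights[i] * stats::dnorm(x, spec$means[i], spec$sds[i])
  d
}

#' Solve the mixture weight that places the antimode at a target
#'
#' For a two-component normal mixture in log2 space,
#' `f(x) = w1 N(m1, s1) + (1 - w1) N(m2, s2)`, finds the weight `w1` such
#' that the density derivative vanishes at `target` and the point is an
#' interior local minimum between the two modes.  The root of
#' `w -> f'(target; w)` is located by 1-D root finding.
#'
#' @param m1,s1 mean and sd of the short-intron component (log2 bp).
#' @param m2,s2 mean and sd of the long-intron component (log2 bp).
#' @param target desired antimode position, `m1 < target < m2`.
#' @return the solved weight `w1` in (0, 1).
#' @examples
#' solve_mixture_weight(7, 0.5, 9, 0.5, 8)  # symmetric: 0.5
#' @export
solve_mixture_weight <- function(m1, s1, m2, s2, target) {
  stopifnot(s1 > 0, s2 > 0)
  if (!(m1 < target && target < m2))
    stop("target antimode must lie strictly between the component means")
  # f'(t) = w g1'(t) + (1-w) g2'(t), gi'(t) = dnorm(t, mi, si) (mi - t)/si^2
  g1p <- stats::dnorm(target, m1, s1) * (m1 - target) / s1^2
  g2p <- stats::dnorm(target, m2, s2) * (m2 - target) / s2^2
  dfdw <- function(w) w * g1p + (1 - w) * g2p
  eps <- 1e-12
  if (dfdw(eps) * dfdw(1 - eps) >= 0)
    stop("no weight in (0, 1) places a stationary point at the target antimode")
  w1 <- stats::uniroot(dfdw, c(eps, 1 - eps), tol = 1e-14)$root
  # must be a local minimum, not a shoulder or maximum
  h <- min(s1, s2) / 20
  spec <- list(means = c(m1, m2), sds = c(s1, s2), weights = c(w1, 1 - w1))
  class(spec) <- "mixture_spec"
  f <- mixture_density(c(target - h, target, target + h), spec)
  if (!(f[2] < f[1] && f[2] < f[3]))
    stop("solved stationary point at the target is not a local minimum; ",
         "the requested antimode is infeasible for these components")
  w1
}

#' Default teleost-type (TD) intron-size mixture
#'
#' Short-intron peak at 2^6.5 (~90 bp), broad long-intron peak at 2^10
#' (~1 kb), free weight solved so the antimode sits at 2^8 (~256 bp), the
#' position typical of the teleost distribution.
#'
#' @param antimode antimode position, log2 bp.
#' @return a [mixture_spec()].
#' @export
td_mixture <- function(antimode = 8.0) {
  mixture_spec(means = c(6.5, 10.0), sds = c(0.35, 1.2), antimode = antimode)
}

#' Default vertebrate-typical (non-TD) intron-size mixture
#'
#' Minor short-intron peak at 2^6.5 and a dominant broad peak at 2^9.75,
#' free weight solved so the antimode sits at 2^7.25 (~150 bp), the position
#' typical of non-teleost vertebrates.
#'
#' @param antimode antimode position, log2 bp.
#' @return a [mixture_spec()].
#' @export
vertebrate_mixture <- function(antimode = 7.25) {
  mixture_spec(means = c(6.5, 9.75), sds = c(0.3, 1.25), antimode = antimode)
}

#' Sample intron sizes from a log2 mixture
#'
#' Sizes are realised as `round(2^x)` for `x` drawn from the mixture; draws
#' below the size floor are rejected and redrawn, which truncates the
#' distribution without piling mass at the floor.
#'
#' @param spec a [mixture_spec()] with resolved weights.
#' @param n number of sizes to draw.
#' @param seed integer seed; the draw is bit-reproducible given the seed.
#' @return integer vector of `n` intron sizes in bp, all `>= spec$floor`.
#' @export
sample_intron_sizes <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"), n > 0)
  if (is.null(spec$weights)) stop("mixture weights are unresolved")
  with_seed(seed, {
    out <- integer(0)
    remaining <- as.integer(n)
    while (remaining > 0L) {
      comp <- sample.int(length(spec$weights), remaining, replace = TRUE,
                         prob = spec$weights)
      x <- stats::rnorm(remaining, spec$means[comp], spec$sds[comp])
      sizes <- as.integer(round(2^x))
      sizes <- sizes[sizes >= spec$floor]
      out <- c(out, sizes)
      remaining <- as.integer(n) - length(out)
    }
    out[seq_len(n)]
  })
}
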