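# TD / non-TD classification of intron-size distributions.
#
# The teleost distribution (TD) is log-bimodal with an antimode at or above
# 2^8 bp and a dominant short-intron peak; non-teleost vertebrates share an
# antimode near 2^7.25 bp.  Two summaries drive the call: the mean density
# over (2^8, 2^8.5) ("d8") and over (2^11, 2^11.5) ("d11").  Species whose
# (d11, d8) point lies strictly below a dividing line are called TD.

#' Locate the antimode of a bimodal size distribution
#'
#' Densities are smoothed with a 3-bin moving average; the two highest local
#' maxima inside the search window are located (window-boundary bins count
#' as candidate maxima), and the argmin of the smoothed density strictly
#' between them is refined by quadratic interpolation through the three
#' unsmoothed bins around the minimum (smoothing robustifies localisation
#' but would bias the refined position towards the flatter flank).  Returns `NA` when fewer than two local maxima exist
#' or when the dip between the chosen peaks is not pronounced (smoothed
#' minimum above `dip_ratio` times the lower peak), which rejects unimodal
#' samples whose noise wiggles would otherwise masquerade as modes.
#'
#' @param dist a [log2_histogram()] result.
#' @param search_lo,search_hi search window in log2 bp; default (6.5, 10.5)
#'   spans the vertebrate and teleost antimode positions.
#' @param dip_ratio maximum ratio of the smoothed minimum to the lower of
#'   the two peak heights for the dip to count as an antimode.
#' @return antimode position in log2 bp, or `NA_real_` if none found.
#' @export
find_antimode <- function(dist, search_lo = 6.5, search_hi = 10.5,
                          dip_ratio = 0.8) {
  stopifnot(inherits(dist, "size_distribution"), search_lo < search_hi)
  mids <- dist$mids
  if (search_lo < dist$edges[1] - dist$bin_width ||
      search_hi > dist$edges[length(dist$edges)] + dist$bin_width)
    stop("search window lies outside the distribution support")
  # 3-bin moving average (edge bins averaged over available neighbours)
  d <- dist$density
  nb <- length(d)
  sm <- vapply(seq_len(nb), function(i)
    mean(d[max(1L, i - 1L):min(nb, i + 1L)]), numeric(1))
  win <- which(mids >= search_lo & mids < search_hi)
  if (length(win) < 3L) return(NA_real_)
  s <- sm[win]
  # local maxima within the window, boundaries included
  is_max <- vapply(seq_along(s), function(i) {
    left <- if (i > 1L) s[i] >= s[i - 1L] else TRUE
    right <- if (i < length(s)) s[i] >= s[i + 1L] else TRUE
    left && right
  }, logical(1))
  peaks <- which(is_max)
  # collapse plateaus of equal smoothed density into one candidate
  if (length(peaks) > 1L)
    peaks <- peaks[c(TRUE, diff(peaks) > 1L | diff(s[peaks]) != 0)]
  if (length(peaks) < 2L) return(NA_real_)
  top2 <- peaks[order(s[peaks], decreasing = TRUE)[1:2]]
  lo_pk <- min(top2); hi_pk <- max(top2)
  if (hi_pk - lo_pk < 2L) return(NA_real_)
  inner <- (lo_pk + 1L):(hi_pk - 1L)
  imin <- inner[which.min(s[inner])]
  if (s[imin] > dip_ratio * min(s[top2])) return(NA_real_)
  # quadratic refinement through the three raw bins around the minimum:
  # smoothing is used only to locate the dip robustly, because the moving
  # average shifts the minimum towards the flatter flank
  gi <- win[imin]
  if (gi <= 1L || gi >= nb) return(mids[gi])
  y <- d[(gi - 1L):(gi + 1L)]
  denom <- y[1] - 2 * y[2] + y[3]
  offset <- if (denom > 0) 0.5 * (y[1] - y[3]) / denom else 0
  offset <- max(-0.5, min(0.5, offset))
  mids[gi] + offset * dist$bin_width
}

#' Dividing line for the two-interval TD rule
#'
#' A species is called TD when its d8 density lies strictly below
#' `intercept + slope * d11`.  The line is configuration, not a constant:
#' the default was calibrated once on the package's synthetic ensemble
#' (analytic interval densities of [td_mixture()] and
#' [vertebrate_mixture()]) and frozen.
#'
#' @param intercept density units.
#' @param slope dimensionless, `>= 0`.
#' @return object of class `dividing_line`.
#' @export
dividing_line <- function(intercept = 0.02, slope = 0.5) {
  stopifnot(slope >= 0)
  structure(list(intercept = intercept, slope = slope),
            class = "dividing_line")
}

#' Classify a distribution as TD or non-TD from two interval densities
#'
#' @param d8 mean density over (2^8, 2^8.5) log2 bp.
#' @param d11 mean density over (2^11, 2^11.5) log2 bp.
#' @param line a [dividing_line()].
#' @return `"TD"` if the (d11, d8) point lies strictly below the line,
#'   otherwise `"non-TD"` (exact equality is non-TD).
#' @export
classify_td <- function(d8, d11, line = dividing_line()) {
  stopifnot(inherits(line, "dividing_line"),
            is.finite(d8), is.finite(d11), d8 >= 0, d11 >= 0)
  if (d8 < line$intercept + line$slope * d11) "TD" else "non-TD"
}

#' Summarise a species' annotation into a TD call record
#'
#' Chains [extract_introns()], [log2_histogram()], [interval_density()] on
#' the two rule intervals, [find_antimode()] and [classify_td()].  Species
#' with fewer introns than `min_introns` are called `"ambiguous"`.
#'
#' @param ann an `annotation_set`.
#' @param species species identifier for the record.
#' @param bin_width histogram bin width, log2 units.
#' @param line a [dividing_line()].
#' @param dedupe passed to [extract_introns()].
#' @param min_introns minimum intron count for a confident call.
#' @param d8_interval,d11_interval rule intervals in log2 bp.
#' @return one-row data.frame: `species`, `n_introns`, `d8`, `d11`,
#'   `antimode_log2`, `call`.
#' @export
summarize_species <- function(ann, species = "species", bin_width = 0.25,
                              line = dividing_line(), dedupe = TRUE,
                              min_introns = 1000,
                              d8_interval = c(8, 8.5),
                              d11_interval = c(11, 11.5)) {
  introns <- extract_introns(ann, dedupe = dedupe)
  n <- nrow(introns)
  if (n < min_introns) {
    message("species ", species, ": only ", n,
            " introns (< ", min_introns, "); call ambiguous")
    return(data.frame(species = species, n_introns = n, d8 = NA_real_,
                      d11 = NA_real_, antimode_log2 = NA_real_,
                      call = "ambiguous", stringsAsFactors = FALSE))
  }
  dist <- log2_histogram(introns$size, bin_width = bin_width)
  d8 <- interval_density(dist, d8_interval[1], d8_interval[2])
  d11 <- interval_density(dist, d11_interval[1], d11_interval[2])
  am <- find_antimode(dist)
  data.frame(species = species, n_introns = n, d8 = d8, d11 = d11,
             antimode_log2 = am, call = classify_td(d8, d11, line),
             stringsAsFactors = FALSE)
}
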