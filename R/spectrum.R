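# Co-60 virtual-source energy spectrum: the two emission lines plus a
# parametric scatter continuum from photons degraded in the collimator body.

#' Maximum energy transferable to a Compton electron (the Compton edge)
#'
#' Closed form: \eqn{T_{max} = E \cdot 2\alpha/(1+2\alpha)} with
#' \eqn{\alpha = E/m_e c^2}. For the Co-60 lines at 1.33 and 1.17 MeV this
#' gives 1.12 and 0.96 MeV (to the printed precision).
#'
#' @param E Photon energy in MeV (vectorised).
#' @return Edge (maximum electron) energy in MeV.
#' @export
compton_edge <- function(E) {
  a <- E / 0.510998928
  E * 2 * a / (1 + 2 * a)
}

#' Default Co-60 virtual-source spectrum
#'
#' Two equal-weight lines at 1.17 and 1.33 MeV carry `p_line` of the
#' probability mass; the remainder is a falling exponential continuum of
#' collimator-scattered photons, supported between the minimum single-scatter
#' energy of the 1.33 MeV line (1.33 minus its Compton edge) and 1.33 MeV.
#' The same normalised spectrum is used for all three collimators.
#'
#' @param p_line Fraction of emission in the two discrete lines (0, 1].
#' @param E0 Exponential continuum scale in MeV.
#' @param n_bins Continuum histogram bins.
#' @return A `gk_spectrum`: list with `lines` (data.frame energy/prob),
#'   `continuum` (list `edges`, `density`, `cdf`), `p_line`.
#' @export
default_spectrum <- function(p_line = 0.8, E0 = 0.3, n_bins = 64) {
  stopifnot(p_line > 0, p_line <= 1, E0 > 0)
  lines <- data.frame(energy = c(1.17, 1.33), prob = c(0.5, 0.5) * p_line)
  e_min <- 1.33 - compton_edge(1.33)     # minimum scattered energy
  e_max <- 1.33
  edges <- seq(e_min, e_max, length.out = n_bins + 1)
  dens <- exp(-(edges[-1] + edges[-(n_bins + 1)]) / 2 / E0)
  mass <- dens * diff(edges)
  cdf <- cumsum(mass) / sum(mass)
  structure(list(lines = lines,
                 continuum = list(edges = edges,
                                  density = dens / sum(mass) * (1 - p_line),
                                  cdf = cdf),
                 p_line = p_line), class = "gk_spectrum")
}

#' Custom spectrum from explicit (energy, weight) pairs
#'
#' @param energy,weight Discrete line energies (MeV, in (0, 1.33]) and
#'   weights (renormalised).
#' @return A pure-line `gk_spectrum`.
#' @export
line_spectrum <- function(energy, weight = rep(1, length(energy))) {
  stopifnot(length(energy) == length(weight), all(energy > 0),
            all(energy <= 1.33), all(weight >= 0), sum(weight) > 0)
  structure(list(lines = data.frame(energy = energy,
                                    prob = weight / sum(weight)),
                 continuum = list(edges = c(0.1, 0.2),
                                  density = 0, cdf = 1),
                 p_line = 1), class = "gk_spectrum")
}

#' @export
print.gk_spectrum <- function(x, ...) {
  cat(sprintf(
    "<gk_spectrum> lines at %s MeV (p_line = %.3g), mean %.4g MeV\n",
    paste(x$lines$energy, collapse = ", "), x$p_line, mean_energy(x)))
  invisible(x)
}

#' Analytic mean energy of a spectrum
#' @param spec A `gk_spectrum`.
#' @return Mean energy in MeV.
#' @export
mean_energy <- function(spec) {
  m_line <- sum(spec$lines$energy * spec$lines$prob)
  if (spec$p_line >= 1) return(m_line)
  ed <- spec$continuum$edges
  mid <- (ed[-1] + ed[-length(ed)]) / 2
  mass <- spec$continuum$density * diff(ed)
  m_line + sum(mid * mass)
}

#' Total probability of a spectrum (should be 1)
#' @param spec A `gk_spectrum`.
#' @export
spectrum_norm <- function(spec) {
  sum(spec$lines$prob) +
    if (spec$p_line >= 1) 0 else
      sum(spec$continuum$density * diff(spec$continuum$edges))
}

#' Sample photon energies from a spectrum
#'
#' Chooses lines versus continuum by `p_line`, then inverse-CDF sampling
#' within the continuum histogram (uniform within a bin).
#'
#' @param spec A `gk_spectrum`.
#' @param n Number of samples.
#' @param seed Seed.
#' @return Numeric vector of energies in MeV.
#' @export
sample_energy <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "gk_spectrum"), n >= 1)
  set.seed(seed)
  isline <- runif(n) < spec$p_line
  out <- numeric(n)
  nl <- sum(isline)
  if (nl > 0)
    out[isline] <- sample(spec$lines$energy, nl, replace = TRUE,
                          prob = spec$lines$prob)
  nc <- n - nl
  if (nc > 0) {
    ed <- spec$continuum$edges
    cdf <- spec$continuum$cdf
    u <- runif(nc)
    bin <- findInterval(u, c(0, cdf), rightmost.closed = TRUE,
                        all.inside = TRUE)
    c0 <- c(0, cdf)[bin]
    f <- (u - c0) / (cdf[bin] - c0)
    out[!isline] <- ed[bin] + f * (ed[bin + 1] - ed[bin])
  }
  out
}

# internal: flatten a spectrum for the transport kernel
spectrum_for_kernel <- function(spec) {
  list(line_energy = spec$lines$energy, line_prob = spec$lines$prob,
       p_line = spec$p_line,
       cont_edges = spec$continuum$edges,
       cont_cdf = spec$continuum$cdf)
}
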