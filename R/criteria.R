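#' Table of coefficient extrema over one period
#'
#' One (inf, sup) pair per reaction coefficient of the simplified model.
#' These suprema/infima are the only ingredients of the persistence bounds
#' and hypothesis margins.
#'
#' @param model an \code{ecoEpidemicModel}.
#' @return object of class \code{extremaTable}: a named list of
#'   \code{c(inf, sup)} pairs over r1, b, beta, delta, c, psi, alpha, a, e,
#'   gamma, r2, d.
#' @export
extremaTable <- function(model) {
  stopifnot(inherits(model, "ecoEpidemicModel"))
  tab <- lapply(model$coefs[reactionCoefNames], extremaPeriodic)
  structure(tab, class = "extremaTable")
}

tabInf <- function(tab, nm) tab[[nm]][["inf"]]
tabSup <- function(tab, nm) tab[[nm]][["sup"]]

#' Starred ultimate bounds from coefficient extrema
#'
#' The six asymptotic bounds derived by differential comparison, computed
#' sequentially: each starred value uses the band value chosen for the
#' previous one.  Band values can be supplied explicitly (e.g. to reproduce
#' published tables); any not supplied defaults to the corresponding starred
#' value itself, which leaves the formulas exact in the starred quantities.
#'
#' \deqn{M_1^* = r_1^m / b^l}
#' \deqn{M_2^* = (\psi^m M_1 - \delta^l) / c^l}
#' \deqn{M_3^* = (\gamma^m M_2 - r_2^l) / d^l}
#' \deqn{m_1^* = (r_1^l - (b^m + \beta^m) M_2) / b^m}
#' \deqn{m_2^* = (\psi^l m_1 - \alpha^m M_3 - \delta^m) / c^m}
#' \deqn{m_3^* = \gamma^l m_2 / (d^m (1 + a^m M_2 + e^m M_3)) - r_2^m / d^m}
#'
#' @param tab an \code{extremaTable}.
#' @param M1,M2,M3,m1,m2 optional explicit band values feeding the chain.
#' @return named list with \code{M1star..M3star}, \code{m1star..m3star}.
#' @export
starredBounds <- function(tab, M1 = NULL, M2 = NULL, M3 = NULL,
                          m1 = NULL, m2 = NULL) {
  stopifnot(inherits(tab, "extremaTable"))
  for (nm in c("b", "c", "d"))
    if (tabInf(tab, nm) <= 0 || tabSup(tab, nm) <= 0)
      stop("non-positive denominator extrema for coefficient '", nm, "'")
  M1star <- tabSup(tab, "r1") / tabInf(tab, "b")
  if (is.null(M1)) M1 <- M1star
  M2star <- (tabSup(tab, "psi") * M1 - tabInf(tab, "delta")) /
    tabInf(tab, "c")
  if (is.null(M2)) M2 <- M2star
  M3star <- (tabSup(tab, "gamma") * M2 - tabInf(tab, "r2")) /
    tabInf(tab, "d")
  if (is.null(M3)) M3 <- M3star
  m1star <- (tabInf(tab, "r1") -
               (tabSup(tab, "b") + tabSup(tab, "beta")) * M2) /
    tabSup(tab, "b")
  if (is.null(m1)) m1 <- m1star
  m2star <- (tabInf(tab, "psi") * m1 - tabSup(tab, "alpha") * M3 -
               tabSup(tab, "delta")) / tabSup(tab, "c")
  if (is.null(m2)) m2 <- m2star
  m3star <- tabInf(tab, "gamma") * m2 /
    (tabSup(tab, "d") * (1 + tabSup(tab, "a") * M2 + tabSup(tab, "e") * M3)) -
    tabSup(tab, "r2") / tabSup(tab, "d")
  list(M1star = M1star, M2star = M2star, M3star = M3star,
       m1star = m1star, m2star = m2star, m3star = m3star)
}

# truncate towards zero at 'digits' decimals; the published bands are
# truncations of the starred values nudged outward by the margin
trunc4 <- function(x, digits) {
  if (is.null(digits)) return(x)
  trunc(x * 10^digits) / 10^digits
}

#' Persistence bands from coefficient extrema
#'
#' Computes the starred bounds sequentially and picks the bands
#' \code{Mi > Mi*}, \code{mi < mi*}: each band is the 4-decimal truncation of
#' its starred value nudged outward by \code{margin} (upper bands up, lower
#' bands down).  Comparisons downstream always use the full-precision band
#' values stored here; \code{roundingDecimals} only controls the truncation
#' grid (set it to \code{NULL} for pure \code{star +/- margin} bands).
#'
#' The bands certify permanence only when all six starred values are
#' positive; \code{$certifying} records this, and the bands are still
#' reported when they certify nothing.
#'
#' @param tab an \code{extremaTable}.
#' @param margin band offset added beyond the truncated starred value.
#' @param roundingDecimals decimals of the truncation grid (default 4).
#' @return object of class \code{persistenceBounds}.
#' @export
ultimateBounds <- function(tab, margin = 1e-4, roundingDecimals = 4) {
  stopifnot(inherits(tab, "extremaTable"), margin >= 0)
  up <- function(star) trunc4(star, roundingDecimals) + margin
  dn <- function(star) trunc4(star, roundingDecimals) - margin
  s <- list()
  s$M1star <- starredBounds(tab)$M1star
  M1 <- up(s$M1star)
  s2 <- starredBounds(tab, M1 = M1)
  M2 <- up(s2$M2star)
  s3 <- starredBounds(tab, M1 = M1, M2 = M2)
  M3 <- up(s3$M3star)
  m1 <- dn(s3$m1star)
  s4 <- starredBounds(tab, M1 = M1, M2 = M2, M3 = M3, m1 = m1)
  m2 <- dn(s4$m2star)
  s5 <- starredBounds(tab, M1 = M1, M2 = M2, M3 = M3, m1 = m1, m2 = m2)
  m3 <- dn(s5$m3star)
  stars <- c(M1star = s$M1star, M2star = s2$M2star, M3star = s3$M3star,
             m1star = s3$m1star, m2star = s4$m2star, m3star = s5$m3star)
  certifying <- all(stars > 0)
  if (s5$m3star <= 0)
    message("no positive band for predator: m3* = ",
            formatC(s5$m3star, digits = 4, format = "g"),
            " <= 0; bounds certify nothing")
  structure(list(M1star = stars[["M1star"]], M2star = stars[["M2star"]],
                 M3star = stars[["M3star"]], m1star = stars[["m1star"]],
                 m2star = stars[["m2star"]], m3star = stars[["m3star"]],
                 M1 = M1, M2 = M2, M3 = M3, m1 = m1, m2 = m2, m3 = m3,
                 margin = margin, roundingDecimals = roundingDecimals,
                 certifying = certifying),
            class = "persistenceBounds")
}

#' Bands supplied by hand
#'
#' Wraps externally chosen band values (for instance a published table) into
#' a \code{persistenceBounds} object usable by \code{\link{hypothesisMargins}}
#' and \code{\link{persistenceBandReport}}; starred values are recomputed
#' from \code{tab} through the supplied bands.
#'
#' @param tab an \code{extremaTable}.
#' @param M1,M2,M3,m1,m2,m3 band values.
#' @inheritParams ultimateBounds
#' @return a \code{persistenceBounds}.
#' @export
explicitBounds <- function(tab, M1, M2, M3, m1, m2, m3, margin = 1e-4) {
  s <- starredBounds(tab, M1 = M1, M2 = M2, M3 = M3, m1 = m1, m2 = m2)
  structure(c(s, list(M1 = M1, M2 = M2, M3 = M3, m1 = m1, m2 = m2, m3 = m3,
                      margin = margin, roundingDecimals = NULL,
                      certifying = all(unlist(s) > 0))),
            class = "persistenceBounds")
}

#' Hypothesis margins for permanence and global stability
#'
#' Margins of the eight sufficient conditions.  (H1)--(H5) certify permanence
#' of the reduced system (and of the reaction-diffusion system); (H6)--(H8)
#' additionally certify a strictly positive spatially homogeneous periodic
#' solution that is globally asymptotically stable, with Lyapunov decay rate
#' \code{alpha = min(H6, H7, H8)}.
#'
#' \itemize{
#'   \item H1 = \eqn{\psi^m M_1 - \delta^l}
#'   \item H2 = \eqn{\gamma^m M_2 - r_2^l}
#'   \item H3 = \eqn{r_1^l - (b^m + \beta^m) M_2}
#'   \item H4 = \eqn{\psi^l m_1 - (\alpha^m M_3 + \delta^m)}
#'   \item H5 = \eqn{\gamma^l m_2 / (d^m (1 + a^m M_2 + e^m M_3)) - r_2^m / d^m}
#'   \item H6 = \eqn{b^l - \psi^m}
#'   \item H7 = \eqn{c^l - b^m - \beta^m -
#'     (a^m \alpha^m M_3 + \gamma^m (1 + e^m M_3)) / (1 + a^l m_2 + e^l m_3)^2}
#'   \item H8 = \eqn{d^l - (\alpha^m + a^m \alpha^m M_2 - \gamma^l e^l m_2) /
#'     (1 + a^l m_2 + e^l m_3)^2}
#' }
#'
#' A hypothesis holds iff its margin is positive.  Margins are reported even
#' when the bounds do not certify (flagged via \code{$certifying}).
#'
#' @param tab an \code{extremaTable}.
#' @param bounds a \code{persistenceBounds} computed from \code{tab}.
#' @return object of class \code{hypothesisReport} with \code{$margins}
#'   (named H1..H8), \code{$satisfied}, \code{$permanent},
#'   \code{$globallyStable}, \code{$decayRateAlpha} (NA unless H6--H8 all
#'   hold), \code{$certifying}.
#' @export
hypothesisMargins <- function(tab, bounds) {
  stopifnot(inherits(tab, "extremaTable"),
            inherits(bounds, "persistenceBounds"))
  inf <- function(nm) tabInf(tab, nm); sup <- function(nm) tabSup(tab, nm)
  den <- (1 + inf("a") * bounds$m2 + inf("e") * bounds$m3)^2
  if (den <= 0)
    stop("degenerate Lyapunov denominator: 1 + a^l*m2 + e^l*m3 <= 0")
  H <- c(
    H1 = sup("psi") * bounds$M1 - inf("delta"),
    H2 = sup("gamma") * bounds$M2 - inf("r2"),
    H3 = inf("r1") - (sup("b") + sup("beta")) * bounds$M2,
    H4 = inf("psi") * bounds$m1 - (sup("alpha") * bounds$M3 + sup("delta")),
    H5 = inf("gamma") * bounds$m2 /
      (sup("d") * (1 + sup("a") * bounds$M2 + sup("e") * bounds$M3)) -
      sup("r2") / sup("d"),
    H6 = inf("b") - sup("psi"),
    H7 = inf("c") - sup("b") - sup("beta") -
      (sup("a") * sup("alpha") * bounds$M3 +
         sup("gamma") * (1 + sup("e") * bounds$M3)) / den,
    H8 = inf("d") - (sup("alpha") + sup("a") * sup("alpha") * bounds$M2 -
                       inf("gamma") * inf("e") * bounds$m2) / den)
  satisfied <- H > 0
  permanent <- all(satisfied[1:5])
  globallyStable <- all(satisfied)
  alpha <- if (all(satisfied[6:8])) min(H[6:8]) else NA_real_
  structure(list(margins = H, satisfied = satisfied, permanent = permanent,
                 globallyStable = globallyStable, decayRateAlpha = alpha,
                 certifying = bounds$certifying),
            class = "hypothesisReport")
}

#' Full criteria report for a model
#'
#' Convenience wrapper: extrema table, bounds with the default band policy,
#' and hypothesis margins in one call.
#'
#' @param model an \code{ecoEpidemicModel}.
#' @inheritParams ultimateBounds
#' @return list with \code{$table}, \code{$bounds}, \code{$report}.
#' @export
criteriaReport <- function(model, margin = 1e-4, roundingDecimals = 4) {
  tab <- extremaTable(model)
  bounds <- ultimateBounds(tab, margin, roundingDecimals)
  list(table = tab, bounds = bounds,
       report = hypothesisMargins(tab, bounds))
}

#' @export
print.extremaTable <- function(x, ...) {
  cat("<extremaTable>\n")
  for (nm in names(x))
    cat(sprintf("  %-6s [%.6g, %.6g]\n", nm, x[[nm]][["inf"]],
                x[[nm]][["sup"]]))
  invisible(x)
}

#' @export
print.persistenceBounds <- function(x, ...) {
  cat("<persistenceBounds>",
      if (x$certifying) "(certifying)" else "(NOT certifying)", "\n")
  for (i in 1:3)
    cat(sprintf("  species %d: m%d = %.4f  (m%d* = %.6g)   M%d = %.4f  (M%d* = %.6g)\n",
                i, i, x[[paste0("m", i)]], i, x[[paste0("m", i, "star")]],
                i, x[[paste0("M", i)]], i, x[[paste0("M", i, "star")]]))
  invisible(x)
}

#' @export
print.hypothesisReport <- function(x, ...) {
  cat("<hypothesisReport>\n")
  for (k in 1:8)
    cat(sprintf("  H%d: margin %+.4f  %s\n", k, x$margins[[k]],
                if (x$satisfied[[k]]) "holds" else "fails"))
  cat("  permanent:", x$permanent, " globallyStable:", x$globallyStable, "\n")
  if (!is.na(x$decayRateAlpha))
    cat("  Lyapunov decay rate alpha =", format(x$decayRateAlpha), "\n")
  if (!x$certifying)
    cat("  NOTE: bounds not certifying (a starred value is non-positive)\n")
  invisible(x)
}
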