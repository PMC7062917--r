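## Median-effect dose-response fitting and combination-index synergy.
##
## The median-effect model fa/(1-fa) = (D/Dm)^m linearises to a straight
## line in log10(D); Dm (the GI50 when fa measures growth inhibition) and
## the slope m come from ordinary least squares on that line. For a dose
## pair (d1, d2) producing a combined affected fraction fa, the combination
## index is CI = d1/Dx1(fa) + d2/Dx2(fa) where Dxi(fa) is the dose at which
## agent i alone reaches fa; CI < 1 is synergy, CI = 1 additivity, CI > 1
## antagonism. The classic two-term (mutually exclusive) form is the
## default; the non-exclusive third term is available behind a flag.

FA_CLAMP <- c(0.005, 0.995)

#' Affected fraction from fresh weights
#'
#' `fa = 1 - weight_treated / weight_control`, clamped into
#' `[0.005, 0.995]` so the log-odds transform of the median-effect fit
#' stays finite.
#'
#' @param weightTreated,weightControl Positive fresh weights (mg),
#'   vectorised.
#' @return Clamped affected fractions.
#' @examples
#' faFromFreshWeight(50, 100)  # 0.5
#' @export
faFromFreshWeight <- function(weightTreated, weightControl) {
  if (any(weightControl <= 0)) stop("control weight must be positive")
  if (any(weightTreated <= 0)) stop("treated weight must be positive")
  fa <- 1 - weightTreated / weightControl
  pmin(FA_CLAMP[2L], pmax(FA_CLAMP[1L], fa))
}

#' Fit the median-effect model to a dose-response table
#'
#' OLS of `log10(fa/(1-fa))` on `log10(D)`: the slope is `m` and the
#' intercept `-m log10(Dm)`.
#'
#' @param doses Positive doses (uM).
#' @param fa Affected fractions in (0,1); values outside
#'   `[0.005, 0.995]` are clamped first.
#' @param agent Label stored on the fit.
#' @return A [MedianEffectFit-class].
#' @examples
#' dr <- simulateDoseResponse(1, 10, c(2.5, 5, 10, 20, 40))
#' fitMedianEffect(dr$dose, dr$fa)
#' @export
fitMedianEffect <- function(doses, fa, agent = "agent") {
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(unique(doses)) < 2L)
    stop("need >= 2 distinct doses to fit the median-effect line")
  fa <- pmin(FA_CLAMP[2L], pmax(FA_CLAMP[1L], fa))
  if (all(fa == FA_CLAMP[1L]) || all(fa == FA_CLAMP[2L]))
    stop("all affected fractions at a clamp bound; no information to fit")
  y <- log10(fa / (1 - fa))
  x <- log10(doses)
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2L])
  if (!is.finite(m) || m <= 0)
    stop("median-effect slope not positive; dose-response is not increasing")
  Dm <- 10^(-unname(stats::coef(fit)[1L]) / m)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noise-free fits are exact
  new("MedianEffectFit", agent = as.character(agent), m = m, Dm = Dm,
      r2 = r2, n = length(doses))
}

#' Dose producing a given affected fraction
#'
#' Inverse of the median-effect relation: `Dx = Dm (fa/(1-fa))^(1/m)`.
#'
#' @param fit A [MedianEffectFit-class].
#' @param fa Affected fraction strictly between 0 and 1 (vectorised).
#' @return Dose(s) in the unit of `Dm`.
#' @examples
#' f <- new("MedianEffectFit", agent = "a", m = 1, Dm = 10, r2 = 1, n = 5L)
#' doseForFa(f, 0.75)  # 30
#' @export
doseForFa <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) stop("fa must be strictly inside (0,1)")
  fit@Dm * (fa / (1 - fa))^(1 / fit@m)
}

#' Combination index of a dose pair
#'
#' `CI = d1/Dx1(fa) + d2/Dx2(fa)` (plus `d1 d2/(Dx1 Dx2)` when
#' `nonExclusive = TRUE`), with verdict synergy (`CI < 1`), additive
#' (`CI = 1`) or antagonism (`CI > 1`).
#'
#' @param d1,d2 Combination doses (uM).
#' @param faCombo Observed affected fraction of the combination, in (0,1).
#' @param fit1,fit2 Single-agent [MedianEffectFit-class] objects.
#' @param nonExclusive Add the third (non-exclusive) term.
#' @return List with `d1, d2, fa, ci, verdict`.
#' @export
combinationIndex <- function(d1, d2, faCombo, fit1, fit2,
                             nonExclusive = FALSE) {
  stopifnot(d1 > 0, d2 > 0)
  if (faCombo <= 0 || faCombo >= 1) stop("faCombo must be inside (0,1)")
  dx1 <- doseForFa(fit1, faCombo)
  dx2 <- doseForFa(fit2, faCombo)
  ci <- d1 / dx1 + d2 / dx2
  if (nonExclusive) ci <- ci + (d1 * d2) / (dx1 * dx2)
  verdict <- if (ci < 1) "synergy" else if (ci > 1) "antagonism"
             else "additive"
  list(d1 = d1, d2 = d2, fa = faCombo, ci = ci, verdict = verdict)
}

#' Fa-CI curve over a set of combination observations
#'
#' @param combos `data.frame(d1, d2, fa)` of combination doses and their
#'   observed affected fractions.
#' @param fit1,fit2 Single-agent fits.
#' @param nonExclusive Passed to [combinationIndex()].
#' @return `data.table(fa, d1, d2, ci, verdict)` sorted ascending by `fa`
#'   (duplicates kept).
#' @export
faCICurve <- function(combos, fit1, fit2, nonExclusive = FALSE) {
  combos <- as.data.frame(combos)
  if (nrow(combos) < 1L) stop("need >= 1 combination observation")
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    r <- combinationIndex(combos$d1[i], combos$d2[i], combos$fa[i],
                          fit1, fit2, nonExclusive)
    data.table(fa = r$fa, d1 = r$d1, d2 = r$d2, ci = r$ci,
               verdict = r$verdict)
  })
  out <- rbindlist(rows)
  setorder(out, fa)
  out[]
}

#' Read a single-agent dose table and aggregate to dose-level Fa
#'
#' Input TSV columns: `agent, dose_uM, replicate, fresh_weight_mg`, with
#' dose 0 rows serving as the untreated control. Replicate fresh weights
#' are averaged per dose before computing
#' `fa = 1 - mean(weight_dose) / mean(weight_control)`.
#'
#' @param path Input TSV (with a `#` header line).
#' @return `data.table(agent, dose, fa)` for the non-zero doses.
#' @export
readDoseTable <- function(path) {
  dt <- readTsv(path)
  data.table::setnames(dt, c("agent", "dose_uM", "replicate",
                             "fresh_weight_mg"))
  out <- list()
  for (ag in unique(dt$agent)) {
    d <- dt[agent == ag]
    ctrl <- d[dose_uM == 0, mean(fresh_weight_mg)]
    if (!is.finite(ctrl)) stop("agent ", ag, " has no dose-0 control rows")
    by_dose <- d[dose_uM > 0, .(w = mean(fresh_weight_mg)), by = dose_uM]
    out[[ag]] <- data.table(agent = ag, dose = by_dose$dose_uM,
                            fa = faFromFreshWeight(by_dose$w, ctrl))
  }
  rbindlist(out)[]
}
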