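# Diastolic KE time-curve pattern analysis. Three heart-failure patterns:
# (1) E-wave KE lower than A-wave KE, (2) E-wave KE higher than A-wave KE,
# (3) partial or complete fusion of the two diastolic KE peaks. Controls
# show a separated dominant E-peak and small A-peak. The reference
# classification was visual consensus; the prominence/trough thresholds
# here are this package's operationalisation and are reported with labels.

# Peak prominence on a short series: height minus the higher of the two
# key saddles (minima scanned until a strictly higher value or the window
# border on each side).
peakProminences <- function(x) {
  n <- length(x)
  isMax <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) x[i - 1L] else -Inf
    right <- if (i < n) x[i + 1L] else -Inf
    x[i] > left && x[i] >= right
  }, logical(1))
  peaks <- which(isMax)
  prom <- vapply(peaks, function(i) {
    lmin <- x[i]; j <- i
    while (j > 1L && x[j - 1L] <= x[i]) { j <- j - 1L; lmin <- min(lmin, x[j]) }
    rmin <- x[i]; j <- i
    while (j < n && x[j + 1L] <= x[i]) { j <- j + 1L; rmin <- min(rmin, x[j]) }
    x[i] - max(lmin, rmin)
  }, numeric(1))
  list(peaks = peaks, prominence = prom)
}

#' Detect diastolic E- and A-wave KE peaks
#'
#' Local maxima of total KE over diastole with prominence at least
#' \code{prominence * max(diastolic KE)} are candidate peaks; the earliest
#' is the E-peak and the latest the A-peak. The curve is fused when fewer
#' than two candidates exist or when the inter-peak trough exceeds
#' \code{troughRatio * min(keE, keA)}. Spill-over is KE at the first
#' systolic phase (onset of systole, ED) above \code{spillover *
#' max(diastolic KE)}. A light cyclic 3-point binomial smoother (weights
#' 1/4, 1/2, 1/4) is applied before peak detection (default on) since
#' measured KE curves are smooth and phase-wise noise otherwise spawns
#' spurious candidates.
#'
#' @param curve a [KECurve-class].
#' @param phases a [CardiacPhases-class]; diastole must span >= 4 phases.
#' @param prominence candidate-peak prominence threshold as a fraction of
#'   the diastolic maximum (default 0.10).
#' @param troughRatio fused when trough > troughRatio * min(keE, keA)
#'   (default 0.7).
#' @param spillover spill-over threshold as a fraction of the diastolic
#'   maximum (default 0.5).
#' @param smooth apply the cyclic binomial smoother before detection
#'   (default TRUE).
#' @return A [PatternResult-class] with features set and label NA.
#' @export
detectDiastolicPeaks <- function(curve, phases, prominence = 0.10,
                                 troughRatio = 0.7, spillover = 0.5,
                                 smooth = TRUE) {
  if (length(phases@diastole) < 4L)
    stop("diastole must span at least 4 phases")
  tot <- curve@total
  if (smooth) {
    n <- length(tot)
    tot <- (tot[c(n, 1:(n - 1L))] + 2 * tot + tot[c(2:n, 1L)]) / 4
  }
  dia <- tot[phases@diastole]
  if (all(dia == 0)) stop("all-zero diastolic KE curve")
  diaMax <- max(dia)
  pp <- peakProminences(dia)
  keep <- pp$prominence >= prominence * diaMax
  cand <- pp$peaks[keep]
  spill <- tot[phases@systole[1L]] > spillover * diaMax
  if (length(cand) < 2L) {
    return(new("PatternResult", keE = NA_real_, keA = NA_real_,
               fused = TRUE, spillover = spill, label = NA_character_,
               tie = FALSE,
               params = list(prominence = prominence,
                             troughRatio = troughRatio,
                             spillover = spillover, smooth = smooth)))
  }
  e <- cand[1L]; a <- cand[length(cand)]
  keE <- dia[e]; keA <- dia[a]
  trough <- min(dia[e:a])
  fused <- trough > troughRatio * min(keE, keA)
  new("PatternResult",
      keE = if (fused) NA_real_ else keE,
      keA = if (fused) NA_real_ else keA,
      fused = fused, spillover = spill, label = NA_character_,
      tie = !fused && keE == keA,
      params = list(prominence = prominence, troughRatio = troughRatio,
                    spillover = spillover, smooth = smooth))
}

#' Classify a KE time curve into the three heart-failure patterns
#'
#' Fused peaks give pattern p3. Otherwise \code{keE < keA} gives p1 and
#' \code{keE > keA} gives p2 for patients; controls with a dominant,
#' separated E-peak (\code{keE > keA}, not fused) are labelled
#' \code{control_like}. Exact ties are labelled p2 with the tie flag set.
#'
#' @param features a [PatternResult-class] from [detectDiastolicPeaks()].
#' @param subjectClass \code{"patient"} or \code{"control"}.
#' @return The [PatternResult-class] with \code{label} set.
#' @export
classifyPattern <- function(features, subjectClass = c("patient", "control")) {
  subjectClass <- match.arg(subjectClass)
  label <- if (features@fused) {
    "p3"
  } else if (features@tie) {
    "p2"
  } else if (features@keE < features@keA) {
    "p1"
  } else if (subjectClass == "control") {
    "control_like"
  } else {
    "p2"
  }
  features@label <- label
  features
}

#' Build a pattern-vs-grade agreement table
#'
#' Aligns the KE-curve pattern labels with the diastolic-dysfunction
#' grades (p1 <-> impaired relaxation, p2 <-> pseudonormal filling,
#' p3 <-> restrictive filling). Subjects with undetermined grade are
#' excluded and counted.
#'
#' @param labels character, pattern labels ("p1", "p2", "p3").
#' @param grades character, one of \code{"impaired"}, \code{"pseudonormal"},
#'   \code{"restrictive"}, \code{"undetermined"}.
#' @return An [AgreementTable-class].
#' @export
buildAgreementTable <- function(labels, grades) {
  stopifnot(length(labels) == length(grades))
  keep <- grades != "undetermined"
  counts <- table(factor(labels[keep], levels = c("p1", "p2", "p3")),
                  factor(grades[keep],
                         levels = c("impaired", "pseudonormal",
                                    "restrictive")))
  m <- matrix(as.integer(counts), 3L, 3L,
              dimnames = dimnames(counts))
  new("AgreementTable", counts = m, excluded = sum(!keep))
}

#' Cohen's kappa with asymptotic standard error
#'
#' Unweighted kappa \eqn{(P_o - P_e)/(1 - P_e)} on a square contingency
#' table, with the Fleiss-Cohen-Everitt large-sample standard error and the
#' normal-approximation 95\% confidence interval.
#'
#' @param table an [AgreementTable-class] or a square numeric count matrix.
#' @return \code{list(kappa, se, ci)} with \code{ci} a length-2 vector.
#' @examples
#' # printed pattern-vs-grade counts (n = 25): kappa ~ 0.41
#' m <- rbind(c(7, 3, 0), c(0, 2, 2), c(1, 4, 6))
#' cohenKappa(m)$kappa
#' @export
cohenKappa <- function(table) {
  m <- if (is(table, "AgreementTable")) table@counts else as.matrix(table)
  if (nrow(m) != ncol(m)) stop("contingency table must be square")
  n <- sum(m)
  if (n < 2) stop("at least 2 rated subjects are required")
  p <- m / n
  po <- sum(diag(p))
  pi_ <- rowSums(p)
  pj <- colSums(p)
  pe <- sum(pi_ * pj)
  if (pe >= 1) stop("degenerate marginals: expected agreement is 1")
  kappa <- (po - pe) / (1 - pe)
  k <- nrow(m)
  A <- sum(vapply(seq_len(k), function(i)
    p[i, i] * ((1 - pe) - (pj[i] + pi_[i]) * (1 - po))^2, numeric(1)))
  B <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    B <- B + p[i, j] * (pj[i] + pi_[j])^2
  B <- (1 - po)^2 * B
  C <- (po * pe - 2 * pe + po)^2
  se <- sqrt((A + B - C) / (n * (1 - pe)^4))
  list(kappa = kappa, se = se,
       ci = kappa + c(-1, 1) * stats::qnorm(0.975) * se)
}

#' Coefficient of variation of KE time curves
#'
#' CV = sample SD / mean of each subject's total-KE curve, tabulated for
#' group comparison.
#'
#' @param curves named list of [KECurve-class] objects.
#' @return data.frame with columns \code{subject} and \code{cv}.
#' @export
curveCVCompare <- function(curves) {
  if (!length(curves)) stop("no curves supplied")
  cvs <- vapply(curves, function(cu) {
    m <- mean(cu@total)
    if (m <= 0) stop("KE curve mean must be positive for CV")
    stats::sd(cu@total) / m
  }, numeric(1))
  data.frame(subject = names(curves) %||% as.character(seq_along(curves)),
             cv = unname(cvs))
}
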