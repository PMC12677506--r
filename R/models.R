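#' @include AllClasses.R
NULL

#' Signed multiexponential inversion-recovery signal
#'
#' Evaluates the discrete inversion-recovery model
#' \deqn{y(t_i) = \sum_j A_j (1 - 2 e^{-t_i / T_{1j}})}
#' at the supplied inversion times. Padded zero-amplitude slots (T1 = NA)
#' contribute nothing.
#'
#' @param components A [ComponentSet-class] with at least one component.
#' @param ti Numeric vector of nonnegative inversion times (ms).
#' @return Numeric vector of signed signal values, one per inversion time.
#' @examples
#' irSignal(ComponentSet(1, 1000), 0)            # -1: full inversion
#' irSignal(ComponentSet(1, 1000), 1000 * log(2)) # 0: the null point
#' @export
irSignal <- function(components, ti) {
  stopifnot(is(components, "ComponentSet"))
  if (nComponents(components) == 0)
    stop("degenerate model: component set is empty")
  ti <- as.numeric(ti)
  if (any(ti < 0)) stop("inversion times must be nonnegative")
  A <- amplitudes(components)
  T1 <- t1Values(components)
  keep <- !is.na(T1)
  if (!any(keep)) return(rep(0, length(ti)))
  # N x J kernel evaluated against real components only
  K <- 1 - 2 * exp(-outer(ti, 1 / T1[keep]))
  as.numeric(K %*% A[keep])
}

#' Magnitude multiexponential inversion-recovery signal
#'
#' Element-wise absolute value of [irSignal()]; the model observed under
#' magnitude-only image reconstruction, fitted without polarity restoration.
#'
#' @inheritParams irSignal
#' @return Numeric vector of nonnegative signal values.
#' @examples
#' magnitudeIRSignal(ComponentSet(1, 1000), 0)  # 1
#' @export
magnitudeIRSignal <- function(components, ti) {
  abs(irSignal(components, ti))
}

# Shared sign-pattern application: negate samples strictly before nullIdx.
applySignPattern <- function(magnitude, nullIdx) {
  s <- rep(1, length(magnitude))
  if (nullIdx > 1) s[seq_len(nullIdx - 1L)] <- -1
  s * magnitude
}

# Null-point index of a complex IR signal from the |Re|/|Im| crossing;
# returns NA when the two never cross.
complexNullIndex <- function(values) {
  d <- abs(Re(values)) - abs(Im(values))
  exact <- which(d == 0)
  crossings <- which(d[-length(d)] * d[-1] < 0)
  if (length(exact) == 0 && length(crossings) == 0) return(NA_integer_)
  if (length(exact) > 0 && (length(crossings) == 0 || exact[1] <= crossings[1]))
    return(exact[1])
  i <- crossings[1]
  # nearer of the two bracketing samples: smaller |d| wins, ties to the left
  if (abs(d[i]) <= abs(d[i + 1L])) i else i + 1L
}

#' @describeIn restorePolarity Complex curves use the `|Re|`/`|Im|` crossing;
#'   magnitude curves use the global minimum as the null index.
setMethod("restorePolarity", "IRCurve", function(curve) {
  kind <- signalKind(curve)
  v <- signalValues(curve)
  if (kind == "signed_real")
    stop("curve already carries signed values; nothing to restore")
  if (kind == "complex") {
    m <- Mod(v)
    nullIdx <- complexNullIndex(v)
    if (is.na(nullIdx)) {
      warning("no |Re|/|Im| crossing found; falling back to the minimum-magnitude index")
      nullIdx <- which.min(m)
    }
  } else {
    m <- v
    nullIdx <- which.min(m)
  }
  IRCurve(inversionTimes(curve), applySignPattern(m, nullIdx), "signed_real")
})
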