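# Gaussian-copula information estimators and phase-amplitude coupling.
#
# All mutual-information quantities are reported in bits (log base 2).
# No analytic small-sample bias term is applied inside the estimators:
# bias is removed downstream by permutation (median-null subtraction).

#' Gaussian-copula rank transform
#'
#' Maps each variable (column) to the standard-normal quantiles of its
#' ranks: `qnorm((rank - 0.5) / n)`, with average ranks for ties. The
#' transform is invariant to strictly monotone transformations of the
#' input, which makes all downstream information estimates bin-less and
#' robust to marginal distributions.
#'
#' @param x Numeric vector or matrix (columns are dimensions), n >= 8.
#' @return A matrix of the same shape with copula-normalized columns.
#' @export
#' @examples
#' z <- copula_transform(rexp(100))
#' round(mean(z), 2)
copula_transform <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 8L) stop_invalid("need at least 8 samples, got %d", n)
  if (!all(is.finite(x))) stop_invalid("input must be finite")
  out <- apply(x, 2L, function(col) {
    if (max(col) == min(col)) stop_invalid("degenerate input: constant dimension")
    stats::qnorm((rank(col, ties.method = "average") - 0.5) / n)
  })
  matrix(out, nrow = n)
}

# log2 determinant of a covariance; errors on (near-)singular matrices.
logdet2 <- function(m) {
  ev <- determinant(m, logarithm = TRUE)
  if (ev$sign <= 0) stop_invalid("degenerate input: singular joint covariance")
  as.numeric(ev$modulus) / log(2)
}

# Covariance of pre-transformed columns (mean is ~0 by construction but
# demeaning costs nothing and guards subsetting).
cov_of <- function(m) stats::cov(m)

#' Gaussian-copula mutual information
#'
#' Mutual information, in bits, between two (possibly multivariate)
#' continuous variables under a Gaussian copula: both variables are
#' rank-normalized with [copula_transform()] and the Gaussian MI
#' `0.5 * log2(det(Cxx) det(Cyy) / det(Cxy))` is evaluated on the joint
#' sample covariance. Non-negative by construction; invariant to
#' monotone marginal transforms; symmetric in its arguments.
#'
#' @param x,y Numeric vectors or matrices with equal row counts; at most
#'   3 columns each.
#' @param transformed Set `TRUE` when inputs are already
#'   copula-transformed (skips the rank step).
#' @return Mutual information in bits (>= 0).
#' @export
#' @examples
#' n <- 2000; x <- rnorm(n); y <- 0.5 * x + rnorm(n, sd = sqrt(0.75))
#' gcmi_mi(x, y)  # close to -0.5 * log2(1 - 0.25) = 0.2075
gcmi_mi <- function(x, y, transformed = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop_invalid("x and y must have equal sample counts")
  if (ncol(x) > 3L || ncol(y) > 3L) stop_invalid("at most 3 dimensions per variable")
  if (!transformed) { x <- copula_transform(x); y <- copula_transform(y) }
  cxy <- cov_of(cbind(x, y))
  ix <- seq_len(ncol(x)); iy <- ncol(x) + seq_len(ncol(y))
  mi <- 0.5 * (logdet2(cxy[ix, ix, drop = FALSE]) +
               logdet2(cxy[iy, iy, drop = FALSE]) - logdet2(cxy))
  max(mi, 0)
}

#' Gaussian-copula conditional mutual information
#'
#' `I(x; y | z)` in bits under the Gaussian-copula model, evaluated from
#' the partitioned joint covariance:
#' `0.5 * log2(det(Cxz) det(Cyz) / (det(Cz) det(Cxyz)))`.
#'
#' @param x,y,z Numeric vectors or matrices with equal row counts.
#' @param transformed Set `TRUE` when inputs are already copula-transformed.
#' @return Conditional mutual information in bits (>= 0).
#' @export
gcmi_cmi <- function(x, y, z, transformed = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y); z <- as.matrix(z)
  if (nrow(x) != nrow(y) || nrow(x) != nrow(z)) {
    stop_invalid("x, y, z must have equal sample counts")
  }
  if (!transformed) {
    x <- copula_transform(x); y <- copula_transform(y); z <- copula_transform(z)
  }
  cc <- cov_of(cbind(x, y, z))
  ix <- seq_len(ncol(x))
  iy <- ncol(x) + seq_len(ncol(y))
  iz <- ncol(x) + ncol(y) + seq_len(ncol(z))
  # y fully explained by the conditioning set: I(x; y | z) = 0 (the
  # joint covariance is singular there, but the limit is exact)
  eyz <- eigen(cc[c(iy, iz), c(iy, iz), drop = FALSE], symmetric = TRUE,
               only.values = TRUE)$values
  if (min(eyz) < 1e-12 * max(eyz)) return(0)
  cmi <- 0.5 * (logdet2(cc[c(ix, iz), c(ix, iz), drop = FALSE]) +
                logdet2(cc[c(iy, iz), c(iy, iz), drop = FALSE]) -
                logdet2(cc[iz, iz, drop = FALSE]) - logdet2(cc))
  max(cmi, 0)
}

#' Normalized information-theoretic redundancy
#'
#' Percentage of the total feature information about the neural signal
#' that is shared between two stimulus features (speech envelope and lip
#' trajectory): `(MI_speech + MI_lip - MI_joint) / (MI_speech + MI_lip) * 100`.
#' Under this normalization full overlap yields 50%.
#'
#' @param mi_speech,mi_lip Marginal MI values in bits.
#' @param mi_joint Joint MI `I(neural; speech, lip)` in bits.
#' @return Redundancy in percent.
#' @export
redundancy <- function(mi_speech, mi_lip, mi_joint) {
  denom <- mi_speech + mi_lip
  if (!is.finite(denom) || denom <= 0) stop_invalid("degenerate input: mi_speech + mi_lip must be > 0")
  (mi_speech + mi_lip - mi_joint) / denom * 100
}

#' Audio-visual information decomposition
#'
#' Bundles the marginal, joint, conditional and redundancy terms for one
#' neural signal and the two stimulus features. `cmi = mi_joint - mi_lip`
#' is the speech information conditioned on the lip trajectory.
#'
#' @param neural,speech,lip Numeric vectors/matrices of equal length.
#' @return A list with `mi_speech`, `mi_lip`, `mi_joint`, `cmi`,
#'   `red_percent` (all MI terms in bits).
#' @export
info_decomp <- function(neural, speech, lip) {
  nt <- copula_transform(neural)
  st <- copula_transform(speech)
  lt <- copula_transform(lip)
  mi_s <- gcmi_mi(nt, st, transformed = TRUE)
  mi_l <- gcmi_mi(nt, lt, transformed = TRUE)
  mi_j <- gcmi_mi(nt, cbind(st, lt), transformed = TRUE)
  list(mi_speech = mi_s, mi_lip = mi_l, mi_joint = mi_j,
       cmi = mi_j - mi_l,
       red_percent = redundancy(mi_s, mi_l, mi_j))
}

#' Phase-amplitude coupling
#'
#' Modulus of the amplitude-weighted mean phase vector,
#' `|mean((A / mean(A)) * exp(i * theta))|`, where `A` is the
#' high-frequency Hilbert amplitude and `theta` the low-frequency phase.
#' Amplitudes are normalized by their mean so the statistic is
#' dimensionless and lies in \\[0, 1\\]: 0 for amplitude independent of
#' phase (in expectation), approaching 1 when all amplitude concentrates
#' at one phase.
#'
#' @param amp_high Non-negative amplitude sequence (or `analytic_signal`).
#' @param phase_low Phase sequence in radians (or `analytic_signal`).
#' @return Coupling strength in \\[0, 1\\].
#' @export
pac <- function(amp_high, phase_low) {
  a <- if (inherits(amp_high, "analytic_signal")) amp_high$amplitude else as.numeric(amp_high)
  th <- if (inherits(phase_low, "analytic_signal")) phase_low$phase else as.numeric(phase_low)
  if (length(a) != length(th)) stop_invalid("amplitude and phase must have equal length")
  if (any(a < 0)) stop_invalid("amplitudes must be non-negative")
  ma <- mean(a)
  if (ma <= 0) stop_invalid("degenerate input: zero amplitude everywhere")
  min(Mod(mean((a / ma) * exp(1i * th))), 1)
}
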