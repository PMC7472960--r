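#' Build the 2x2 voxel contingency table
#'
#' At one voxel, for a two-level phenotype split: \code{a} patients of
#' phenotype A with tumor at the voxel, \code{b} of phenotype B with tumor,
#' \code{c} of A tumor-free, \code{d} of B tumor-free, \code{n = a+b+c+d}.
#'
#' @param countA,countB occupying-patient counts at the voxel per group.
#' @param nA,nB group sizes.
#' @return object of class \code{contingency_table} with fields
#'   \code{a,b,c,d,n}.
#' @export
voxel_contingency <- function(countA, nA, countB, nB) {
  if (countA < 0 || countB < 0 || countA > nA || countB > nB)
    stop("counts must lie in [0, group size]", call. = FALSE)
  structure(list(a = as.integer(countA), b = as.integer(countB),
                 c = as.integer(nA - countA), d = as.integer(nB - countB),
                 n = as.integer(nA + nB)),
            class = "contingency_table")
}

as_abcd <- function(t) {
  if (inherits(t, "contingency_table")) c(t$a, t$b, t$c, t$d)
  else if (is.matrix(t) && all(dim(t) == 2L)) c(t[1, 1], t[1, 2],
                                                t[2, 1], t[2, 2])
  else if (length(t) == 4L) as.numeric(t)
  else stop("expected a contingency_table, 2x2 matrix, or length-4 vector",
            call. = FALSE)
}

# log point probability of the table (a, k-a, nA-a, nB-k+a) for a vector of
# a values, conditioning on margins (nA, nB, k = lesion total)
log_hyper_prob <- function(a, nA, nB, k) {
  n <- nA + nB
  (lgamma(k + 1) + lgamma(n - k + 1) + lgamma(nA + 1) + lgamma(nB + 1) -
     lgamma(n + 1)) -
    (lgamma(a + 1) + lgamma(k - a + 1) + lgamma(nA - a + 1) +
       lgamma(nB - k + a + 1))
}

#' Hypergeometric point probability of a 2x2 table
#'
#' The probability of observing exactly this table under fixed margins:
#' (a+b)! (c+d)! (a+c)! (b+d)! / (a! b! c! d! n!), evaluated in log space
#' via \code{lgamma} for numerical stability.
#'
#' @param t a \code{\link{voxel_contingency}} table, 2x2 matrix, or numeric
#'   vector \code{c(a, b, c, d)}.
#' @return the point probability in (0, 1].
#' @examples
#' hypergeometric_point_probability(c(1, 1, 1, 1))  # 2/3
#' @export
hypergeometric_point_probability <- function(t) {
  v <- as_abcd(t)
  if (any(v < 0)) stop("table entries must be nonnegative", call. = FALSE)
  if (sum(v) < 1) stop("table total must be >= 1", call. = FALSE)
  exp(log_hyper_prob(v[1], v[1] + v[3], v[2] + v[4], v[1] + v[2]))
}

# core two-tailed Fisher by the method of small p-values, one scalar table.
# Tables are canonicalised (smaller group first) so the group-swap image
# follows the identical floating-point path and symmetry is bitwise exact.
fisher_two_tailed_scalar <- function(a, nA, nB, k, rel_tol = 1e-7) {
  if (nA > nB || (nA == nB && a > k - a)) {
    tmp <- nA; nA <- nB; nB <- tmp
    a <- k - a
  }
  lo <- max(0, k - nB)
  hi <- min(k, nA)
  if (lo == hi) return(1)
  xs <- lo:hi
  lp <- log_hyper_prob(xs, nA, nB, k)
  lobs <- lp[a - lo + 1L]
  keep <- lp <= lobs + log1p(rel_tol)
  if (all(keep)) return(1)  # every table qualifies: p is exactly 1
  min(1, sum(exp(lp[keep])))
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Enumerates every table with the observed margins and sums the point
#' probabilities of all tables whose probability does not exceed the
#' observed one ("method of small p-values"), with a relative tolerance of
#' 1e-7 guarding against floating-point ties. Degenerate margins (a row or
#' column total of zero) admit a single table and give p = 1.
#'
#' @inheritParams hypergeometric_point_probability
#' @return two-tailed p-value in (0, 1].
#' @examples
#' fisher_exact_two_tailed(c(5, 0, 0, 5))  # 2/252
#' @export
fisher_exact_two_tailed <- function(t) {
  v <- as_abcd(t)
  if (any(v < 0)) stop("table entries must be nonnegative", call. = FALSE)
  fisher_two_tailed_scalar(v[1], v[1] + v[3], v[2] + v[4], v[1] + v[2])
}

# vectorised + memoised over repeated (countA, countB) pairs at fixed group
# sizes: voxel tables repeat massively across a map, so each distinct table
# is enumerated once. Returns list(p, n_distinct).
fisher_p_vector <- function(countA, countB, nA, nB) {
  key <- countA * (nB + 1) + countB
  ukey <- unique(key)
  ua <- ukey %/% (nB + 1)
  ub <- ukey %% (nB + 1)
  up <- vapply(seq_along(ukey), function(i)
    fisher_two_tailed_scalar(ua[i], nA, nB, ua[i] + ub[i]), numeric(1))
  list(p = up[match(key, ukey)], n_distinct = length(ukey))
}
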