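#' Kruskal-Wallis one-way analysis of variance by ranks
#'
#' H statistic with midranks and the standard tie correction; the p-value
#' comes from the chi-square approximation with k - 1 degrees of freedom,
#' or from full enumeration of all distinct group labellings when
#' `exact = TRUE` (practical for total N up to about 10).
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @param exact compute the permutation p-value by full enumeration.
#' @return A `test_result`: `statistic` (H), `p_value`, `method`, `df`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(x)
  if (N < 3) stop("need total N >= 3")
  H <- kw_statistic(x, g)
  k <- length(groups)
  if (exact) {
    Hs <- apply(group_labellings(table(g)), 2L,
                function(perm) kw_statistic(x, perm))
    p <- mean(Hs >= H - 1e-12)
    method <- "Kruskal-Wallis (exact permutation)"
  } else {
    p <- pchisq(H, df = k - 1, lower.tail = FALSE)
    method <- "Kruskal-Wallis (chi-square approximation)"
  }
  structure(list(statistic = H, p_value = p, adjusted_p = NULL,
                 method = method, df = k - 1), class = "test_result")
}

kw_statistic <- function(x, g) {
  N <- length(x)
  r <- rank(x)  # midranks
  Rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(n * Rbar^2) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(0)
  H / C
}

# all distinct assignments of observations to groups with the given sizes:
# returns an N x (number of labellings) integer matrix
group_labellings <- function(sizes) {
  sizes <- as.integer(sizes)
  N <- sum(sizes)
  rec <- function(remaining_idx, sizes_left) {
    if (length(sizes_left) == 1L) {
      m <- matrix(0L, N, 1L)
      m[remaining_idx, 1L] <- length(sizes_left)
      return(m)
    }
    gidx <- length(sizes_left)
    picks <- utils::combn(remaining_idx, sizes_left[gidx],
                          simplify = FALSE)
    cols <- lapply(picks, function(p) {
      rest <- rec(setdiff(remaining_idx, p), sizes_left[-gidx])
      rest[p, ] <- gidx
      rest
    })
    do.call(cbind, cols)
  }
  rec(seq_len(N), sizes)
}

#' Mann-Whitney U test
#'
#' U computed from midranks. For small samples without ties
#' (`max(n) <= exact_limit`) the two-sided p-value is exact, by full
#' enumeration of all group labellings; otherwise the normal approximation
#' with tie correction and continuity correction is used. Two-sided.
#'
#' @param a,b numeric vectors, non-empty.
#' @param exact_limit per-group size up to which the exact enumeration is
#'   used (when there are no ties).
#' @return A `test_result`: `statistic` (U of the first sample),
#'   `p_value`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_limit = 8) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  U <- mw_u(a, b)
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && max(n1, n2) <= exact_limit) {
    x <- c(a, b)
    picks <- utils::combn(n1 + n2, n1, simplify = FALSE)
    Us <- vapply(picks, function(p) mw_u(x[p], x[-p]), 0)
    centre <- n1 * n2 / 2
    p <- mean(abs(Us - centre) >= abs(U - centre) - 1e-12)
    method <- "Mann-Whitney (exact enumeration)"
  } else {
    N <- n1 + n2
    tie_tab <- table(c(a, b))
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "Mann-Whitney (normal approximation, tie-corrected)"
  }
  structure(list(statistic = U, p_value = p, adjusted_p = NULL,
                 method = method), class = "test_result")
}

mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for each p-value; `m` defaults to the number of
#' p-values, which for the three-member family post hoc is the 3 pairwise
#' comparisons.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param m number of comparisons.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  pmin(1, pvals * m)
}

#' Omnibus test with conditional post hoc pairwise comparisons
#'
#' Runs the Kruskal-Wallis omnibus test across the groups; only if it is
#' significant at `alpha` are Mann-Whitney pairwise comparisons performed,
#' with Bonferroni adjustment over the number of pairs.
#'
#' @param groups named list of numeric vectors (one per phantom family
#'   member).
#' @param alpha omnibus significance criterion (default 0.05).
#' @return list with `omnibus` (`test_result`) and `posthoc` (data frame
#'   of pairwise results, or NULL if the omnibus test is not significant).
#' @export
kw_with_posthoc <- function(groups, alpha = 0.05) {
  omni <- kruskal_wallis(groups)
  posthoc <- NULL
  if (omni$p_value < alpha) {
    nms <- names(groups)
    if (is.null(nms)) nms <- paste0("group", seq_along(groups))
    pairs <- utils::combn(length(groups), 2)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      mw <- mann_whitney_u(groups[[i1]], groups[[i2]])
      data.frame(group1 = nms[i1], group2 = nms[i2], U = mw$statistic,
                 p_value = mw$p_value, method = mw$method,
                 stringsAsFactors = FALSE)
    })
    posthoc <- do.call(rbind, rows)
    posthoc$adjusted_p <- bonferroni(posthoc$p_value, m = nrow(posthoc))
  }
  list(omnibus = omni, posthoc = posthoc)
}
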