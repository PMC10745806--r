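# Group comparison machinery: normality-gated scalar tests and per-position
# profile comparisons with step-up false-discovery-rate control.

#' Shapiro-Wilk normality p-value
#'
#' @param sample Numeric vector, 3 <= n <= 5000, non-constant.
#' @return The Shapiro-Wilk p-value.
#' @export
shapiro_wilk <- function(sample) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk needs 3 <= n <= 5000")
  if (max(sample) == min(sample)) stop("constant sample has no normality test")
  stats::shapiro.test(sample)$p.value
}

#' Two-sided Mann-Whitney U test
#'
#' U is the number of (a, b) pairs with a > b (ties counting one half). The
#' p-value is exact (full rank-assignment distribution) when the smaller
#' group has at most `exact_max` observations and there are no ties, and
#' otherwise uses the normal approximation with mid-ranks, tie-corrected
#' variance and continuity correction.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest min(n) for which the exact distribution is used.
#' @return List with `U`, `p_value`, `exact`.
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Normality-gated two-group comparison of scalar measurements
#'
#' Both groups are first screened with the Shapiro-Wilk test; if both pass
#' (p > `alpha_normality`) an unpaired two-sided Student t test (pooled
#' variance) is used, otherwise a two-sided Mann-Whitney test.
#'
#' @param a,b Numeric samples, each n >= 3.
#' @param alpha_normality Normality screening level (default 0.05).
#' @return An `axo_scalar_test`: `test_used` ("student_t" or "mann_whitney"),
#'   `statistic`, `p_value`, `normality_p` (per group), `group_ns`.
#' @export
compare_scalars <- function(a, b, alpha_normality = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  norm_p <- c(a = shapiro_wilk(a), b = shapiro_wilk(b))
  if (all(norm_p > alpha_normality)) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(test_used = "student_t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    mw <- mann_whitney(a, b)
    res <- list(test_used = "mann_whitney", statistic = mw$U,
                p_value = mw$p_value)
  }
  structure(c(res, list(normality_p = norm_p,
                        group_ns = c(a = length(a), b = length(b)))),
            class = "axo_scalar_test")
}

#' @export
print.axo_scalar_test <- function(x, ...) {
  cat(sprintf("<axo_scalar_test> %s: statistic %.4g, p = %.4g (n = %d, %d)\n",
              x$test_used, x$statistic, x$p_value,
              x$group_ns[1], x$group_ns[2]))
  invisible(x)
}

#' Step-up false-discovery-rate discoveries
#'
#' `bh` is the Benjamini-Hochberg linear step-up; `bky` is the two-stage
#' linear step-up of Benjamini, Krieger and Yekutieli (the default FDR of
#' common statistics software at q = 5%): stage one runs BH at
#' q' = q / (1 + q) to estimate the number of true nulls, stage two reruns
#' BH at q' scaled by m / m0_hat.
#'
#' @param p Vector of raw p-values.
#' @param q FDR level (default 0.05).
#' @param method `"bky"` (default) or `"bh"`.
#' @return Logical vector of discoveries.
#' @export
fdr_discoveries <- function(p, q = 0.05, method = c("bky", "bh")) {
  method <- match.arg(method)
  if (!is.numeric(q) || q < 0 || q >= 1) stop("q must be in [0, 1)")
  if (!length(p)) return(logical(0))
  if (q == 0) return(rep(FALSE, length(p)))
  bh <- function(pv, level) stats::p.adjust(pv, "BH") <= level
  if (method == "bh") return(bh(p, q))
  q1 <- q / (1 + q)
  r1 <- sum(bh(p, q1))
  m <- length(p)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh(p, q1 * m / (m - r1))
}

#' Per-position profile comparison with FDR control
#'
#' Runs a two-sided Mann-Whitney test at every shared profile position, the
#' per-image profile values being the observations, and flags discoveries by
#' a step-up FDR procedure at level `q` across all tested positions jointly.
#' Positions with fewer than `min_n` valid observations in either group are
#' excluded from testing and reported with `tested = FALSE`.
#'
#' @param group_a,group_b `axo_profile` objects (their `per_image` matrices
#'   are used), or plain numeric matrices (rows = images, columns =
#'   positions) with a `positions` attribute or matching `positions`
#'   argument.
#' @param q FDR level (default 0.05).
#' @param method FDR flavour, `"bky"` (default) or `"bh"`.
#' @param min_n Minimum valid observations per group per position.
#' @param positions Optional positions (um) when matrices are supplied.
#' @return A data.frame of class `axo_profile_comparison`: `position`, `n_a`,
#'   `n_b`, `U`, `p`, `discovery`, `tested`; attributes `q` and `method`.
#' @export
compare_profiles <- function(group_a, group_b, q = 0.05,
                             method = c("bky", "bh"), min_n = 3L,
                             positions = NULL) {
  method <- match.arg(method)
  ga <- profile_matrix(group_a, positions)
  gb <- profile_matrix(group_b, positions)
  shared <- intersect_positions(ga$positions, gb$positions)
  ia <- match(round(shared, 9), round(ga$positions, 9))
  ib <- match(round(shared, 9), round(gb$positions, 9))
  np <- length(shared)
  out <- data.frame(position = shared, n_a = NA_integer_, n_b = NA_integer_,
                    U = NA_real_, p = NA_real_, discovery = FALSE,
                    tested = FALSE)
  for (k in seq_len(np)) {
    va <- ga$values[, ia[k]]; va <- va[is.finite(va)]
    vb <- gb$values[, ib[k]]; vb <- vb[is.finite(vb)]
    out$n_a[k] <- length(va); out$n_b[k] <- length(vb)
    if (length(va) >= min_n && length(vb) >= min_n) {
      if (max(c(va, vb)) == min(c(va, vb))) {   # all values identical
        out$U[k] <- length(va) * length(vb) / 2
        out$p[k] <- 1
      } else {
        mw <- mann_whitney(va, vb)
        out$U[k] <- mw$U
        out$p[k] <- mw$p_value
      }
      out$tested[k] <- TRUE
    }
  }
  out$discovery[out$tested] <- fdr_discoveries(out$p[out$tested], q, method)
  attr(out, "q") <- q
  attr(out, "method") <- method
  class(out) <- c("axo_profile_comparison", class(out))
  out
}

# ---- internal ---------------------------------------------------------------

profile_matrix <- function(g, positions = NULL) {
  if (inherits(g, "axo_profile"))
    return(list(values = g$per_image, positions = g$positions))
  m <- as.matrix(g)
  pos <- positions %||% attr(g, "positions")
  if (is.null(pos)) stop("positions required for plain matrices")
  if (length(pos) != ncol(m)) stop("positions length must match columns")
  list(values = m, positions = pos)
}

intersect_positions <- function(a, b) {
  shared <- intersect(round(a, 9), round(b, 9))
  if (!length(shared)) stop("profiles share no positions")
  sort(shared)
}
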