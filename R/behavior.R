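#' Remove bivariate outliers by the Tukey fence rule
#'
#' A point is dropped when its x or y value falls outside
#' \[Q1 - k IQR, Q3 + k IQR\] of that variable (single pass; fences computed
#' once on the input). Quartiles use linear interpolation between order
#' statistics (`stats::quantile` type 7). The fence interval is closed, so a
#' point exactly on a fence is retained.
#'
#' @param x,y Paired numeric vectors (no missing values; filter first).
#' @param k Fence multiplier; default 1.5.
#' @return Integer vector of kept indices, with attribute `"removed"` (the
#'   dropped indices).
#' @export
remove_outliers <- function(x, y, k = 1.5) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y))))
    stop("x and y must be finite and complete")
  if (length(x) < 5) stop("need at least 5 paired points")
  inside <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    v >= q[1] - k * iqr & v <= q[2] + k * iqr
  }
  keep <- which(inside(x) & inside(y))
  if (length(keep) < 5) stop("fewer than 5 points survive outlier removal")
  attr(keep, "removed") <- setdiff(seq_along(x), keep)
  keep
}

#' Spearman rank correlation test
#'
#' rho is the Pearson correlation of mid-ranks (ties get average ranks). The
#' two-tailed p-value is exact (enumeration over all rank permutations) for
#' n <= 7 without ties, and otherwise uses the t approximation
#' t = rho sqrt((n-2) / (1-rho^2)) on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, n >= 5.
#' @return List with `rho`, `p.value`, `n` and `method` ("exact" or
#'   "t-approximation").
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- any(duplicated(x)) || any(duplicated(y))
  if (n <= 7 && !ties) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  list(rho = rho, p.value = p, n = n, method = method)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Associate altered connectivity measures with cognitive scores
#'
#' Spearman correlation between each altered measure and each available
#' cognitive score, computed in the patient group only, after removing
#' outliers with [remove_outliers()]. Missing scores are dropped pairwise.
#' No multiplicity correction is applied (exploratory tier); rows are flagged
#' at p < `alpha` uncorrected and sorted by p.
#'
#' @param measures Data frame of per-subject measures (patients), one column
#'   per measure, plus optionally an `id` column.
#' @param scores Data frame with the same subjects (row-aligned) holding the
#'   score columns named in `score_names`.
#' @param altered_ids Character vector of measure columns to test.
#' @param score_names Score columns; default `c("mmse", "moca")`.
#' @param outlier_k Tukey fence multiplier passed to [remove_outliers()];
#'   `NULL` disables outlier removal.
#' @param alpha Uncorrected flag threshold; default 0.05.
#' @return Data frame `measure score rho p n_used removed_indices sig_unc`,
#'   sorted by p. Pairs with too few usable points are omitted with a
#'   warning.
#' @export
associate_alterations <- function(measures, scores, altered_ids,
                                  score_names = c("mmse", "moca"),
                                  outlier_k = 1.5, alpha = 0.05) {
  missing_ids <- setdiff(altered_ids, names(measures))
  if (length(missing_ids) > 0)
    stop("unknown measure(s): ", paste(missing_ids, collapse = ", "))
  score_names <- intersect(score_names, names(scores))
  rows <- list()
  skipped <- character(0)
  for (m in altered_ids) for (s in score_names) {
    x <- as.numeric(measures[[m]])
    y <- as.numeric(scores[[s]])
    ok <- which(is.finite(x) & is.finite(y))
    res <- tryCatch({
      kept <- ok
      removed <- integer(0)
      if (!is.null(outlier_k)) {
        ki <- remove_outliers(x[ok], y[ok], k = outlier_k)
        removed <- ok[attr(ki, "removed")]
        kept <- ok[ki]
      }
      st <- spearman_test(x[kept], y[kept])
      data.frame(measure = m, score = s, rho = st$rho, p = st$p.value,
                 n_used = st$n,
                 removed_indices = paste(removed, collapse = ";"),
                 sig_unc = st$p.value < alpha)
    }, error = function(e) NULL)
    if (is.null(res)) skipped <- c(skipped, paste0(m, "/", s))
    else rows[[length(rows) + 1]] <- res
  }
  if (length(skipped) > 0)
    warning("pairs omitted (too few usable points or constant input): ",
            paste(skipped, collapse = ", "))
  if (length(rows) == 0)
    return(data.frame(measure = character(0), score = character(0),
                      rho = numeric(0), p = numeric(0), n_used = integer(0),
                      removed_indices = character(0), sig_unc = logical(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
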