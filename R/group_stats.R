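#' Kruskal-Wallis omnibus test
#'
#' Rank-based one-way comparison of k groups with the standard tie
#' correction; the p-value uses the chi-squared approximation with k - 1
#' degrees of freedom. The fully degenerate case (every observation
#' identical) is reported as H = 0, p = 1.
#'
#' @param groups Named list of numeric vectors (one per group).
#' @return List with `H`, `p`, `df`, and `n` (per-group sizes).
#' @export
kruskal_wallis <- function(groups) {
  groups <- validate_groups(groups, min_groups = 2L)
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) stop("need at least 3 observations in total")
  g <- factor(rep(names(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p = 1, df = length(groups) - 1L, n = lengths(groups)))
  }
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = lengths(groups))
}

#' Dunn-Holland-Wolfe pairwise rank comparisons
#'
#' Large-sample joint-rank procedure following a significant Kruskal-Wallis
#' test. For groups i, j:
#' `Z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j))`
#' with mid-ranks over the pooled sample and tie correction
#' `T = sum(t^3 - t) / (12 (N - 1))`. Groups are declared different when
#' `|Z_ij| >= z_(1 - alpha / (k (k - 1)))`, a single-step Bonferroni-type
#' adjustment over all ordered pairs that controls the familywise error at
#' `alpha`.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Familywise significance level (default 0.05).
#' @return A `pairwise_result`: list with `Z` (k x k), `decisions` (logical
#'   k x k, TRUE = different), `critical`, `alpha`, `mean_ranks`.
#' @export
dunn_holland_wolfe <- function(groups, alpha = 0.05) {
  groups <- validate_groups(groups, min_groups = 2L)
  k <- length(groups)
  nv <- lengths(groups)
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  r <- rank(values) # mid-ranks
  idx <- rep(seq_len(k), nv)
  rbar <- vapply(seq_len(k), function(j) mean(r[idx == j]), numeric(1))
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  varfac <- N * (N + 1) / 12 - tie_term
  Z <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      se <- sqrt(varfac * (1 / nv[i] + 1 / nv[j]))
      z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
      Z[i, j] <- z
      Z[j, i] <- -z
    }
  }
  critical <- stats::qnorm(1 - alpha / (k * (k - 1)))
  decisions <- abs(Z) >= critical
  diag(decisions) <- FALSE
  structure(
    list(Z = Z, decisions = decisions, critical = critical, alpha = alpha,
         mean_ranks = stats::setNames(rbar, names(groups))),
    class = "pairwise_result"
  )
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("<pairwise_result> %d groups, alpha %.3g, |Z| critical %.3f\n",
              nrow(x$Z), x$alpha, x$critical))
  print(x$decisions)
  invisible(x)
}

#' Compact letter display (insert-and-absorb)
#'
#' Assigns letters to groups so that two groups share at least one letter if
#' and only if they were *not* declared different. Implements the
#' insert-and-absorb algorithm: starting from a single letter covering all
#' groups, each significant pair splits every letter column containing both
#' members, and redundant columns (subsets of another column) are absorbed.
#'
#' @param decisions Symmetric logical matrix (TRUE = the pair differs),
#'   empty diagonal; row/column names are the group names.
#' @return Named character vector of letter strings, one per group.
#' @export
letter_display <- function(decisions) {
  decisions <- as.matrix(decisions)
  k <- nrow(decisions)
  if (k != ncol(decisions) || !identical(decisions, t(decisions)) ||
      any(diag(decisions))) {
    stop("decisions must be a symmetric logical matrix with an empty diagonal")
  }
  nms <- rownames(decisions)
  if (is.null(nms)) nms <- paste0("g", seq_len(k))
  cols <- list(seq_len(k)) # letter columns as index sets
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!decisions[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, j)), list(setdiff(col, i)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns contained in another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  if (length(cols) > 26L) stop("more than 26 letter columns required")
  letters_out <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
           collapse = "")
  }, character(1))
  stats::setNames(letters_out, nms)
}

#' One-call group comparison
#'
#' Kruskal-Wallis omnibus test, Dunn-Holland-Wolfe pairwise comparisons and
#' the compact letter display, bundled.
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Familywise significance level.
#' @return A `group_comparison`: list with `omnibus`, `pairwise`, `letters`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  omnibus <- kruskal_wallis(groups)
  pairwise <- dunn_holland_wolfe(groups, alpha = alpha)
  structure(
    list(omnibus = omnibus, pairwise = pairwise,
         letters = letter_display(pairwise$decisions)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4g, df = %d, p = %.4g\n",
              x$omnibus$H, x$omnibus$df, x$omnibus$p))
  cat("Letters:", paste(names(x$letters), x$letters, sep = ":",
                        collapse = "  "), "\n")
  invisible(x)
}

validate_groups <- function(groups, min_groups = 2L) {
  if (!is.list(groups) || length(groups) < min_groups) {
    stop("groups must be a list of at least ", min_groups, " numeric vectors")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  if (any(!vapply(groups, is.numeric, logical(1))) ||
      any(lengths(groups) < 1L)) {
    stop("every group must be a non-empty numeric vector")
  }
  lapply(groups, as.numeric)
}
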