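#' Two-sided Fisher exact test for 2 x k tables
#'
#' For 2 x 2 tables this is the classical conditional exact test; for 2 x 3
#' tables the Freeman-Halton extension: with all margins fixed, the p-value
#' sums the probabilities of every table whose hypergeometric probability does
#' not exceed that of the observed table (within relative tolerance 1e-7).
#'
#' @param table non-negative integer matrix with 2 rows and 2 or 3 columns
#'   (row 1 = event present, row 2 = absent; columns = sites).
#' @return two-sided p-value in (0, 1]. A table with a zero margin carries no
#'   information and returns 1.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || !ncol(table) %in% c(2L, 3L))
    stop("fisher_exact expects a 2x2 or 2x3 table")
  if (any(table < 0)) stop("negative count in contingency table")
  if (any(table != round(table))) stop("non-integer count in contingency table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: adjusted p-values are capped at 1 and monotonized from
#' the largest rank downward, so reordering the input permutes the output
#' identically and no adjusted value falls below its raw value.
#'
#' @param raw numeric vector of p-values in [0, 1].
#' @return list with \code{raw}, \code{adjusted} and \code{method = "BH"}.
#' @export
bh_adjust <- function(raw) {
  if (length(raw) && (any(raw < 0) || any(raw > 1)))
    stop("p-values must lie in [0, 1]")
  list(raw = raw, adjusted = stats::p.adjust(raw, method = "BH"), method = "BH")
}

#' Kruskal-Wallis omnibus test with Dunn post-hoc comparisons
#'
#' The omnibus p-value comes from the chi-square approximation with tie
#' correction. Pairwise Dunn z statistics use the pooled mid-ranks,
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) /
#'   \sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12(N-1)}\right)
#'   (1/n_i + 1/n_j)},}
#' with two-sided normal p-values, Benjamini-Hochberg adjusted across the
#' k(k-1)/2 pairs.
#'
#' @param groups named list of numeric vectors (k >= 2, none empty).
#' @return list: \code{omnibus_p}, \code{statistic} (Kruskal-Wallis H), and a
#'   data.frame \code{pairwise} with \code{group1}, \code{group2}, \code{z},
#'   \code{p}, \code{q}.
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  kw <- stats::kruskal.test(values, g)

  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  var0 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))

  pairs <- utils::combn(names(groups), 2L)
  z <- (rbar[pairs[1L, ]] - rbar[pairs[2L, ]]) /
    sqrt(var0 * (1 / n[pairs[1L, ]] + 1 / n[pairs[2L, ]]))
  z[!is.finite(z)] <- 0  # all observations tied
  p <- 2 * stats::pnorm(-abs(z))
  # all groups identical => H = 0 and every z = 0
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         z = as.numeric(z), p = as.numeric(p),
                         q = stats::p.adjust(p, method = "BH"),
                         stringsAsFactors = FALSE)
  list(omnibus_p = if (is.nan(kw$p.value)) 1 else kw$p.value,
       statistic = unname(kw$statistic), pairwise = pairwise)
}

#' Log2 frequency ratio
#'
#' The fold difference, on the log2 scale, between two event frequencies, as
#' reported for cohort comparisons (e.g. a frequency of 0.143 against 0.426
#' gives -1.57). Callers must apply the minimum-occurrence filter first; zero
#' frequencies are rejected.
#'
#' @param f_num,f_den frequencies in (0, 1].
#' @return log2(f_num / f_den).
#' @export
log2_frequency_ratio <- function(f_num, f_den) {
  if (any(f_num <= 0) || any(f_den <= 0) || any(f_num > 1) || any(f_den > 1))
    stop("frequencies must lie in (0, 1]")
  log2(f_num / f_den)
}
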