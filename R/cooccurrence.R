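#' Exact null distribution of pairwise co-occurrence counts
#'
#' Under a random association of two events with fixed marginal counts
#' \code{n_a} and \code{n_b} among \code{N} samples, the number \code{j} of
#' samples carrying both follows
#' \deqn{P(j) = \frac{{n_a \choose j}{N - n_a \choose n_b - j}}{{N \choose n_b}}}
#' over the feasible range \code{max(0, n_a + n_b - N) <= j <= min(n_a, n_b)}.
#' Probabilities are computed in log space via \code{lchoose}.
#'
#' @param N number of samples.
#' @param n_a,n_b marginal occurrence counts of the two events.
#' @return data.frame with columns \code{j} and \code{p}; the probabilities
#'   sum to 1.
#' @export
cooccurrence_distribution <- function(N, n_a, n_b) {
  if (N < 0 || n_a < 0 || n_b < 0 || n_a > N || n_b > N)
    stop("infeasible arguments: need 0 <= n_a, n_b <= N")
  j <- seq.int(max(0L, n_a + n_b - N), min(n_a, n_b))
  logp <- lchoose(n_a, j) + lchoose(N - n_a, n_b - j) - lchoose(N, n_b)
  data.frame(j = j, p = exp(logp))
}

#' Test a pair of binary event columns for co-occurrence
#'
#' Tail probabilities of the observed joint count under the exact
#' co-occurrence model. Both tails include the observed count, so
#' \code{p_lt + p_gt >= 1}. An event present in every sample or in none is
#' uninformative and yields \code{p = 1}.
#'
#' @param a,b binary (0/1) vectors of equal length, or a two-column matrix
#'   passed as \code{a}.
#' @param event_a,event_b optional labels.
#' @return a one-row data.frame: \code{event_a}, \code{event_b}, \code{N},
#'   \code{n_a}, \code{n_b}, \code{j_obs}, \code{expected}, \code{p_lt},
#'   \code{p_gt}.
#' @export
test_pair <- function(a, b = NULL, event_a = "a", event_b = "b") {
  if (is.null(b)) {
    stopifnot(ncol(a) == 2L)
    if (!is.null(colnames(a))) { event_a <- colnames(a)[1L]; event_b <- colnames(a)[2L] }
    b <- a[, 2L]; a <- a[, 1L]
  }
  if (length(a) != length(b)) stop("columns differ in length")
  a <- as.integer(a != 0); b <- as.integer(b != 0)
  N <- length(a); n_a <- sum(a); n_b <- sum(b); j_obs <- sum(a & b)
  if (n_a %in% c(0L, N) || n_b %in% c(0L, N)) {
    p_lt <- p_gt <- 1
  } else {
    d <- cooccurrence_distribution(N, n_a, n_b)
    p_lt <- sum(d$p[d$j <= j_obs])
    p_gt <- sum(d$p[d$j >= j_obs])
  }
  data.frame(event_a = event_a, event_b = event_b, N = N, n_a = n_a, n_b = n_b,
             j_obs = j_obs, expected = n_a * n_b / N,
             p_lt = min(1, p_lt), p_gt = min(1, p_gt),
             stringsAsFactors = FALSE)
}

#' Screen all event pairs of a CI matrix for co-occurrence
#'
#' Events are binarized (presence of the signed event); extra binary tracks
#' (e.g. mutations) may be appended. Pairs are filtered by a minimum marginal
#' count and a minimum expected joint count; the gain and the loss of the same
#' locus are structurally exclusive and never tested against each other.
#' Benjamini-Hochberg control is applied jointly over both tails of all
#' retained pairs; a pair is classified positive when its upper-tail q-value
#' falls below \code{alpha}, negative for the lower tail, otherwise ns.
#'
#' @param matrix a \code{ci_matrix} or a binary 0/1 matrix.
#' @param extra optional binary matrix of additional tracks (same samples).
#' @param min_freq minimum marginal count per event (default 3).
#' @param min_expected minimum expected joint count per pair (default 1).
#' @param alpha significance level on adjusted tails (default 0.05).
#' @return object of class \code{cooccurrence_screen}: a data.frame of pairs
#'   with tail p- and q-values and a \code{class} column in
#'   \{positive, negative, ns\}; skipped structural pairs are recorded in the
#'   \code{skipped} attribute.
#' @export
cooccurrence_screen <- function(matrix, extra = NULL, min_freq = 3,
                                min_expected = 1, alpha = 0.05) {
  if (inherits(matrix, "ci_matrix")) {
    pres <- ci_presence(matrix)
    ev <- ci_events(matrix)
    locus <- paste(ev$chromosome, ev$arm, ev$band_lo, ev$band_hi, ev$high_level)
  } else {
    pres <- as.matrix(matrix)
    locus <- colnames(pres)
  }
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    stopifnot(nrow(extra) == nrow(pres))
    pres <- cbind(pres, extra)
    locus <- c(locus, paste0("track:", colnames(extra)))
  }
  keep <- colSums(pres != 0) >= min_freq
  pres <- pres[, keep, drop = FALSE]
  locus <- locus[keep]
  k <- ncol(pres)
  if (k < 2L) {
    res <- data.frame()
    class(res) <- c("cooccurrence_screen", "data.frame")
    return(res)
  }
  pairs <- utils::combn(k, 2L)
  skipped <- character(0)
  rows <- vector("list", ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1L, m]; j <- pairs[2L, m]
    if (locus[i] == locus[j] && colnames(pres)[i] != colnames(pres)[j]) {
      skipped <- c(skipped, paste(colnames(pres)[i], colnames(pres)[j], sep = " / "))
      next
    }
    tp <- test_pair(pres[, i], pres[, j],
                    event_a = colnames(pres)[i], event_b = colnames(pres)[j])
    if (tp$expected < min_expected) next
    rows[[m]] <- tp
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame()
  if (nrow(res)) {
    q <- stats::p.adjust(c(res$p_lt, res$p_gt), method = "BH")
    res$q_lt <- q[seq_len(nrow(res))]
    res$q_gt <- q[nrow(res) + seq_len(nrow(res))]
    res$class <- ifelse(res$q_gt < alpha, "positive",
                        ifelse(res$q_lt < alpha, "negative", "ns"))
    rownames(res) <- NULL
  }
  structure(res, skipped = skipped, alpha = alpha,
            class = c("cooccurrence_screen", "data.frame"))
}

#' @export
print.cooccurrence_screen <- function(x, ...) {
  cat("Co-occurrence screen: ", nrow(x), " pairs tested",
      if (length(attr(x, "skipped")))
        paste0(" (", length(attr(x, "skipped")), " structural pairs skipped)"),
      "\n", sep = "")
  if (nrow(x)) {
    cat("  positive: ", sum(x$class == "positive"),
        "; negative: ", sum(x$class == "negative"),
        "; ns: ", sum(x$class == "ns"), "\n", sep = "")
    sig <- x[x$class != "ns", , drop = FALSE]
    if (nrow(sig)) {
      ord <- order(pmin(sig$q_lt, sig$q_gt))
      print.data.frame(utils::head(sig[ord, ], 10L), digits = 3)
    }
  }
  invisible(x)
}

#' Serialize a co-occurrence screen as a signed -log10(q) square matrix
#'
#' Positive associations carry +(-log10 q_gt), negative ones -(-log10 q_lt),
#' non-significant pairs 0; suitable for triangular heat-mapping.
#'
#' @param x a \code{cooccurrence_screen}.
#' @return symmetric numeric matrix over all screened events.
#' @export
cooccurrence_matrix <- function(x) {
  evs <- sort(unique(c(x$event_a, x$event_b)))
  m <- matrix(0, length(evs), length(evs), dimnames = list(evs, evs))
  for (r in seq_len(nrow(x))) {
    val <- switch(x$class[r],
                  positive = -log10(x$q_gt[r]),
                  negative = log10(x$q_lt[r]),
                  0)
    m[x$event_a[r], x$event_b[r]] <- m[x$event_b[r], x$event_a[r]] <- val
  }
  m
}
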