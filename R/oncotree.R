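#' Maximum-weight spanning arborescence (Chu-Liu/Edmonds)
#'
#' Finds the spanning arborescence rooted at node 1 that maximizes the total
#' edge weight of a dense digraph. Used to initialize the oncogenetic tree
#' from pointwise-mutual-information edge weights.
#'
#' @param w square weight matrix, \code{w[u, v]} the weight of edge u -> v;
#'   \code{-Inf} marks a forbidden edge. Node 1 is the root.
#' @return integer vector of parents (0 for the root).
#' @export
max_arborescence <- function(w) {
  n <- nrow(w)
  if (n != ncol(w)) stop("weight matrix must be square")
  if (n == 1L) return(0L)
  w <- as.matrix(w)
  diag(w) <- -Inf
  w[, 1L] <- -Inf

  best_u <- rep(NA_integer_, n)
  for (v in 2:n) {
    u <- which.max(w[, v])
    if (!is.finite(w[u, v])) stop("node ", v, " has no incoming edge")
    best_u[v] <- u
  }

  # cycle detection over the greedy parent pointers
  state <- integer(n)  # 0 new, 1 on current path, 2 settled
  state[1L] <- 2L
  cyc <- NULL
  for (s in 2:n) {
    if (state[s]) next
    path <- integer(0)
    v <- s
    while (state[v] == 0L) {
      state[v] <- 1L
      path <- c(path, v)
      v <- best_u[v]
    }
    if (state[v] == 1L) {
      cyc <- path[match(v, path):length(path)]
    }
    state[path] <- 2L
    if (!is.null(cyc)) break
  }
  if (is.null(cyc)) {
    parent <- best_u
    parent[1L] <- 0L
    return(parent)
  }

  # contract the cycle into a super-node and recurse
  keep <- setdiff(seq_len(n), cyc)
  m <- length(keep) + 1L          # contracted size; super-node is index m
  wc <- matrix(-Inf, m, m)
  wc[seq_along(keep), seq_along(keep)] <- w[keep, keep]
  cyc_cost <- w[cbind(best_u[cyc], cyc)]

  # u (outside) -> cycle: enter at the node where the swap costs least
  enter_at <- matrix(NA_integer_, length(keep), 1L)
  for (i in seq_along(keep)) {
    adj <- w[keep[i], cyc] - cyc_cost
    j <- which.max(adj)
    if (is.finite(adj[j])) {
      wc[i, m] <- adj[j]
      enter_at[i] <- cyc[j]
    }
  }
  # cycle -> v (outside): leave from the best cycle node
  leave_from <- rep(NA_integer_, length(keep))
  for (i in seq_along(keep)) {
    j <- which.max(w[cyc, keep[i]])
    if (is.finite(w[cyc[j], keep[i]])) {
      wc[m, i] <- w[cyc[j], keep[i]]
      leave_from[i] <- cyc[j]
    }
  }

  sub <- max_arborescence(wc)

  parent <- rep(NA_integer_, n)
  parent[1L] <- 0L
  parent[cyc] <- best_u[cyc]
  for (i in seq_along(keep)) {
    p <- sub[i]
    if (p == 0L) { parent[keep[i]] <- 0L }
    else if (p == m) parent[keep[i]] <- leave_from[i]
    else parent[keep[i]] <- keep[p]
  }
  pc <- sub[m]  # parent of the super-node: break the cycle at the entry point
  entry <- enter_at[pc]
  parent[entry] <- keep[pc]
  parent[1L] <- 0L
  parent
}

# Log-likelihood of binary presence data under a single-pass oncogenetic tree:
# the root is present; each event is present with probability theta given its
# parent is present (absent otherwise); every observation is flipped
# independently with probability eps. Sum over latent presence patterns by
# tree-structured dynamic programming, vectorized across samples.
oncotree_loglik <- function(parent, theta, X, eps) {
  k <- length(parent)
  n <- nrow(X)
  children <- lapply(0:k, function(u) which(parent == u))
  # post-order: process deepest first
  depth <- integer(k)
  for (v in seq_len(k)) {
    d <- 0L; u <- v
    while (parent[u] != 0L) { u <- parent[u]; d <- d + 1L }
    depth[v] <- d
  }
  ord <- order(depth, decreasing = TRUE)
  g1 <- matrix(0, n, k)  # P(obs subtree | latent present)
  g0 <- matrix(0, n, k)
  for (v in ord) {
    e1 <- ifelse(X[, v] == 1L, 1 - eps, eps)
    e0 <- ifelse(X[, v] == 1L, eps, 1 - eps)
    p1 <- e1; p0 <- e0
    for (ch in children[[v + 1L]]) {
      p1 <- p1 * (theta[ch] * g1[, ch] + (1 - theta[ch]) * g0[, ch])
      p0 <- p0 * g0[, ch]
    }
    g1[, v] <- p1
    g0[, v] <- p0
  }
  lik <- rep(1, n)
  for (ch in children[[1L]]) {
    lik <- lik * (theta[ch] * g1[, ch] + (1 - theta[ch]) * g0[, ch])
  }
  sum(log(pmax(lik, .Machine$double.xmin)))
}

#' Fit an oncogenetic tree by maximum likelihood
#'
#' Reconstructs a rooted tree over the most frequent CI events of a cohort
#' subset (typically one metastatic site). The tree is initialized as the
#' maximum-weight spanning arborescence of the complete digraph with weights
#' \code{w(root -> v) = log f_v} and
#' \code{w(u -> v) = log f_uv - log f_u - log f_v} for \code{f_u >= f_v}
#' (pointwise mutual information with a frequency-ordering constraint), then
#' refined by a deterministic hill-climb over single-parent reattachments that
#' accepts only strict improvements of the model likelihood. The model: the
#' root is present; an event is present with probability \code{theta_v} given
#' its parent is present, absent otherwise; observations are flipped
#' independently with error rate \code{epsilon}. Transition probabilities are
#' the empirical conditionals \code{theta_v = f_{pa(v),v} / f_{pa(v)}};
#' frequencies use pseudocount 0.5.
#'
#' @param matrix a \code{ci_matrix} (restricted by the caller to one
#'   metastasis site) or a binary 0/1 matrix.
#' @param top_k number of most frequent events to model (default 25).
#' @param epsilon symmetric observation error rate (default 0.01).
#' @param autosomes_only drop X/Y events before ranking (default TRUE).
#' @return object of class \code{oncotree}: \code{events}, \code{parent}
#'   (event label of each parent, "root" at the top), \code{theta},
#'   \code{distance} (root distance, summed -log theta), \code{loglik},
#'   \code{loglik_path} (likelihood after each accepted move), \code{epsilon},
#'   \code{n}, \code{freq}.
#' @export
fit_oncotree <- function(matrix, top_k = 25, epsilon = 0.01,
                         autosomes_only = TRUE) {
  if (top_k < 2) stop("top_k must be at least 2")
  if (inherits(matrix, "ci_matrix")) {
    pres <- ci_presence(matrix)
    if (autosomes_only) {
      ev <- ci_events(matrix)
      pres <- pres[, !ev$chromosome %in% c("X", "Y"), drop = FALSE]
    }
  } else {
    pres <- as.matrix(matrix)
  }
  n <- nrow(pres)
  counts <- colSums(pres)
  ord <- order(-counts, colnames(pres))
  keep <- ord[seq_len(min(top_k, ncol(pres)))]
  keep <- keep[counts[keep] > 0L]
  if (length(keep) < 1L) stop("no events left to model")
  X <- pres[, keep, drop = FALSE]
  k <- ncol(X)
  events <- colnames(X)

  f <- (colSums(X) + 0.5) / (n + 1)
  fj <- (crossprod(X) + 0.5) / (n + 1)

  # complete digraph: node 1 = root, nodes 1+1..1+k = events
  w <- matrix(-Inf, k + 1L, k + 1L)
  w[1L, -1L] <- log(f)
  for (u in seq_len(k)) {
    for (v in seq_len(k)) {
      if (u != v && f[u] >= f[v])
        w[u + 1L, v + 1L] <- log(fj[u, v]) - log(f[u]) - log(f[v])
    }
  }
  parent <- max_arborescence(w)[-1L] - 1L  # 0 = root, in event indexing

  theta_of <- function(parent) {
    th <- numeric(k)
    for (v in seq_len(k)) {
      th[v] <- if (parent[v] == 0L) f[v] else fj[parent[v], v] / f[parent[v]]
    }
    pmin(th, 1)
  }
  descendants <- function(parent, v) {
    out <- v
    repeat {
      more <- which(parent %in% out & !seq_len(k) %in% out)
      if (!length(more)) break
      out <- c(out, more)
    }
    out
  }

  theta <- theta_of(parent)
  ll <- oncotree_loglik(parent, theta, X, epsilon)
  ll_path <- ll
  repeat {
    improved <- FALSE
    for (v in seq_len(k)) {
      forbidden <- c(descendants(parent, v), parent[v])
      for (u in c(0L, setdiff(seq_len(k), forbidden))) {
        if (u == parent[v]) next
        cand <- parent
        cand[v] <- u
        th <- theta_of(cand)
        cl <- oncotree_loglik(cand, th, X, epsilon)
        if (cl > ll + 1e-9) {
          parent <- cand; theta <- th; ll <- cl
          ll_path <- c(ll_path, ll)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }

  d <- numeric(k)
  for (v in seq_len(k)) {
    s <- 0; u <- v
    repeat {
      s <- s - log(theta[u])
      if (parent[u] == 0L) break
      u <- parent[u]
    }
    d[v] <- s
  }
  # an edge with theta = 1 contributes zero length; numerical floor at 0
  d <- pmax(d, 0)

  structure(list(
    events = events,
    parent = ifelse(parent == 0L, "root", events[pmax(parent, 1L)]),
    parent_index = parent,
    theta = stats::setNames(theta, events),
    distance = stats::setNames(d, events),
    depth = vapply(seq_len(k), function(v) {
      dd <- 0L; u <- v
      while (parent[u] != 0L) { u <- parent[u]; dd <- dd + 1L }
      dd + 1L
    }, 1L),
    loglik = ll, loglik_path = ll_path,
    epsilon = epsilon, n = n,
    freq = stats::setNames(f, events)
  ), class = "oncotree")
}

#' @export
print.oncotree <- function(x, ...) {
  cat("Oncogenetic tree: ", length(x$events), " events, n = ", x$n,
      " samples, log-likelihood ", format(x$loglik, digits = 6),
      " (epsilon = ", x$epsilon, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.oncotree <- function(object, ...) {
  timing <- classify_event_timing(object)
  df <- data.frame(event = object$events, parent = object$parent,
                   theta = round(unname(object$theta), 3),
                   distance = round(unname(object$distance), 3),
                   class = timing$class[match(object$events, timing$event)],
                   stringsAsFactors = FALSE)
  df[order(df$distance), ]
}

#' Assign early-to-late timing classes to oncogenetic-tree events
#'
#' Each event's distance from the root (the path sum of \code{-log theta} by
#' default, or the topological depth) is binned into \code{n_classes}
#' equal-width, right-closed intervals of \code{[0, d_max]}; class 1 holds the
#' earliest events and class \code{n_classes} the latest.
#'
#' @param tree an \code{oncotree}.
#' @param n_classes number of timing classes (default 9).
#' @param distance "weighted" (default) or "topological".
#' @return data.frame \code{event}, \code{d}, \code{class}.
#' @export
classify_event_timing <- function(tree, n_classes = 9,
                                  distance = c("weighted", "topological")) {
  distance <- match.arg(distance)
  d <- if (distance == "weighted") tree$distance else as.numeric(tree$depth - 1L)
  d_max <- max(d)
  # a single-event tree has no early/late contrast: everything is class 1
  cls <- if (d_max <= 0 || length(d) == 1L) rep(1L, length(d)) else
    pmin(n_classes, pmax(1L, as.integer(ceiling(d / (d_max / n_classes) - 1e-12))))
  data.frame(event = tree$events, d = unname(d), class = cls,
             stringsAsFactors = FALSE)
}

#' Compare event timing classes across site-specific oncogenetic trees
#'
#' @param trees named list of \code{oncotree} objects (one per site).
#' @param n_classes number of timing classes (default 9).
#' @param distance passed to \code{\link{classify_event_timing}}.
#' @return data.frame events x sites of timing classes; \code{NA} marks events
#'   absent from a site's tree.
#' @export
compare_site_trees <- function(trees, n_classes = 9, distance = "weighted") {
  if (is.null(names(trees))) names(trees) <- paste0("site", seq_along(trees))
  timings <- lapply(trees, classify_event_timing, n_classes = n_classes,
                    distance = distance)
  events <- sort(unique(unlist(lapply(timings, `[[`, "event"))))
  out <- data.frame(event = events, stringsAsFactors = FALSE)
  for (s in names(timings)) {
    out[[s]] <- timings[[s]]$class[match(events, timings[[s]]$event)]
  }
  out
}

#' Newick serialization of an oncogenetic tree
#'
#' Edge lengths are \code{-log theta}; event labels containing spaces are
#' single-quoted.
#'
#' @param tree an \code{oncotree}.
#' @return newick string (readable by \code{ape::read.tree}).
#' @export
oncotree_newick <- function(tree) {
  k <- length(tree$events)
  lab <- ifelse(grepl("[ ():,;]", tree$events),
                paste0("'", tree$events, "'"), tree$events)
  children <- lapply(0:k, function(u) which(tree$parent_index == u))
  rec <- function(v) {
    ch <- children[[v + 1L]]
    body <- if (length(ch)) paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")") else ""
    if (v == 0L) return(paste0(body, "root;"))
    paste0(body, lab[v], ":", format(-log(tree$theta[v]), digits = 10))
  }
  rec(0L)
}

#' @export
plot.oncotree <- function(x, ...) {
  tr <- ape::read.tree(text = oncotree_newick(x))
  # zero-length edges are fine for plotting topology-proportional trees
  ape::plot.phylo(tr, show.node.label = TRUE, ...)
  invisible(x)
}

#' Write an oncogenetic tree as newick plus a TSV of event parameters
#' @param tree an \code{oncotree}.
#' @param newick_path,tsv_path output paths (either may be NULL).
#' @export
write_oncotree <- function(tree, newick_path = NULL, tsv_path = NULL) {
  if (!is.null(newick_path)) writeLines(oncotree_newick(tree), newick_path)
  if (!is.null(tsv_path)) {
    utils::write.table(summary(tree), tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(tree)
}

#' Simulate presence data from a fitted oncogenetic tree
#'
#' Draws samples from the fitted single-pass model (top-down Bernoulli
#' acquisition with the fitted transition probabilities, followed by symmetric
#' observation flips at the fitted error rate).
#'
#' @param object an \code{oncotree}.
#' @param nsim number of samples.
#' @param seed optional integer seed.
#' @param ... ignored.
#' @return binary matrix \code{nsim} x events.
#' @export
simulate.oncotree <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(object$events)
  parent <- object$parent_index
  ord <- order(object$depth)
  X <- matrix(0L, nsim, k, dimnames = list(NULL, object$events))
  for (v in ord) {
    pa <- if (parent[v] == 0L) rep(1L, nsim) else X[, parent[v]]
    X[, v] <- as.integer(pa == 1L &
                           stats::runif(nsim) < unname(object$theta[v]))
  }
  flip <- matrix(stats::runif(nsim * k) < object$epsilon, nsim, k)
  X[flip] <- 1L - X[flip]
  X
}
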