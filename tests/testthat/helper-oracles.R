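# Independent brute-force oracles used to validate the package's exact
# statistics and tree algorithms. These deliberately avoid the implementation
# paths they check.

# hypergeometric probability of a 2xk table with fixed margins
.table_prob <- function(tab) {
  exp(sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
        lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
}

# two-sided Fisher p by full enumeration of margin-consistent 2x2/2x3 tables
oracle_fisher <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab)
  if (any(r == 0) || any(cs == 0)) return(1)
  p_obs <- .table_prob(tab)
  total <- 0
  if (ncol(tab) == 2L) {
    for (a in 0:min(r[1], cs[1])) {
      t2 <- rbind(c(a, r[1] - a), c(cs[1] - a, cs[2] - (r[1] - a)))
      if (any(t2 < 0)) next
      p <- .table_prob(t2)
      if (p <= p_obs * (1 + 1e-7)) total <- total + p
    }
  } else {
    for (a in 0:min(r[1], cs[1])) for (b in 0:min(r[1] - a, cs[2])) {
      c3 <- r[1] - a - b
      if (c3 < 0 || c3 > cs[3]) next
      t2 <- rbind(c(a, b, c3), c(cs[1] - a, cs[2] - b, cs[3] - c3))
      if (any(t2 < 0)) next
      p <- .table_prob(t2)
      if (p <= p_obs * (1 + 1e-7)) total <- total + p
    }
  }
  min(total, 1)
}

# co-occurrence pmf by enumerating every placement of the second event set
oracle_cooccurrence <- function(N, n_a, n_b) {
  sets <- utils::combn(N, n_b)
  overlap <- colSums(sets <= n_a)  # event A occupies samples 1..n_a
  tab <- table(factor(overlap, levels = max(0, n_a + n_b - N):min(n_a, n_b)))
  as.numeric(tab) / ncol(sets)
}

# closed-form product formula for the co-occurrence pmf
veech_product <- function(N, n_a, n_b, j) {
  exp(lchoose(N, j) + lchoose(N - j, n_b - j) + lchoose(N - n_b, n_a - j) -
        lchoose(N, n_b) - lchoose(N, n_a))
}

# maximum-weight arborescence by enumeration of all parent assignments
oracle_max_arborescence <- function(w) {
  k <- nrow(w) - 1L
  if (k == 0L) return(list(weight = 0, parent = integer(0)))
  opts <- lapply(seq_len(k), function(v) setdiff(0:k, v))
  grid <- as.matrix(expand.grid(opts))
  # acyclicity: repeated parent jumps must reach the root (0) from everywhere
  reach <- grid
  for (step in seq_len(k)) {
    for (v in seq_len(k)) {
      cur <- reach[, v]
      nz <- cur != 0L
      reach[nz, v] <- grid[cbind(which(nz), cur[nz])]
    }
  }
  valid <- rowSums(reach != 0L) == 0L
  wt <- rep(0, nrow(grid))
  for (v in seq_len(k)) wt <- wt + w[grid[, v] + 2L - 1L, v + 1L]
  wt[!valid] <- -Inf
  best <- which.max(wt)
  list(weight = wt[best], parent = as.integer(grid[best, ]))
}

# minimum parsimony score by enumerating all rooted binary topologies over the
# tumor taxa and, per topology, all internal 0/1 labelings (root fixed at the
# all-absent normal taxon); change counting is plain edge disagreement.
oracle_parsimony <- function(chars) {
  taxa <- setdiff(rownames(chars), "normal")
  k <- length(taxa)
  trees <- list(list(taxa[1L], taxa[2L]))
  if (k > 2L) {
    for (t in 3:k) {
      grown <- list()
      for (tr in trees) grown <- c(grown, .oracle_insert(tr, taxa[t]))
      trees <- grown
    }
  }
  best <- Inf
  for (tr in trees) {
    edges_nodes <- .oracle_edges(tr)
    edges <- edges_nodes$edges      # matrix parent,child over node ids
    leaf_of <- edges_nodes$leaf_of  # node id -> taxon label or NA
    n_nodes <- edges_nodes$n
    internal <- which(is.na(leaf_of))
    score <- 0
    for (ch in colnames(chars)) {
      states <- ifelse(is.na(leaf_of), NA_integer_, NA_integer_)
      base <- integer(n_nodes)
      base[!is.na(leaf_of)] <- chars[leaf_of[!is.na(leaf_of)], ch]
      best_c <- Inf
      grid <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
      for (g in seq_len(nrow(grid))) {
        st <- base
        st[internal] <- grid[g, ]
        changes <- sum(st[edges[, 1L]] != st[edges[, 2L]])
        if (changes < best_c) best_c <- changes
      }
      score <- score + best_c
    }
    if (score < best) best <- score
  }
  best
}

.oracle_insert <- function(tree, leaf) {
  out <- list(list(tree, leaf))
  if (is.list(tree)) {
    for (side in 1:2) {
      for (sub in .oracle_insert(tree[[side]], leaf)) {
        t2 <- tree
        t2[[side]] <- sub
        out <- c(out, list(t2))
      }
    }
  }
  out
}

# flatten: node 1 = normal root (state 0 enforced via leaf_of = "normal")
.oracle_edges <- function(tree) {
  leaf_of <- "normal"
  edges <- matrix(integer(0), 0L, 2L)
  add <- function(sub, parent) {
    id <- length(leaf_of) + 1L
    leaf_of <<- c(leaf_of, if (is.list(sub)) NA_character_ else sub)
    edges <<- rbind(edges, c(parent, id))
    if (is.list(sub)) { add(sub[[1L]], id); add(sub[[2L]], id) }
    id
  }
  add(tree, 1L)
  list(edges = edges, leaf_of = leaf_of, n = length(leaf_of))
}

# tiny random ci_matrix over signed arm events
random_ci_matrix <- function(n_samples, events, rate = 0.3) {
  vals <- matrix(rbinom(n_samples * length(events), 1L, rate),
                 n_samples, length(events),
                 dimnames = list(sprintf("s%03d", seq_len(n_samples)), events))
  sign <- ifelse(substr(events, 1L, 1L) == "-", -1L, 1L)
  ci_matrix(sweep(vals, 2L, sign, `*`), mask = NULL)
}
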