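test_that("nested presence data yield the chain topology", {
  set.seed(13)
  n <- 100
  A <- rbinom(n, 1, 0.9)
  B <- A * rbinom(n, 1, 0.66)   # marginal ~0.6
  C <- B * rbinom(n, 1, 0.5)    # marginal ~0.3
  X <- cbind("+13q" = A, "-18q" = B, "+20q" = C)
  tr <- fit_oncotree(X, top_k = 3, epsilon = 0.01)
  parent <- setNames(tr$parent, tr$events)
  expect_equal(parent[["+13q"]], "root")
  expect_equal(parent[["-18q"]], "+13q")
  expect_equal(parent[["+20q"]], "-18q")
})

test_that("independent events attach directly to the root", {
  set.seed(17)
  n <- 400
  X <- cbind("+13q" = rbinom(n, 1, 0.5), "-18q" = rbinom(n, 1, 0.45))
  tr <- fit_oncotree(X, top_k = 2, epsilon = 0.01)
  expect_equal(unname(tr$parent), c("root", "root"))
})

test_that("a single modeled event hangs off the root with theta = f", {
  X <- cbind("+13q" = c(rep(1L, 7), rep(0L, 3)))
  rownames(X) <- paste0("s", 1:10)
  tr <- fit_oncotree(X, top_k = 2, epsilon = 0.01)
  expect_equal(tr$parent, "root")
  expect_equal(unname(tr$theta), (7 + 0.5) / 11, tolerance = 1e-12)
  expect_error(fit_oncotree(X, top_k = 1), "top_k")
})

test_that("arborescence step matches brute force on random small digraphs", {
  set.seed(37)
  for (i in 1:60) {
    k <- sample(2:5, 1)
    w <- matrix(round(rnorm((k + 1)^2), 2), k + 1, k + 1)
    w[sample(length(w), (k + 1))] <- -Inf  # some forbidden edges
    w[, 1] <- -Inf
    diag(w) <- -Inf
    w[1, 2:(k + 1)] <- round(abs(rnorm(k)), 2)  # keep every node reachable
    par <- max_arborescence(w)  # node-indexed parents, 0 only for the root
    wt <- sum(w[cbind(par[-1], 2:(k + 1))])
    oracle <- oracle_max_arborescence(w)
    expect_equal(wt, oracle$weight, tolerance = 1e-9, label = paste("case", i))
  }
})

test_that("hill-climb never decreases the likelihood", {
  set.seed(43)
  for (i in 1:5) {
    X <- matrix(rbinom(9 * 120, 1, runif(1, 0.2, 0.6)), 120, 9)
    colnames(X) <- sprintf("+%dq", 2:10)
    tr <- fit_oncotree(X, top_k = 9, epsilon = 0.01)
    expect_true(all(diff(tr$loglik_path) > 0))
    expect_gte(tr$loglik, tr$loglik_path[1])
  }
})

test_that("fitted trees recover the generating structure", {
  spec <- default_tree_spec()
  # oncotree-shaped object holding the known generating tree
  tr0 <- list(events = spec$event,
              parent = spec$parent,
              parent_index = match(spec$parent, spec$event, nomatch = 0L),
              theta = setNames(spec$theta, spec$event),
              depth = {
                pidx <- match(spec$parent, spec$event, nomatch = 0L)
                vapply(seq_along(pidx), function(v) {
                  d <- 1L; u <- v
                  while (pidx[u] != 0L) { u <- pidx[u]; d <- d + 1L }
                  d
                }, 1L)
              },
              epsilon = 0.01)
  class(tr0) <- "oncotree"
  X <- simulate(tr0, nsim = 500, seed = 47)
  fit <- fit_oncotree(X, top_k = 16, epsilon = 0.01)
  truth <- setNames(spec$parent, spec$event)
  est <- setNames(fit$parent, fit$events)
  shared <- intersect(names(truth), names(est))
  recovered <- sum(est[shared] == truth[shared]) / length(truth)
  expect_gte(recovered, 0.8)
})

test_that("timing classes bin root distances into nine equal intervals", {
  mk_tree <- function(theta, chain = TRUE) {
    k <- length(theta)
    structure(list(events = sprintf("+%dq", seq_len(k) + 1),
                   parent = c("root", sprintf("+%dq", seq_len(k - 1) + 1)),
                   parent_index = 0:(k - 1),
                   theta = theta,
                   distance = cumsum(-log(theta)),
                   depth = seq_len(k),
                   loglik = 0, epsilon = 0.01, n = 1),
              class = "oncotree")
  }
  # chain with theta 0.5 each: distances (1,2,3)*log2 -> classes 3, 6, 9
  tt <- classify_event_timing(mk_tree(c(0.5, 0.5, 0.5)))
  expect_equal(tt$class, c(3L, 6L, 9L))
  # the deepest event always lands in the last class
  set.seed(53)
  tt2 <- classify_event_timing(mk_tree(runif(6, 0.3, 0.9)))
  expect_equal(tt2$class[which.max(tt2$d)], 9L)
  # an event adjacent to the root with theta = 1 has distance 0, class 1
  tt3 <- classify_event_timing(mk_tree(c(1, 0.5)))
  expect_equal(tt3$class[1], 1L)
  expect_equal(tt3$d[1], 0)
  # degenerate tree: single event -> class 1
  tt4 <- classify_event_timing(mk_tree(0.7))
  expect_equal(tt4$class, 1L)
})

test_that("timing class is monotone along root paths", {
  set.seed(59)
  n <- 150
  a <- rbinom(n, 1, 0.7)
  b <- a * rbinom(n, 1, 0.7)
  c_ <- b * rbinom(n, 1, 0.6)
  d <- a * rbinom(n, 1, 0.4)
  e <- rbinom(n, 1, 0.5)
  f <- e * rbinom(n, 1, 0.5)
  X <- cbind("+2q" = a, "+3q" = b, "+4q" = c_, "+5q" = d, "+6q" = e, "+7q" = f)
  tr <- fit_oncotree(X, top_k = 6)
  expect_true(any(tr$parent != "root"))
  tt <- classify_event_timing(tr)
  cls <- setNames(tt$class, tt$event)
  for (v in seq_along(tr$events)) {
    if (tr$parent[v] != "root")
      expect_gte(cls[[tr$events[v]]], cls[[tr$parent[v]]])
  }
})

test_that("site trees compare into a joint timing table", {
  set.seed(61)
  X <- matrix(rbinom(6 * 200, 1, 0.5), 200, 6)
  colnames(X) <- sprintf("+%dq", 2:7)
  trees <- list(liver = fit_oncotree(X, top_k = 6),
                lung = fit_oncotree(X, top_k = 6),
                brain = fit_oncotree(X, top_k = 4))
  cmp <- compare_site_trees(trees)
  expect_equal(cmp$liver, cmp$lung)           # same input, same classes
  expect_equal(sum(is.na(cmp$brain)), 2)      # below top_k -> absent
})

test_that("newick export round-trips through ape", {
  set.seed(67)
  X <- matrix(rbinom(5 * 80, 1, 0.5), 80, 5)
  colnames(X) <- c("+13q", "-18q", "+20q", "-8p", "+12p amp")
  tr <- fit_oncotree(X, top_k = 5)
  phy <- ape::read.tree(text = oncotree_newick(tr))
  expect_s3_class(phy, "phylo")
  labels <- gsub("'", "", c(phy$tip.label, phy$node.label))
  expect_setequal(setdiff(labels, "root"), tr$events)
})
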