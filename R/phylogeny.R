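#' Build a patient character matrix from a CI matrix
#'
#' Extracts the samples of one patient and encodes each CI event as a binary
#' character; high-level amplifications (+2) become separate characters. A
#' synthetic all-absent "normal" taxon is prepended as outgroup/root.
#'
#' @param matrix a \code{ci_matrix}.
#' @param samples sample ids of the patient (>= 2 tumor samples).
#' @return binary matrix taxa x characters, first row "normal".
#' @export
patient_character_matrix <- function(matrix, samples) {
  if (length(samples) < 2L) stop("need at least two tumor samples")
  miss <- setdiff(samples, rownames(matrix))
  if (length(miss)) stop("samples not in CI matrix: ", paste(miss, collapse = ", "))
  pres <- ci_presence(matrix[match(samples, rownames(matrix)), , drop = FALSE],
                      amp_separate = TRUE)
  pres <- pres[, colSums(pres) > 0L, drop = FALSE]
  rbind(normal = rep(0L, ncol(pres)), pres)
}

# --- internal tree machinery -------------------------------------------------
# A rooted binary tumor subtree is a nested list: a leaf is an integer taxon
# index, an internal node a list(left, right). The full tree roots the subtree
# under the all-absent normal taxon.

# all ways to insert a new leaf into a subtree (on every edge incl. above root)
.insert_leaf <- function(tree, leaf) {
  out <- list(list(tree, leaf))
  if (is.list(tree)) {
    for (side in 1:2) {
      for (sub in .insert_leaf(tree[[side]], leaf)) {
        t2 <- tree
        t2[[side]] <- sub
        out <- c(out, list(t2))
      }
    }
  }
  out
}

# Fitch state sets encoded as integers: 1 = {0}, 2 = {1}, 3 = {0,1};
# returns list(sets = vector over characters at the subtree root,
# score = number of union events below)
.fitch <- function(tree, X) {
  if (!is.list(tree)) {
    return(list(sets = ifelse(X[tree, ] == 1L, 2L, 1L), score = 0L))
  }
  l <- .fitch(tree[[1L]], X)
  r <- .fitch(tree[[2L]], X)
  inter <- bitwAnd(l$sets, r$sets)
  union_needed <- inter == 0L
  sets <- ifelse(union_needed, bitwOr(l$sets, r$sets), inter)
  list(sets = sets, score = l$score + r$score + sum(union_needed))
}

# parsimony score of the full tree (tumor subtree + normal root, state 0)
.tree_score <- function(tree, X) {
  f <- .fitch(tree, X)
  # joining the all-zero root: a union is needed where the set is {1}
  f$score + sum(f$sets == 2L)
}

# canonical newick of the tumor subtree (children sorted), for tie-breaking
.canonical <- function(tree, taxa) {
  if (!is.list(tree)) return(taxa[tree])
  ch <- sort(c(.canonical(tree[[1L]], taxa), .canonical(tree[[2L]], taxa)))
  paste0("(", ch[1L], ",", ch[2L], ")")
}

# exhaustive / branch-and-bound search over rooted binary subtree topologies
.search_topologies <- function(X, exhaustive_limit = 8L) {
  k <- nrow(X) - 1L  # tumor taxa (row 1 is normal)
  taxa_idx <- 2:(k + 1L)
  best <- list(score = Inf, trees = list())
  consider <- function(tree) {
    s <- .tree_score(tree, X)
    if (s < best$score) best <<- list(score = s, trees = list(tree))
    else if (s == best$score) best$trees[[length(best$trees) + 1L]] <<- tree
  }
  if (k == 2L) {
    consider(list(taxa_idx[1L], taxa_idx[2L]))
  } else if (k <= exhaustive_limit) {
    grow <- function(tree, remaining) {
      if (!length(remaining)) { consider(tree); return(invisible()) }
      for (t2 in .insert_leaf(tree, remaining[1L]))
        grow(t2, remaining[-1L])
    }
    grow(list(taxa_idx[1L], taxa_idx[2L]), taxa_idx[-(1:2)])
  } else {
    # branch and bound: partial Fitch score never decreases under insertion
    grow <- function(tree, remaining) {
      s <- .tree_score(tree, X)
      if (s > best$score) return(invisible())
      if (!length(remaining)) { consider(tree); return(invisible()) }
      for (t2 in .insert_leaf(tree, remaining[1L]))
        grow(t2, remaining[-1L])
    }
    grow(list(taxa_idx[1L], taxa_idx[2L]), taxa_idx[-(1:2)])
  }
  best
}

# flatten the chosen subtree into node tables rooted at the normal taxon
.build_nodes <- function(tree, taxa) {
  nodes <- data.frame(id = 1L, parent = 0L, label = "normal",
                      stringsAsFactors = FALSE)
  add <- function(sub, parent_id) {
    id <- nrow(nodes) + 1L
    if (!is.list(sub)) {
      nodes[id, ] <<- list(id, parent_id, taxa[sub])
      return(id)
    }
    nodes[id, ] <<- list(id, parent_id, NA_character_)
    add(sub[[1L]], id)
    add(sub[[2L]], id)
    id
  }
  add(tree, 1L)
  nodes
}

#' Fit a per-patient maximum-parsimony phylogeny
#'
#' Searches rooted binary tree topologies over the patient's tumor samples
#' (exhaustive for up to 8 samples, branch-and-bound above) for the minimum
#' Fitch parsimony score on the binary CI characters, with the synthetic
#' all-absent normal taxon as root. Characters may change in both directions
#' at equal cost. Ties are broken by the lexicographically smallest canonical
#' newick string. Events are then mapped to edges at their earliest
#' most-parsimonious placement (see \code{\link{map_events_to_edges}}) and
#' edges are labeled trunk / branches / sub-branches by the number of tumor
#' branching nodes above them (0 / 1 / >= 2).
#'
#' @param chars binary character matrix from
#'   \code{\link{patient_character_matrix}} (a "normal" all-zero row is added
#'   if missing).
#' @param patient optional patient id stored on the result.
#' @return object of class \code{patient_phylogeny}: \code{nodes} (id, parent,
#'   label, segment per non-root edge), \code{score}, \code{events} (character,
#'   edge id, direction, depth, segment), \code{newick}, \code{taxa}.
#' @export
fit_parsimony_tree <- function(chars, patient = NA_character_) {
  chars <- as.matrix(chars)
  if (!"normal" %in% rownames(chars)) {
    chars <- rbind(normal = rep(0L, ncol(chars)), chars)
  } else {
    chars <- chars[c("normal", setdiff(rownames(chars), "normal")), , drop = FALSE]
    if (any(chars["normal", ] != 0L)) stop("normal taxon must be all-absent")
  }
  if (nrow(chars) < 3L) stop("need at least two tumor samples")
  taxa <- rownames(chars)

  best <- .search_topologies(chars)
  keys <- vapply(best$trees, .canonical, "", taxa = taxa)
  tree <- best$trees[[order(keys)[1L]]]

  nodes <- .build_nodes(tree, taxa)
  events <- map_events_to_edges(nodes, chars)

  # segment of an edge: number of tumor branching nodes on the root path up to
  # and including the edge's parent (0 = trunk, 1 = branches, >= 2 = sub-branches)
  is_branching <- vapply(nodes$id, function(i)
    sum(nodes$parent == i) >= 2L, TRUE)
  seg_of_edge <- function(child_id) {
    nb <- 0L
    p <- nodes$parent[child_id]
    while (p != 0L) {
      if (is_branching[p]) nb <- nb + 1L
      p <- nodes$parent[p]
    }
    c("trunk", "branches", "sub-branches")[pmin(nb, 2L) + 1L]
  }
  nodes$segment <- NA_character_
  for (i in which(nodes$parent != 0L)) nodes$segment[i] <- seg_of_edge(i)
  events$segment <- nodes$segment[events$edge]

  structure(list(
    patient = patient,
    nodes = nodes,
    score = best$score,
    n_trees_tied = length(best$trees),
    events = events,
    taxa = taxa,
    newick = .phylo_newick(nodes, events)
  ), class = "patient_phylogeny")
}

# newick of the full patient tree; branch lengths = number of mapped events;
# the synthetic normal appears as a zero-length outgroup tip
.phylo_newick <- function(nodes, events) {
  n_ev <- table(factor(events$edge, levels = nodes$id))
  rec <- function(id) {
    ch <- nodes$id[nodes$parent == id]
    lab <- nodes$label[id]
    lab <- if (is.na(lab)) "" else gsub("[ ():,;]", "_", lab)
    body <- if (length(ch))
      paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")") else ""
    paste0(body, lab, ":", n_ev[[as.character(id)]])
  }
  root <- nodes$id[nodes$parent == 0L]
  ch <- nodes$id[nodes$parent == root]
  paste0("(normal:0,", paste(vapply(ch, rec, ""), collapse = ","), ");")
}

#' Map characters to tree edges at their earliest parsimonious placement
#'
#' For each character, all minimum-change labelings of the internal nodes are
#' enumerated (the normal root is fixed absent); among them the labeling whose
#' sorted vector of change-edge depths is lexicographically smallest is chosen,
#' placing ambiguous changes on the edge closest to the root. Both gains
#' (0 to 1) and losses (1 to 0) are recorded.
#'
#' @param tree node table as built by \code{\link{fit_parsimony_tree}} (or a
#'   \code{patient_phylogeny}, whose nodes are used).
#' @param chars the binary character matrix (rows must match node labels).
#' @return data.frame \code{character}, \code{edge} (child node id),
#'   \code{direction} (gain/loss), \code{depth}.
#' @export
map_events_to_edges <- function(tree, chars) {
  nodes <- if (inherits(tree, "patient_phylogeny")) tree$nodes else tree
  internal <- nodes$id[is.na(nodes$label)]
  leaves <- nodes$id[!is.na(nodes$label)]
  depth <- integer(nrow(nodes))
  for (i in nodes$id) {
    d <- 0L; p <- nodes$parent[i]
    while (p != 0L) { d <- d + 1L; p <- nodes$parent[p] }
    depth[i] <- d
  }
  edges <- nodes$id[nodes$parent != 0L]

  n_int <- length(internal)
  grid <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  state <- integer(nrow(nodes))

  out <- list()
  for (ch in colnames(chars)) {
    state[leaves] <- chars[nodes$label[leaves], ch]
    best_g <- NA_integer_
    best_key <- NULL
    best_score <- Inf
    for (g in seq_len(nrow(grid))) {
      state[internal] <- grid[g, ]
      chg <- edges[state[edges] != state[nodes$parent[edges]]]
      sc <- length(chg)
      if (sc > best_score) next
      key <- sort(depth[chg])
      if (sc < best_score || .lex_less(key, best_key)) {
        best_score <- sc
        best_g <- g
        best_key <- key
      }
    }
    if (best_score > 0L) {
      state[internal] <- grid[best_g, ]
      chg <- edges[state[edges] != state[nodes$parent[edges]]]
      out[[ch]] <- data.frame(
        character = ch,
        edge = chg,
        direction = ifelse(state[chg] == 1L, "gain", "loss"),
        depth = depth[chg],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(character = character(0), edge = integer(0),
                      direction = character(0), depth = integer(0))
  rownames(res) <- NULL
  res
}

.lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' @export
print.patient_phylogeny <- function(x, ...) {
  cat("Patient phylogeny", if (!is.na(x$patient)) paste0(" (", x$patient, ")"),
      ": ", length(x$taxa) - 1L, " tumor samples, parsimony score ", x$score,
      if (x$n_trees_tied > 1L) paste0(" (", x$n_trees_tied, " tied topologies)"),
      "\n", sep = "")
  seg <- table(factor(x$events$segment,
                      levels = c("trunk", "branches", "sub-branches")))
  cat("  events by segment: trunk ", seg[["trunk"]], ", branches ",
      seg[["branches"]], ", sub-branches ", seg[["sub-branches"]], "\n", sep = "")
  invisible(x)
}

#' @export
plot.patient_phylogeny <- function(x, ...) {
  tr <- ape::read.tree(text = x$newick)
  ape::plot.phylo(tr, ...)
  invisible(x)
}

#' Per-segment CI scores of a patient phylogeny
#'
#' The CI score of a segment (trunk, branches, sub-branches) is the mean
#' timing class of the events mapped to the segment's edges, with classes
#' taken from an oncogenetic tree of the patient's metastasis site. Events
#' without a timing class are excluded (with a message); a segment with no
#' classified events gets no score.
#'
#' @param tree a \code{patient_phylogeny}.
#' @param timing data.frame from \code{\link{classify_event_timing}}.
#' @return data.frame \code{patient}, \code{segment}, \code{score},
#'   \code{n_events}.
#' @export
segment_and_score <- function(tree, timing) {
  ev <- tree$events
  # amplification characters inherit the class of their base event if the
  # amplification itself was not modeled
  base <- sub(" amp$", "", ev$character)
  cls <- timing$class[match(ev$character, timing$event)]
  cls[is.na(cls)] <- timing$class[match(base[is.na(cls)], timing$event)]
  if (anyNA(cls)) {
    message(sum(is.na(cls)), " event(s) without timing class excluded: ",
            paste(unique(ev$character[is.na(cls)]), collapse = ", "))
  }
  keep <- !is.na(cls)
  ev <- ev[keep, , drop = FALSE]
  cls <- cls[keep]
  segs <- c("trunk", "branches", "sub-branches")
  out <- data.frame(
    patient = tree$patient,
    segment = factor(segs, levels = segs),
    score = vapply(segs, function(s)
      if (any(ev$segment == s)) mean(cls[ev$segment == s]) else NA_real_, 1),
    n_events = vapply(segs, function(s) sum(ev$segment == s), 1L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[!is.na(out$score), , drop = FALSE]
}

#' Permutation trend test of CI scores across tree segments
#'
#' Tests whether per-patient CI scores differ between trunk, branches and
#' sub-branches. The statistic for a segment pair is the difference of segment
#' means pooled across patients; the null distribution is built by permuting
#' segment labels within each patient, which respects the per-patient
#' stratification. The omnibus p-value uses the maximum absolute pairwise
#' statistic; pairwise p-values are Benjamini-Hochberg adjusted.
#'
#' @param scores data.frame with columns \code{patient}, \code{segment},
#'   \code{score} (stacked output of \code{\link{segment_and_score}}).
#' @param n_perm number of permutations (default 1e5).
#' @param seed optional integer seed.
#' @return list: \code{omnibus_p}, \code{pairwise} (data.frame with
#'   \code{segment1}, \code{segment2}, \code{statistic}, \code{p}, \code{q}),
#'   \code{n_patients}, \code{n_perm}.
#' @export
test_segment_trend <- function(scores, n_perm = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scores$segment <- as.character(scores$segment)
  by_pat <- split(seq_len(nrow(scores)), scores$patient)
  multi <- vapply(by_pat, function(i) length(unique(scores$segment[i])) >= 2L, TRUE)
  if (sum(multi) < 2L)
    stop("need at least two patients with scores in >= 2 segments")
  if (sum(multi) < 5L)
    warning("fewer than 5 patients with >= 2 scored segments; ",
            "the permutation test will have little power")
  segs <- intersect(c("trunk", "branches", "sub-branches"),
                    unique(scores$segment))
  if (length(segs) < 2L) stop("need scores in at least two segments")
  pairs <- utils::combn(segs, 2L)

  stat_of <- function(lab) {
    m <- tapply(scores$score, factor(lab, levels = segs), mean)
    m[pairs[1L, ]] - m[pairs[2L, ]]
  }
  obs <- stat_of(scores$segment)

  exceed_pair <- numeric(ncol(pairs))
  exceed_max <- 0
  obs_max <- max(abs(obs), na.rm = TRUE)
  for (b in seq_len(n_perm)) {
    lab <- scores$segment
    for (i in by_pat) lab[i] <- lab[i][sample.int(length(i))]
    st <- stat_of(lab)
    exceed_pair <- exceed_pair + (abs(st) >= abs(obs) - 1e-12)
    exceed_max <- exceed_max + (max(abs(st), na.rm = TRUE) >= obs_max - 1e-12)
  }
  p_pair <- (exceed_pair + 1) / (n_perm + 1)
  list(
    omnibus_p = (exceed_max + 1) / (n_perm + 1),
    pairwise = data.frame(segment1 = pairs[1L, ], segment2 = pairs[2L, ],
                          statistic = as.numeric(obs), p = as.numeric(p_pair),
                          q = stats::p.adjust(p_pair, method = "BH"),
                          stringsAsFactors = FALSE),
    n_patients = sum(multi), n_perm = n_perm)
}
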