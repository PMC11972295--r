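#' Default oncogenetic tree used by the cohort simulator
#'
#' A 16-event tree mirroring the canonical copy-number progression of
#' colorectal cancer: -18q, +13q and +20q arise directly from the root,
#' -8p/+8q, -18p, +7p/+7q, +20p and -17p follow, and the brain-tropic events
#' (-3q, +5q, -6q, +12p) sit deepest. Transition probabilities lie in
#' [0.3, 0.9].
#'
#' @return data.frame \code{event}, \code{parent} ("root" at the top),
#'   \code{theta}.
#' @export
default_tree_spec <- function() {
  data.frame(
    event  = c("-18q", "+13q", "+20q", "-18p", "-8p", "+8q", "+7p", "+7q",
               "+20p", "-17p", "-4q", "-1p", "+12p", "+5q", "-6q", "-3q"),
    parent = c("root", "root", "root", "-18q", "-18q", "-8p", "+13q", "+7p",
               "+20q", "+20q", "-17p", "-17p", "+7q", "+8q", "-18p", "-4q"),
    theta  = c(0.70, 0.65, 0.55, 0.50, 0.50, 0.60, 0.50, 0.50,
               0.45, 0.50, 0.40, 0.35, 0.30, 0.30, 0.30, 0.30),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the tumor-evolution cohort simulator
#'
#' The defaults emulate a metastatic colorectal-cancer cohort: a liver-heavy
#' site mix (liver : lung : brain = 0.50 : 0.33 : 0.17), tree-structured event
#' accumulation over the \code{\link{default_tree_spec}} tree, four
#' four brain-designated late events (-3q, +5q, -6q, +12p) with acquisition
#' multiplier 3 in brain lineages, four liver-and-brain designated events
#' (+7p, +8q, -18p, +20p) with multipliers 1.5-2 in both sites, dissemination
#' uniform over the primary's acquisition order,
#' symmetric observation noise of 1 percent, and independent focal background
#' events.
#'
#' @param n_patients number of patients (default 200).
#' @param site_mix named proportions over liver/lung/brain (must sum to 1).
#' @param tree tree specification (data.frame event/parent/theta).
#' @param multipliers named list site -> named numeric vector of per-event
#'   acquisition multipliers (events not listed have multiplier 1).
#' @param n_passes_primary,n_passes_met number of top-down acquisition passes
#'   before and after dissemination (defaults 3 and 3).
#' @param p_extra_met probability of a second metastasis sample per patient
#'   (default 0.3), providing multi-sample patients for phylogenies.
#' @param epsilon symmetric observation flip rate (default 0.01).
#' @param focal_events,focal_rate independent Bernoulli background events.
#' @param seed integer seed (mandatory).
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(
    n_patients = 200,
    site_mix = c(liver = 0.50, lung = 0.33, brain = 0.17),
    tree = default_tree_spec(),
    multipliers = list(
      brain = c("-3q" = 3, "+5q" = 3, "-6q" = 3, "+12p" = 3,
                "+7p" = 2, "+8q" = 1.5, "-18p" = 2, "+20p" = 2),
      liver = c("+7p" = 2, "+8q" = 1.5, "-18p" = 2, "+20p" = 2)
    ),
    n_passes_primary = 1,
    n_passes_met = 2,
    p_extra_met = 0.3,
    epsilon = 0.01,
    focal_events = c("+8q23-q24", "-4p15", "+6p21", "-10q25",
                     "+11q13", "-2q33", "+17q21", "-12q21"),
    focal_rate = 0.08,
    seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(abs(sum(site_mix) - 1) < 1e-8,
            all(names(site_mix) %in% c("liver", "lung", "brain")),
            all(tree$theta > 0 & tree$theta <= 1))
  if (any(unlist(multipliers) < 0)) stop("multipliers must be >= 0")
  # parents must precede children (topological order by construction)
  known <- "root"
  for (i in seq_len(nrow(tree))) {
    if (!tree$parent[i] %in% known)
      stop("tree parent '", tree$parent[i], "' not defined before '",
           tree$event[i], "'")
    known <- c(known, tree$event[i])
  }
  structure(list(n_patients = n_patients, site_mix = site_mix, tree = tree,
                 multipliers = multipliers,
                 n_passes_primary = n_passes_primary,
                 n_passes_met = n_passes_met, p_extra_met = p_extra_met,
                 epsilon = epsilon, focal_events = focal_events,
                 focal_rate = focal_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

# one lineage continuation: top-down Bernoulli passes over the tree
.acquire <- function(tree, acquired, n_passes, theta) {
  order_new <- character(0)
  for (pass in seq_len(n_passes)) {
    for (i in seq_len(nrow(tree))) {
      v <- tree$event[i]
      if (v %in% acquired) next
      pa <- tree$parent[i]
      if (pa != "root" && !pa %in% acquired) next
      if (stats::runif(1) < theta[i]) {
        acquired <- c(acquired, v)
        order_new <- c(order_new, v)
      }
    }
  }
  list(acquired = acquired, order = order_new)
}

#' Simulate a tumor-evolution cohort
#'
#' Per patient: the primary lineage acquires events by top-down Bernoulli
#' passes over the true tree; a dissemination index is drawn uniformly over
#' the primary's acquisition order; the metastasis lineage inherits the events
#' acquired up to that index and continues acquiring with site-multiplied
#' transition probabilities. One primary and one metastasis sample are emitted
#' per patient (a second metastasis with probability \code{p_extra_met}), with
#' symmetric observation flips and independent focal background events.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list: \code{matrix} (a \code{ci_matrix}), \code{meta} (a
#'   \code{cohort_table}), \code{truth} (true enrichment/timing per event and
#'   per-patient lineage records).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- config$tree
  events <- tree$event
  sites <- names(config$site_mix)

  theta_site <- list()
  clipped <- character(0)
  for (s in sites) {
    m <- rep(1, nrow(tree))
    names(m) <- events
    mult <- config$multipliers[[s]]
    if (!is.null(mult)) m[names(mult)] <- mult
    th <- tree$theta * m
    clipped <- c(clipped, events[th > 1])
    theta_site[[s]] <- pmin(th, 1)
  }
  if (length(clipped))
    warning("theta * multiplier clipped to 1 for: ",
            paste(unique(clipped), collapse = ", "))

  all_events <- c(events, config$focal_events)
  ids <- character(0)
  rows <- list()
  meta <- list()
  patients <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", i)
    site <- sample(sites, 1L, prob = config$site_mix)
    prim <- .acquire(tree, character(0), config$n_passes_primary, tree$theta)

    emit <- function(acquired, sample_id, s_site, s_timing) {
      pres <- as.integer(all_events %in% acquired)
      # observation noise on tree events; focal events are background noise
      flip <- stats::runif(length(events)) < config$epsilon
      pres[seq_along(events)][flip] <- 1L - pres[seq_along(events)][flip]
      nf <- length(config$focal_events)
      if (nf) {
        pres[length(events) + seq_len(nf)] <-
          as.integer(stats::runif(nf) < config$focal_rate)
      }
      ids <<- c(ids, sample_id)
      rows[[length(rows) + 1L]] <<- pres
      meta[[length(meta) + 1L]] <<- data.frame(
        sample = sample_id, patient = pid, site = s_site, timing = s_timing,
        stringsAsFactors = FALSE)
    }

    mets <- list()
    n_mets <- 1L + (stats::runif(1) < config$p_extra_met)
    for (mi in seq_len(n_mets)) {
      k <- sample.int(length(prim$order) + 1L, 1L) - 1L
      inherited <- prim$order[seq_len(k)]
      met <- .acquire(tree, inherited, config$n_passes_met, theta_site[[site]])
      timing <- sample(c("synchronous", "metachronous"), 1L)
      emit(met$acquired, sprintf("%s_M%d", pid, mi), site, timing)
      mets[[mi]] <- list(diss_index = k, inherited = inherited,
                         order = met$order)
    }
    emit(prim$acquired, paste0(pid, "_P"), "primary", "primary")
    patients[[pid]] <- list(site = site, primary_order = prim$order,
                            mets = mets)
  }

  values <- if (length(rows)) do.call(rbind, rows) else
    matrix(integer(0), nrow = 0L, ncol = length(all_events))
  dir_sign <- ifelse(substr(all_events, 1L, 1L) == "-", -1L, 1L)
  values <- sweep(values, 2L, dir_sign, `*`)
  dimnames(values) <- list(ids, all_events)
  mat <- ci_matrix(values, mask = NULL)
  meta_df <- if (length(meta)) {
    cohort_table(do.call(rbind, c(meta, list(make.row.names = FALSE))), mat)
  } else {
    cohort_table(data.frame(sample = character(0), patient = character(0),
                            site = character(0), timing = character(0),
                            stringsAsFactors = FALSE))
  }

  # true timing classes from the spec tree (-log theta root distances)
  parent_index <- match(tree$parent, tree$event, nomatch = 0L)
  d <- numeric(nrow(tree))
  for (v in seq_len(nrow(tree))) {
    s <- 0; u <- v
    repeat {
      s <- s - log(tree$theta[u])
      if (parent_index[u] == 0L) break
      u <- parent_index[u]
    }
    d[v] <- s
  }
  width <- max(d) / 9
  enr <- vapply(events, function(e) {
    hits <- names(config$multipliers)[vapply(config$multipliers, function(m)
      e %in% names(m) && m[[e]] > 1, TRUE)]
    paste(hits, collapse = ";")
  }, "")
  truth_events <- data.frame(
    event = events, parent = tree$parent, theta = tree$theta,
    distance = d,
    timing_class = pmin(9L, pmax(1L, as.integer(ceiling(d / width - 1e-12)))),
    enriched_sites = enr, stringsAsFactors = FALSE)

  list(matrix = mat, meta = meta_df,
       truth = list(events = truth_events, patients = patients,
                    config = config))
}

#' Simulate a null CI matrix of independent events
#'
#' @param N number of samples.
#' @param freqs named vector of per-event Bernoulli rates (names are canonical
#'   event strings).
#' @param seed integer seed.
#' @return a \code{ci_matrix} with independent columns.
#' @export
simulate_null_matrix <- function(N, freqs, seed) {
  if (any(freqs < 0 | freqs > 1)) stop("rates must lie in [0, 1]")
  set.seed(seed)
  values <- vapply(freqs, function(p) stats::rbinom(N, 1L, p), integer(N))
  if (N == 1L) values <- matrix(values, nrow = 1L)
  sign <- ifelse(substr(names(freqs), 1L, 1L) == "-", -1L, 1L)
  values <- sweep(values, 2L, sign, `*`)
  dimnames(values) <- list(sprintf("S%04d", seq_len(N)), names(freqs))
  ci_matrix(values, mask = NULL)
}

#' Simulate a dependent pair of binary events
#'
#' Draws from the bivariate Bernoulli distribution with the requested
#' marginals and log-odds coupling (Plackett construction).
#'
#' @param N number of samples.
#' @param p_a,p_b marginal rates.
#' @param log_odds log odds-ratio of the joint distribution (finite).
#' @param seed integer seed.
#' @return integer matrix N x 2 (columns "a" and "b").
#' @export
simulate_dependent_pair <- function(N, p_a, p_b, log_odds, seed) {
  if (!is.finite(log_odds)) stop("coupling must be finite")
  if (any(c(p_a, p_b) < 0 | c(p_a, p_b) > 1)) stop("marginals must lie in [0, 1]")
  set.seed(seed)
  if (abs(log_odds) < 1e-12) {
    p11 <- p_a * p_b
  } else {
    psi <- exp(log_odds)
    S <- 1 + (p_a + p_b) * (psi - 1)
    disc <- S^2 - 4 * psi * (psi - 1) * p_a * p_b
    if (disc < 0) stop("infeasible marginal/odds combination")
    p11 <- (S - sqrt(disc)) / (2 * (psi - 1))
  }
  lo <- max(0, p_a + p_b - 1)
  hi <- min(p_a, p_b)
  if (p11 < lo - 1e-9 || p11 > hi + 1e-9)
    stop("infeasible marginal/odds combination")
  p11 <- min(max(p11, lo), hi)
  probs <- c(p11, p_a - p11, p_b - p11, 1 - p_a - p_b + p11)
  cell <- sample.int(4L, N, replace = TRUE, prob = pmax(probs, 0))
  cbind(a = as.integer(cell %in% c(1L, 2L)),
        b = as.integer(cell %in% c(1L, 3L)))
}
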