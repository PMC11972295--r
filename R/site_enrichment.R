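#' Per-event CI frequencies by metastatic site
#'
#' Computes, for every CI event, the occurrence count and relative frequency
#' in liver, lung, and brain metastases. Denominators are the per-site
#' metastasis counts after the one-metastasis-per-patient filter. Events seen
#' fewer than \code{min_count} times across all metastases are dropped; gains
#' and losses of the same arm are distinct events. Sex-chromosome events are
#' excluded by default, matching the autosomal scope of the organotropic
#' summary.
#'
#' @param matrix a \code{ci_matrix} over all samples.
#' @param meta a \code{cohort_table}; restricted internally to one metastasis
#'   per patient via \code{\link{select_one_met_per_patient}} unless it already
#'   contains metastases only, one per patient.
#' @param min_count minimum occurrence across all metastases (default 3).
#' @param autosomes_only drop X/Y events (default TRUE).
#' @return data.frame, one row per retained event: per-site \code{count_*},
#'   \code{n_*}, \code{f_*}, plus \code{f_overall}.
#' @export
compute_site_frequencies <- function(matrix, meta, min_count = 3,
                                     autosomes_only = TRUE) {
  meta <- cohort_table(meta)
  mets <- meta[meta$site != "primary", , drop = FALSE]
  if (any(duplicated(mets$patient)) || nrow(mets) != nrow(meta)) {
    mets <- select_one_met_per_patient(matrix, meta)
  }
  sites <- c("liver", "lung", "brain")
  n_site <- vapply(sites, function(s) sum(mets$site == s), 1L)
  if (any(n_site == 0L))
    stop("no metastasis for site(s): ",
         paste(sites[n_site == 0L], collapse = ", "))
  sub <- matrix[match(mets$sample, rownames(matrix)), , drop = FALSE]
  pres <- ci_presence(sub)
  ev <- ci_events(sub)
  if (autosomes_only) {
    auto <- !ev$chromosome %in% c("X", "Y")
    pres <- pres[, auto, drop = FALSE]
    ev <- ev[auto, , drop = FALSE]
  }
  if (!ncol(pres)) {
    return(data.frame(event = character(0), stringsAsFactors = FALSE))
  }
  counts <- sapply(sites, function(s)
    colSums(pres[mets$site == s, , drop = FALSE]))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(ev$event, sites))
  total <- rowSums(counts)
  keep <- total >= min_count
  out <- data.frame(event = ev$event[keep], stringsAsFactors = FALSE)
  for (s in sites) {
    out[[paste0("count_", s)]] <- counts[keep, s]
    out[[paste0("n_", s)]] <- n_site[[s]]
    out[[paste0("f_", s)]] <- counts[keep, s] / n_site[[s]]
  }
  out$f_overall <- total[keep] / sum(n_site)
  rownames(out) <- NULL
  out
}

#' Organotropic map: site-enrichment testing of CI events
#'
#' For each event an omnibus 2x3 Fisher exact test (present/absent by site) is
#' computed and Benjamini-Hochberg adjusted across events. For events with
#' omnibus q below \code{alpha}, pairwise 2x2 Fisher tests compare the
#' maximum-frequency site against each other site (BH across all pairwise
#' tests); the enriched-site set is the maximum-frequency site together with
#' any site not significantly below it. Ternary (barycentric) coordinates
#' place each event by its relative per-site frequencies,
#' \code{c_s = f_s / (f_liver + f_lung + f_brain)}.
#'
#' @param freqs frequency table from \code{\link{compute_site_frequencies}}.
#' @param alpha significance level (default 0.05).
#' @return object of class \code{organotropic_map}: a data.frame with ternary
#'   coordinates \code{c_liver}, \code{c_lung}, \code{c_brain}, omnibus
#'   \code{p}/\code{q}, pairwise q-values, \code{enriched_sites}
#'   (semicolon-joined; empty when q >= alpha) and \code{bubble_size}
#'   (overall frequency).
#' @export
organotropic_map <- function(freqs, alpha = 0.05) {
  sites <- c("liver", "lung", "brain")
  if (!nrow(freqs)) {
    res <- cbind(freqs[0, , drop = FALSE])
    return(structure(res, alpha = alpha,
                     class = c("organotropic_map", "data.frame")))
  }
  f <- as.matrix(freqs[, paste0("f_", sites)])
  denom <- rowSums(f)
  coords <- f / ifelse(denom > 0, denom, 1)
  colnames(coords) <- paste0("c_", sites)

  p <- vapply(seq_len(nrow(freqs)), function(i) {
    tab <- rbind(present = as.numeric(freqs[i, paste0("count_", sites)]),
                 absent = as.numeric(freqs[i, paste0("n_", sites)]) -
                          as.numeric(freqs[i, paste0("count_", sites)]))
    fisher_exact(tab)
  }, 1)
  q <- stats::p.adjust(p, method = "BH")

  # pairwise post-hoc for omnibus-significant events: max-frequency site
  # against each of the two others, BH jointly across all pairwise tests
  pw <- data.frame(event = character(0), site = character(0),
                   other = character(0), p = numeric(0))
  for (i in which(q < alpha)) {
    top <- sites[which.max(f[i, ])]
    for (other in setdiff(sites, top)) {
      tab <- rbind(c(freqs[[paste0("count_", top)]][i],
                     freqs[[paste0("count_", other)]][i]),
                   c(freqs[[paste0("n_", top)]][i] -
                       freqs[[paste0("count_", top)]][i],
                     freqs[[paste0("n_", other)]][i] -
                       freqs[[paste0("count_", other)]][i]))
      pw <- rbind(pw, data.frame(event = freqs$event[i], site = top,
                                 other = other, p = fisher_exact(tab),
                                 stringsAsFactors = FALSE))
    }
  }
  pw$q <- if (nrow(pw)) stats::p.adjust(pw$p, method = "BH") else numeric(0)

  enriched <- character(nrow(freqs))
  q_pair <- matrix(NA_real_, nrow(freqs), length(sites),
                   dimnames = list(NULL, paste0("q_vs_", sites)))
  for (i in which(q < alpha)) {
    top <- sites[which.max(f[i, ])]
    set <- top
    for (other in setdiff(sites, top)) {
      row <- pw$event == freqs$event[i] & pw$other == other
      q_pair[i, paste0("q_vs_", other)] <- pw$q[row]
      if (pw$q[row] >= alpha) set <- c(set, other)  # not significantly below
    }
    enriched[i] <- paste(sites[sites %in% set], collapse = ";")
  }

  res <- cbind(freqs, coords,
               data.frame(p = p, q = q, q_pair, enriched_sites = enriched,
                          bubble_size = freqs$f_overall,
                          stringsAsFactors = FALSE))
  rownames(res) <- NULL
  structure(res, alpha = alpha, pairwise = pw,
            class = c("organotropic_map", "data.frame"))
}

#' @export
print.organotropic_map <- function(x, ...) {
  alpha <- attr(x, "alpha")
  cat("Organotropic map: ", nrow(x), " events tested, ",
      sum(nzchar(x$enriched_sites)), " significant at q < ", alpha, "\n",
      sep = "")
  sig <- x[nzchar(x$enriched_sites), c("event", "f_liver", "f_lung", "f_brain",
                                       "q", "enriched_sites"), drop = FALSE]
  if (nrow(sig)) print.data.frame(sig[order(sig$q), ], digits = 3)
  invisible(x)
}

#' Ternary scatter of an organotropic map
#'
#' Projects each event into the barycentric triangle spanned by the three
#' metastatic sites; bubble area scales with the overall frequency and
#' significant events are filled.
#'
#' @param x an \code{organotropic_map}.
#' @param ... passed to \code{plot}.
#' @export
plot.organotropic_map <- function(x, ...) {
  # corners: liver bottom-left, lung bottom-right, brain top
  cx <- x$c_lung + 0.5 * x$c_brain
  cy <- x$c_brain * sqrt(3) / 2
  graphics::plot(NA, xlim = c(-0.08, 1.08), ylim = c(-0.08, sqrt(3) / 2 + 0.08),
                 axes = FALSE, xlab = "", ylab = "", asp = 1, ...)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  graphics::text(c(0, 1, 0.5), c(-0.05, -0.05, sqrt(3) / 2 + 0.05),
                 c("liver", "lung", "brain"))
  sig <- nzchar(x$enriched_sites)
  graphics::symbols(cx, cy, circles = 0.12 * sqrt(x$bubble_size),
                    inches = FALSE, add = TRUE,
                    bg = ifelse(sig, grDevices::adjustcolor("firebrick", 0.6), NA))
  sel <- sig | x$bubble_size >= stats::quantile(x$bubble_size, 0.8)
  graphics::text(cx[sel], cy[sel], x$event[sel], cex = 0.6, pos = 3)
  invisible(x)
}

#' Write an organotropic map as TSV
#' @param x an \code{organotropic_map}.
#' @param path output file.
#' @export
write_organotropic_map <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
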