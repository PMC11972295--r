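#' Construct a CI matrix
#'
#' A \code{ci_matrix} holds copy-number imbalance calls for a set of samples
#' over a set of canonical CI events. Values are signed presence codes:
#' gains carry 0/1/2 (2 = high-level amplification), losses carry 0/-1.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   events in columns (colnames = canonical event strings).
#' @param mask optional \code{exclusion_mask}; events intersecting the mask are
#'   dropped with a warning. \code{NULL} keeps all events.
#' @return object of class \code{ci_matrix}: the validated integer matrix with
#'   an \code{events} attribute (parsed event table).
#' @export
ci_matrix <- function(values, mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("ci_matrix requires sample ids as rownames")
  if (ncol(values) > 0L && is.null(colnames(values)))
    stop("ci_matrix requires event strings as colnames")
  if (ncol(values) == 0L) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate event: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  events <- parse_ci_events(colnames(values))

  if (!is.null(mask)) {
    drop <- event_excluded(events, mask)
    if (any(drop)) {
      warning(sum(drop), " event(s) intersecting the exclusion mask dropped: ",
              paste(events$event[drop], collapse = ", "))
      values <- values[, !drop, drop = FALSE]
      events <- events[!drop, , drop = FALSE]
      rownames(events) <- NULL
    }
  }

  ok <- values %in% c(-1, 0, 1, 2)
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow(values)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid code %s at sample '%s', event '%s' (allowed: -1, 0, 1, 2)",
                 values[bad[1L], bad[2L]], rownames(values)[bad[1L]],
                 colnames(values)[bad[2L]]))
  }
  storage.mode(values) <- "integer"

  # normalize: presence of a loss event is stored as -1 (readers may code it 1)
  is_loss <- events$direction == "loss"
  if (any(is_loss)) {
    loss <- values[, is_loss, drop = FALSE]
    if (any(loss == 2L))
      stop("code 2 (amplification) is not valid for a loss event")
    loss[loss == 1L] <- -1L
    values[, is_loss] <- loss
  }
  if (any(values[, !is_loss, drop = FALSE] < 0L))
    stop("code -1 is not valid for a gain event")

  # a sample cannot carry both the gain and the loss of the same locus
  key <- paste(events$chromosome, events$arm, events$band_lo, events$band_hi,
               events$high_level)
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    g <- idx[events$direction[idx] == "gain"]
    l <- idx[events$direction[idx] == "loss"]
    if (length(g) && length(l)) {
      both <- rowSums(values[, g, drop = FALSE] != 0L) > 0L &
              rowSums(values[, l, drop = FALSE] != 0L) > 0L
      if (any(both))
        stop("sample '", rownames(values)[which(both)[1L]],
             "' carries both gain and loss of the same locus (",
             events$event[g[1L]], " / ", events$event[l[1L]], ")")
    }
  }

  structure(values, events = events, class = "ci_matrix")
}

#' @export
print.ci_matrix <- function(x, ...) {
  ev <- ci_events(x)
  cat("CI matrix: ", nrow(x), " samples x ", ncol(x), " events (",
      sum(ev$direction == "gain"), " gains, ", sum(ev$direction == "loss"),
      " losses; ", sum(ev$focal), " focal)\n", sep = "")
  invisible(x)
}

#' Event table of a CI matrix
#' @param x a \code{ci_matrix}.
#' @export
ci_events <- function(x) attr(x, "events")

#' Subset a CI matrix, keeping the event table in step
#' @param x a \code{ci_matrix}.
#' @param i,j row (sample) and column (event) indices.
#' @param ... ignored.
#' @param drop ignored; dimensions are always kept.
#' @export
`[.ci_matrix` <- function(x, i, j, ..., drop = FALSE) {
  ev <- ci_events(x)
  m <- unclass(x)
  attr(m, "events") <- NULL
  m <- m[i, j, drop = FALSE]
  if (!missing(j)) {
    ev <- ev[match(colnames(m), ev$event), , drop = FALSE]
    rownames(ev) <- NULL
  }
  structure(m, events = ev, class = "ci_matrix")
}

#' Binary presence matrix of a CI matrix
#'
#' @param x a \code{ci_matrix}.
#' @param amp_separate if \code{TRUE}, high-level amplification codes (+2) are
#'   emitted twice: once on the gain event and once on an extra \code{" amp"}
#'   character column, as used for patient phylogenies.
#' @return integer 0/1 matrix.
#' @export
ci_presence <- function(x, amp_separate = FALSE) {
  m <- unclass(x)
  attr(m, "events") <- NULL
  pres <- (m != 0L) * 1L
  if (amp_separate) {
    ev <- ci_events(x)
    amp_cols <- which(colSums(m == 2L) > 0L & !ev$high_level)
    if (length(amp_cols)) {
      extra <- (m[, amp_cols, drop = FALSE] == 2L) * 1L
      colnames(extra) <- paste0(colnames(m)[amp_cols], " amp")
      pres <- cbind(pres, extra)
    }
  }
  pres
}

#' Read a CI matrix from a tab-separated file
#'
#' First column holds the sample id; remaining column names are canonical CI
#' event strings; codes are -1/0/1/2 (losses may be coded 1 or -1).
#'
#' @param path file path.
#' @param mask exclusion mask applied to the event columns
#'   (default \code{default_exclusion_mask()}).
#' @return a \code{ci_matrix}.
#' @export
read_ci_matrix <- function(path, mask = default_exclusion_mask()) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 2L) stop("CI matrix file needs a sample column plus events: ", path)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v) || !all(v %in% c(-1, 0, 1, 2)))
      stop(sprintf("malformed code in column '%s' (row %d of %s)",
                   names(vals)[j],
                   which(!(suppressWarnings(as.numeric(v)) %in% c(-1, 0, 1, 2)))[1L],
                   path))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  ci_matrix(m, mask = mask)
}

#' Write a CI matrix as TSV
#' @param x a \code{ci_matrix}.
#' @param path output file.
#' @param header optional comment lines (e.g. run seed) written before the
#'   table, "# "-prefixed; \code{read_ci_matrix} skips them.
#' @export
write_ci_matrix <- function(x, path, header = NULL) {
  df <- data.frame(sample = rownames(x), unclass(x), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a cohort metadata table
#'
#' @param meta data.frame with columns \code{sample}, \code{patient},
#'   \code{site} (primary/liver/lung/brain) and \code{timing}
#'   (primary/synchronous/metachronous); optional \code{sex}, \code{age}.
#' @param matrix optional \code{ci_matrix}; if given, every sample of the
#'   matrix must have exactly one metadata row.
#' @return the validated data.frame (class \code{cohort_table}).
#' @export
cohort_table <- function(meta, matrix = NULL) {
  need <- c("sample", "patient", "site", "timing")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  meta$sample <- as.character(meta$sample)
  meta$patient <- as.character(meta$patient)
  if (anyDuplicated(meta$sample)) stop("duplicate sample id in cohort table")
  if (!all(meta$site %in% c("primary", "liver", "lung", "brain")))
    stop("site must be one of primary/liver/lung/brain")
  if (!all(meta$timing %in% c("primary", "synchronous", "metachronous")))
    stop("timing must be one of primary/synchronous/metachronous")
  if (any((meta$site == "primary") != (meta$timing == "primary")))
    stop("site == 'primary' must coincide with timing == 'primary'")
  if (!is.null(matrix)) {
    missing_rows <- setdiff(rownames(matrix), meta$sample)
    if (length(missing_rows))
      stop("samples without metadata: ", paste(missing_rows, collapse = ", "))
  }
  class(meta) <- c("cohort_table", "data.frame")
  meta
}

#' Per-sample CI counts
#'
#' Counts arm-level aneuploidies and focal CIs per sample. A high-level
#' amplification (+2) counts once, as a gain. Whole-arm events on the short
#' arms of the acrocentric chromosomes (13p, 14p, 15p, 21p, 22p) never enter
#' the aneuploidy count; to preserve \code{n_total = n_arm + n_focal} they are
#' tallied with the focal events.
#'
#' @param matrix a \code{ci_matrix}.
#' @return data.frame with one row per sample: \code{sample},
#'   \code{n_arm_aneuploidies}, \code{n_focal}, \code{n_losses},
#'   \code{n_gains}, \code{n_total}.
#' @export
summarize_ci <- function(matrix) {
  ev <- ci_events(matrix)
  pres <- ci_presence(matrix)
  acro <- acrocentric_short_arms()
  is_acro <- paste(ev$chromosome, ev$arm) %in% paste(acro$chromosome, acro$arm)
  arm_event <- !ev$focal & !is_acro
  gains <- ev$direction == "gain"
  data.frame(
    sample = rownames(matrix),
    n_arm_aneuploidies = as.integer(pres[, arm_event, drop = FALSE] %*%
                                      rep(1L, sum(arm_event))),
    n_focal = as.integer(pres[, !arm_event, drop = FALSE] %*%
                           rep(1L, sum(!arm_event))),
    n_losses = as.integer(pres[, !gains, drop = FALSE] %*% rep(1L, sum(!gains))),
    n_gains = as.integer(pres[, gains, drop = FALSE] %*% rep(1L, sum(gains))),
    n_total = as.integer(rowSums(pres)),
    stringsAsFactors = FALSE
  )
}

#' Select one metastasis per patient
#'
#' For each patient the single metastasis entering cohort-level statistics is
#' chosen by site priority brain > lung > liver (rarer sites first); among
#' several metastases at the chosen site, the lesion with the lowest total CI
#' count is taken (ties broken by sample id). Patients with only primary
#' samples are excluded with a warning.
#'
#' @param matrix a \code{ci_matrix} covering all samples.
#' @param meta a \code{cohort_table}.
#' @return the \code{cohort_table} rows of the selected metastases, one per
#'   patient.
#' @export
select_one_met_per_patient <- function(matrix, meta) {
  meta <- cohort_table(meta, matrix)
  mets <- meta[meta$site != "primary" & meta$sample %in% rownames(matrix), ,
               drop = FALSE]
  dropped <- setdiff(meta$patient, mets$patient)
  if (length(dropped))
    warning("patient(s) without metastasis sample excluded: ",
            paste(sort(dropped), collapse = ", "))
  if (!nrow(mets)) return(mets)
  counts <- summarize_ci(matrix)
  mets$n_ci <- counts$n_total[match(mets$sample, counts$sample)]
  prio <- c(brain = 1L, lung = 2L, liver = 3L)
  ord <- order(mets$patient, prio[mets$site], mets$n_ci, mets$sample)
  mets <- mets[ord, , drop = FALSE]
  sel <- mets[!duplicated(mets$patient), , drop = FALSE]
  sel$n_ci <- NULL
  rownames(sel) <- NULL
  sel
}
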