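#' Read a UCSC-style cytoband file
#'
#' Expects the cytoBand.txt dialect: chrom, chromStart, chromEnd, name
#' (band, e.g. "q22.1"), gieStain; tab-separated, no header, optional "chr"
#' prefix on the chromosome.
#'
#' @param path file path.
#' @return data.frame with \code{chromosome}, \code{start}, \code{end}
#'   (0-based half-open, as in the source format), \code{band}, \code{stain},
#'   \code{arm}.
#' @export
read_cytoband <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chromosome", "start", "end", "band", "stain"))
  tab$chromosome <- sub("^chr", "", tab$chromosome)
  tab$arm <- substr(tab$band, 1L, 1L)
  if (!all(tab$arm %in% c("p", "q")))
    stop("cytoband names must start with the arm letter (p/q): ", path)
  if (any(tab$start >= tab$end)) stop("cytoband with start >= end in ", path)
  tab
}

#' Build arm definitions from cytobands
#'
#' Bands sharing the arm letter are merged into one interval per
#' (chromosome, arm). Coordinates stay 0-based half-open internally.
#'
#' @param cytoband data.frame from \code{read_cytoband}.
#' @return data.frame \code{chromosome}, \code{arm}, \code{start}, \code{end},
#'   \code{acrocentric_short}.
#' @export
arm_definitions <- function(cytoband) {
  key <- interaction(cytoband$chromosome, cytoband$arm, drop = TRUE)
  arms <- do.call(rbind, lapply(split(cytoband, key), function(b) {
    data.frame(chromosome = b$chromosome[1L], arm = b$arm[1L],
               start = min(b$start), end = max(b$end),
               stringsAsFactors = FALSE)
  }))
  rownames(arms) <- NULL
  if (anyDuplicated(paste(arms$chromosome, arms$arm)))
    stop("duplicate (chromosome, arm) pair")
  stopifnot(all(arms$start < arms$end))
  acro <- acrocentric_short_arms()
  arms$acrocentric_short <- paste(arms$chromosome, arms$arm) %in%
    paste(acro$chromosome, acro$arm)
  arms[order(suppressWarnings(as.integer(arms$chromosome)), arms$chromosome,
             arms$arm), , drop = FALSE]
}

#' Read a SEG file of copy-number segments
#'
#' Standard columns ID, chrom, loc.start, loc.end, seg.mean (num.mark
#' optional); 1-based inclusive coordinates. Column matching is by position
#' for the five mandatory fields after dropping a num.mark column if present.
#'
#' @param path file path.
#' @return data.frame \code{sample}, \code{chromosome}, \code{start},
#'   \code{end} (converted to 0-based half-open), \code{seg_mean}.
#' @export
read_seg <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  mark <- grep("num[._]?mark", nm)
  if (length(mark)) tab <- tab[, -mark, drop = FALSE]
  if (ncol(tab) < 5L) stop("SEG file needs ID, chrom, loc.start, loc.end, seg.mean")
  out <- data.frame(sample = as.character(tab[[1L]]),
                    chromosome = sub("^chr", "", as.character(tab[[2L]])),
                    start = as.numeric(tab[[3L]]) - 1,  # to half-open
                    end = as.numeric(tab[[4L]]),
                    seg_mean = as.numeric(tab[[5L]]),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("segment with non-positive length")
  out
}

#' Call arm-level copy-number events from segmented data
#'
#' A simplified arm caller for one sample. Per arm, the covered fraction is
#' the summed segment overlap divided by the arm length; arms covered below
#' \code{coverage_min} yield no call (flagged uncovered). Otherwise the arm is
#' called gained (+1) when at least \code{alteration_min} of the covered length
#' has \code{seg_mean >= amp_threshold}, lost (-1) symmetrically, and neutral
#' (0) otherwise. A gain is upgraded to a high-level amplification (+2) when
#' the length-weighted mean \code{seg_mean} of the gained segments is >= 1.0.
#'
#' @param segments data.frame from \code{read_seg} (one sample).
#' @param arms arm definitions from \code{arm_definitions}.
#' @param amp_threshold log2-ratio threshold for gain/loss (default 0.2).
#' @param coverage_min minimum covered fraction of the arm (default 0.5).
#' @param alteration_min minimum altered fraction of the covered length
#'   (default 0.7).
#' @param mask exclusion mask applied to the resulting events.
#' @return one-sample \code{ci_matrix} of whole-arm events, with an
#'   \code{uncovered} attribute listing arms below \code{coverage_min}.
#' @export
call_arm_events <- function(segments, arms, amp_threshold = 0.2,
                            coverage_min = 0.5, alteration_min = 0.7,
                            mask = default_exclusion_mask()) {
  if (length(unique(segments$sample)) != 1L)
    stop("call_arm_events expects segments of a single sample")
  if (any(segments$end <= segments$start)) stop("segment with non-positive length")
  sample_id <- segments$sample[1L]

  # every segment must fall inside some defined arm
  for (i in seq_len(nrow(segments))) {
    hit <- arms$chromosome == segments$chromosome[i] &
      arms$start < segments$end[i] & arms$end > segments$start[i]
    if (!any(hit))
      stop("segment outside any defined arm: ", segments$chromosome[i], ":",
           segments$start[i] + 1, "-", segments$end[i])
  }

  calls <- character(0)
  codes <- integer(0)
  uncovered <- character(0)
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    arm_name <- paste0(a$chromosome, a$arm)
    sel <- segments$chromosome == a$chromosome &
      segments$start < a$end & segments$end > a$start
    seg <- segments[sel, , drop = FALSE]
    len <- pmin(seg$end, a$end) - pmax(seg$start, a$start)
    covered <- sum(len)
    if (covered / (a$end - a$start) < coverage_min) {
      uncovered <- c(uncovered, arm_name)
      next
    }
    gain_len <- sum(len[seg$seg_mean >= amp_threshold])
    loss_len <- sum(len[seg$seg_mean <= -amp_threshold])
    if (gain_len / covered >= alteration_min) {
      g <- seg$seg_mean >= amp_threshold
      wmean <- sum(seg$seg_mean[g] * len[g]) / gain_len
      calls <- c(calls, paste0("+", arm_name))
      codes <- c(codes, if (wmean >= 1.0) 2L else 1L)
    } else if (loss_len / covered >= alteration_min) {
      calls <- c(calls, paste0("-", arm_name))
      codes <- c(codes, -1L)
    }
  }
  if (!length(calls)) {
    m <- matrix(integer(0), nrow = 1L, dimnames = list(sample_id, NULL))
    res <- structure(m, events = parse_ci_events(character(0)),
                     class = "ci_matrix")
  } else {
    m <- matrix(codes, nrow = 1L, dimnames = list(sample_id, calls))
    res <- ci_matrix(m, mask = mask)
  }
  attr(res, "uncovered") <- uncovered
  res
}
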