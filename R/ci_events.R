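#' Parse canonical chromosomal-imbalance event strings
#'
#' A CI event is written as a signed chromosome-arm label, optionally with a
#' band interval for focal (sub-arm) events and an \code{" amp"} suffix for
#' high-level amplifications: \code{"+7p"}, \code{"-18q"}, \code{"+8q23-q24"},
#' \code{"+12p amp"}. Whole-arm events carry no band interval.
#'
#' @param x character vector of event strings.
#' @return a data.frame with one row per event: \code{event}, \code{chromosome}
#'   (1-22, X, Y), \code{arm} (p/q), \code{band_lo}/\code{band_hi} (numeric,
#'   \code{NA} for whole-arm events, \code{Inf} encodes a *ter* endpoint),
#'   \code{direction} (gain/loss), \code{high_level}, \code{focal}.
#' @export
parse_ci_events <- function(x) {
  x <- as.character(x)
  if (!length(x)) {
    return(data.frame(event = character(0), chromosome = character(0),
                      arm = character(0), band_lo = numeric(0),
                      band_hi = numeric(0), direction = character(0),
                      high_level = logical(0), focal = logical(0),
                      stringsAsFactors = FALSE))
  }
  rx <- "^([+-])(2[0-2]|1[0-9]|[1-9]|X|Y)([pq])((?:[0-9]+(?:\\.[0-9]+)?|ter)(?:-[pq]?(?:[0-9]+(?:\\.[0-9]+)?|ter))?)?( amp)?$"
  m <- regmatches(x, regexec(rx, x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed CI event string(s): ", paste(x[bad], collapse = ", "))
  }
  parts <- do.call(rbind, m)
  band <- parts[, 5L]
  lo <- hi <- rep(NA_real_, length(x))
  has_band <- nzchar(band)
  if (any(has_band)) {
    ends <- strsplit(band[has_band], "-", fixed = TRUE)
    band_num <- function(b) {
      b <- sub("^[pq]", "", b)
      if (b == "ter") Inf else as.numeric(b)
    }
    lo[has_band] <- vapply(ends, function(e) band_num(e[[1L]]), 1)
    hi[has_band] <- vapply(ends, function(e) band_num(e[[length(e)]]), 1)
  }
  swap <- has_band & hi < lo
  tmp <- lo[swap]; lo[swap] <- hi[swap]; hi[swap] <- tmp
  data.frame(
    event = x,
    chromosome = parts[, 3L],
    arm = parts[, 4L],
    band_lo = lo,
    band_hi = hi,
    direction = ifelse(parts[, 2L] == "+", "gain", "loss"),
    high_level = nzchar(parts[, 6L]),
    focal = has_band,
    stringsAsFactors = FALSE
  )
}

#' @rdname parse_ci_events
#' @param events a data.frame as returned by \code{parse_ci_events}.
#' @export
format_ci_event <- function(events) {
  sign <- ifelse(events$direction == "gain", "+", "-")
  band <- ifelse(events$focal,
    ifelse(is.infinite(events$band_lo), "ter", format(events$band_lo)),
    "")
  hi <- ifelse(events$focal & events$band_hi != events$band_lo,
    paste0("-", events$arm,
           ifelse(is.infinite(events$band_hi), "ter", format(events$band_hi))),
    "")
  amp <- ifelse(events$high_level, " amp", "")
  paste0(sign, events$chromosome, events$arm, band, hi, amp)
}

#' Default exclusion mask for band-resolution CI profiles
#'
#' Regions that CGH-based CI profiling cannot score reliably and that are
#' therefore excluded from all analyses: 1p32 to pter, the short arms of the
#' acrocentric chromosomes 13, 14, 15, 21 and 22, telomeric bands, and the
#' constitutive heterochromatic regions of 1q, 9q, 16q and Yq.
#'
#' @return an object of class \code{exclusion_mask}: a data.frame of regions
#'   (\code{chromosome}, \code{arm}, \code{band_lo}, \code{band_hi},
#'   \code{whole_arm}) with attribute \code{telomeres = TRUE} indicating that
#'   events written with explicit *ter* bands are also excluded.
#' @export
default_exclusion_mask <- function() {
  regions <- data.frame(
    chromosome = c("1", "13", "14", "15", "21", "22", "1", "9", "16", "Y"),
    arm        = c("p", "p",  "p",  "p",  "p",  "p",  "q", "q", "q",  "q"),
    band_lo    = c(32,  NA,   NA,   NA,   NA,   NA,   11,  11,  11,   11),
    band_hi    = c(Inf, NA,   NA,   NA,   NA,   NA,   12.99, 12.99, 11.99, 12.99),
    whole_arm  = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  structure(regions, telomeres = TRUE, class = c("exclusion_mask", "data.frame"))
}

#' Arms whose short-arm aneuploidies are never counted
#' @keywords internal
acrocentric_short_arms <- function() {
  data.frame(chromosome = c("13", "14", "15", "21", "22"), arm = "p",
             stringsAsFactors = FALSE)
}

#' Identify events intersecting an exclusion mask
#'
#' Whole-arm mask entries exclude every event on that arm. Partial entries
#' (e.g. 1p32-pter, heterochromatic blocks) exclude focal events whose band
#' interval intersects the masked interval; whole-arm events on partially
#' masked arms are retained, since an apparent whole-arm imbalance refers to
#' the analyzable portion of the arm. With the telomere flag set, events whose
#' band interval reaches a *ter* endpoint are excluded as well.
#'
#' @param events data.frame from \code{parse_ci_events}.
#' @param mask an \code{exclusion_mask}; \code{NULL} disables masking.
#' @return logical vector, \code{TRUE} where the event is excluded.
#' @export
event_excluded <- function(events, mask = default_exclusion_mask()) {
  if (is.null(mask)) return(rep(FALSE, nrow(events)))
  out <- rep(FALSE, nrow(events))
  for (i in seq_len(nrow(mask))) {
    on_arm <- events$chromosome == mask$chromosome[i] & events$arm == mask$arm[i]
    if (mask$whole_arm[i]) {
      out <- out | on_arm
    } else {
      hit <- on_arm & events$focal &
        events$band_hi >= mask$band_lo[i] & events$band_lo <= mask$band_hi[i]
      out <- out | hit
    }
  }
  if (isTRUE(attr(mask, "telomeres"))) {
    out <- out | (events$focal & is.infinite(events$band_hi))
  }
  out
}
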