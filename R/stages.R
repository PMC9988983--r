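#' Sleep stage coding
#'
#' Stages follow the five-class AASM scheme coded as integers:
#' 0 = W (wake), 1 = N1, 2 = N2, 3 = N3 (slow-wave sleep), 4 = REM.
#' Epochs scored MOVEMENT or UNKNOWN carry the mask sentinel -1 and are
#' excluded from losses and metrics.
#'
#' @return `stage_levels()` returns the five stage labels in coding order.
#' @export
stage_levels <- function() c("W", "N1", "N2", "N3", "REM")

#' @rdname stage_levels
#' @param code integer stage codes in \{-1, 0, ..., 4\}.
#' @export
stage_label <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- code %in% 0:4
  out[ok] <- stage_levels()[code[ok] + 1L]
  out[code == -1L] <- "MASK"
  if (anyNA(out)) stop("invalid stage code(s): ",
                       paste(unique(code[is.na(out)]), collapse = ", "))
  out
}

MASK_CODE <- -1L

#' Per-epoch stage label sequence
#'
#' A hypnogram: one integer stage label per 30-second epoch, with -1 marking
#' masked (MOVEMENT/UNKNOWN) epochs.
#'
#' @param labels integer vector with values in \{-1, 0, 1, 2, 3, 4\}.
#' @param epoch_len_s epoch length in seconds (30 by convention).
#' @return an integer vector of class `stage_sequence`.
#' @export
stage_sequence <- function(labels, epoch_len_s = 30) {
  labels <- as.integer(labels)
  if (length(labels) && !all(labels %in% c(-1L, 0:4)))
    stop("stage labels must lie in {-1, 0, 1, 2, 3, 4}")
  if (epoch_len_s <= 0) stop("epoch_len_s must be positive")
  structure(labels, epoch_len_s = epoch_len_s, class = "stage_sequence")
}

#' @export
print.stage_sequence <- function(x, ...) {
  cat("<stage_sequence> ", length(x), " epochs of ",
      attr(x, "epoch_len_s"), " s\n", sep = "")
  tab <- table(factor(stage_label(unclass(x)),
                      levels = c(stage_levels(), "MASK")))
  print(tab)
  invisible(x)
}

#' Harmonize raw stage labels onto the 5-class AASM alphabet
#'
#' Maps source-convention labels to the integer coding of
#' [stage_sequence()]. Under the R&K convention the N4 (S4) stage is merged
#' into N3; MOVEMENT and UNKNOWN epochs become the mask sentinel -1.
#'
#' @param labels character vector of raw labels.
#' @param scheme source convention, `"AASM"` or `"R&K"`.
#' @return a [stage_sequence()] of the same length.
#' @export
harmonize_stages <- function(labels, scheme = c("AASM", "R&K")) {
  scheme <- match.arg(scheme)
  labels <- toupper(trimws(as.character(labels)))
  map <- c(W = 0L, WAKE = 0L,
           N1 = 1L, S1 = 1L, N2 = 2L, S2 = 2L, N3 = 3L, S3 = 3L,
           REM = 4L, R = 4L,
           MOVEMENT = MASK_CODE, MT = MASK_CODE, UNKNOWN = MASK_CODE,
           MASK = MASK_CODE, "?" = MASK_CODE)
  if (scheme == "R&K") map <- c(map, N4 = 3L, S4 = 3L)
  bad <- setdiff(unique(labels), names(map))
  if (length(bad))
    stop("unknown stage label(s) for scheme ", scheme, ": ",
         paste(bad, collapse = ", "))
  stage_sequence(unname(map[labels]))
}
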