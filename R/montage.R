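#' Channel derivation
#'
#' An ordered (active, reference) electrode pair with a modality tag. The
#' derived signal is `active - reference`, pointwise.
#'
#' @param active,reference electrode labels (must differ).
#' @param modality `"EEG"` or `"EOG"`.
#' @export
derivation <- function(active, reference, modality = c("EEG", "EOG")) {
  modality <- match.arg(modality)
  if (identical(active, reference))
    stop("active and reference electrodes must differ")
  structure(list(active = active, reference = reference,
                 modality = modality), class = "derivation")
}

#' @export
format.derivation <- function(x, ...) paste0(x$active, "-", x$reference)

#' @export
print.derivation <- function(x, ...) {
  cat("<derivation ", x$modality, "> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse an "ACTIVE-REFERENCE" derivation string
#' @param s string such as `"C4-M1"`.
#' @param modality `"EEG"` or `"EOG"`.
#' @export
parse_derivation <- function(s, modality = c("EEG", "EOG")) {
  parts <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("derivation must be 'ACTIVE-REFERENCE': ", s)
  derivation(parts[1], parts[2], match.arg(modality))
}

#' AASM-recommended derivation table
#'
#' The standard frontal/central/occipital EEG derivations against the
#' contralateral mastoid, and both EOG electrodes against M2. Overridable
#' wherever a derivation table is accepted.
#' @export
aasm_derivation_table <- function() {
  c(lapply(c("F4-M1", "C4-M1", "O2-M1", "F3-M2", "C3-M2", "O1-M2"),
           parse_derivation, modality = "EEG"),
    lapply(c("E1-M2", "E2-M2"), parse_derivation, modality = "EOG"))
}

#' Compute a derived (referential difference) signal
#'
#' @param recording a [psg_recording()].
#' @param d a [derivation()]. The reserved reference label `"ZERO"` denotes
#'   a pre-derived virtual channel (reference identically zero).
#' @return numeric signal vector.
#' @export
derive_signal <- function(recording, d) {
  stopifnot(inherits(d, "derivation"))
  for (el in c(d$active, if (d$reference != "ZERO") d$reference)) {
    if (!el %in% recording$electrodes)
      stop("electrode not present in recording: ", el)
  }
  a <- recording$signals[d$active, ]
  if (d$reference == "ZERO") a else a - recording$signals[d$reference, ]
}

#' Recommended derivations realizable on a montage
#'
#' Intersects the configured AASM table with the available electrodes. At
#' least one EEG and one EOG derivation must be realizable.
#'
#' @param available_electrodes electrode labels present.
#' @param table derivation table, defaults to [aasm_derivation_table()].
#' @return list of [derivation()] objects.
#' @export
recommended_derivations <- function(available_electrodes,
                                    table = aasm_derivation_table()) {
  keep <- Filter(function(d) {
    d$active %in% available_electrodes &&
      (d$reference == "ZERO" || d$reference %in% available_electrodes)
  }, table)
  mods <- vapply(keep, `[[`, "", "modality")
  if (!any(mods == "EEG")) stop("no recommended EEG derivation realizable")
  if (!any(mods == "EOG")) stop("no recommended EOG derivation realizable")
  keep
}

#' Atypical (random) derivations
#'
#' Uniformly samples ordered pairs of distinct electrodes: EEG pairs from
#' the scalp + mastoid electrodes, EOG pairs with the active electrode in
#' \{E1, E2\} and any other electrode as reference. Emulates training on
#' non-conventional montages.
#'
#' @param available_electrodes electrode labels present.
#' @param n_eeg,n_eog number of EEG / EOG derivations to draw (distinct).
#' @param seed integer seed or `NULL`.
#' @return list of [derivation()] objects (EEG first).
#' @export
atypical_derivations <- function(available_electrodes, n_eeg = 1, n_eog = 1,
                                 seed = NULL) {
  eog_el <- intersect(available_electrodes, c("E1", "E2"))
  head_el <- setdiff(available_electrodes, eog_el)
  eeg_pairs <- expand.grid(active = head_el, reference = head_el,
                           stringsAsFactors = FALSE)
  eeg_pairs <- eeg_pairs[eeg_pairs$active != eeg_pairs$reference, ]
  eog_pairs <- expand.grid(active = eog_el,
                           reference = available_electrodes,
                           stringsAsFactors = FALSE)
  eog_pairs <- eog_pairs[eog_pairs$active != eog_pairs$reference, ]
  if (n_eeg > nrow(eeg_pairs)) stop("n_eeg exceeds the number of distinct EEG pairs")
  if (n_eog > nrow(eog_pairs)) stop("n_eog exceeds the number of distinct EOG pairs")
  with_seed(seed, {
    ie <- sample.int(nrow(eeg_pairs), n_eeg)
    io <- sample.int(nrow(eog_pairs), n_eog)
    c(lapply(ie, function(i) derivation(eeg_pairs$active[i],
                                        eeg_pairs$reference[i], "EEG")),
      lapply(io, function(i) derivation(eog_pairs$active[i],
                                        eog_pairs$reference[i], "EOG")))
  })
}

#' Enumerate all EEG x EOG derivation combinations
#'
#' Full Cartesian product in deterministic EEG-major order; with 2 EEG and
#' 2 EOG derivations, four combinations result.
#'
#' @param eeg_derivs,eog_derivs non-empty lists of [derivation()] objects.
#' @return list of `list(eeg = , eog = )` pairs.
#' @export
enumerate_combinations <- function(eeg_derivs, eog_derivs) {
  if (!length(eeg_derivs) || !length(eog_derivs))
    stop("both derivation lists must be non-empty")
  out <- vector("list", length(eeg_derivs) * length(eog_derivs))
  k <- 0L
  for (e in eeg_derivs) for (o in eog_derivs) {
    k <- k + 1L
    out[[k]] <- list(eeg = e, eog = o)
  }
  out
}

split_by_modality <- function(derivs) {
  mods <- vapply(derivs, `[[`, "", "modality")
  list(eeg = derivs[mods == "EEG"], eog = derivs[mods == "EOG"])
}
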