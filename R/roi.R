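# Regions of interest: 8 gyral ROIs per hemisphere plus a catch-all.

#' ROI labels used by the analysis
#'
#' Eight gyral regions of interest per hemisphere (posterior/anterior
#' middle-frontal gyrus, posterior inferior-frontal gyrus, orbitofrontal,
#' supramarginal, inferior precentral, posterior superior- and
#' middle-temporal gyri) plus `"others"` for electrodes outside them.
#'
#' @param include_others include the `"others"` catch-all label.
#' @return character vector of ROI labels.
#' @export
roi_labels <- function(include_others = TRUE) {
  labs <- c("posterior_MFG", "anterior_MFG", "posterior_IFG", "orbitofrontal",
            "supramarginal", "inferior_precentral", "posterior_STG",
            "posterior_MTG")
  if (include_others) c(labs, "others") else labs
}

#' Default electrode layout across ROIs
#'
#' Analyzable electrode counts (and contributing patient counts) per ROI and
#' hemisphere in the default simulated cohort: 626 left, 493 right, 1119
#' total, mirroring a typical multi-patient subdural sampling of the lateral
#' cortex.
#'
#' @return data.frame with columns `roi`, `hemisphere`, `n_electrodes`,
#'   `n_patients`.
#' @export
roi_layout_default <- function() {
  left  <- c(31, 38, 30, 22, 57, 27, 49, 24, 348)
  right <- c(18, 23, 20, 18, 34, 30, 26, 15, 309)
  pat_l <- c(4, 7, 7, 6, 10, 6, 9, 7, 14)
  pat_r <- c(4, 4, 5, 4, 8, 7, 6, 7, 12)
  data.frame(
    roi = rep(roi_labels(), 2L),
    hemisphere = rep(c("left", "right"), each = 9L),
    n_electrodes = c(left, right),
    n_patients = c(pat_l, pat_r),
    stringsAsFactors = FALSE
  )
}

#' Composite prefrontal ROI definitions
#'
#' Posterior prefrontal = posterior MFG plus posterior IFG; anterior
#' prefrontal = anterior MFG plus orbitofrontal (per hemisphere).
#'
#' @return named list mapping composite label to member ROI labels.
#' @export
roi_composites <- function() {
  list(
    posterior_prefrontal = c("posterior_MFG", "posterior_IFG"),
    anterior_prefrontal  = c("anterior_MFG", "orbitofrontal")
  )
}

electrode_statuses <- function() {
  c("analyzable", "excluded_soz", "excluded_spiking", "excluded_lesion",
    "excluded_artifact")
}

validate_electrodes <- function(electrodes) {
  req <- c("electrode_id", "patient_id", "hemisphere", "roi", "status")
  miss <- setdiff(req, names(electrodes))
  if (length(miss)) {
    stop_param("electrode table lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad_roi <- setdiff(unique(electrodes$roi), roi_labels())
  if (length(bad_roi)) {
    stop_param("unknown ROI label(s): ", paste(bad_roi, collapse = ", "))
  }
  bad_st <- setdiff(unique(electrodes$status), electrode_statuses())
  if (length(bad_st)) {
    stop_param("unknown electrode status(es): ", paste(bad_st, collapse = ", "))
  }
  if (anyDuplicated(electrodes$electrode_id)) {
    stop_param("duplicated electrode_id in electrode table")
  }
  invisible(electrodes)
}

#' Restrict an electrode table to analyzable sites
#'
#' Electrodes in the seizure-onset zone, interictal spiking zone, structural
#' lesions or with artifacts never enter any statistic.
#'
#' @param electrodes electrode data.frame.
#' @param quiet suppress the exclusion-count message.
#' @return the analyzable subset.
#' @export
analyzable <- function(electrodes, quiet = FALSE) {
  validate_electrodes(electrodes)
  keep <- electrodes$status == "analyzable"
  if (!quiet && any(!keep)) {
    message(sum(!keep), " electrode(s) excluded by status (",
            paste(names(table(electrodes$status[!keep])), collapse = ", "), ")")
  }
  electrodes[keep, , drop = FALSE]
}
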