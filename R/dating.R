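# Ks-to-age dating and cross-lineage synonymous-rate correction.

#' Date a Ks value with a synonymous substitution rate
#'
#' Under approximately clock-like synonymous accumulation, a pair separated
#' by Ks synonymous substitutions per site diverged `Ks / (2 r)` years ago
#' (each lineage contributes half the divergence). The default rate is the
#' *Ceratopteris thalictroides* estimate of 11.04e-9 synonymous
#' substitutions per site per year.
#'
#' @param ks Pairwise synonymous divergence (>= 0).
#' @param r Synonymous substitution rate per site per year.
#' @return A `dating_result` list: `ks`, `r`, `date_mya`.
#' @export
date_from_ks <- function(ks, r = 11.04e-9) {
  if (any(ks < 0)) stop("ks must be non-negative")
  if (any(r <= 0)) stop("rate r must be > 0")
  structure(list(ks = ks, r = r, date_mya = ks / (2 * r) / 1e6),
            class = "dating_result")
}

#' @export
print.dating_result <- function(x, ...) {
  cat(sprintf("Ks = %g at r = %g /site/year -> %.2f Mya\n",
              x$ks, x$r, x$date_mya))
  invisible(x)
}

#' Compare a dated event to a time window
#'
#' Windows are closed intervals in Mya; larger Mya means earlier in time,
#' so a date above `upper_mya + tol_mya` is `earlier_than` the window and a
#' date below `lower_mya - tol_mya` is `later_than`.
#'
#' @param result A [date_from_ks()] result (or a number in Mya).
#' @param lower_mya,upper_mya Window bounds (lower <= upper).
#' @param tol_mya Tolerance applied at both bounds.
#' @return `"earlier_than"`, `"within"` or `"later_than"`.
#' @export
compare_to_window <- function(result, lower_mya, upper_mya, tol_mya = 0) {
  date <- if (inherits(result, "dating_result")) result$date_mya else result
  if (lower_mya > upper_mya) stop("window bounds out of order")
  if (date > upper_mya + tol_mya) "earlier_than"
  else if (date < lower_mya - tol_mya) "later_than"
  else "within"
}

#' Lineage correction coefficient from two shared-event Ks peaks
#'
#' A WGD shared by two lineages shows a Ks peak in each; the ratio of the
#' reference lineage's peak to the other lineage's peak measures how much
#' slower (or faster) the other lineage accumulates synonymous
#' substitutions, and rescales its Ks values onto the reference scale.
#'
#' @param ks_ref_peak Shared-event peak Ks in the reference lineage.
#' @param ks_other_peak Shared-event peak Ks in the lineage to correct.
#' @return `ks_ref_peak / ks_other_peak`.
#' @export
correction_coefficient <- function(ks_ref_peak, ks_other_peak) {
  if (ks_ref_peak <= 0 || ks_other_peak <= 0)
    stop("peak Ks values must be > 0")
  ks_ref_peak / ks_other_peak
}

#' Build a cross-lineage rate-correction chain
#'
#' When the target lineage shares no datable event with the reference, a
#' bridge lineage sharing an event with the reference links them: the
#' bridge coefficient comes from the shared-event peaks, coefficients of
#' ortholog Ks distributions are arithmetic means of the two lineage
#' coefficients, and the target coefficient follows by aligning the
#' bridge-target ortholog peak to the corrected bridge-reference one. The
#' reference lineage's own coefficient is fixed at 1 (it defines the
#' scale).
#'
#' @param ks_ref_peak,ks_bridge_peak Shared-WGD peak Ks in the reference and
#'   bridge lineages.
#' @param ks_bridge_ref_ortho Peak Ks of the bridge-reference interspecific
#'   (ortholog) distribution.
#' @param ks_bridge_target_ortho Peak Ks of the bridge-target interspecific
#'   distribution.
#' @param reference,bridge,target Optional lineage labels.
#' @return A `correction_chain` with all coefficients:
#'   `C_bridge = ks_ref_peak / ks_bridge_peak`,
#'   `C_b_bridge_ref = (C_bridge + 1) / 2`,
#'   `ks_bridge_ref_corrected = C_b_bridge_ref * ks_bridge_ref_ortho`,
#'   `C_b_bridge_target = ks_bridge_ref_corrected / ks_bridge_target_ortho`,
#'   `C_target = 2 * C_b_bridge_target - C_bridge`.
#' @export
correction_chain <- function(ks_ref_peak, ks_bridge_peak,
                             ks_bridge_ref_ortho, ks_bridge_target_ortho,
                             reference = "reference", bridge = "bridge",
                             target = "target") {
  if (any(c(ks_ref_peak, ks_bridge_peak, ks_bridge_ref_ortho,
            ks_bridge_target_ortho) <= 0))
    stop("all chain peak Ks values must be > 0")
  C_bridge <- correction_coefficient(ks_ref_peak, ks_bridge_peak)
  C_b_bridge_ref <- (C_bridge + 1) / 2
  ks_prime_bridge_ref <- C_b_bridge_ref * ks_bridge_ref_ortho
  C_b_bridge_target <- ks_prime_bridge_ref / ks_bridge_target_ortho
  C_target <- 2 * C_b_bridge_target - C_bridge
  if (C_target <= 0)
    stop("inconsistent rate geometry: target coefficient is not positive")
  structure(list(reference = reference, bridge = bridge, target = target,
                 ks_ref_peak = ks_ref_peak, ks_bridge_peak = ks_bridge_peak,
                 ks_bridge_ref_ortho = ks_bridge_ref_ortho,
                 ks_bridge_target_ortho = ks_bridge_target_ortho,
                 C_reference = 1, C_bridge = C_bridge,
                 C_b_bridge_ref = C_b_bridge_ref,
                 ks_bridge_ref_corrected = ks_prime_bridge_ref,
                 C_b_bridge_target = C_b_bridge_target,
                 C_target = C_target),
            class = "correction_chain")
}

#' @export
print.correction_chain <- function(x, ...) {
  cat(sprintf("correction_chain %s -> %s -> %s\n", x$reference, x$bridge,
              x$target))
  cat(sprintf("  C_%s = %.4f (= %.4f / %.4f)\n", x$bridge, x$C_bridge,
              x$ks_ref_peak, x$ks_bridge_peak))
  cat(sprintf("  C_%s = %.4f\n", x$target, x$C_target))
  invisible(x)
}

#' Rescale target-lineage Ks values onto the reference rate scale
#'
#' @param chain A [correction_chain()].
#' @param ks_target_values Ks values measured in the target lineage.
#' @return Corrected Ks' values, `C_target * Ks`.
#' @export
correct_target_ks <- function(chain, ks_target_values) {
  stopifnot(inherits(chain, "correction_chain"))
  chain$C_target * ks_target_values
}
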