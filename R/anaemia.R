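#' Classify anaemia from haemoglobin concentration
#'
#' Applies the WHO grading for adult men: not anaemic if haemoglobin is at
#' least 13.0 g/dL, mild for 12.0-12.9, moderate for 9.0-11.9 and severe
#' below 9.0, with the binary flag 1 exactly when haemoglobin is below 13.0.
#' The boundary value 13.0 itself is assigned to "none" (non-anaemic); the
#' grading gap between 8.9 and 9.0 in the verbal rule is closed at 9.0
#' (values in [8.9, 9.0) are severe).
#'
#' @param hb numeric haemoglobin concentrations in g/dL; must be finite.
#'   Values outside the plausible 2-25 g/dL range trigger a warning.
#' @return data frame with columns `haemoglobin`, `severity` (ordered factor
#'   none < mild < moderate < severe) and `anaemic` (0/1).
#' @examples
#' classify_anaemia(c(14, 13, 12.95, 10, 8.95))
#' @export
classify_anaemia <- function(hb) {
  if (any(!is.finite(hb))) {
    stop("non-finite haemoglobin values", call. = FALSE)
  }
  if (any(hb < 2 | hb > 25)) {
    warning("haemoglobin values outside the plausible 2-25 g/dL range")
  }
  severity <- cut(hb, breaks = c(-Inf, 9, 12, 13, Inf), right = FALSE,
                  labels = c("severe", "moderate", "mild", "none"))
  severity <- factor(severity, levels = c("none", "mild", "moderate", "severe"),
                     ordered = TRUE)
  data.frame(haemoglobin = hb, severity = severity,
             anaemic = as.integer(hb < 13))
}
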