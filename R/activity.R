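# Activity class codes and the merged-group mapping.
#
# Ten activities are distinguished: slow/fast walking (WS, WF), slow/fast
# running (RS, RF), stairs up/down (SU, SD), jumping rope (JR), standing up
# (ST), sitting down (SI) and remaining still (NA).  Mutually confusable
# pairs merge into WX (walking), RX (running) and SX (stairs), yielding a
# seven-class grouping used for the merged evaluation.
#
# Note: the still class is literally coded "NA"; it is always handled as the
# character string "NA", never as R's missing value.

#' Canonical activity codes
#'
#' @return Character vector of the ten activity codes in canonical order:
#'   WS, WF, RS, RF, SU, SD, JR, ST, SI, NA.
#' @export
#' @examples
#' activity_codes()
activity_codes <- function() {
  c("WS", "WF", "RS", "RF", "SU", "SD", "JR", "ST", "SI", "NA")
}

#' Merged activity groups
#'
#' @return Character vector of the seven merged groups in canonical order:
#'   WX, RX, SX, JR, ST, SI, NA.
#' @export
merged_codes <- function() {
  c("WX", "RX", "SX", "JR", "ST", "SI", "NA")
}

#' Map activity codes onto merged groups
#'
#' The mapping is total and surjective: WS,WF -> WX; RS,RF -> RX;
#' SU,SD -> SX; JR, ST, SI and NA map to themselves.
#'
#' @param codes Character vector of activity codes (default: all ten).
#' @return Named character vector `merged group` with `codes` as names.
#' @export
#' @examples
#' merge_map(c("WS", "SD"))
merge_map <- function(codes = activity_codes()) {
  tab <- c(WS = "WX", WF = "WX", RS = "RX", RF = "RX",
           SU = "SX", SD = "SX", JR = "JR", ST = "ST",
           SI = "SI", `NA` = "NA")
  bad <- setdiff(codes, names(tab))
  if (length(bad)) {
    stop_harcnn("harcnn_bad_class", "unknown activity code(s): %s",
                paste(bad, collapse = ", "))
  }
  out <- tab[codes]
  names(out) <- codes
  out
}

assert_activity_code <- function(code) {
  if (!(is.character(code) && length(code) == 1L &&
        code %in% activity_codes())) {
    stop_harcnn("harcnn_bad_class",
                "'%s' is not one of the ten activity codes",
                paste(format(code), collapse = ","))
  }
  invisible(code)
}
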