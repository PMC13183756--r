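#' Speaker classes
#'
#' The four voice types used throughout the package, in their fixed matrix
#' order: the key child wearing the device (`CHI`), other children (`OCH`),
#' female adults (`FEM`) and male adults (`MAL`). All 4x4 confusion matrices
#' index sources (true speakers) by row and targets (attributed speakers) by
#' column in this order.
#'
#' @return Character vector `c("CHI", "OCH", "FEM", "MAL")`.
#' @export
#' @examples
#' speaker_classes()
speaker_classes <- function() c("CHI", "OCH", "FEM", "MAL")

# internal: validate and order a length-4 count vector
as_count4 <- function(x, what = "counts") {
  if (!is.null(names(x)) && all(speaker_classes() %in% names(x))) {
    x <- x[speaker_classes()]
  }
  if (length(x) != 4L) stop(what, " must have length 4 (CHI, OCH, FEM, MAL)")
  if (anyNA(x)) stop(what, " must not contain NA")
  x <- unname(x)
  if (any(x < 0)) stop(what, " must be non-negative")
  x
}

as_int_count4 <- function(x, what = "counts") {
  x <- as_count4(x, what)
  if (any(abs(x - round(x)) > 1e-8)) stop(what, " must be integer-valued")
  as.integer(round(x))
}
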