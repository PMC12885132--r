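# Spline bases used for covariate adjustment.

#' Spline basis construction
#'
#' Natural cubic splines (`kind = "natural_cubic"`) place interior knots at
#' quantiles and boundary knots at the data range (via [splines::ns()]);
#' thin-plate regression splines (`kind = "thin_plate_2d"`) build the
#' r^2 log r radial kernel on the 2-d coordinates and reduce it to `df`
#' columns by eigendecomposition with absorbed centring constraints (via
#' [mgcv::smoothCon()]). Both bases contain the linear functions of their
#' inputs, so a linear trend is exactly representable, and the thin-plate
#' basis fit is invariant to coordinate translation.
#'
#' @param values numeric vector (natural cubic) or 2-column matrix /
#'   data.frame of coordinates (thin plate).
#' @param df number of basis columns to return (`>= 1`).
#' @param kind `"natural_cubic"` or `"thin_plate_2d"`.
#' @return numeric matrix with `df` columns and `prediction` attribute-free
#'   deterministic content given the data.
#' @export
spline_basis <- function(values, df, kind = c("natural_cubic",
                                              "thin_plate_2d")) {
  kind <- match.arg(kind)
  df <- assert_scalar_count(df, "df")
  if (kind == "natural_cubic") {
    v <- as.numeric(values)
    if (length(unique(v[!is.na(v)])) <= df)
      stopf("df = %d exceeds the number of distinct values", df)
    b <- splines::ns(v, df = df)
    colnames(b) <- paste0("ns", seq_len(df))
    return(unclass(b)[, , drop = FALSE])
  }
  xy <- as.matrix(values)
  if (ncol(xy) != 2L) stopf("thin-plate basis needs 2-d coordinates")
  if (nrow(unique(xy)) <= df)
    stopf("df = %d exceeds the number of distinct locations", df)
  dat <- data.frame(x_ = xy[, 1], y_ = xy[, 2])
  sm <- mgcv::smoothCon(mgcv::s(x_, y_, bs = "tp", k = df + 1L),
                        data = dat, absorb.cons = TRUE)[[1]]
  b <- sm$X
  colnames(b) <- paste0("tp", seq_len(ncol(b)))
  b
}
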