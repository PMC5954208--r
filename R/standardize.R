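#' Standardize variety features for clustering
#'
#' Centers and scales the feature columns of a profile table so the four
#' variety dimensions contribute comparably to squared-distance clustering.
#' `"zscore"` (the clustering default) subtracts the column mean and divides
#' by the sample SD; `"minmax"` maps the column range to `[0, 1]` (the
#' display convention for cross-team feature bars). Transform parameters are
#' attached so the mapping can be inverted with [unstandardize_features()].
#'
#' @param profiles A tibble from [variety_profiles()], or any data
#'   frame/matrix containing the feature columns.
#' @param method `"zscore"` or `"minmax"`.
#' @param features Character vector of feature columns (default the four
#'   variety dimensions).
#' @return A numeric matrix (rows named by `session_id` when available) with
#'   attributes `center`, `scale` and `method`.
#' @export
standardize_features <- function(profiles, method = c("zscore", "minmax"),
                                 features = c("shape_variety",
                                              "direction_variety",
                                              "length_variety", "n_bouts")) {
  method <- match.arg(method)
  if (is.matrix(profiles)) profiles <- as.data.frame(profiles)
  missing_cols <- setdiff(features, names(profiles))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "varietywalk_format_error")
  }
  X <- as.matrix(as.data.frame(profiles)[features])
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) {
    abort("need at least 2 profiles to standardize",
          class = "varietywalk_validation_error")
  }
  if (anyNA(X)) {
    abort("undefined (NA) feature values among clustered features; drop or impute first",
          class = "varietywalk_validation_error")
  }
  if ("session_id" %in% names(profiles)) {
    rownames(X) <- profiles[["session_id"]]
  }
  if (method == "zscore") {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
  } else {
    center <- apply(X, 2L, min)
    scale <- apply(X, 2L, max) - center
  }
  zero <- scale <= 0
  if (any(zero)) {
    warn(paste0("zero-variance feature(s) left centered at 0: ",
                paste(features[zero], collapse = ", ")))
    scale[zero] <- 1
  }
  out <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  structure(out, center = center, scale = scale, method = method)
}

#' Invert a feature standardization
#'
#' @param X A matrix returned by [standardize_features()] (the `center` and
#'   `scale` attributes are required).
#' @return The matrix on the original feature scale.
#' @export
unstandardize_features <- function(X) {
  center <- attr(X, "center")
  scale <- attr(X, "scale")
  if (is.null(center) || is.null(scale)) {
    abort("X lacks center/scale attributes; not a standardized matrix",
          class = "varietywalk_format_error")
  }
  out <- sweep(sweep(X, 2L, scale, "*"), 2L, center, "+")
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  attr(out, "method") <- NULL
  out
}
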