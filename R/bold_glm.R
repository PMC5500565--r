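#' 4-D BOLD volume container
#'
#' @param data Numeric array x * y * z * volumes.
#' @param TR Repetition time in seconds.
#' @param mask Optional logical 3-D array of in-brain voxels (default all).
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, TR, mask = NULL) {
  stopifnot(length(dim(data)) == 4, TR > 0)
  d <- dim(data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  stopifnot(identical(dim(mask), d[1:3]))
  if (anyNA(data[rep(mask, d[4])])) stop("non-finite data inside mask")
  structure(list(data = data, TR = TR, mask = mask),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat("Volume series:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "volumes, TR =", x$TR, "s,", sum(x$mask), "in mask\n")
  invisible(x)
}

#' Read/write a volume series in NIfTI format
#'
#' @param vs A `volume_series`.
#' @param path File path (`.nii` / `.nii.gz`).
#' @return `read_volume_series()` returns a `volume_series` (mask all
#'   TRUE).
#' @export
write_volume_series <- function(vs, path) {
  RNifti::writeNifti(RNifti::asNifti(vs$data, pixdim = c(1, 1, 1, vs$TR)),
                     path)
  invisible(path)
}

#' @rdname write_volume_series
#' @export
read_volume_series <- function(path) {
  img <- RNifti::readNifti(path)
  TR <- RNifti::pixdim(img)[4]
  if (!is.finite(TR) || TR <= 0) TR <- 1
  volume_series(array(as.numeric(img), dim = dim(img)), TR)
}

#' Voxelwise ordinary-least-squares GLM
#'
#' Fits Y = X beta + e independently in every masked voxel and converts
#' each regressor's t statistic to a Z score through the normal quantile
#' of the t cumulative distribution.  Noise is assumed white (the
#' synthetic generator's default); no autocorrelation correction is
#' applied.
#'
#' @param Y A [volume_series()].
#' @param X A [build_design()] result (or numeric matrix).
#' @return An object of class `bold_glm`: `beta` and `z` (voxels x
#'   regressors, masked voxels only), `residual_df`, `mask`, `dim`,
#'   `names`.
#' @seealso [beta_map()], [z_map()], [group_level()]
#' @export
bold_glm <- function(Y, X) {
  Xm <- if (inherits(X, "design_matrix")) X$X else as.matrix(X)
  d <- dim(Y$data)
  if (nrow(Xm) != d[4])
    stop("design has ", nrow(Xm), " rows but data has ", d[4], " volumes")
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qrX$pivot[(qrX$rank + 1):ncol(Xm)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  vox <- which(Y$mask)
  Ymat <- t(matrix(Y$data, prod(d[1:3]), d[4])[vox, , drop = FALSE])
  beta <- qr.coef(qrX, Ymat)                      # regressors x voxels
  res <- Ymat - Xm %*% beta
  df <- d[4] - ncol(Xm)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot),
                                drop = FALSE]
  se <- sqrt(outer(diag(XtXinv), sigma2))
  tstat <- beta / se
  z <- t_to_z(tstat, df)
  structure(list(beta = t(beta), z = t(z), residual_df = df,
                 mask = Y$mask, dim = d[1:3], names = colnames(Xm),
                 voxels = vox),
            class = "bold_glm")
}

# Numerically stable t -> Z conversion (per tail).
t_to_z <- function(tstat, df) {
  tstat[is.nan(tstat)] <- 0            # 0/0: zero effect with zero residual
  z <- tstat
  neg <- tstat <= 0
  z[neg] <- stats::qnorm(stats::pt(tstat[neg], df, log.p = TRUE),
                         log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(-tstat[!neg], df, log.p = TRUE),
                           log.p = TRUE)
  z
}

#' @export
print.bold_glm <- function(x, ...) {
  cat("Voxelwise GLM:", length(x$voxels), "voxels x", length(x$names),
      "regressors, df =", x$residual_df, "\n")
  invisible(x)
}

#' @export
coef.bold_glm <- function(object, ...) object$beta

#' Rebuild a whole-brain map from a fitted GLM
#'
#' @param fit A `bold_glm`.
#' @param regressor Regressor name or index.
#' @return 3-D array (NA outside the mask) of per-voxel beta (or Z)
#'   values.
#' @export
beta_map <- function(fit, regressor) {
  j <- if (is.character(regressor)) match(regressor, fit$names) else regressor
  if (is.na(j)) stop("unknown regressor: ", regressor)
  out <- array(NA_real_, fit$dim)
  out[fit$voxels] <- fit$beta[, j]
  out
}

#' @rdname beta_map
#' @export
z_map <- function(fit, regressor) {
  j <- if (is.character(regressor)) match(regressor, fit$names) else regressor
  if (is.na(j)) stop("unknown regressor: ", regressor)
  out <- array(NA_real_, fit$dim)
  out[fit$voxels] <- fit$z[, j]
  out
}

#' Group-level one-sample Z map
#'
#' Combines per-subject beta maps with a one-sample t test across subjects
#' at every voxel, converting t to Z.  This is a deliberately simple
#' random-effects group model: subjects are the only random factor and
#' within-subject variance is not propagated.
#'
#' @param subject_betas List (length >= 2) of identically shaped 3-D
#'   arrays.
#' @return 3-D array of Z values (NA where any subject is NA).
#' @export
group_level <- function(subject_betas) {
  if (length(subject_betas) < 2)
    stop("group level requires at least 2 subjects")
  d <- dim(subject_betas[[1]])
  stopifnot(all(vapply(subject_betas, function(b) identical(dim(b), d),
                       logical(1))))
  B <- vapply(subject_betas, as.numeric,
              numeric(prod(d)))                    # voxels x subjects
  n <- ncol(B)
  m <- rowMeans(B)
  s <- sqrt(rowSums((B - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  z <- t_to_z(matrix(tstat, ncol = 1), n - 1)
  array(z, d)
}
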