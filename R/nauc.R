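#' Mean HU of tumor and normal pancreas per phase
#'
#' Samples the raw (not NC-subtracted) Hounsfield values of the tumor (HUm)
#' and the normal-parenchyma reference (HUp) on each of the three phases,
#' as whole-mask means. These are the six quantities entering the nAUC
#' ratio, which performs its own NC subtraction.
#'
#' @param study a [registered_study()].
#' @param masks a [mask_set()]; the tumor and `npp` masks are used.
#' @return Object of class `sampled_hu` with elements `hum_nc`, `hum_ar`,
#'   `hum_pv` (tumor) and `hup_nc`, `hup_ar`, `hup_pv` (parenchyma).
#' @export
sample_hu <- function(study, masks) {
  if (!inherits(study, "registered_study") || !inherits(masks, "mask_set")) {
    stop("`study`/`masks` must be registered_study / mask_set", call. = FALSE)
  }
  if (!identical(dim(masks$tumor), dim(study$nc))) {
    stop("masks do not match the study grid (alignment error)", call. = FALSE)
  }
  if (sum(masks$tumor) == 0 || sum(masks$npp) == 0) {
    stop("tumor and NPP masks must be non-empty", call. = FALSE)
  }
  structure(list(
    hum_nc = mean(study$nc[masks$tumor]),
    hum_ar = mean(study$ar[masks$tumor]),
    hum_pv = mean(study$pv[masks$tumor]),
    hup_nc = mean(study$nc[masks$npp]),
    hup_ar = mean(study$ar[masks$npp]),
    hup_pv = mean(study$pv[masks$npp])
  ), class = "sampled_hu")
}

#' Normalized area under the enhancement curve (nAUC)
#'
#' The tumor-to-parenchyma ratio of time-weighted enhancement,
#' \deqn{\mathrm{nAUC} = \frac{5\,\Delta m_{AR} + 35(\Delta m_{AR} +
#'   \Delta m_{PV})}{5\,\Delta p_{AR} + 35(\Delta p_{AR} + \Delta p_{PV})}}
#' where \eqn{\Delta m} and \eqn{\Delta p} are the NC-subtracted mean HU of
#' tumor and parenchyma at the AR and PV phases. The weights 5 and 35 are
#' fixed acquisition-timing constants. The ratio summarizes the tumor's mass
#' transport relative to normal pancreas: 1 means tumor and parenchyma
#' enhance identically.
#'
#' @param s a `sampled_hu` from [sample_hu()], or a named list carrying the
#'   six `hum_*`/`hup_*` means.
#' @return the nAUC ratio (dimensionless).
#' @export
compute_nauc <- function(s) {
  need <- c("hum_nc", "hum_ar", "hum_pv", "hup_nc", "hup_ar", "hup_pv")
  if (!all(need %in% names(s))) {
    stop("`s` must carry ", paste(need, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(s[need])
  if (!all(is.finite(vals))) stop("HU means must be finite", call. = FALSE)
  dm_ar <- s$hum_ar - s$hum_nc
  dm_pv <- s$hum_pv - s$hum_nc
  dp_ar <- s$hup_ar - s$hup_nc
  dp_pv <- s$hup_pv - s$hup_nc
  den <- 5 * dp_ar + 35 * (dp_ar + dp_pv)
  if (den <= 0) {
    stop("parenchyma enhancement denominator is not positive ",
         "(degenerate-parenchyma error)", call. = FALSE)
  }
  (5 * dm_ar + 35 * (dm_ar + dm_pv)) / den
}
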