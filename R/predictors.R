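#' Reference statistics for the landscape heterogeneity index
#'
#' The landscape heterogeneity index (LHI) standardizes two landscape
#' variables -- the square root of the proportion seminatural pasture and the
#' proportion field border -- against a *representative* set of
#' non-overlapping landscapes covering the study region, rather than against
#' the (design-biased) study landscapes themselves. This constructor computes
#' the required means and standard deviations from such a representative
#' table.
#'
#' @param pasture_prop numeric vector of seminatural-pasture proportions of
#'   farmland, one per representative landscape, in `[0, 1]`. The square-root
#'   transform is applied internally before the moments are taken.
#' @param border_prop numeric vector of field-border proportions of farmland
#'   (field borders are taken as 1 m wide, so border length in m equals
#'   border area in m^2).
#' @return An object of class `"reference_stats"`: a list with elements
#'   `mean_sqrt_pasture`, `sd_sqrt_pasture`, `mean_border`, `sd_border`.
#' @seealso [compute_lhi()]
#' @export
reference_stats <- function(pasture_prop, border_prop) {
  stopifnot(is.numeric(pasture_prop), is.numeric(border_prop),
            length(pasture_prop) == length(border_prop))
  if (any(pasture_prop < 0 | pasture_prop > 1, na.rm = TRUE))
    stop("pasture_prop must lie in [0, 1]")
  sp <- sqrt(pasture_prop)
  out <- list(
    mean_sqrt_pasture = mean(sp),
    sd_sqrt_pasture   = stats::sd(sp),
    mean_border       = mean(border_prop),
    sd_border         = stats::sd(border_prop)
  )
  if (!is.finite(out$sd_sqrt_pasture) || out$sd_sqrt_pasture <= 0 ||
      !is.finite(out$sd_border) || out$sd_border <= 0)
    stop("invalid reference set: zero or non-finite standard deviation")
  class(out) <- "reference_stats"
  out
}

#' Landscape heterogeneity index (LHI)
#'
#' Combines the proportion of seminatural pasture (square-root transformed)
#' and the proportion of field border in a landscape into a single score on
#' the scale of the first principal component of the two standardized
#' variables:
#' \deqn{LHI = \frac{\sqrt{2}}{2}\left( z_{\sqrt{pasture}} + z_{border}
#' \right)}
#' where each z-score uses the mean and standard deviation of the
#' representative landscape set ([reference_stats()]). For two standardized
#' variables with equal loadings this is exactly the PC1 projection.
#'
#' @param pasture_prop proportion seminatural pasture of farmland, in
#'   `[0, 1]` (untransformed; the square root is applied here).
#' @param border_prop proportion field border of farmland.
#' @param ref a [reference_stats()] object.
#' @return Numeric vector of LHI scores (unitless).
#' @export
compute_lhi <- function(pasture_prop, border_prop, ref) {
  if (!inherits(ref, "reference_stats"))
    stop("ref must be a reference_stats object")
  if (ref$sd_sqrt_pasture <= 0 || ref$sd_border <= 0)
    stop("invalid reference: standard deviations must be positive")
  zp <- (sqrt(pasture_prop) - ref$mean_sqrt_pasture) / ref$sd_sqrt_pasture
  zb <- (border_prop - ref$mean_border) / ref$sd_border
  (sqrt(2) / 2) * (zp + zb)
}

#' Proportion extensive cropping (PE)
#'
#' The proportion of the summed area of ley and fallow on the total arable
#' (tillable) land area of the landscape, i.e. excluding permanent
#' seminatural grassland. Measures how much of the crop rotation is under
#' extensive (low-input, low-disturbance) use.
#'
#' @param ley_area,fallow_area,arable_area areas in hectares; `arable_area`
#'   must be positive.
#' @return PE in `[0, 1]`.
#' @export
proportion_extensive <- function(ley_area, fallow_area, arable_area) {
  check_nonneg(ley_area, fallow_area, arable_area)
  if (any(arable_area == 0))
    stop("undefined predictor: arable_area is zero")
  if (any(ley_area + fallow_area > arable_area + 1e-9))
    stop("ley_area + fallow_area exceeds arable_area")
  (ley_area + fallow_area) / arable_area
}

#' Extensive quality (EQ)
#'
#' Among the extensive land uses (fallow plus all ley), the share made up of
#' the higher-quality classes (fallow plus non-managed ley), square-root
#' transformed to even out its distribution:
#' \deqn{EQ = \sqrt{\frac{fallow + nonmanaged\ ley}{fallow + all\ ley}}}
#' Landscapes with no extensive land at all have an undefined ratio; these
#' receive the `undefined` value (default 0) with a warning, so that the
#' handling is explicit and reproducible.
#'
#' @param fallow_area,ley_area,nonmanaged_ley_area areas in hectares;
#'   `nonmanaged_ley_area` must not exceed `ley_area`.
#' @param undefined value imputed where `fallow_area + ley_area == 0`.
#' @return EQ in `[0, 1]`.
#' @export
extensive_quality <- function(fallow_area, ley_area, nonmanaged_ley_area,
                              undefined = 0) {
  check_nonneg(fallow_area, ley_area, nonmanaged_ley_area)
  if (any(nonmanaged_ley_area > ley_area + 1e-9))
    stop("nonmanaged_ley_area exceeds ley_area")
  denom <- fallow_area + ley_area
  out <- rep(NA_real_, length(denom))
  ok <- denom > 0
  out[ok] <- sqrt((fallow_area[ok] + nonmanaged_ley_area[ok]) / denom[ok])
  if (any(!ok)) {
    warning(sum(!ok), " landscape(s) with no extensive land; EQ set to ",
            undefined)
    out[!ok] <- undefined
  }
  out
}

#' Crop diversity (CD)
#'
#' Shannon diversity of the 13 structural crop types, expressed as a Hill
#' number of order 1 (the *effective number of crop types*):
#' \deqn{CD = \exp\left(-\sum_t p_t \ln p_t\right)}
#' with \eqn{p_t} the area share of crop type t and \eqn{0 \ln 0 := 0}.
#' CD is 1 when a single type dominates completely and equals the number of
#' types when all have equal area.
#'
#' @param crop_type_areas numeric vector (or matrix with one row per
#'   landscape) of nonnegative areas per structural crop type.
#' @return CD in `[1, n_types]`.
#' @export
crop_diversity <- function(crop_type_areas) {
  if (is.matrix(crop_type_areas) || is.data.frame(crop_type_areas))
    return(apply(as.matrix(crop_type_areas), 1, crop_diversity))
  if (any(crop_type_areas < 0)) stop("crop areas must be nonnegative")
  tot <- sum(crop_type_areas)
  if (tot == 0) stop("undefined predictor: all crop areas are zero")
  p <- crop_type_areas / tot
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

#' Proportion spring-sown crops (PSS)
#'
#' The proportion of the cereal and oil-seed rape area that was spring sown
#' (as opposed to autumn sown).
#'
#' @param spring_cereal_osr_area,total_cereal_osr_area areas in hectares;
#'   the total must be positive and at least the spring-sown part.
#' @return PSS in `[0, 1]`.
#' @export
proportion_spring_sown <- function(spring_cereal_osr_area,
                                   total_cereal_osr_area) {
  check_nonneg(spring_cereal_osr_area, total_cereal_osr_area)
  if (any(total_cereal_osr_area == 0))
    stop("undefined predictor: total cereal + oil-seed rape area is zero")
  if (any(spring_cereal_osr_area > total_cereal_osr_area + 1e-9))
    stop("spring-sown area exceeds total cereal + oil-seed rape area")
  spring_cereal_osr_area / total_cereal_osr_area
}

#' Expected ley proportion from the three previous years
#'
#' Ley rotates between years, so the expected amount of ley in a landscape
#' is estimated as the mean of the ley proportions (of farmland area) in the
#' three previous years. Used at the design stage when selecting landscapes;
#' the fitted model uses current-year values.
#'
#' @param ley_area_prev3 numeric vector of length 3 (one landscape) or a
#'   3-column matrix (one row per landscape) of ley areas, hectares.
#' @param farmland_area farmland area in hectares, positive.
#' @return Mean ley proportion.
#' @export
mean_ley_3yr <- function(ley_area_prev3, farmland_area) {
  if (is.matrix(ley_area_prev3)) {
    if (ncol(ley_area_prev3) != 3)
      stop("ley_area_prev3 must have exactly 3 yearly values")
    stopifnot(length(farmland_area) == nrow(ley_area_prev3))
    if (any(farmland_area <= 0)) stop("farmland_area must be positive")
    return(rowMeans(ley_area_prev3) / farmland_area)
  }
  if (length(ley_area_prev3) != 3)
    stop("ley_area_prev3 must have exactly 3 yearly values")
  if (farmland_area <= 0) stop("farmland_area must be positive")
  mean(ley_area_prev3) / farmland_area
}

#' Variance inflation factors
#'
#' Collinearity diagnostic for a table of predictors:
#' \deqn{VIF_k = 1 / (1 - R^2_k)} where \eqn{R^2_k} is the coefficient of
#' determination from regressing predictor k on all the others.
#'
#' @param predictors data.frame or matrix of numeric predictors, more rows
#'   than columns, at least two columns.
#' @return Named numeric vector of VIFs. Perfectly collinear predictors give
#'   `Inf` with a warning.
#' @export
variance_inflation <- function(predictors) {
  x <- as.matrix(predictors)
  if (ncol(x) < 2) stop("need at least 2 predictors")
  if (nrow(x) <= ncol(x)) stop("need more rows than predictors")
  if (anyNA(x)) stop("predictors contain missing values")
  vif <- vapply(seq_len(ncol(x)), function(k) {
    fit <- stats::lm.fit(cbind(1, x[, -k, drop = FALSE]), x[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, k] - mean(x[, k]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(x)
  if (any(is.infinite(vif)))
    warning("perfect collinearity detected: infinite VIF for ",
            paste(names(vif)[is.infinite(vif)], collapse = ", "))
  vif
}

#' Build the landscape-predictor table from raw land-use areas
#'
#' Computes the six model predictors -- farmland area (FA), landscape
#' heterogeneity index (LHI), proportion extensive cropping (PE), extensive
#' quality (EQ), crop diversity (CD) and proportion spring-sown crops (PSS)
#' -- for every landscape in a raw land-use table, together with
#' within-dataset standardized versions (columns suffixed `_std`).
#'
#' @param raw data.frame with one row per landscape and columns `site_id`,
#'   `farmland_area`, `pasture_prop`, `border_prop`, `ley_area`,
#'   `fallow_area`, `nonmanaged_ley_area`, `arable_area`,
#'   `spring_cereal_osr_area`, `total_cereal_osr_area` and 13 crop-type area
#'   columns `crop01` .. `crop13` (hectares; see [crop_type_legend()]).
#' @param ref a [reference_stats()] object for the LHI standardization.
#' @param eq_undefined imputation for EQ where a landscape has no extensive
#'   land (see [extensive_quality()]).
#' @return data.frame of class `"landscape_predictors"` with columns
#'   `site_id`, `FA`, `LHI`, `PE`, `EQ`, `CD`, `PSS` and their `_std`
#'   z-scored counterparts.
#' @export
landscape_predictors <- function(raw, ref, eq_undefined = 0) {
  req <- c("site_id", "farmland_area", "pasture_prop", "border_prop",
           "ley_area", "fallow_area", "nonmanaged_ley_area", "arable_area",
           "spring_cereal_osr_area", "total_cereal_osr_area",
           sprintf("crop%02d", 1:13))
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("raw landscape table lacks columns: ", paste(miss, collapse = ", "))
  crops <- as.matrix(raw[sprintf("crop%02d", 1:13)])
  out <- data.frame(
    site_id = raw$site_id,
    FA  = raw$farmland_area,
    LHI = compute_lhi(raw$pasture_prop, raw$border_prop, ref),
    PE  = proportion_extensive(raw$ley_area, raw$fallow_area,
                               raw$arable_area),
    EQ  = extensive_quality(raw$fallow_area, raw$ley_area,
                            raw$nonmanaged_ley_area, undefined = eq_undefined),
    CD  = crop_diversity(crops),
    PSS = proportion_spring_sown(raw$spring_cereal_osr_area,
                                 raw$total_cereal_osr_area)
  )
  for (v in c("FA", "LHI", "PE", "EQ", "CD", "PSS")) {
    s <- stats::sd(out[[v]])
    out[[paste0(v, "_std")]] <-
      if (s > 0) (out[[v]] - mean(out[[v]])) / s else 0 * out[[v]]
  }
  class(out) <- c("landscape_predictors", "data.frame")
  out
}

#' Structural crop-type legend
#'
#' The 13 structural crop types over which crop diversity is computed. Crops
#' are grouped by structure and phenology as relevant to birds (e.g.
#' spring-sown vs autumn-sown cereals are distinct types). The legend here is
#' a user-editable default; a mapping from national land-use register codes
#' to these types must be supplied by the user for real data.
#'
#' @return data.frame with columns `code` (`crop01` .. `crop13`) and `label`.
#' @export
crop_type_legend <- function() {
  data.frame(
    code = sprintf("crop%02d", 1:13),
    label = c("spring-sown cereal", "autumn-sown cereal",
              "spring-sown oil-seed rape", "autumn-sown oil-seed rape",
              "ley (managed)", "ley (non-managed)", "fallow",
              "sugar beet", "potato", "legumes", "maize",
              "vegetables/horticulture", "other arable crops")
  )
}

# shared nonnegativity check
check_nonneg <- function(...) {
  args <- list(...)
  nm <- as.character(substitute(list(...)))[-1]
  for (i in seq_along(args))
    if (any(args[[i]] < 0, na.rm = TRUE))
      stop(nm[i], " must be nonnegative")
  invisible(TRUE)
}

#' Write/read landscape-predictor tables
#'
#' Plain-CSV I/O for predictor tables and VIF reports.
#'
#' @param x object to write.
#' @param path file path.
#' @name predictor_io
#' @export
write_predictors <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname predictor_io
#' @export
read_predictors <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("landscape_predictors", "data.frame")
  out
}
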