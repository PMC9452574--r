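#' Registry of the 93 radiomic features
#'
#' The feature set covered by [extract_features()]: 18 first-order
#' (histogram) statistics and five texture-matrix families computed from
#' the grey-level co-occurrence (GLCM, 24), dependence (GLDM, 14),
#' run-length (GLRLM, 16), size-zone (GLSZM, 16) and neighbouring
#' grey-tone difference (NGTDM, 5) matrices. Shape features are out of
#' scope: the analysis assumes one delineation per tumour, so shape
#' carries no condition-level variance.
#'
#' @return A data frame with columns `category`, `feature` (short name
#'   within the category) and `name` (unique `category_feature` id), in
#'   fixed registry order.
#' @examples
#' nrow(feature_registry())  # 93
#' table(feature_registry()$category)
#' @export
feature_registry <- function() {
  fam <- list(
    firstorder = c(
      "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
      "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
      "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
      "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"),
    glcm = c(
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
      "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
      "JointEnergy", "JointEntropy", "MaximumProbability", "MCC",
      "SumAverage", "SumEntropy", "SumSquares"),
    gldm = c(
      "DependenceEntropy", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "DependenceVariance",
      "GrayLevelNonUniformity", "GrayLevelVariance",
      "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
      "LargeDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
      "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
      "SmallDependenceLowGrayLevelEmphasis"),
    glrlm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
      "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
      "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
      "ShortRunLowGrayLevelEmphasis"),
    glszm = c(
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
      "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "ZoneEntropy", "ZonePercentage", "ZoneVariance"),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  )
  data.frame(
    category = rep(names(fam), lengths(fam)),
    feature = unlist(fam, use.names = FALSE),
    name = paste(rep(names(fam), lengths(fam)),
                 unlist(fam, use.names = FALSE), sep = "_"),
    stringsAsFactors = FALSE
  )
}

#' @rdname feature_registry
#' @export
feature_names <- function() feature_registry()$name
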