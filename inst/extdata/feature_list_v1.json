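{
  "version": "1.0",
  "total": 105,
  "note": "dropped GLCM SumAverage (redundant with JointAverage) and MCC",
  "features": {
    "FirstOrder": ["Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10", "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange", "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"],
    "GLCM": ["Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade", "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "InverseVariance", "JointEnergy", "JointEntropy", "MaximumProbability", "SumEntropy", "SumSquares", "Imc1", "Imc2"],
    "GLDM": ["SmallDependenceEmphasis", "LargeDependenceEmphasis", "GrayLevelNonUniformity", "DependenceNonUniformity", "DependenceNonUniformityNormalized", "GrayLevelVariance", "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis", "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis", "SmallDependenceHighGrayLevelEmphasis", "LargeDependenceLowGrayLevelEmphasis", "LargeDependenceHighGrayLevelEmphasis"],
    "GLRLM": ["ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity", "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance", "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"],
    "GLSZM": ["SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance", "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"],
    "NGTDM": ["Coarseness", "Contrast", "Busyness", "Complexity", "Strength"],
    "Shape": ["VoxelVolume", "VoxelCount", "SurfaceArea", "SurfaceVolumeRatio", "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice", "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness"]
  }
}
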