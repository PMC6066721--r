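#' @export
setGeneric("mixingWeight", function(x) standardGeneric("mixingWeight"))
#' @export
setGeneric("gammaShape", function(x) standardGeneric("gammaShape"))
#' @export
setGeneric("gammaScale", function(x) standardGeneric("gammaScale"))
#' @export
setGeneric("wallDistance", function(x) standardGeneric("wallDistance"))
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @export
setGeneric("relFreq", function(x) standardGeneric("relFreq"))
#' @export
setGeneric("binBreaks", function(x) standardGeneric("binBreaks"))
#' @export
setGeneric("binMidpoints", function(x) standardGeneric("binMidpoints"))
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @export
setGeneric("reliability", function(x) standardGeneric("reliability"))
#' @export
setGeneric("patternPoints", function(x) standardGeneric("patternPoints"))
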